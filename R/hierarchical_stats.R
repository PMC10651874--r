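#' Hierarchical bootstrap for nested (animals then neurons) data
#'
#' Respects the nesting of neurons within animals when comparing two
#' group means. Each replicate resamples animals with replacement (same
#' number as observed), then within every drawn animal resamples its
#' values with replacement (that animal's own count), pools the values
#' and takes the mean. Replicates of the two groups are paired by index
#' and the p value is the proportion of replicate pairs whose mean
#' difference is zero or opposite in sign to the observed group
#' difference. The p value is directional with respect to the observed
#' difference, so its null distribution is uniform on (0, 0.5].
#'
#' @param values_a,values_b numeric outcomes per unit.
#' @param animals_a,animals_b animal identifier per unit.
#' @param n_reps bootstrap replicates (p has resolution `1/n_reps`).
#' @param seed optional RNG seed.
#' @return list of class `ss_bootstrap`: `p`, `n_reps`,
#'   `observed_difference` (`mean(values_a) - mean(values_b)`),
#'   `boot_means_a`, `boot_means_b`, `flagged_single_animal`.
#' @export
hierarchical_bootstrap <- function(values_a, animals_a, values_b, animals_b,
                                   n_reps = 1000, seed = NULL) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must contain at least one value", call. = FALSE)
  }
  stopifnot(length(values_a) == length(animals_a),
            length(values_b) == length(animals_b), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)

  boot_group <- function(values, animals) {
    by_animal <- split(values, animals)
    n_an <- length(by_animal)
    sizes <- lengths(by_animal)
    offsets <- cumsum(c(0, sizes[-n_an]))
    flat <- unlist(by_animal, use.names = FALSE)
    means <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      an <- sample.int(n_an, n_an, replace = TRUE)
      cnt <- sizes[an]
      draws <- floor(stats::runif(sum(cnt)) * rep(cnt, cnt)) +
        rep(offsets[an], cnt) + 1L
      means[r] <- mean(flat[draws])
    }
    list(means = means, n_animals = n_an)
  }

  single <- length(unique(animals_a)) < 2 || length(unique(animals_b)) < 2
  if (single) {
    warning("a group has a single animal; hierarchical p is unreliable")
  }
  ba <- boot_group(values_a, animals_a)
  bb <- boot_group(values_b, animals_b)
  d_obs <- mean(values_a) - mean(values_b)
  d_rep <- ba$means - bb$means
  p <- mean(d_rep * sign(d_obs) <= 0)
  structure(list(p = p, n_reps = as.integer(n_reps),
                 observed_difference = d_obs,
                 boot_means_a = ba$means, boot_means_b = bb$means,
                 flagged_single_animal = single),
            class = "ss_bootstrap")
}

#' Standard two-sided tests used throughout the pipeline
#'
#' Thin wrappers around the stock implementations, collected so every
#' reported contrast goes through one audited interface. No
#' multiple-comparison correction is applied.
#'
#' @param x,y numeric samples (paired for `sign_rank_test`).
#' @return the p value.
#' @name standard_tests
NULL

#' @rdname standard_tests
#' @export
rank_sum_test <- function(x, y) {
  suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))$p.value
}

#' @rdname standard_tests
#' @export
sign_rank_test <- function(x, y = NULL) {
  p <- suppressWarnings(
    if (is.null(y)) stats::wilcox.test(x, exact = FALSE)
    else stats::wilcox.test(x, y, paired = TRUE, exact = FALSE))$p.value
  if (is.na(p)) 1 else p
}

#' @rdname standard_tests
#' @param k1,n1,k2,n2 successes and totals of the two groups.
#' @export
fisher_count_test <- function(k1, n1, k2, n2) {
  stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2))$p.value
}

#' @rdname standard_tests
#' @param value numeric outcome.
#' @param f1,f2 factors; `f2 = NULL` gives a one-way ANOVA.
#' @return for the ANOVA wrapper, a named vector of p values (main
#'   effects and, with two factors, their interaction).
#' @export
anova_test <- function(value, f1, f2 = NULL) {
  f1 <- factor(f1)
  if (is.null(f2)) {
    fit <- stats::aov(value ~ f1)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    return(c(f1 = p))
  }
  f2 <- factor(f2)
  fit <- stats::aov(value ~ f1 * f2)
  tab <- summary(fit)[[1]][["Pr(>F)"]]
  c(f1 = tab[1], f2 = tab[2], interaction = tab[3])
}
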