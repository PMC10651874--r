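#' Modulation index
#'
#' `MI = (S - R) / (S + R)` where `S` and `R` are the mean evoked
#' amplitudes for self-generated and random sounds. `MI = -1` means
#' response only to random sounds, `0` equal responses, `+1` response only
#' to self-generated sounds. Undefined (NA) when `S + R = 0`. Negative
#' amplitudes (suppression below baseline) can push the index outside
#' `[-1, 1]`; such units are retained but should be flagged by callers.
#'
#' @param amp_self,amp_random mean evoked amplitudes (Hz).
#' @return dimensionless index (vectorized).
#' @export
#' @examples
#' modulation_index(0.6, 1)   # -0.25
modulation_index <- function(amp_self, amp_random) {
  s <- amp_self + amp_random
  ifelse(s == 0, NA_real_, (amp_self - amp_random) / s)
}

#' Percent reduction of self-generated responses implied by an MI
#'
#' Inverts the modulation index: `S / R = (1 + MI) / (1 - MI)`, so the
#' reduction of the self-generated response relative to the random one is
#' `100 * (1 - (1 + MI) / (1 - MI))` percent.
#'
#' @param mi modulation index, `mi < 1`.
#' @return percent reduction (negative values mean enhancement).
#' @export
#' @examples
#' percent_reduction(-0.25)  # 40
percent_reduction <- function(mi) {
  stopifnot(all(mi < 1))
  100 * (1 - (1 + mi) / (1 - mi))
}

#' Per-unit significance class of the self/random contrast
#'
#' Two-sided Wilcoxon rank-sum test on per-trial amplitudes; a unit is
#' `attenuated` when p < alpha with self responses shifted below random,
#' `enhanced` when shifted above, otherwise `ns`.
#'
#' @param per_trial_self,per_trial_random per-trial amplitudes (Hz).
#' @param alpha significance level.
#' @return one of `"attenuated"`, `"enhanced"`, `"ns"`.
#' @export
classify_unit_modulation <- function(per_trial_self, per_trial_random,
                                     alpha = 0.05) {
  if (length(per_trial_self) < 2 || length(per_trial_random) < 2) {
    return("ns")
  }
  p <- suppressWarnings(
    stats::wilcox.test(per_trial_self, per_trial_random, exact = FALSE)
  )$p.value
  if (is.na(p) || p >= alpha) return("ns")
  shift <- stats::median(per_trial_self) - stats::median(per_trial_random)
  if (shift == 0) shift <- mean(per_trial_self) - mean(per_trial_random)
  if (shift < 0) "attenuated" else if (shift > 0) "enhanced" else "ns"
}

#' Modulation index by cortical depth
#'
#' Assigns units to half-open depth bins `[lo, hi)` (the last bin closed
#' on the right) and reports the per-bin mean and SEM of the MI.
#'
#' @param mi modulation indices.
#' @param depth_um unit depths (micrometres).
#' @param bin_edges increasing depth-bin edges; default five 200 um bins
#'   spanning 100--1100 um.
#' @return data.frame with `bin`, `lo_um`, `hi_um`, `n`, `mean_mi`,
#'   `sem_mi`.
#' @export
depth_profile <- function(mi, depth_um, bin_edges = seq(100, 1100, by = 200)) {
  stopifnot(length(mi) == length(depth_um), !is.unsorted(bin_edges))
  keep <- !is.na(mi) & depth_um >= bin_edges[1] &
    depth_um <= bin_edges[length(bin_edges)]
  mi <- mi[keep]; depth_um <- depth_um[keep]
  idx <- findInterval(depth_um, bin_edges, rightmost.closed = TRUE)
  n_bin <- length(bin_edges) - 1L
  res <- lapply(seq_len(n_bin), function(b) {
    x <- mi[idx == b]
    data.frame(bin = sprintf("%d-%d", bin_edges[b], bin_edges[b + 1]),
               lo_um = bin_edges[b], hi_um = bin_edges[b + 1],
               n = length(x),
               mean_mi = if (length(x)) mean(x) else NA_real_,
               sem_mi = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                        else NA_real_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Early/late block modulation indices of one unit
#'
#' Computes the MI independently within each experience block using that
#' block's retained sounds (from [split_blocks()]).
#'
#' @param spikes sorted spike times (s) of the unit.
#' @param blocks result of [split_blocks()].
#' @return list with `mi_early`, `mi_late` (NA when the session is
#'   excluded) and `excluded`.
#' @export
block_modulation <- function(spikes, blocks) {
  if (isTRUE(blocks$excluded)) {
    return(list(mi_early = NA_real_, mi_late = NA_real_, excluded = TRUE))
  }
  mi_of <- function(b) {
    s <- mean(per_event_amplitudes(spikes, b$self_times))
    r <- mean(per_event_amplitudes(spikes, b$random_times))
    modulation_index(s, r)
  }
  list(mi_early = mi_of(blocks$early), mi_late = mi_of(blocks$late),
       excluded = FALSE)
}

#' Genotype-level summary of modulation indices
#'
#' Pooled-neuron mean and SEM per genotype, per-animal means with their
#' across-genotype comparison, a rank-sum test on pooled units, and a
#' hierarchical-bootstrap p value (animals resampled before neurons).
#'
#' @param units data.frame with columns `mi`, `animal_id`, `genotype`
#'   (exactly two genotype levels; typically restricted to responsive
#'   units).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return list with per-genotype summaries, `p_ranksum`,
#'   `p_ranksum_animals`, `p_bootstrap`, and `underpowered` (TRUE when a
#'   genotype has a single animal).
#' @export
genotype_summary <- function(units, n_boot = 1000, seed = 1) {
  stopifnot(all(c("mi", "animal_id", "genotype") %in% names(units)))
  units <- units[!is.na(units$mi), , drop = FALSE]
  gts <- unique(units$genotype)
  stopifnot(length(gts) == 2)
  per_g <- lapply(gts, function(g) {
    x <- units[units$genotype == g, , drop = FALSE]
    am <- tapply(x$mi, x$animal_id, mean)
    list(genotype = g, n_units = nrow(x), mean_mi = mean(x$mi),
         sem_mi = stats::sd(x$mi) / sqrt(nrow(x)),
         animal_means = as.numeric(am), n_animals = length(am),
         mean_animal_mi = mean(am),
         sem_animal_mi = if (length(am) > 1)
           stats::sd(am) / sqrt(length(am)) else NA_real_)
  })
  names(per_g) <- gts
  a <- units[units$genotype == gts[1], , drop = FALSE]
  b <- units[units$genotype == gts[2], , drop = FALSE]
  p_rs <- suppressWarnings(
    stats::wilcox.test(a$mi, b$mi, exact = FALSE))$p.value
  underpowered <- per_g[[1]]$n_animals < 2 || per_g[[2]]$n_animals < 2
  p_rs_animals <- if (underpowered) NA_real_ else suppressWarnings(
    stats::wilcox.test(per_g[[1]]$animal_means,
                       per_g[[2]]$animal_means, exact = TRUE))$p.value
  p_boot <- if (underpowered) NA_real_ else
    hierarchical_bootstrap(a$mi, a$animal_id, b$mi, b$animal_id,
                           n_reps = n_boot, seed = seed)$p
  list(genotypes = per_g, p_ranksum = p_rs,
       p_ranksum_animals = p_rs_animals, p_bootstrap = p_boot,
       underpowered = underpowered)
}
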