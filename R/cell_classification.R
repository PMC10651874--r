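#' Waveform feature extraction
#'
#' Computes, from a mean spike waveform sampled on the standard window
#' (495 us before to 1287 us after the trough), the two features used for
#' cell-type classification: the trough width at half of the trough
#' amplitude (half-width) and the time from the trough to the subsequent
#' positive peak (trough-to-peak). The amplitude reference is the mean of
#' the first five samples; half-maximum crossings are located by linear
#' interpolation between samples.
#'
#' @param amplitude numeric vector of waveform samples.
#' @param sample_us sampling interval in microseconds.
#' @return list with `half_width_us` and `trough_to_peak_us`.
#' @export
extract_features <- function(amplitude, sample_us = 33) {
  n <- length(amplitude)
  stopifnot(n >= 8)
  baseline <- mean(amplitude[1:5])
  k <- which.min(amplitude)
  trough <- amplitude[k]
  if (trough >= baseline || k == 1 || k == n) {
    stop("waveform has no interior trough below baseline", call. = FALSE)
  }
  half <- baseline + (trough - baseline) / 2

  # half-width: crossings of `half` on either side of the trough
  cross_left <- NA_real_
  for (i in seq(k, 2)) {
    if (amplitude[i - 1] > half && amplitude[i] <= half) {
      f <- (half - amplitude[i - 1]) / (amplitude[i] - amplitude[i - 1])
      cross_left <- (i - 1) + f
      break
    }
  }
  cross_right <- NA_real_
  for (i in seq(k, n - 1)) {
    if (amplitude[i] <= half && amplitude[i + 1] > half) {
      f <- (half - amplitude[i]) / (amplitude[i + 1] - amplitude[i])
      cross_right <- i + f
      break
    }
  }
  if (is.na(cross_left) || is.na(cross_right)) {
    stop("could not locate half-amplitude crossings around the trough",
         call. = FALSE)
  }
  half_width <- (cross_right - cross_left) * sample_us

  post <- amplitude[(k + 1):n]
  peak_idx <- which.max(post) + k
  trough_to_peak <- (peak_idx - k) * sample_us
  list(half_width_us = half_width, trough_to_peak_us = trough_to_peak)
}

#' Extract features for every unit in a waveforms table
#'
#' @param waveforms data.frame with columns `unit_id`, `sample_index`,
#'   `amplitude`.
#' @param sample_us sampling interval in microseconds.
#' @return data.frame with `unit_id`, `half_width_us`, `trough_to_peak_us`;
#'   units whose waveform has no usable trough are dropped with a warning.
#' @export
waveform_features <- function(waveforms, sample_us = 33) {
  stopifnot(all(c("unit_id", "sample_index", "amplitude") %in%
                names(waveforms)))
  res <- lapply(split(waveforms, waveforms$unit_id), function(w) {
    w <- w[order(w$sample_index), ]
    f <- tryCatch(extract_features(w$amplitude, sample_us),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(unit_id = w$unit_id[1], half_width_us = f$half_width_us,
               trough_to_peak_us = f$trough_to_peak_us)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0) {
    warning(sprintf("%d waveform(s) had no usable trough and were dropped",
                    dropped))
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Classify units into putative pyramidal neurons and interneurons
#'
#' Fits a two-component full-covariance Gaussian mixture to the pooled
#' (half-width, trough-to-peak) features of all units (both genotypes
#' combined). The component with the smaller mean trough-to-peak time is
#' labeled `pIN` (narrow-spiking, putative interneuron), the other `pPN`.
#' Units whose maximum posterior class probability falls below
#' `confidence` are labeled `unclassified` and should be excluded from
#' cell-type contrasts. Degenerate fits are retried with a covariance
#' prior; if that also fails every unit is returned `unclassified`.
#'
#' @param features data.frame from [waveform_features()].
#' @param confidence posterior threshold for accepting a label.
#' @return data.frame: `unit_id`, `half_width_us`, `trough_to_peak_us`,
#'   `cell_class` (`pPN`/`pIN`/`unclassified`), `posterior`.
#' @importFrom mclust Mclust mclustBIC priorControl
#' @export
classify_cells <- function(features, confidence = 0.95) {
  stopifnot(nrow(features) >= 20)
  X <- as.matrix(features[, c("half_width_us", "trough_to_peak_us")])
  fit <- tryCatch(
    Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    message("degenerate mixture fit; retrying with covariance prior")
    fit <- tryCatch(
      Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE,
             prior = priorControl()),
      error = function(e) NULL)
  }
  out <- features
  if (is.null(fit) || is.null(fit$z)) {
    out$cell_class <- "unclassified"
    out$posterior <- 0.5
    return(out)
  }
  narrow <- which.min(fit$parameters$mean["trough_to_peak_us", ])
  labels <- ifelse(fit$classification == narrow, "pIN", "pPN")
  posterior <- apply(fit$z, 1, max)
  out$cell_class <- ifelse(posterior < confidence, "unclassified", labels)
  out$posterior <- posterior
  out
}
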