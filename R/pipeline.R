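#' Percentage from a count ratio
#'
#' The formatter used by all report fractions: `100 * num / den` rounded
#' to two decimals, matching how headline fractions are printed.
#'
#' @param num,den counts.
#' @param digits decimals to keep.
#' @return numeric percentage.
#' @export
#' @examples
#' fraction_pct(89, 187)  # 47.59
fraction_pct <- function(num, den, digits = 2) {
  stopifnot(den > 0)
  round(100 * num / den, digits)
}

#' @rdname fraction_pct
#' @export
format_fraction <- function(num, den, digits = 2) {
  sprintf("%.*f%% (%d/%d)", digits, 100 * num / den, num, den)
}

#' Write a session to delimited text tables
#'
#' Writes `units.tsv`, `spikes.tsv`, `events.tsv`, `waveforms.tsv`
#' (tab-separated, with headers; times in seconds, depths in
#' micrometres).
#'
#' @param session a session list (`units`, `spikes`, `events`,
#'   `waveforms`).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("units", "spikes", "events", "waveforms")) {
    utils::write.table(session[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read and validate a session from delimited text tables
#'
#' Schema violations are hard errors reported with the offending row.
#'
#' @param dir directory containing the four tables written by
#'   [write_session()].
#' @return a validated session list.
#' @export
read_session <- function(dir) {
  read_one <- function(nm, cols) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(path)) stop("missing table: ", path, call. = FALSE)
    x <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    miss <- setdiff(cols, names(x))
    if (length(miss)) {
      stop(sprintf("table '%s' lacks column(s): %s", nm,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    x
  }
  units <- read_one("units", c("unit_id", "animal_id", "genotype",
                               "depth_um"))
  spikes <- read_one("spikes", c("unit_id", "time_s"))
  events <- read_one("events", c("time_s", "event_type", "duration_s"))
  waveforms <- read_one("waveforms", c("unit_id", "sample_index",
                                       "amplitude"))
  validate_session(list(units = units, spikes = spikes, events = events,
                        waveforms = waveforms))
}

#' Validate a session's internal consistency
#'
#' @param session a session list.
#' @return the session (class `ss_session`), or an error naming the first
#'   violation.
#' @export
validate_session <- function(session) {
  ev <- session$events
  if (nrow(ev) > 0 && is.unsorted(ev$time_s)) {
    row <- which(diff(ev$time_s) < 0)[1] + 1L
    stop(sprintf("events out of order at row %d (t = %g)", row,
                 ev$time_s[row]), call. = FALSE)
  }
  orphan <- setdiff(unique(session$spikes$unit_id), session$units$unit_id)
  if (length(orphan)) {
    stop("spikes reference unknown unit id(s): ",
         paste(utils::head(orphan, 3), collapse = ", "), call. = FALSE)
  }
  if (any(session$events$duration_s < 0)) {
    stop("negative event duration at row ",
         which(session$events$duration_s < 0)[1], call. = FALSE)
  }
  structure(session, class = "ss_session")
}

## Analyze one session: selection + per-unit profiles, MI, significance
## class, block MIs, preparatory summary. Returns a per-unit data.frame.
analyze_session <- function(session, sel_cfg = selection_config()) {
  sel <- select_sounds(session$events, sel_cfg)
  blocks <- split_blocks(session$events, sel_cfg)
  prep_presses <- select_preparatory_presses(session$events, sel_cfg)
  res <- lapply(seq_len(nrow(session$units)), function(i) {
    u <- session$units[i, ]
    sp <- session$spikes$time_s[session$spikes$unit_id == u$unit_id]
    prof <- response_profile(sp, sel$self_times, sel$random_times)
    bm <- block_modulation(sp, blocks)
    prep <- if (length(prep_presses) >= 10) {
      preparatory_activity(sp, prep_presses)$summary_delta_hz
    } else NA_real_
    data.frame(
      unit_id = u$unit_id, animal_id = u$animal_id, genotype = u$genotype,
      depth_um = u$depth_um,
      baseline_mean = prof$baseline_mean, baseline_sd = prof$baseline_sd,
      amp_random = prof$amp_random, amp_self = prof$amp_self,
      z_random = prof$z_random, z_self = prof$z_self,
      is_responsive = prof$is_responsive,
      mi = modulation_index(prof$amp_self, prof$amp_random),
      sig_class = classify_unit_modulation(prof$per_trial_amp_self,
                                           prof$per_trial_amp_random),
      mi_early = bm$mi_early, mi_late = bm$mi_late,
      prep_delta_hz = prep,
      n_trials_random = prof$n_trials_random,
      n_trials_self = prof$n_trials_self
    )
  })
  out <- do.call(rbind, res)
  attr(out, "n_self_retained") <- length(sel$self_times)
  attr(out, "n_random_retained") <- length(sel$random_times)
  attr(out, "blocks_excluded") <- isTRUE(blocks$excluded)
  out
}

#' Run the full analysis over a cohort of sessions
#'
#' Orchestrates event selection, per-unit response profiling, modulation
#' and block analyses, preparatory activity, waveform cell-typing (pooled
#' across genotypes) and genotype-level inference, and assembles a
#' report. Stages that fail are marked failed in the report and do not
#' abort the others.
#'
#' @param sessions list of session objects (one per animal), or a single
#'   session.
#' @param sel_cfg a [selection_config()].
#' @param seed seed for the hierarchical bootstrap.
#' @param n_boot bootstrap replicates.
#' @param celltype run waveform classification (needs >= 20 units).
#' @return list of class `ss_report`: `units` (per-unit table),
#'   `summary` (headline quantities), `stages` (status per stage).
#' @export
run_full_analysis <- function(sessions, sel_cfg = selection_config(),
                              seed = 1, n_boot = 1000, celltype = TRUE) {
  if (inherits(sessions, "ss_session")) sessions <- list(sessions)
  stages <- list()

  units_list <- list()
  retained <- data.frame()
  for (nm in names(sessions) %||% seq_along(sessions)) {
    s <- sessions[[nm]]
    tab <- tryCatch(analyze_session(s, sel_cfg), error = function(e) e)
    if (inherits(tab, "error")) {
      stages[[paste0("session_", nm)]] <- conditionMessage(tab)
      next
    }
    units_list[[length(units_list) + 1L]] <- tab
    retained <- rbind(retained, data.frame(
      session = nm,
      n_self_retained = attr(tab, "n_self_retained"),
      n_random_retained = attr(tab, "n_random_retained"),
      blocks_excluded = attr(tab, "blocks_excluded")))
  }
  if (length(units_list) == 0) {
    stop("no session could be analyzed", call. = FALSE)
  }
  units <- do.call(rbind, units_list)
  stages$profiles <- "ok"

  gts <- unique(units$genotype)
  resp <- units[units$is_responsive, , drop = FALSE]
  per_gt <- lapply(gts, function(g) {
    all_g <- units[units$genotype == g, , drop = FALSE]
    r <- resp[resp$genotype == g, , drop = FALSE]
    list(genotype = g,
         n_units = nrow(all_g), n_responsive = nrow(r),
         pct_responsive = fraction_pct(nrow(r), nrow(all_g)),
         n_attenuated = sum(r$sig_class == "attenuated"),
         n_enhanced = sum(r$sig_class == "enhanced"),
         pct_attenuated = if (nrow(r)) fraction_pct(
           sum(r$sig_class == "attenuated"), nrow(r)) else NA_real_,
         pct_enhanced = if (nrow(r)) fraction_pct(
           sum(r$sig_class == "enhanced"), nrow(r)) else NA_real_,
         mi_mean = mean(r$mi, na.rm = TRUE),
         mi_sem = stats::sd(r$mi, na.rm = TRUE) /
           sqrt(sum(!is.na(r$mi))),
         mi_early_mean = mean(r$mi_early, na.rm = TRUE),
         mi_late_mean = mean(r$mi_late, na.rm = TRUE),
         prep_delta_mean_hz = mean(r$prep_delta_hz, na.rm = TRUE),
         depth_profile = depth_profile(r$mi, r$depth_um))
  })
  names(per_gt) <- gts
  stages$modulation <- "ok"

  gt_tests <- if (length(gts) == 2 && all(table(resp$genotype) >= 2)) {
    tryCatch(
      genotype_summary(resp[, c("mi", "animal_id", "genotype")],
                       n_boot = n_boot, seed = seed),
      error = function(e) {
        stages$genotype_tests <<- conditionMessage(e); NULL
      })
  } else NULL
  if (!is.null(gt_tests)) stages$genotype_tests <- "ok"

  ct <- NULL
  if (celltype) {
    wf <- do.call(rbind, lapply(sessions, function(s) s$waveforms))
    ct <- tryCatch({
      feats <- waveform_features(wf)
      classify_cells(feats)
    }, error = function(e) {
      stages$celltype <<- conditionMessage(e); NULL
    })
    if (!is.null(ct)) {
      stages$celltype <- "ok"
      units <- merge(units, ct[, c("unit_id", "cell_class", "posterior")],
                     by = "unit_id", all.x = TRUE, sort = FALSE)
    }
  }

  summary <- list(
    genotypes = per_gt,
    genotype_tests = if (is.null(gt_tests)) NULL else
      gt_tests[c("p_ranksum", "p_ranksum_animals", "p_bootstrap")],
    celltype = if (is.null(ct)) NULL else list(
      n_pPN = sum(ct$cell_class == "pPN"),
      n_pIN = sum(ct$cell_class == "pIN"),
      n_unclassified = sum(ct$cell_class == "unclassified"),
      pct_pIN_of_classified = fraction_pct(
        sum(ct$cell_class == "pIN"),
        max(1L, sum(ct$cell_class != "unclassified"))),
      pct_classified = fraction_pct(sum(ct$cell_class != "unclassified"),
                                    nrow(ct))),
    retained = retained,
    seed = seed
  )
  structure(list(units = units, summary = summary, stages = stages),
            class = "ss_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a report to JSON
#'
#' Keys are written in a stable order and numbers at full precision, so a
#' fixed-seed run is byte-reproducible.
#'
#' @param report an `ss_report` (or any list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  x$units <- NULL                           # per-unit table stays tabular
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  invisible(path)
}
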