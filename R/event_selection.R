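#' Event-selection configuration
#'
#' Inclusion/exclusion rules applied to the stimulus stream before any
#' response is measured. A sound is analyzable only if the gap to the
#' immediately preceding sound of any type is at least `refractory`
#' seconds (onset-to-onset), which limits contamination by sensory
#' adaptation. Random sounds are additionally filtered to match the
#' behavioral state of self-generated sounds, by default by requiring that
#' the immediately preceding sound was self-generated.
#'
#' @param refractory minimum gap (s) to the previous sound of any type.
#' @param random_rule behavioral-state rule for random sounds: one of
#'   `"preceded_by_self"`, `"pre_press_window"`, `"lever_held"`.
#' @param pre_press_window window (s) before a press within which a random
#'   sound counts as occurring during pressing (rule `pre_press_window`).
#' @param block_size number of self-generated sounds per experience block.
#' @param block_refractory refractory (s) used within block analyses; a
#'   laxer value keeps more sessions analyzable.
#' @param min_session_self minimum total self-generated sounds for a
#'   session to enter block analyses.
#' @param min_block_events minimum retained sounds of each class per block.
#' @param preparatory_gap minimum gap (s) from the previous sound to a
#'   lever press used in preparatory-activity analyses.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(refractory = 1.0,
                             random_rule = c("preceded_by_self",
                                             "pre_press_window",
                                             "lever_held"),
                             pre_press_window = 1.0,
                             block_size = 300L,
                             block_refractory = 0.5,
                             min_session_self = 400L,
                             min_block_events = 20L,
                             preparatory_gap = 2.0) {
  random_rule <- match.arg(random_rule)
  stopifnot(refractory >= 0, block_size > 0, block_refractory >= 0,
            pre_press_window > 0, preparatory_gap >= 0)
  structure(list(refractory = refractory, random_rule = random_rule,
                 pre_press_window = pre_press_window,
                 block_size = as.integer(block_size),
                 block_refractory = block_refractory,
                 min_session_self = as.integer(min_session_self),
                 min_block_events = as.integer(min_block_events),
                 preparatory_gap = preparatory_gap),
            class = "selection_config")
}

## Internal: per-sound retention flags. Gaps are always computed against
## the full physical sound sequence (including sounds that end up
## excluded), because adaptation depends on stimulus history rather than
## on analysis choices.
sound_retention <- function(events, cfg, refractory = cfg$refractory) {
  snd <- events[events$event_type %in% c("sound_self", "sound_random"), ,
                drop = FALSE]
  snd <- snd[order(snd$time_s), , drop = FALSE]
  n <- nrow(snd)
  if (n == 0) {
    return(data.frame(time_s = numeric(0), event_type = character(0),
                      retained = logical(0), reason = character(0)))
  }
  gap <- c(Inf, diff(snd$time_s))
  pass_refr <- gap >= refractory          # no predecessor: vacuously TRUE
  is_self <- snd$event_type == "sound_self"
  prev_type <- c(NA_character_, snd$event_type[-n])

  pass_rule <- rep(TRUE, n)
  if (cfg$random_rule == "preceded_by_self") {
    pass_rule[!is_self] <- !is.na(prev_type[!is_self]) &
      prev_type[!is_self] == "sound_self"
  } else if (cfg$random_rule == "pre_press_window") {
    presses <- events$time_s[events$event_type == "press"]
    idx <- which(!is_self)
    if (length(presses) == 0) {
      pass_rule[idx] <- FALSE
    } else {
      # time to the next press, NA if none follows
      nxt <- findInterval(snd$time_s[idx], presses) + 1L
      to_press <- ifelse(nxt <= length(presses),
                         presses[nxt] - snd$time_s[idx], Inf)
      pass_rule[idx] <- to_press <= cfg$pre_press_window
    }
  } else if (cfg$random_rule == "lever_held") {
    presses <- events[events$event_type == "press", , drop = FALSE]
    idx <- which(!is_self)
    if (nrow(presses) == 0) {
      pass_rule[idx] <- FALSE
    } else {
      k <- findInterval(snd$time_s[idx], presses$time_s)
      held <- k >= 1
      held[held] <- snd$time_s[idx][held] <=
        presses$time_s[k[held]] + presses$duration_s[k[held]]
      pass_rule[idx] <- held
    }
  }

  reason <- ifelse(!pass_refr, "refractory",
                   ifelse(!pass_rule, cfg$random_rule, "retained"))
  data.frame(time_s = snd$time_s, event_type = snd$event_type,
             retained = pass_refr & pass_rule, reason = reason)
}

#' Select analyzable self-generated and random sounds
#'
#' Applies the refractory rule (gap to the immediately preceding sound of
#' any type, retained or not, must be at least `cfg$refractory`) to both
#' sound classes, and the configured behavioral-state rule to random
#' sounds. Under `preceded_by_self`, a random sound with no predecessor is
#' excluded because the predecessor condition cannot be verified.
#'
#' @param events event-log data.frame (`time_s`, `event_type`,
#'   `duration_s`).
#' @param cfg a [selection_config()].
#' @return list with `self_times`, `random_times` (numeric vectors) and
#'   `audit`, a per-sound table of retention decisions.
#' @export
select_sounds <- function(events, cfg = selection_config()) {
  stopifnot(inherits(cfg, "selection_config"))
  tab <- sound_retention(events, cfg)
  list(self_times = tab$time_s[tab$retained & tab$event_type == "sound_self"],
       random_times = tab$time_s[tab$retained &
                                 tab$event_type == "sound_random"],
       audit = tab)
}

#' Split a session into early and late experience blocks
#'
#' Blocks are defined on the ordinal sequence of all self-generated sounds
#' (the physical sequence, before retention): the first `block_size`
#' sounds form the early block and the subsequent `block_size` the late
#' block (or the remaining sounds if fewer). Random sounds are assigned to
#' the block whose time span (first to last self sound, half-open on the
#' right) contains them. Retention within blocks uses `block_refractory`.
#' The session is excluded when it has fewer than `min_session_self` self
#' sounds in total, or when any block retains fewer than
#' `min_block_events` sounds of either class.
#'
#' @inheritParams select_sounds
#' @return list with `excluded` (logical), `reason`, and when not excluded
#'   `early` and `late`, each a list with `self_times` and `random_times`.
#' @export
split_blocks <- function(events, cfg = selection_config()) {
  stopifnot(inherits(cfg, "selection_config"))
  self_all <- sort(events$time_s[events$event_type == "sound_self"])
  n_self <- length(self_all)
  if (n_self < cfg$min_session_self) {
    return(list(excluded = TRUE,
                reason = sprintf("only %d self-generated sounds (< %d)",
                                 n_self, cfg$min_session_self)))
  }
  bs <- cfg$block_size
  early_idx <- seq_len(min(bs, n_self))
  late_idx <- seq.int(bs + 1L, min(2L * bs, n_self))
  tab <- sound_retention(events, cfg, refractory = cfg$block_refractory)

  block_sets <- lapply(list(early = early_idx, late = late_idx), function(ix) {
    span <- c(self_all[ix[1]], self_all[ix[length(ix)]])
    self_block <- tab$event_type == "sound_self" &
      tab$time_s >= span[1] & tab$time_s <= span[2]
    rand_block <- tab$event_type == "sound_random" &
      tab$time_s >= span[1] & tab$time_s < span[2]
    list(self_times = tab$time_s[self_block & tab$retained],
         random_times = tab$time_s[rand_block & tab$retained])
  })
  counts <- unlist(lapply(block_sets, function(b)
    c(length(b$self_times), length(b$random_times))))
  if (any(counts < cfg$min_block_events)) {
    return(list(excluded = TRUE,
                reason = sprintf(
                  "a block retains fewer than %d sounds of one class",
                  cfg$min_block_events)))
  }
  list(excluded = FALSE, reason = "included",
       early = block_sets$early, late = block_sets$late)
}

#' Select lever presses for preparatory-activity analyses
#'
#' Keeps presses whose gap to the most recent prior sound of any type is
#' at least `cfg$preparatory_gap` seconds, so pre-press firing is not
#' contaminated by residual auditory responses. A press with no prior
#' sound is retained (the condition is vacuously satisfied). The sound
#' triggered by the press itself (at the press time) does not count as a
#' prior sound.
#'
#' @inheritParams select_sounds
#' @return numeric vector of press times.
#' @export
select_preparatory_presses <- function(events, cfg = selection_config()) {
  stopifnot(inherits(cfg, "selection_config"))
  presses <- sort(events$time_s[events$event_type == "press"])
  sounds <- sort(events$time_s[events$event_type %in%
                               c("sound_self", "sound_random")])
  if (length(presses) == 0) return(numeric(0))
  if (length(sounds) == 0) return(presses)
  # index of last sound strictly before each press
  k <- findInterval(presses - 1e-9, sounds)
  gap <- ifelse(k >= 1, presses - sounds[pmax(k, 1L)], Inf)
  presses[gap >= cfg$preparatory_gap]
}
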