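# Independent per-event rule checker for sound selection: a deliberately
# plain loop, kept separate from the vectorized implementation it audits.
oracle_select_sounds <- function(events, cfg) {
  snd <- events[events$event_type %in% c("sound_self", "sound_random"), ]
  snd <- snd[order(snd$time_s), ]
  self_keep <- numeric(0)
  rand_keep <- numeric(0)
  for (i in seq_len(nrow(snd))) {
    t <- snd$time_s[i]
    ty <- snd$event_type[i]
    ok <- TRUE
    if (i > 1 && t - snd$time_s[i - 1] < cfg$refractory) ok <- FALSE
    if (ok && ty == "sound_random") {
      if (cfg$random_rule == "preceded_by_self") {
        ok <- i > 1 && snd$event_type[i - 1] == "sound_self"
      } else if (cfg$random_rule == "pre_press_window") {
        presses <- events$time_s[events$event_type == "press"]
        later <- presses[presses >= t]
        ok <- length(later) > 0 && min(later) - t <= cfg$pre_press_window
      } else if (cfg$random_rule == "lever_held") {
        pr <- events[events$event_type == "press", ]
        ok <- FALSE
        for (j in seq_len(nrow(pr))) {
          if (t >= pr$time_s[j] && t <= pr$time_s[j] + pr$duration_s[j]) {
            ok <- TRUE
            break
          }
        }
      }
    }
    if (ok && ty == "sound_self") self_keep <- c(self_keep, t)
    if (ok && ty == "sound_random") rand_keep <- c(rand_keep, t)
  }
  list(self_times = self_keep, random_times = rand_keep)
}

# Random small event log for property tests.
random_event_log <- function(n_events = 15, t_max = 30) {
  types <- sample(c("sound_self", "sound_random", "press", "release"),
                  n_events, replace = TRUE,
                  prob = c(0.35, 0.35, 0.2, 0.1))
  t <- sort(round(runif(n_events, 0, t_max), 2))
  # couple each self sound to a press at the same time
  ev <- data.frame(time_s = t, event_type = types,
                   duration_s = ifelse(types == "press", runif(n_events, 0.2, 1), 0))
  selfs <- ev[ev$event_type == "sound_self", ]
  if (nrow(selfs) > 0) {
    ev <- rbind(ev, data.frame(time_s = selfs$time_s, event_type = "press",
                               duration_s = 0.5))
  }
  ev <- ev[order(ev$time_s, ev$event_type), ]
  rownames(ev) <- NULL
  ev
}

# Deterministic spike train: one spike at a fixed offset after each event.
spikes_at_offset <- function(event_times, offset) sort(event_times + offset)
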