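# Task protocol and TMS pulse-train scheduling for the auditory
# working-memory training task: 15-s trials, first tone sequence at 0 ms,
# visual reorder cue at 5000 ms, probe sequence at 10000 ms.

TRIAL_EVENT_TIMES_MS <- c(tone_onset = 0, cue_onset = 5000, probe_onset = 10000)
TRIAL_DURATION_MS <- 15000

# the five reorder cues: all permutations of "123" except identity
MANIPULATION_CUES <- c("132", "213", "231", "312", "321")

#' Build a session protocol
#'
#' A session consists of `runs` runs of `trials_per_run` trials each;
#' `n_simple` trials per run are simple (retention-only, cue "123"), the
#' rest are manipulation trials with a random non-identity reorder cue.
#' Trial order is shuffled within each run (seed-fixed), and match/mismatch
#' ground truth is balanced 50/50 within each trial type.
#'
#' Defaults reproduce the training-session structure: 3 runs x 42 trials
#' (14 simple + 28 manipulation) = 126 trials.
#'
#' @param runs number of runs (>= 1).
#' @param trials_per_run trials per run (>= 1).
#' @param n_simple simple trials per run (0..trials_per_run).
#' @param match_prop proportion of match trials within each type (default
#'   0.5).
#' @param seed integer seed for trial order, cue sampling, and match
#'   assignment.
#' @return a `session_protocol` object: data.frame with columns run, trial,
#'   trial_type, cue, is_match; event times in attribute `"event_times_ms"`.
#' @export
build_protocol <- function(runs = 3, trials_per_run = 42, n_simple = 14,
                           match_prop = 0.5, seed = NULL) {
  if (runs < 1 || trials_per_run < 1) {
    stop("build_protocol: runs and trials_per_run must be positive")
  }
  if (n_simple < 0 || n_simple > trials_per_run) {
    stop("build_protocol: n_simple must be in 0..trials_per_run")
  }
  with_seed(seed, {
    per_run <- lapply(seq_len(runs), function(r) {
      n_manip <- trials_per_run - n_simple
      type <- c(rep("simple", n_simple), rep("manipulation", n_manip))
      cue <- c(
        rep("123", n_simple),
        sample(MANIPULATION_CUES, n_manip, replace = TRUE)
      )
      balanced_match <- function(n) {
        if (n == 0) return(logical(0))
        m <- c(rep(TRUE, round(n * match_prop)),
          rep(FALSE, n - round(n * match_prop)))
        sample(m)
      }
      is_match <- logical(trials_per_run)
      is_match[type == "simple"] <- balanced_match(n_simple)
      is_match[type == "manipulation"] <- balanced_match(n_manip)
      ord <- sample.int(trials_per_run)
      data.frame(
        run = r, trial = seq_len(trials_per_run),
        trial_type = type[ord], cue = cue[ord], is_match = is_match[ord],
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, per_run)
    rownames(out) <- NULL
    attr(out, "event_times_ms") <- TRIAL_EVENT_TIMES_MS
    attr(out, "trial_duration_ms") <- TRIAL_DURATION_MS
    class(out) <- c("session_protocol", "data.frame")
    out
  })
}

#' Schedule TMS pulse trains for a protocol
#'
#' Every trial receives one pulse train starting at the cue onset: pulse k
#' (k = 0..n_pulses-1) at `cue_onset + k * 1000/freq_hz` ms relative to the
#' first-tone onset. The default 10 pulses at 5 Hz span 5000..6800 ms, i.e.
#' 420 pulses over a default 42-trial run; note that the source protocol's
#' own total-per-session count (2,160) disagrees with its per-block
#' arithmetic (3 x 420 = 1,260) — the scheduler follows the per-block rule.
#'
#' A train that would overrun the probe onset (10000 ms) triggers a warning,
#' not an error.
#'
#' @param protocol a [build_protocol()] result.
#' @param freq_hz pulse frequency (> 0), default 5.
#' @param n_pulses pulses per train (>= 1), default 10.
#' @return a `stim_schedule` object: data.frame with columns run, trial,
#'   pulse (1-based), onset_ms (trial-relative).
#' @export
schedule_tms <- function(protocol, freq_hz = 5, n_pulses = 10) {
  stopifnot(inherits(protocol, "session_protocol"))
  if (freq_hz <= 0) stop("schedule_tms: freq_hz must be > 0")
  if (n_pulses < 1) stop("schedule_tms: n_pulses must be >= 1")
  cue <- attr(protocol, "event_times_ms")[["cue_onset"]]
  probe <- attr(protocol, "event_times_ms")[["probe_onset"]]
  onsets <- cue + (seq_len(n_pulses) - 1) * 1000 / freq_hz
  if (max(onsets) >= probe) {
    warning(sprintf(
      "schedule_tms: train overruns probe onset (last pulse %.1f ms >= %g ms)",
      max(onsets), probe
    ))
  }
  n_tr <- nrow(protocol)
  out <- data.frame(
    run = rep(protocol$run, each = n_pulses),
    trial = rep(protocol$trial, each = n_pulses),
    pulse = rep(seq_len(n_pulses), times = n_tr),
    onset_ms = rep(onsets, times = n_tr)
  )
  attr(out, "freq_hz") <- freq_hz
  attr(out, "n_pulses") <- n_pulses
  class(out) <- c("stim_schedule", "data.frame")
  out
}
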