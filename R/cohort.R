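# Subject profiles and behavioral response simulation. A cohort is a table
# of per-subject ground-truth parameters (baseline sensitivity, learning
# slope, theta gain, rhTMS entrainment gain); responses come from an
# equal-variance Gaussian observer.

#' Effect specification for simulated cohorts
#'
#' Population parameters of the simulated study. Defaults follow the
#' study-scale world: baseline manipulation d' around 1.7 (groups balanced
#' at assignment), near-ceiling simple-trial d' around 2.9, an rhTMS
#' learning-slope advantage of 0.2 d'/session over sham (sham mean 0),
#' endogenous theta burst amplitude ~5 uV over ~10 uV 1/f background, and
#' an rhTMS entrainment gain of ~4 uV.
#'
#' @param base_manip_mean,base_manip_sd baseline manipulation d' population
#'   mean/SD.
#' @param base_simple_mean,base_simple_sd baseline simple-trial d'.
#' @param slope_rhtms,slope_sham group mean learning slopes (d'/session).
#' @param slope_sd between-subject slope SD.
#' @param slope_simple learning slope on simple trials (both groups).
#' @param theta_gain_uv,theta_gain_sd endogenous theta burst amplitude (uV).
#' @param entrain_gain_uv,entrain_gain_sd extra theta amplitude under real
#'   rhTMS (uV); always 0 for sham.
#' @param balance_tol maximum allowed group difference in mean baseline d'.
#' @param max_tries bounded retries for the balance constraint.
#' @return a list of class `cohort_effects`.
#' @export
cohort_effects <- function(base_manip_mean = 1.7, base_manip_sd = 0.5,
                           base_simple_mean = 2.9, base_simple_sd = 0.5,
                           slope_rhtms = 0.2, slope_sham = 0,
                           slope_sd = 0.1, slope_simple = 0,
                           theta_gain_uv = 5, theta_gain_sd = 1.5,
                           entrain_gain_uv = 4, entrain_gain_sd = 1,
                           balance_tol = 0.25, max_tries = 200) {
  out <- as.list(environment())
  class(out) <- "cohort_effects"
  out
}

#' Simulate a cohort of subject profiles
#'
#' Draws `2 * n_per_group` subjects and assigns them to rhTMS and sham
#' groups balanced on mean baseline manipulation d' (pair-matched on sorted
#' baselines with randomized within-pair assignment, re-drawn until the
#' group means differ by at most `effects$balance_tol`). Sham subjects have
#' entrainment gain exactly 0.
#'
#' @param n_per_group subjects per group (>= 1).
#' @param effects a [cohort_effects()] specification.
#' @param seed integer master seed.
#' @return a `cohort` data.frame: subject, group, base_dprime_manip,
#'   base_dprime_simple, slope, slope_simple, theta_gain_uv,
#'   entrain_gain_uv, seed.
#' @export
simulate_cohort <- function(n_per_group, effects = cohort_effects(),
                            seed = NULL) {
  if (n_per_group < 1) stop("simulate_cohort: n_per_group must be >= 1")
  e <- effects
  n <- 2 * n_per_group
  with_seed(seed, {
    for (try in seq_len(e$max_tries)) {
      base_m <- stats::rnorm(n, e$base_manip_mean, e$base_manip_sd)
      # pair-match: sort, randomize assignment within consecutive pairs
      ord <- order(base_m)
      grp <- character(n)
      for (p in seq_len(n_per_group)) {
        pair <- ord[c(2 * p - 1, 2 * p)]
        grp[pair] <- sample(c("rhTMS", "sham"))
      }
      dm <- abs(mean(base_m[grp == "rhTMS"]) - mean(base_m[grp == "sham"]))
      if (dm <= e$balance_tol) break
      if (try == e$max_tries) {
        stop(sprintf(
          "simulate_cohort: could not balance baselines to +-%g in %d tries",
          e$balance_tol, e$max_tries
        ))
      }
    }
    is_rh <- grp == "rhTMS"
    slope <- stats::rnorm(n, ifelse(is_rh, e$slope_rhtms, e$slope_sham),
      e$slope_sd)
    out <- data.frame(
      subject = sprintf("S%02d", seq_len(n)),
      group = grp,
      base_dprime_manip = base_m,
      base_dprime_simple = stats::rnorm(n, e$base_simple_mean,
        e$base_simple_sd),
      slope = slope,
      slope_simple = rep(e$slope_simple, n),
      theta_gain_uv = pmax(0, stats::rnorm(n, e$theta_gain_uv,
        e$theta_gain_sd)),
      entrain_gain_uv = ifelse(is_rh,
        pmax(0, stats::rnorm(n, e$entrain_gain_uv, e$entrain_gain_sd)), 0),
      seed = vapply(seq_len(n), function(i) {
        derive_seed(if (is.null(seed)) 0 else seed, 101, i)
      }, 0L),
      stringsAsFactors = FALSE
    )
    class(out) <- c("cohort", "data.frame")
    out
  })
}

# effective sensitivity of a profile in a given session (floored at 0)
session_dprime <- function(profile, session, trial_type) {
  base <- if (trial_type == "manipulation") {
    profile$base_dprime_manip
  } else {
    profile$base_dprime_simple
  }
  sl <- if (trial_type == "manipulation") profile$slope else profile$slope_simple
  max(0, base + sl * (session - 1))
}

#' Simulate per-trial responses for one subject and session
#'
#' Equal-variance Gaussian observer: on a mismatch (signal) trial the
#' internal evidence is N(d', 1), on a match (noise) trial N(0, 1); the
#' observer responds "mismatch" when evidence exceeds `d'/2 + c`.
#' Sensitivity is `baseline + slope * (session - 1)`, floored at 0, with
#' the manipulation/simple baseline and slope chosen per trial type.
#'
#' @param profile one row of a [simulate_cohort()] table (or equivalent
#'   list).
#' @param protocol a [build_protocol()] result.
#' @param session session index 1..7 (1 = pre-training, 2..6 = training
#'   days, 7 = post-training).
#' @param criterion observer criterion c (default 0 = unbiased).
#' @param seed integer seed; defaults to a deterministic function of the
#'   profile seed and session.
#' @return a behavior table: data.frame with columns subject, group,
#'   session, run, trial, trial_type, cue, is_match, response, correct.
#' @export
simulate_responses <- function(profile, protocol, session, criterion = 0,
                               seed = NULL) {
  stopifnot(session >= 1, session <= 7)
  profile <- as.list(profile)
  if (is.null(seed)) seed <- derive_seed(profile$seed, 7, session)
  n <- nrow(protocol)
  with_seed(seed, {
    dps <- vapply(protocol$trial_type, function(tt) {
      session_dprime(profile, session, tt)
    }, 0)
    evidence <- stats::rnorm(n,
      mean = ifelse(protocol$is_match, 0, dps), sd = 1)
    resp_mismatch <- evidence > dps / 2 + criterion
    out <- data.frame(
      subject = profile$subject,
      group = profile$group,
      session = session,
      run = protocol$run,
      trial = protocol$trial,
      trial_type = protocol$trial_type,
      cue = protocol$cue,
      is_match = protocol$is_match,
      response = ifelse(resp_mismatch, "mismatch", "match"),
      correct = resp_mismatch == !protocol$is_match,
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}
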