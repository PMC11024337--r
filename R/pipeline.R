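# End-to-end study replica: simulate -> preprocess -> theta envelope ->
# cluster statistics -> behavioral statistics -> report bundle.

#' Study configuration
#'
#' All knobs of the end-to-end replica in one serializable list. Defaults
#' follow the source protocol (7 subjects/group, 7 sessions, 3 runs x 42
#' trials, EEG at sessions 1/3/5/7, 5 Hz x 10-pulse trains on training
#' sessions); `eeg_runs` and `eeg_trials_cap` exist to scale the EEG volume
#' down for constrained environments.
#'
#' @param n_per_group subjects per group.
#' @param sessions session indices (1 = pre, 2..6 training, 7 = post).
#' @param runs,trials_per_run,n_simple protocol shape.
#' @param eeg_sessions sessions with EEG recording.
#' @param tms_sessions sessions with real stimulation (rhTMS group).
#' @param eeg_runs how many runs get EEG simulation per EEG session.
#' @param eeg_trials_cap optional cap on EEG trials per session (NULL =
#'   all).
#' @param srate simulated sampling rate (Hz).
#' @param effects a [cohort_effects()] list.
#' @param band analysis band (Hz).
#' @param baseline_ms,window_ms analysis windows.
#' @param alpha,n_perm cluster-test parameters.
#' @param preprocess run the artifact-removal/filter/resample chain on the
#'   simulated EEG (TRUE) or analyze the clean epochs directly (FALSE,
#'   faster; the preprocessing chain has its own verification suite).
#' @param seed master seed.
#' @return a `study_config` list.
#' @export
study_config <- function(n_per_group = 7, sessions = 1:7, runs = 3,
                         trials_per_run = 42, n_simple = 14,
                         eeg_sessions = c(1, 3, 5, 7),
                         tms_sessions = 2:6,
                         eeg_runs = 1, eeg_trials_cap = NULL,
                         srate = 1000, effects = cohort_effects(),
                         band = c(4, 8), baseline_ms = c(-1000, 0),
                         window_ms = c(5000, 10000),
                         alpha = 0.05, n_perm = 1000,
                         preprocess = TRUE, seed = 1) {
  out <- as.list(environment())
  class(out) <- "study_config"
  out
}

# per-subject theta topography for one EEG session
subject_session_topography <- function(profile, config, montage, session,
                                       schedule_active) {
  proto <- build_protocol(config$eeg_runs, config$trials_per_run,
    config$n_simple,
    seed = derive_seed(config$seed, 31, session))
  if (!is.null(config$eeg_trials_cap) &&
      nrow(proto) > config$eeg_trials_cap) {
    at <- attributes(proto)
    proto <- proto[seq_len(config$eeg_trials_cap), , drop = FALSE]
    attr(proto, "event_times_ms") <- at$event_times_ms
    attr(proto, "trial_duration_ms") <- at$trial_duration_ms
    class(proto) <- c("session_protocol", "data.frame")
  }
  sched <- NULL
  if (schedule_active) sched <- schedule_tms(proto)
  simc <- sim_config(
    n_channels = nrow(montage), srate = config$srate,
    seed = derive_seed(config$seed, 37, profile$seed, session)
  )
  ep <- simulate_epochs(profile, proto, sched, montage, simc,
    session = session)
  if (isTRUE(config$preprocess)) {
    rec <- epochs_to_recording(ep, sched)
    pp <- preprocess_chain(rec, sched,
      metadata = ep$info,
      target_hz = min(500, config$srate),
      seed = derive_seed(config$seed, 41, profile$seed, session)
    )
    ep <- pp$epochs
  }
  man <- ep$info$trial_type == "manipulation"
  env_man <- band_envelope(subset_epochs(ep, man), config$band,
    baseline_ms = config$baseline_ms, window_ms = config$window_ms)
  env_sim <- NULL
  if (any(!man)) {
    env_sim <- band_envelope(subset_epochs(ep, !man), config$band,
      baseline_ms = config$baseline_ms, window_ms = config$window_ms)
  }
  list(manipulation = env_man$topography,
    simple = if (is.null(env_sim)) NULL else env_sim$topography)
}

#' Subset trials of an epoched recording
#' @param epochs an [eeg_epochs()].
#' @param idx logical or integer trial index.
#' @return the subsetted [eeg_epochs()].
#' @export
subset_epochs <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$info <- epochs$info[idx, , drop = FALSE]
  epochs
}

#' Run the full study replica
#'
#' Simulates a cohort, behavioral responses for every session, and EEG for
#' the EEG sessions; then computes (i) the pre-training manipulation vs
#' simple theta-topography paired cluster test, (ii) the across-subject
#' theta-power vs d' correlation at pre-training, (iii) the group
#' learning-slope Mann-Whitney comparison, (iv) the training-day rhTMS vs
#' sham theta cluster test, and (v) post-vs-pre within-group and
#' post-training between-group theta cluster tests. Writes CSV/JSON
#' outputs plus a run log when `out_dir` is given.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory (created if missing).
#' @return a `study_report` list with elements `behavior`, `dprime`,
#'   `slopes`, `tests`, `topographies`, `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  logit <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
      sprintf(...))
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  montage <- load_montage()
  adj <- build_adjacency(montage)
  cohort <- simulate_cohort(config$n_per_group, config$effects,
    seed = derive_seed(config$seed, 1))
  logit("cohort: %d subjects (%d per group)", nrow(cohort),
    config$n_per_group)

  # behavioral simulation: every session, full protocol
  behavior <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    do.call(rbind, lapply(config$sessions, function(s) {
      proto <- build_protocol(config$runs, config$trials_per_run,
        config$n_simple, seed = derive_seed(config$seed, 2, s))
      simulate_responses(cohort[i, ], proto, s)
    }))
  }))
  dp <- dprime_table(behavior)
  dp_simple <- dprime_table(behavior, "simple")
  slopes <- slope_table(dp)
  logit("behavior: %d trials, %d d' cells", nrow(behavior), nrow(dp))

  # EEG topographies per subject x EEG session
  topo <- list()
  for (s in intersect(config$eeg_sessions, config$sessions)) {
    active <- s %in% config$tms_sessions
    topo[[as.character(s)]] <- lapply(seq_len(nrow(cohort)), function(i) {
      subject_session_topography(cohort[i, ], config, montage, s, active)
    })
    logit("EEG session %d: topographies for %d subjects (tms=%s)",
      s, nrow(cohort), active)
  }

  grp <- cohort$group
  rh <- grp == "rhTMS"
  tests <- list()
  stack <- function(sess, what) {
    t(vapply(topo[[as.character(sess)]], function(x) x[[what]],
      numeric(nrow(montage))))
  }

  pre_s <- intersect(config$eeg_sessions, config$sessions)[1]
  if (!is.null(topo[[as.character(pre_s)]])) {
    man <- stack(pre_s, "manipulation")
    if (!is.null(topo[[as.character(pre_s)]][[1]]$simple)) {
      sim <- stack(pre_s, "simple")
      tests$manip_vs_simple <- cluster_permutation_test(
        man, sim, "paired", adj,
        alpha = config$alpha, n_perm = config$n_perm,
        seed = derive_seed(config$seed, 51)
      )
      logit("manip vs simple (session %d): %d clusters", pre_s,
        nrow(tests$manip_vs_simple$clusters))
    }
    dpre <- dp[dp$session == pre_s, ]
    dpre <- dpre[match(cohort$subject, dpre$subject), ]
    tests$power_behavior <- tf_behavior_correlation(
      lapply(seq_len(nrow(man)), function(i) man[i, ]), dpre$dprime
    )
    logit("power-behavior correlation: peak r = %.3f",
      tests$power_behavior$peak$r)
  }

  tr_sessions <- intersect(intersect(config$tms_sessions,
    config$eeg_sessions), config$sessions)
  if (length(tr_sessions) > 0) {
    tr <- Reduce(`+`, lapply(tr_sessions, stack, what = "manipulation")) /
      length(tr_sessions)
    tests$training_group <- cluster_permutation_test(
      tr[rh, , drop = FALSE], tr[!rh, , drop = FALSE], "independent", adj,
      alpha = config$alpha, n_perm = config$n_perm,
      seed = derive_seed(config$seed, 52)
    )
    logit("training rhTMS vs sham: %d clusters (min p %s)",
      nrow(tests$training_group$clusters),
      if (nrow(tests$training_group$clusters) > 0) {
        format(min(tests$training_group$clusters$p), digits = 3)
      } else "-")
  }

  post_s <- utils::tail(intersect(config$eeg_sessions, config$sessions), 1)
  if (length(post_s) == 1 && post_s != pre_s) {
    post <- stack(post_s, "manipulation")
    pre <- stack(pre_s, "manipulation")
    tests$post_vs_pre_rhtms <- cluster_permutation_test(
      post[rh, , drop = FALSE], pre[rh, , drop = FALSE], "paired", adj,
      alpha = config$alpha, n_perm = config$n_perm,
      seed = derive_seed(config$seed, 53)
    )
    tests$post_vs_pre_sham <- cluster_permutation_test(
      post[!rh, , drop = FALSE], pre[!rh, , drop = FALSE], "paired", adj,
      alpha = config$alpha, n_perm = config$n_perm,
      seed = derive_seed(config$seed, 54)
    )
    tests$post_group <- cluster_permutation_test(
      post[rh, , drop = FALSE], post[!rh, , drop = FALSE], "independent",
      adj, alpha = config$alpha, n_perm = config$n_perm,
      seed = derive_seed(config$seed, 55)
    )
    logit("post-training contrasts computed (session %d vs %d)",
      post_s, pre_s)
  }

  # behavioral group statistics
  sl_rh <- slopes$slope[slopes$group == "rhTMS"]
  sl_sh <- slopes$slope[slopes$group == "sham"]
  tests$slope_mw <- mannwhitney_u(sl_rh, sl_sh, "two")
  tests$slope_rhtms_pos <- wilcoxon_signed(sl_rh, tail = "greater")
  tests$slope_sham_pos <- wilcoxon_signed(sl_sh, tail = "greater")
  d_last <- dp[dp$session == max(config$sessions), ]
  tests$effect_size <- cohens_d(
    mean(d_last$dprime[d_last$group == "rhTMS"]),
    stats::sd(d_last$dprime[d_last$group == "rhTMS"]),
    mean(d_last$dprime[d_last$group == "sham"]),
    stats::sd(d_last$dprime[d_last$group == "sham"])
  )
  tests$sample_size <- if (is.finite(tests$effect_size) &&
    abs(tests$effect_size) > 0) {
    required_sample_size(abs(tests$effect_size))
  } else {
    list(n_per_group = NA, total = NA, achieved_power = NA)
  }
  logit("slope MW U=%g p=%.4f; effect size d=%.3f",
    tests$slope_mw$U, tests$slope_mw$p, tests$effect_size)

  report <- structure(
    list(behavior = behavior, dprime = dp, dprime_simple = dp_simple,
      slopes = slopes, tests = tests, topographies = topo,
      cohort = cohort, config = config,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "study_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(behavior, file.path(out_dir, "behavior.csv"),
      row.names = FALSE)
    utils::write.csv(dp, file.path(out_dir, "dprime_manipulation.csv"),
      row.names = FALSE)
    utils::write.csv(slopes, file.path(out_dir, "slopes.csv"),
      row.names = FALSE)
    for (s in names(topo)) {
      tm <- stack(as.numeric(s), "manipulation")
      colnames(tm) <- montage$label
      utils::write.csv(
        cbind(data.frame(subject = cohort$subject, group = grp), tm),
        file.path(out_dir, sprintf("topography_session%s.csv", s)),
        row.names = FALSE
      )
    }
    jsonlite::write_json(
      serialize_tests(tests),
      file.path(out_dir, "tests.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    writeLines(log_lines, file.path(out_dir, "run.log"))
    logit("report written to %s", out_dir)
  }
  report
}

serialize_tests <- function(tests) {
  lapply(tests, function(t) {
    if (inherits(t, "cluster_result")) {
      list(
        design = t$design, tail = t$tail, n_perm = t$n_perm,
        exact = t$exact, tcrit = t$tcrit,
        clusters = t$clusters
      )
    } else if (inherits(t, "correlation_map")) {
      list(n = t$n, peak_r = t$peak$r)
    } else {
      t
    }
  })
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf(
    "<study_report> %d subjects, %d behavior trials, %d test blocks (%.1f s)\n",
    nrow(x$cohort), nrow(x$behavior), length(x$tests), x$elapsed_s
  ))
  invisible(x)
}
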