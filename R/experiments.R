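## Shared machinery for the three experiment drivers.
##
## Every experiment is a pure function of (cfg, seed): the cohort, the
## sessions and every candidate evaluation derive their seeds from the
## master seed, so reruns are bit-identical.  Each candidate connectome is
## simulated once per coupling value against all of a subject's sessions
## (the cheap PP mode), at G = G_frac * G_c(candidate) so that every
## connectome sits at the same relative distance from its own instability.

sim_fc_for <- function(c, cfg, p, seed) {
  cn <- normalize_weights(c, "max")
  p$G <- cfg$G_frac * critical_coupling(cn, p)
  bt <- simulate_bold(cn, p, duration = cfg$session_duration + 30,
                      TR = cfg$TR, dt = cfg$dt, seed = seed,
                      transient = 30, fic = TRUE)
  static_fc(bt$values)
}

cohort_sessions <- function(cohort, cfg, p, seed) {
  lapply(seq_along(cohort$subjects), function(s) {
    cs <- cohort$subjects[[s]]
    cn <- normalize_weights(cs, "max")
    ps <- p
    ps$G <- cfg$G_frac * critical_coupling(cn, ps)
    make_sessions(cn, cfg$n_sessions, ps,
                  duration = cfg$session_duration, TR = cfg$TR, dt = cfg$dt,
                  session_noise = cfg$session_noise,
                  seed = derive_seed(seed, 100L + s), transient = 30,
                  fic = TRUE)
  })
}

pp_rows <- function(fc_sim, sessions, label, subject, G) {
  data.frame(
    connectome_label = label, subject = subject,
    session = seq_along(sessions), coupling_G = G,
    pp = vapply(sessions, function(emp) predictive_power(fc_sim, emp),
                numeric(1)),
    stringsAsFactors = FALSE)
}

#' Predictive-power ranking experiment
#'
#' Runs the full in-silico comparison of connectome variants: builds a
#' cohort, simulates multi-session "empirical" FC from each subject's true
#' connectome, then scores candidate connectomes against those sessions by
#' predictive power.  Candidates per subject: the true connectome (the
#' tracer analog), the union-mask-filtered true connectome (false negatives
#' only), the symmetrized true connectome (directionality removed), the
#' subject's tractography-degraded connectomes (deterministic and
#' probabilistic presets), and the group average of the deterministic
#' degraded connectomes.  Emits the raw PP table plus Welch tests
#' (Bonferroni-corrected), Cohen's d and bootstrap confidence intervals for
#' the planned contrasts.
#'
#' @param cfg a [synth_config()].
#' @param seed master seed; every stage derives its own stream from it.
#' @param p [dmf_params()] template (its `G` is set per connectome).
#' @param n_sim independent stochastic simulations per candidate; each is
#'   scored against all sessions, so PP distributions average over both
#'   session and simulation noise.
#' @param contrasts two-column character matrix of candidate labels to
#'   compare (row = contrast, columns = (a, b), tested as b vs a).
#' @return object of class `pp_ranking`: list with `pp_results` (tidy
#'   data.frame), `contrasts` (tidy stats table), `mean_pp` (per candidate).
#' @export
experiment_pp_ranking <- function(cfg, seed, p = dmf_params(w = cfg$session_w),
                                  n_sim = 3L,
                                  contrasts = rbind(
                                    c("symmetrized", "true"),
                                    c("symmetrized", "filtered"),
                                    c("group-average", "individual-det"),
                                    c("individual-prob", "individual-det"))) {
  stopifnot(inherits(cfg, "synth_config"))
  cohort <- make_cohort(cfg, seed = derive_seed(seed, 1L))
  sessions <- cohort_sessions(cohort, cfg, p, seed)
  ## one degradation seed for the whole cohort: the tractography pipeline's
  ## false-negative/false-positive pattern is systematic, not per-subject
  dets <- lapply(cohort$subjects, function(cs)
    degrade_dmri(cs, "deterministic", seed = derive_seed(seed, 200L),
                 cfg = cfg))
  probs <- lapply(cohort$subjects, function(cs)
    degrade_dmri(cs, "probabilistic", seed = derive_seed(seed, 300L),
                 cfg = cfg))
  avg <- average_group(dets)
  rows <- list()
  for (s in seq_along(cohort$subjects)) {
    cand <- list(
      "true" = cohort$subjects[[s]],
      "filtered" = filter_by_union_mask(cohort$subjects[[s]], dets),
      "symmetrized" = symmetrize(cohort$subjects[[s]]),
      "individual-det" = dets[[s]],
      "individual-prob" = probs[[s]],
      "group-average" = avg)
    for (k in seq_along(cand)) {
      cn <- normalize_weights(cand[[k]], "max")
      G <- cfg$G_frac * critical_coupling(cn, p)
      for (r in seq_len(n_sim)) {
        fc_sim <- sim_fc_for(cand[[k]], cfg, p,
                             seed = derive_seed(seed, 1000L * k + 40L * r + s))
        rows[[length(rows) + 1L]] <-
          pp_rows(fc_sim, sessions[[s]], names(cand)[k], s, G)
      }
    }
  }
  pp_results <- do.call(rbind, rows)
  contr <- contrast_table(pp_results, contrasts, seed)
  mean_pp <- sort(tapply(pp_results$pp, pp_results$connectome_label, mean),
                  decreasing = TRUE)
  structure(list(pp_results = pp_results, contrasts = contr,
                 mean_pp = mean_pp, seed = seed),
            class = "pp_ranking")
}

contrast_table <- function(pp_results, contrasts, seed) {
  m <- nrow(contrasts)
  out <- lapply(seq_len(m), function(i) {
    a <- pp_results$pp[pp_results$connectome_label == contrasts[i, 1]]
    b <- pp_results$pp[pp_results$connectome_label == contrasts[i, 2]]
    wt <- welch_test(a, b)
    ci <- bootstrap_ci_mean_diff(a, b, n_boot = 2000L,
                                 seed = derive_seed(seed, 5000L + i))
    data.frame(comparison = paste(contrasts[i, 2], "vs", contrasts[i, 1]),
               n1 = length(a), n2 = length(b),
               mean1 = mean(a), mean2 = mean(b),
               t = wt$t, p_raw = wt$p, d = cohens_d(a, b),
               ci_lo = ci$lo, ci_hi = ci$hi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_bonferroni <- bonferroni(out$p_raw, m)
  out
}

#' @export
print.pp_ranking <- function(x, ...) {
  cat("<pp_ranking> mean PP by candidate:\n")
  print(round(x$mean_pp, 3))
  cat("contrasts:\n")
  print(x$contrasts[, c("comparison", "mean1", "mean2", "p_bonferroni", "d")],
        digits = 3)
  invisible(x)
}

#' Corrupt one region's connection profile
#'
#' Emulates a region that tractography reconstructs particularly badly:
#' a fraction of its incoming and outgoing connections is deleted and the
#' survivors get a strong multiplicative weight distortion.  Used to set up
#' the hybrid-rescue experiment.
#'
#' @param c a [connectome()].
#' @param region region index whose profile is corrupted.
#' @param drop_frac fraction of the region's connections removed.
#' @param jitter_sd SD of the log-normal distortion on the survivors.
#' @param seed integer seed.
#' @return the corrupted [connectome()].
#' @export
corrupt_region_profile <- function(c, region, drop_frac = 0.7,
                                   jitter_sd = 1, seed) {
  stopifnot(inherits(c, "connectome"))
  n <- n_regions(c)
  if (region < 1 || region > n) stop("region out of range", call. = FALSE)
  with_seed(seed, function() {
    W <- c$weights
    idx <- cbind(c(rep(region, n), seq_len(n)),
                 c(seq_len(n), rep(region, n)))
    idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
    on <- which(W[idx] > 0)
    if (length(on)) {
      drop <- on[runif(length(on)) < drop_frac]
      keep <- setdiff(on, drop)
      W[idx[drop, , drop = FALSE]] <- 0
      W[idx[keep, , drop = FALSE]] <- W[idx[keep, , drop = FALSE]] *
        exp(rnorm(length(keep), 0, jitter_sd))
    }
    if (!c$directed) W <- (W + t(W)) / 2
    connectome(W, c$regions, lengths = c$lengths, directed = c$directed,
               label = paste0(c$label, "-corrupt"))
  })
}

#' Hybrid-substitution scan experiment
#'
#' For every subject, degrades the true connectome with the deterministic
#' tractography preset and additionally corrupts one region's profile with
#' a strong multiplicative weight distortion (emulating a region whose
#' projections tractography misassigns rather than merely misses: wrong
#' strong connections, the harmful failure mode, rather than missing
#' ones).  Then, for every
#' region, builds the hybrid connectome (that region's incoming/outgoing
#' connections replaced by the group reference's) and measures the change
#' in predictive power `dpp = PP(hybrid) - PP(base)` averaged over the
#' subject's sessions.  Reports the per-(subject, region) table, a
#' one-sample t test per region, and each subject's best-rescuing region
#' (`hybrid_best`).
#'
#' @param cfg a [synth_config()].
#' @param seed master seed.
#' @param p [dmf_params()] template.
#' @param corrupt_region region index to corrupt; `NULL` picks one
#'   deterministically from the seed.
#' @param drop_frac,jitter_sd corruption severity
#'   (see [corrupt_region_profile()]).
#' @return object of class `hybrid_scan`: list with `dpp` (subject x region
#'   data.frame), `region_stats` (per-region t, p), `hybrid_best` (per
#'   subject), `corrupt_region`.
#' @export
experiment_hybrid_scan <- function(cfg, seed,
                                   p = dmf_params(w = cfg$session_w),
                                   corrupt_region = NULL, drop_frac = 0,
                                   jitter_sd = 3) {
  stopifnot(inherits(cfg, "synth_config"))
  cohort <- make_cohort(cfg, seed = derive_seed(seed, 1L))
  n <- n_regions(cohort$ground_truth)
  if (is.null(corrupt_region))
    corrupt_region <- 1L + (derive_seed(seed, 77L) %% n)
  sessions <- cohort_sessions(cohort, cfg, p, seed)
  reference <- normalize_weights(cohort$ground_truth, "max")
  rows <- list()
  for (s in seq_along(cohort$subjects)) {
    base <- degrade_dmri(cohort$subjects[[s]], "deterministic",
                         seed = derive_seed(seed, 200L), cfg = cfg)
    base <- corrupt_region_profile(base, corrupt_region, drop_frac,
                                   jitter_sd,
                                   seed = derive_seed(seed, 400L + s))
    base_n <- normalize_weights(base, "max")
    fc_base <- sim_fc_for(base_n, cfg, p, seed = derive_seed(seed, 600L + s))
    pp_base <- mean(vapply(sessions[[s]],
                           function(emp) predictive_power(fc_base, emp),
                           numeric(1)))
    for (r in seq_len(n)) {
      hyb <- hybridize(base_n, reference, r)
      ## common random numbers: every hybrid reuses the base sim seed, so
      ## dpp reflects the structural substitution, not simulation noise,
      ## and substituting with the base itself gives exactly zero
      fc_h <- sim_fc_for(hyb, cfg, p, seed = derive_seed(seed, 600L + s))
      pp_h <- mean(vapply(sessions[[s]],
                          function(emp) predictive_power(fc_h, emp),
                          numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, region = r,
        acronym = cohort$ground_truth$regions$acronym[r],
        hemisphere = cohort$ground_truth$regions$hemisphere[r],
        pp_base = pp_base, pp_hybrid = pp_h, dpp = pp_h - pp_base,
        stringsAsFactors = FALSE)
    }
  }
  dpp <- do.call(rbind, rows)
  region_stats <- do.call(rbind, lapply(split(dpp, dpp$region), function(g) {
    tt <- if (nrow(g) >= 2 && sd(g$dpp) > 0) t_tests(g$dpp, "one_sample")
          else list(t = NA_real_, p = NA_real_)
    data.frame(region = g$region[1], acronym = g$acronym[1],
               hemisphere = g$hemisphere[1], mean_dpp = mean(g$dpp),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  }))
  hybrid_best <- vapply(split(dpp, dpp$subject),
                        function(g) g$region[which.max(g$dpp)], numeric(1))
  structure(list(dpp = dpp, region_stats = region_stats,
                 hybrid_best = hybrid_best,
                 corrupt_region = corrupt_region, seed = seed),
            class = "hybrid_scan")
}

#' @export
print.hybrid_scan <- function(x, ...) {
  cat("<hybrid_scan> corrupted region:", x$corrupt_region, "\n")
  cat("hybrid_best per subject:",
      paste(x$hybrid_best, collapse = ", "), "\n")
  top <- x$region_stats[order(-x$region_stats$mean_dpp)[1:5], ]
  cat("top regions by mean dPP:\n")
  print(top, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Hemispheric lateralization experiment
#'
#' Quantifies how much is lost when the reference connectome's left
#' hemisphere is a mirror image of the right (the construction forced on
#' tracer atlases built from unilateral injections).  For each subject and
#' each left region, the degraded connectome is hybridized with (a) the true
#' group reference and (b) the mirrored reference, and the difference in
#' predictive power (the mirror penalty) is related to the functional
#' lateralization of that region measured on the subject's empirical
#' sessions.  Also substitutes each right region from the mirrored reference
#' to compare left-vs-right substitution effects (paired t test).
#'
#' @param cfg a [synth_config()]; with `asymmetry_eps = 0` the mirrored and
#'   true references coincide and the penalty is identically zero (the
#'   correlation is then undefined and flagged).
#' @param seed master seed.
#' @param p [dmf_params()] template.
#' @return object of class `lateralization_report`: list with `per_region`
#'   (subject x left-region table: pp_true_ref, pp_mirror_ref, penalty,
#'   dpp_left, dpp_right, fc_distance, LI), `correlation` (penalty vs
#'   fc_distance: r, p, possibly NA), `paired_t` (left vs right dpp),
#'   `mean_pp_true_ref`, `mean_pp_mirror_ref`, `degenerate` (logical).
#' @export
experiment_lateralization <- function(cfg, seed,
                                      p = dmf_params(w = cfg$session_w)) {
  stopifnot(inherits(cfg, "synth_config"))
  cohort <- make_cohort(cfg, seed = derive_seed(seed, 1L))
  gt <- cohort$ground_truth
  ref_true <- normalize_weights(gt, "max")
  ref_mirror <- mirror_left_from_right(ref_true)
  sessions <- cohort_sessions(cohort, cfg, p, seed)
  reg <- gt$regions
  left <- which(reg$hemisphere == "L")
  hm <- reg$homotope
  rows <- list()
  for (s in seq_along(cohort$subjects)) {
    base <- degrade_dmri(cohort$subjects[[s]], "deterministic",
                         seed = derive_seed(seed, 200L), cfg = cfg)
    base_n <- normalize_weights(base, "max")
    fc_base <- sim_fc_for(base_n, cfg, p, seed = derive_seed(seed, 600L + s))
    mean_pp <- function(fc) mean(vapply(sessions[[s]],
      function(emp) predictive_power(fc, emp), numeric(1)))
    pp_base <- mean_pp(fc_base)
    emp_mean_fc <- Reduce(`+`, sessions[[s]]) / length(sessions[[s]])
    lat <- fc_lateralization(emp_mean_fc, reg)
    for (k in seq_along(left)) {
      l <- left[k]; r <- hm[l]
      ## common random numbers across the three substitutions and the
      ## base: penalties are paired differences, and with a perfectly
      ## mirrored brain the two references give bit-identical results
      fc_t <- sim_fc_for(hybridize(base_n, ref_true, l), cfg, p,
                         seed = derive_seed(seed, 600L + s))
      fc_m <- sim_fc_for(hybridize(base_n, ref_mirror, l), cfg, p,
                         seed = derive_seed(seed, 600L + s))
      fc_r <- sim_fc_for(hybridize(base_n, ref_mirror, r), cfg, p,
                         seed = derive_seed(seed, 600L + s))
      pp_t <- mean_pp(fc_t); pp_m <- mean_pp(fc_m); pp_r <- mean_pp(fc_r)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, region = l, acronym = reg$acronym[l],
        pp_true_ref = pp_t, pp_mirror_ref = pp_m,
        penalty = pp_t - pp_m,
        dpp_left = pp_m - pp_base, dpp_right = pp_r - pp_base,
        fc_distance = lat$distance[lat$left == l],
        LI = lat$LI[lat$left == l], stringsAsFactors = FALSE)
    }
  }
  per_region <- do.call(rbind, rows)
  degenerate <- cfg$asymmetry_eps == 0 ||
    sd(per_region$penalty) == 0 || sd(per_region$fc_distance) == 0
  correlation <- if (degenerate) list(r = NA_real_, p = NA_real_)
    else pearson_r_p(per_region$penalty, per_region$fc_distance)
  paired_t <- if (sd(per_region$dpp_left - per_region$dpp_right) == 0)
    list(t = NA_real_, p = NA_real_)
    else t_tests(per_region$dpp_left, "paired", per_region$dpp_right)
  structure(list(per_region = per_region, correlation = correlation,
                 paired_t = paired_t,
                 mean_pp_true_ref = mean(per_region$pp_true_ref),
                 mean_pp_mirror_ref = mean(per_region$pp_mirror_ref),
                 degenerate = degenerate, seed = seed),
            class = "lateralization_report")
}

#' @export
print.lateralization_report <- function(x, ...) {
  cat("<lateralization_report>\n")
  cat(sprintf("  mean PP, true-left reference:   %.3f\n", x$mean_pp_true_ref))
  cat(sprintf("  mean PP, mirrored reference:    %.3f\n", x$mean_pp_mirror_ref))
  if (x$degenerate) {
    cat("  mirror penalty degenerate (no lateralization in config)\n")
  } else {
    cat(sprintf("  penalty ~ FC lateralization: r = %.3f (p = %.3g)\n",
                x$correlation$r, x$correlation$p))
  }
  invisible(x)
}
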