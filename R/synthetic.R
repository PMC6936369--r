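#' Configuration of the synthetic study cohort
#'
#' Bundles every parameter of the synthetic ground truth, the cohort
#' individuality model, the tractography-like degradation and the session
#' generator.  The defaults define a desk-scale stand-in for a mouse study:
#' a directed, weighted, bihemispheric "tracer-like" ground-truth connectome
#' whose left hemisphere is a perturbed mirror of the right; a cohort of
#' subjects sharing that backbone with individual weight jitter and sparse
#' edge flips; and multi-session resting-state recordings simulated from
#' each subject's true connectome.
#'
#' @param n_per_hemisphere regions per hemisphere (default 20, N = 40).
#' @param density target directed connection density in (0, 1].
#' @param weight_mu,weight_sigma mean and SD of the log connection weights
#'   (before the distance decay).
#' @param weight_decay exponential distance rule: log-weights decrease by
#'   `weight_decay` per mm of tract length, so long-range connections are
#'   systematically weak, as in tracer connectomes.
#' @param length_scale mm scale of the distance-dependent wiring probability
#'   `exp(-d / length_scale)`.
#' @param homotopic_boost presence/weight multiplier for homotopic
#'   (mirror-image) contralateral links, which are anatomically the
#'   strongest callosal projections.
#' @param dir_sigma SD of the log ratio between the two directions of a
#'   connection pair (tracer connectomes are strongly asymmetric).
#' @param p_uni probability that one direction of a pair is absent
#'   (unidirectional connection).
#' @param asymmetry_eps SD of the multiplicative log-perturbation applied to
#'   left-seeded connections after mirroring (0 = perfectly mirrored brain).
#' @param subject_jitter SD of the per-subject multiplicative log-jitter on
#'   connection weights.
#' @param flip_rate per-edge probability of a subject-specific edge removal
#'   (matched in expectation by subject-specific additions).
#' @param n_subjects,n_sessions cohort size and recordings per subject.
#' @param session_duration recorded BOLD length per session (s).
#' @param TR BOLD sampling period (s).
#' @param dt integration step (ms).
#' @param session_noise additive measurement noise on BOLD, as a fraction of
#'   the mean regional BOLD SD.
#' @param G_frac operating coupling, as a fraction of each connectome's own
#'   critical coupling [critical_coupling()]; sessions and candidate
#'   evaluations both use `G = G_frac * G_c(connectome)`.
#' @param session_w local recurrence used for resting-state sessions.  The
#'   default 0.6 puts each node in a monostable low-activity configuration,
#'   so the network can be driven close to its critical coupling (where
#'   connectome-shaped fluctuations dominate the FC) without the runaway
#'   escape to the high-activity attractor that the bistable node setting
#'   suffers at desk scale; see the methods vignette.
#' @param length_decay_det,fp_rate_det deterministic-tractography preset:
#'   strong length-dependent false negatives, few false positives.
#' @param length_decay_prob,fp_rate_prob probabilistic-tractography preset:
#'   weaker false-negative filter, many more false positives.
#' @param fp_quantile false-positive weights are drawn uniformly below this
#'   quantile of the true nonzero weights.  The default 1.0 allows
#'   occasional strong spurious bundles, the characteristic failure mode of
#'   probabilistic streamline counting; lower it to keep all spurious
#'   connections weak.
#' @param master_seed integer seed all cohort randomness derives from.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_per_hemisphere = 20L, density = 0.6,
                         weight_mu = 0, weight_sigma = 1,
                         weight_decay = 0.5,
                         length_scale = 3, homotopic_boost = 3,
                         dir_sigma = 1.5, p_uni = 0.3,
                         asymmetry_eps = 0.3, subject_jitter = 1.0,
                         flip_rate = 0.10, n_subjects = 5L,
                         n_sessions = 4L, session_duration = 300,
                         TR = 1, dt = 0.1, session_noise = 0.05,
                         G_frac = 0.88, session_w = 0.6,
                         length_decay_det = 0.10, fp_rate_det = 0.02,
                         length_decay_prob = 0.05, fp_rate_prob = 0.15,
                         fp_quantile = 1.0, master_seed = 42L) {
  cfg <- as.list(environment())
  if (cfg$density <= 0 || cfg$density > 1)
    stop("density must be in (0, 1]", call. = FALSE)
  if (cfg$asymmetry_eps < 0) stop("asymmetry_eps must be >= 0", call. = FALSE)
  for (nm in c("n_per_hemisphere", "n_subjects", "n_sessions"))
    if (cfg[[nm]] < 1) stop(nm, " must be >= 1", call. = FALSE)
  structure(cfg, class = "synth_config")
}

#' Generate the ground-truth connectome
#'
#' Builds a directed weighted bihemispheric connectome: random region
#' centroids (right hemisphere sampled, left mirrored across the midline),
#' connection probability decaying with Euclidean distance, log-normal
#' weights with pairwise directional asymmetry and occasional unidirectional
#' pairs, boosted homotopic links, and tract lengths equal to centroid
#' distances.  The left hemisphere is first built as an exact mirror of the
#' right, then (for `asymmetry_eps > 0`) all left-seeded connections receive
#' a multiplicative log-normal perturbation, so the brain is lateralized by
#' a controlled amount.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed (default `cfg$master_seed`).
#' @return a directed [connectome()] labelled `"ground-truth"`.
#' @export
make_ground_truth <- function(cfg, seed = cfg$master_seed) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(seed, function() {
    n <- cfg$n_per_hemisphere
    N <- 2L * n
    ## centroids: right hemisphere x > 0, left is the mirror image
    cen_r <- cbind(runif(n, 0.5, 4.5), runif(n, 0, 8), runif(n, 0, 5))
    cen <- rbind(cen_r * c(-1, 1, 1)[col(cen_r)], cen_r)  # left rows first
    reg <- region_table(n, centroids = cen)
    d <- as.matrix(dist(cen))
    left <- which(reg$hemisphere == "L")
    right <- which(reg$hemisphere == "R")
    hm <- reg$homotope

    ## wiring probability: exp(-d / length_scale), scaled so the expected
    ## directed density (after unidirectional dropout) hits the target
    q <- exp(-d / cfg$length_scale)
    diag(q) <- 0
    target_pair <- cfg$density / (1 - cfg$p_uni / 2)
    off <- q[upper.tri(q)]
    f <- function(s) mean(pmin(1, s * off)) - target_pair
    if (f(1e6) < -1e-3)
      stop("density target ", cfg$density,
           " unreachable at length_scale ", cfg$length_scale, call. = FALSE)
    s <- uniroot(f, c(1e-9, 1e6), tol = 1e-10)$root
    pmat <- s * q
    pmat[pmat > 1] <- 1
    ## homotopic links: boosted presence and weight
    for (l in left) pmat[hm[l], l] <-
      min(1, cfg$homotopic_boost * pmat[hm[l], l])

    W <- matrix(0, N, N)
    ## right intrahemispheric pairs: shared base weight (exponential
    ## distance rule), asymmetric split
    for (a in right) for (b in right) if (a < b) {
      if (runif(1) < pmat[a, b]) {
        base <- exp(rnorm(1, cfg$weight_mu - cfg$weight_decay * d[a, b],
                          cfg$weight_sigma))
        W[a, b] <- base * exp(rnorm(1, 0, cfg$dir_sigma))
        W[b, a] <- base * exp(rnorm(1, 0, cfg$dir_sigma))
        if (runif(1) < cfg$p_uni) {
          if (runif(1) < 0.5) W[a, b] <- 0 else W[b, a] <- 0
        }
      }
    }
    ## right-seeded contralateral entries (left rows come from the mirror)
    for (a in right) for (b in left) {
      if (runif(1) < pmat[a, b] * (1 - cfg$p_uni / 2)) {
        wgt <- exp(rnorm(1, cfg$weight_mu - cfg$weight_decay * d[a, b],
                         cfg$weight_sigma))
        if (b == hm[a]) wgt <- wgt * cfg$homotopic_boost
        W[a, b] <- wgt
      }
    }
    ## mirror right -> left, then lateralize the left rows
    W[left, left] <- W[hm[left], hm[left]]
    W[left, hm[left]] <- W[hm[left], left]
    if (cfg$asymmetry_eps > 0) {
      pert <- matrix(exp(rnorm(length(left) * N, 0, cfg$asymmetry_eps)),
                     length(left), N)
      W[left, ] <- W[left, ] * pert
    }
    diag(W) <- 0
    connectome(W, reg, lengths = d, directed = TRUE, label = "ground-truth")
  })
}

#' Generate a cohort of individual connectomes
#'
#' Each subject's connectome is the shared ground truth with a subject-
#' specific multiplicative log-normal weight jitter (one factor per
#' unordered region pair, so individual strengths vary while the backbone's
#' direction ratios are shared) plus sparse edge flips (a few removals and
#' additions), so subjects differ both in weight distribution and in
#' topology while remaining correlated through the common backbone.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed (default `cfg$master_seed`).
#' @return list with `ground_truth` (the shared backbone) and `subjects`
#'   (list of `n_subjects` directed [connectome()]s labelled `"sub-01"`...).
#' @export
make_cohort <- function(cfg, seed = cfg$master_seed) {
  stopifnot(inherits(cfg, "synth_config"))
  gt <- make_ground_truth(cfg, seed = seed)
  subjects <- lapply(seq_len(cfg$n_subjects), function(s) {
    with_seed(derive_seed(seed, s), function() {
      W <- gt$weights
      N <- nrow(W)
      ## pairwise multiplicative jitter: one factor per unordered pair, so
      ## a subject's connection strengths are individual while the
      ## direction ratios of the shared backbone are preserved
      F <- matrix(exp(rnorm(N * N, 0, cfg$subject_jitter)), N, N)
      F[lower.tri(F)] <- t(F)[lower.tri(F)]
      nz <- which(W > 0)
      W[nz] <- W[nz] * F[nz]
      if (cfg$flip_rate > 0) {
        drop <- nz[runif(length(nz)) < cfg$flip_rate]
        offdiag <- which(W == 0 & row(W) != col(W))
        add_rate <- cfg$flip_rate * length(nz) / max(1, length(offdiag))
        add <- offdiag[runif(length(offdiag)) < add_rate]
        W[drop] <- 0
        W[add] <- exp(rnorm(length(add),
                            cfg$weight_mu - cfg$weight_decay * gt$lengths[add],
                            cfg$weight_sigma))
      }
      connectome(W, gt$regions, lengths = gt$lengths, directed = TRUE,
                 label = sprintf("sub-%02d", s))
    })
  })
  list(ground_truth = gt, subjects = subjects)
}

#' Tractography-like degradation of a connectome
#'
#' Emulates what diffusion-MRI tractography does to a true connectome:
#' every true directed edge is dropped with probability
#' `1 - exp(-length_decay * length)` (false negatives, preferentially
#' long-range), the result is symmetrized (tractography cannot see
#' directionality), and spurious symmetric edges are added at rate
#' `fp_rate` on absent pairs with weights drawn from the low quantiles of
#' the true weight distribution (false positives are weak).  The
#' `"deterministic"` preset has strong false-negative pruning and almost no
#' false positives (high specificity, low sensitivity); the
#' `"probabilistic"` preset the converse.
#'
#' @param c a directed [connectome()] with lengths.
#' @param mode `"deterministic"` or `"probabilistic"` preset.
#' @param length_decay false-negative rate per mm; `NULL` uses the preset.
#' @param fp_rate probability that an absent pair gains a spurious edge,
#'   in \[0, 1); `NULL` uses the preset.
#' @param seed integer seed; degradations of two connectomes under the
#'   same seed share their false-negative and false-positive patterns
#'   (pipeline biases are systematic across subjects), while different
#'   seeds give independent patterns.
#' @param cfg a [synth_config()] supplying the presets.
#' @return an undirected [connectome()] labelled `"dmri-<mode>"`.
#' @export
degrade_dmri <- function(c, mode = c("deterministic", "probabilistic"),
                         length_decay = NULL, fp_rate = NULL, seed,
                         cfg = synth_config()) {
  stopifnot(inherits(c, "connectome"))
  mode <- match.arg(mode)
  if (is.null(c$lengths)) stop("lengths required", call. = FALSE)
  if (is.null(length_decay))
    length_decay <- if (mode == "deterministic") cfg$length_decay_det
                    else cfg$length_decay_prob
  if (is.null(fp_rate))
    fp_rate <- if (mode == "deterministic") cfg$fp_rate_det
               else cfg$fp_rate_prob
  if (fp_rate >= 1) stop("fp_rate must be < 1", call. = FALSE)
  with_seed(seed, function() {
    ## cell-aligned random fields: two connectomes degraded with the same
    ## seed share their false-negative / false-positive pattern, emulating
    ## the systematic (not subject-specific) biases of a tractography
    ## pipeline -- everyone misses the same long tracts.
    N <- n_regions(c)
    u_drop <- matrix(runif(N * N), N, N)
    u_add <- matrix(runif(N * N), N, N)
    w_fp <- matrix(runif(N * N), N, N)
    W <- c$weights
    nz <- which(W > 0)
    p_drop <- 1 - exp(-length_decay * c$lengths[nz])
    W[nz[u_drop[nz] < p_drop]] <- 0
    sym <- symmetrize(connectome(W, c$regions, lengths = c$lengths,
                                 directed = TRUE, label = c$label))
    Ws <- sym$weights
    if (fp_rate > 0) {
      true_w <- c$weights[c$weights > 0]
      lo <- quantile(true_w, cfg$fp_quantile, names = FALSE)
      absent <- which(Ws == 0 & upper.tri(Ws))
      add <- absent[u_add[absent] < fp_rate]
      if (length(add)) {
        wts <- w_fp[add] * lo
        Ws[add] <- wts
        Ws[cbind(col(Ws)[add], row(Ws)[add])] <- wts
      }
    }
    connectome(Ws, c$regions, lengths = c$lengths, directed = FALSE,
               label = paste0("dmri-", if (mode == "deterministic") "det" else "prob"))
  })
}

#' Simulate multi-session functional data from a true connectome
#'
#' Runs `n_sessions` independent resting-state simulations from the (true)
#' connectome, each with its own derived noise seed, optionally adds
#' measurement noise to the BOLD, and returns the per-session static FC
#' matrices.  Sessions emulate repeated recordings of one subject: they
#' share the structural ground truth and differ only in dynamical and
#' measurement noise.
#'
#' @param c_true the subject's true [connectome()] (any weight scale; it is
#'   max-normalized internally).
#' @param n_sessions number of sessions.
#' @param p [dmf_params()] (set `p$G` to the cohort coupling).
#' @param h [hemodynamic_params()].
#' @param duration,TR,dt session settings: recorded length (s), sampling
#'   period (s), integration step (ms).
#' @param session_noise additive BOLD noise, as a fraction of the mean
#'   regional BOLD SD.
#' @param seed integer seed; session `i` uses seed `derive(seed, i)`.
#' @param transient discarded settle-in time (s), simulated on top of
#'   `duration`; 30 s covers both neural and hemodynamic settling.
#' @param fic use homeostatic input compensation (see [simulate_bold()]).
#' @return list of `n_sessions` FC matrices.
#' @export
make_sessions <- function(c_true, n_sessions, p = dmf_params(),
                          h = hemodynamic_params(), duration = 300, TR = 1,
                          dt = 0.1, session_noise = 0, seed, transient = 30,
                          fic = TRUE) {
  cn <- normalize_weights(c_true, "max")
  lapply(seq_len(n_sessions), function(i) {
    s_i <- derive_seed(seed, i)
    bt <- tryCatch(
      simulate_bold(cn, p, h, duration = duration + transient, TR = TR,
                    dt = dt, seed = s_i, transient = transient, fic = fic),
      error = function(e) stop("session ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    vals <- bt$values
    if (session_noise > 0) {
      scale <- session_noise * mean(apply(vals, 2L, sd))
      vals <- vals + with_seed(derive_seed(s_i, 999L), function()
        matrix(rnorm(length(vals), 0, scale), nrow(vals), ncol(vals)))
    }
    static_fc(vals)
  })
}
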