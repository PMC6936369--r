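## Accept a plain time x region matrix, a bold_trace or a neural_trace.
as_ts <- function(ts) {
  if (inherits(ts, "bold_trace") || inherits(ts, "neural_trace"))
    ts <- ts$values
  ts <- as.matrix(ts)
  storage.mode(ts) <- "double"
  ts
}

upper_tri <- function(m) m[upper.tri(m)]

#' Global signal regression
#'
#' Regresses every region's time series on the spatial mean series (with an
#' intercept) and returns the residuals.  Removes global fluctuations shared
#' by all regions, a standard preprocessing step that sharpens
#' structure-function relations.
#'
#' @param ts time x region matrix (or a bold trace).
#' @return matrix of residuals with the same shape.
#' @export
global_signal_regress <- function(ts) {
  x <- as_ts(ts)
  if (nrow(x) < 2L) stop("need >= 2 time points", call. = FALSE)
  g <- rowMeans(x)
  if (sd(g) == 0) stop("constant global signal", call. = FALSE)
  X <- cbind(1, g)
  x - X %*% solve(crossprod(X), crossprod(X, x))
}

#' Static functional connectivity
#'
#' Pairwise Pearson correlation of the region time series.
#'
#' @param ts time x region matrix (or a bold trace).
#' @return N x N correlation matrix (symmetric, unit diagonal).
#' @export
static_fc <- function(ts) {
  x <- as_ts(ts)
  if (nrow(x) < 3L) stop("need >= 3 time points", call. = FALSE)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0))
    stop("constant time series in region ", which(sds == 0)[1], call. = FALSE)
  fc <- cor(x)
  dimnames(fc) <- dimnames(x)[c(2, 2)]
  fc
}

#' Predictive power of a simulated FC for an empirical FC
#'
#' Pearson correlation between the strictly upper-triangular parts of the
#' two FC matrices (diagonal excluded).  This is the standard scalar used to
#' score how well a connectome-based simulation reproduces an empirically
#' measured functional connectome.
#'
#' @param sim,emp square FC matrices of identical dimension.
#' @return correlation in \[-1, 1\].
#' @export
predictive_power <- function(sim, emp) {
  sim <- as.matrix(sim); emp <- as.matrix(emp)
  if (!identical(dim(sim), dim(emp)))
    stop("dimension mismatch: ", nrow(sim), " vs ", nrow(emp), call. = FALSE)
  a <- upper_tri(sim); b <- upper_tri(emp)
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero-variance upper triangle", call. = FALSE)
  cor(a, b)
}

#' Sliding-window functional connectivity dynamics (FCD)
#'
#' Computes FC in boxcar sliding windows and correlates the upper-triangular
#' FC vectors of every pair of windows.  Blocks of high FCD correlation
#' ("checkerboard" patterns) indicate epochs during which the functional
#' configuration is stable, separated by switches.
#'
#' @param ts time x region matrix (or a bold trace).
#' @param window window length in samples (>= 3).
#' @param step window step in samples.
#' @return list with `values` (n_win x n_win FCD matrix), `window`, `step`,
#'   and `windows` (start index of each window).
#' @export
fcd <- function(ts, window = 60L, step = 5L) {
  x <- as_ts(ts)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 3L) stop("window must span >= 3 samples", call. = FALSE)
  if (nrow(x) < window) stop("series shorter than one window", call. = FALSE)
  starts <- seq(1L, nrow(x) - window + 1L, by = step)
  vecs <- vapply(starts, function(s)
    upper_tri(static_fc(x[s:(s + window - 1L), , drop = FALSE])),
    numeric(ncol(x) * (ncol(x) - 1L) / 2L))
  m <- cor(vecs)
  diag(m) <- 1
  list(values = m, window = window, step = step, windows = starts)
}

#' Functional meta-connectivity (FMC)
#'
#' Correlations between the windowed-FC time courses of individual links:
#' each retained link contributes the series of its FC value across sliding
#' windows, and FMC is the link x link Pearson correlation matrix of those
#' series.
#'
#' @param ts time x region matrix (or a bold trace).
#' @param window,step sliding window length and step in samples.
#' @param links optional integer indices into the upper-triangular link
#'   ordering (column-major, as `which(upper.tri(m))` enumerates them);
#'   default all links.
#' @return list with `values` (link x link matrix), `links` and the
#'   two-column `link_pairs` (region indices of each retained link).
#' @export
fmc <- function(ts, window = 60L, step = 5L, links = NULL) {
  x <- as_ts(ts)
  n <- ncol(x)
  nl <- n * (n - 1L) / 2L
  if (is.null(links)) links <- seq_len(nl)
  if (any(links < 1L | links > nl)) stop("link index out of range", call. = FALSE)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 3L) stop("window must span >= 3 samples", call. = FALSE)
  starts <- seq(1L, nrow(x) - window + 1L, by = step)
  if (length(starts) < 3L) stop("need >= 3 windows", call. = FALSE)
  series <- vapply(starts, function(s)
    upper_tri(static_fc(x[s:(s + window - 1L), , drop = FALSE]))[links],
    numeric(length(links)))
  series <- t(series)  # window x link
  csd <- apply(series, 2L, sd)
  if (any(csd == 0))
    stop("constant link series for link ", links[which(csd == 0)[1]],
         call. = FALSE)
  m <- cor(series)
  diag(m) <- 1
  ut_idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  list(values = m, links = links, link_pairs = ut_idx[links, , drop = FALSE])
}

#' Intersession vs intersubject FC similarity
#'
#' For a labelled collection of per-session FC matrices, returns the Pearson
#' correlations of the upper-triangular FC vectors for all within-subject
#' session pairs (intersession) and all cross-subject session pairs
#' (intersubject).  A cohort whose intersession similarity exceeds its
#' intersubject similarity carries an individual functional fingerprint.
#'
#' @param fcs list of FC matrices.
#' @param subjects vector of subject labels, one per FC matrix.
#' @return list with numeric vectors `intersession` and `intersubject`.
#' @export
session_similarity <- function(fcs, subjects) {
  if (length(fcs) != length(subjects))
    stop("one subject label per FC matrix required", call. = FALSE)
  if (length(unique(subjects)) < 2L)
    stop("need >= 2 subjects", call. = FALSE)
  vecs <- vapply(fcs, function(f) upper_tri(as.matrix(f)),
                 numeric(length(upper_tri(as.matrix(fcs[[1]])))))
  within <- c(); across <- c()
  k <- length(fcs)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    r <- cor(vecs[, i], vecs[, j])
    if (subjects[i] == subjects[j]) within <- c(within, r)
    else across <- c(across, r)
  }
  list(intersession = within, intersubject = across)
}

#' Functional lateralization of homotopic regions
#'
#' For each left region and its right homotope, computes the Euclidean
#' distance between the region's intrahemispheric-left FC profile and the
#' homotope's intrahemispheric-right profile (entries ordered by homotopy,
#' the self pair excluded), plus the lateralization index
#' `LI = 1 / (1 + d)`: identical profiles give `LI = 1`, and LI decreases
#' strictly with the distance.
#'
#' @param fc N x N FC matrix.
#' @param regions region table with a complete homotope map.
#' @return data.frame with `acronym`, `left`, `right` (indices), `distance`
#'   and `LI`, one row per homotopic pair.
#' @export
fc_lateralization <- function(fc, regions) {
  fc <- as.matrix(fc)
  validate_region_table(regions)
  left <- which(regions$hemisphere == "L")
  hm <- regions$homotope
  out <- data.frame(acronym = regions$acronym[left], left = left,
                    right = hm[left], distance = NA_real_, LI = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(left)) {
    l <- left[k]; r <- hm[l]
    others <- setdiff(left, l)
    pl <- fc[l, others]
    pr <- fc[r, hm[others]]
    d <- sqrt(sum((pl - pr)^2))
    out$distance[k] <- d
    out$LI[k] <- 1 / (1 + d)
  }
  out
}

#' Scan the global coupling and score a connectome's predictive power
#'
#' For each value of the global coupling G, simulates one resting-state BOLD
#' session with the connectome and computes the predictive power against
#' every empirical session FC.  `G_star` is the grid value maximizing the
#' mean PP.  With `per_session = TRUE` a fresh simulation (fresh noise seed)
#' is run for every session instead of reusing one simulation per G.
#'
#' @param c a [connectome()] (max-normalized internally).
#' @param sessions list of empirical FC matrices.
#' @param p [dmf_params()]; its `G` field is overridden by the grid.
#' @param grid numeric vector of G values (nonempty).
#' @param h [hemodynamic_params()].
#' @param duration,TR,dt simulation settings passed to [simulate_bold()].
#' @param seed master seed; per-(G, session) seeds are derived from it.
#' @param per_session one simulation per session (TRUE) or per G (FALSE).
#' @param fic use homeostatic input compensation (see [simulate_bold()]).
#' @param label connectome label stored in the result rows.
#' @param subject optional subject id stored in the result rows.
#' @return object of class `coupling_scan`: list with `results` (data.frame
#'   `connectome_label`, `subject`, `session`, `coupling_G`, `pp`) and
#'   `G_star`.
#' @export
scan_coupling <- function(c, sessions, p = dmf_params(), grid,
                          h = hemodynamic_params(), duration = 300,
                          TR = 1, dt = 0.1, seed = 1L,
                          per_session = FALSE, label = c$label,
                          subject = NA, fic = TRUE) {
  if (length(grid) == 0L) stop("empty coupling grid", call. = FALSE)
  if (length(sessions) == 0L) stop("no sessions", call. = FALSE)
  cn <- normalize_weights(c, "max")
  rows <- list()
  for (gi in seq_along(grid)) {
    p$G <- grid[gi]
    sim_fc <- NULL
    if (!per_session) {
      bt <- tryCatch(
        simulate_bold(cn, p, h, duration = duration, TR = TR, dt = dt,
                      seed = derive_seed(seed, gi), fic = fic),
        error = function(e) stop("simulation failed at G = ", grid[gi], ": ",
                                 conditionMessage(e), call. = FALSE))
      sim_fc <- static_fc(bt)
    }
    for (si in seq_along(sessions)) {
      if (per_session) {
        bt <- simulate_bold(cn, p, h, duration = duration, TR = TR, dt = dt,
                            seed = derive_seed(seed, gi * 10000L + si),
                            fic = fic)
        sim_fc <- static_fc(bt)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        connectome_label = label, subject = subject, session = si,
        coupling_G = grid[gi], pp = predictive_power(sim_fc, sessions[[si]]),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  mean_pp <- tapply(results$pp, results$coupling_G, mean)
  G_star <- as.numeric(names(mean_pp))[which.max(mean_pp)]
  structure(list(results = results, G_star = G_star), class = "coupling_scan")
}

#' @export
print.coupling_scan <- function(x, ...) {
  mean_pp <- tapply(x$results$pp, x$results$coupling_G, mean)
  cat("<coupling_scan> G grid:", paste(names(mean_pp), collapse = ", "), "\n")
  cat("  mean PP:", paste(sprintf("%.3f", mean_pp), collapse = ", "), "\n")
  cat("  G* =", x$G_star, "\n")
  invisible(x)
}
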