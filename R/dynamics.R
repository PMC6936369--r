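#' Parameters of the reduced Wong-Wang dynamic mean-field model
#'
#' One cortical region is reduced to a single slow synaptic gating variable
#' `S` with
#' `dS/dt = -S / tau_s + (1 - S) * gamma * H(x)`,
#' `x = w * J_N * S + G * J_N * sum_j C_ji S_j + I_0`,
#' where `H` is the sigmoidal current-to-rate transfer function
#' (see [transfer_rate()]) and `C_ji` the (max-normalized) structural weight
#' from source `j` to target `i`.  The defaults put the isolated node in the
#' bistable regime (a low and a high stable firing state separated by an
#' unstable one), which is what lets noise drive switching between
#' functional configurations; bistability can be checked at any parameter
#' setting with [find_fixed_points()].
#'
#' @param a gain of the transfer function (1/nA).
#' @param b threshold current scale (Hz).
#' @param d curvature of the transfer function (s).
#' @param gamma kinetic rate of gating activation (1/s).
#' @param tau_s gating decay time constant (ms).
#' @param J_N synaptic coupling (nA).
#' @param w local excitatory recurrence (dimensionless); the default 1.0 is
#'   the classical bistable operating point of the isolated node.
#' @param I_0 background input current (nA).
#' @param G global coupling scaling of the network input (dimensionless
#'   and nonnegative).
#' @param sigma noise amplitude (nA, >= 0; 0 gives deterministic dynamics).
#' @return a list of class `dmf_params`.
#' @export
dmf_params <- function(a = 270, b = 108, d = 0.154, gamma = 0.641,
                       tau_s = 100, J_N = 0.2609, w = 1.0, I_0 = 0.32,
                       G = 0, sigma = 0.015) {
  p <- list(a = a, b = b, d = d, gamma = gamma, tau_s = tau_s, J_N = J_N,
            w = w, I_0 = I_0, G = G, sigma = sigma)
  pos <- c("a", "b", "d", "gamma", "tau_s", "J_N", "w", "I_0")
  for (nm in pos) if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
    stop(nm, " must be strictly positive", call. = FALSE)
  if (!is.finite(G) || G < 0) stop("G must be >= 0", call. = FALSE)
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(p, class = "dmf_params")
}

#' Balloon-Windkessel hemodynamic parameters
#'
#' Classical constants of the hemodynamic cascade that maps synaptic
#' activity to BOLD: vasodilatory signal `s`, inflow `f`, venous volume `v`
#' and deoxyhemoglobin content `q`, integrated per region as
#' `ds/dt = S(t) - kappa s - gamma_h (f - 1)`, `df/dt = s`,
#' `tau dv/dt = f - v^(1/alpha)`,
#' `tau dq/dt = f (1 - (1 - rho)^(1/f)) / rho - q v^(1/alpha - 1)`,
#' with BOLD (percent signal change)
#' `100 V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))`.
#'
#' @param kappa rate of vasodilatory signal decay (1/s).
#' @param gamma_h rate of flow-dependent feedback (1/s).
#' @param tau hemodynamic transit time (s).
#' @param alpha Grubb's vessel stiffness exponent, in (0, 1).
#' @param rho resting oxygen extraction fraction, in (0, 1).
#' @param V0 resting venous blood volume fraction.
#' @param k1,k2,k3 BOLD signal weights; defaults `7 rho`, `2`, `2 rho - 0.2`.
#' @return a list of class `hemodynamic_params`.
#' @export
hemodynamic_params <- function(kappa = 0.65, gamma_h = 0.41, tau = 0.98,
                               alpha = 0.32, rho = 0.34, V0 = 0.02,
                               k1 = 7 * rho, k2 = 2, k3 = 2 * rho - 0.2) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (rho <= 0 || rho >= 1) stop("rho must be in (0, 1)", call. = FALSE)
  for (nm in c("kappa", "gamma_h", "tau", "V0"))
    if (get(nm) <= 0) stop(nm, " must be > 0", call. = FALSE)
  structure(list(kappa = kappa, gamma_h = gamma_h, tau = tau, alpha = alpha,
                 rho = rho, V0 = V0, k1 = k1, k2 = k2, k3 = k3),
            class = "hemodynamic_params")
}

#' Current-to-rate transfer function
#'
#' `H(x) = (a x - b) / (1 - exp(-d (a x - b)))`, the effective population
#' input-output curve of the reduced Wong-Wang model.  The removable
#' singularity at `a x = b` is handled analytically (`H = 1/d` there).
#'
#' @param x input current (nA), vectorized.
#' @param p [dmf_params()].
#' @return firing rate (Hz).
#' @export
transfer_rate <- function(x, p = dmf_params()) {
  .dmf_transfer_cpp(as.numeric(x), p$a, p$b, p$d)
}

#' Deterministic drift of the gating variables
#'
#' `dS_i/dt = -S_i / tau_s + (1 - S_i) gamma H(x_i)` with
#' `x_i = w J_N S_i + G J_N sum_j C_ji S_j + I_0` (region `i` receives from
#' its incoming edges `j -> i`).  Time is in seconds.
#'
#' @param S gating vector in \[0, 1\]^N.
#' @param c a [connectome()] (max-normalized weights expected), or `NULL`
#'   for a single isolated node.
#' @param p [dmf_params()].
#' @return dS/dt (1/s), same length as `S`.
#' @export
dmf_drift <- function(S, c = NULL, p = dmf_params()) {
  S <- as.numeric(S)
  coup <- if (is.null(c)) {
    rep(0, length(S))
  } else {
    stopifnot(inherits(c, "connectome"))
    if (length(S) != n_regions(c))
      stop("S has length ", length(S), " but connectome has ",
           n_regions(c), " regions", call. = FALSE)
    as.numeric(crossprod(c$weights, S))  # sum_j W[j, i] S_j
  }
  x <- p$w * p$J_N * S + p$G * p$J_N * coup + p$I_0
  -S / (p$tau_s / 1000) + (1 - S) * p$gamma * transfer_rate(x, p)
}

#' Fixed points of the isolated node
#'
#' Finds all roots of the single-node drift in \[0, 1\] (with `G = 0` and no
#' noise) by dense bracketing and bisection, and classifies their stability
#' from the sign of the drift's derivative.  In the bistable configuration
#' this returns two stable roots separated by an unstable one.
#'
#' @param p [dmf_params()].
#' @param grid_n number of bracketing intervals (default 2000).
#' @return data.frame with columns `S` and `stable`.
#' @export
find_fixed_points <- function(p = dmf_params(), grid_n = 2000L) {
  f <- function(S) dmf_drift(S, NULL, p)
  grid <- seq(0, 1, length.out = grid_n + 1L)
  vals <- f(grid)
  roots <- grid[vals == 0]
  for (k in seq_len(grid_n)) {
    if (vals[k] == 0 || vals[k + 1L] == 0) next
    if (sign(vals[k]) != sign(vals[k + 1L])) {
      r <- uniroot(f, c(grid[k], grid[k + 1L]), tol = 1e-14)$root
      roots <- c(roots, r)
    }
  }
  roots <- sort(unique(roots))
  eps <- 1e-7
  stable <- vapply(roots, function(r) {
    lo <- max(0, r - eps); hi <- min(1, r + eps)
    (f(hi) - f(lo)) / (hi - lo) < 0
  }, logical(1))
  data.frame(S = roots, stable = stable)
}

#' Simulate the coupled reduced Wong-Wang network
#'
#' Euler-Maruyama integration of the gating dynamics on a connectome, with
#' independent per-region noise streams derived from one master seed by a
#' counter-based scheme (so a given region's noise does not depend on how
#' many other regions are simulated, and identical `(seed, inputs)` give
#' bit-identical output).  Noise is generated on a fixed grid of
#' `noise_dt`-millisecond buckets and applied as a Wiener kick of standard
#' deviation `sigma * sqrt(noise_dt / 1000)` at each bucket start, so the
#' driving noise path is unchanged when `dt` is refined.  `S` is clamped to
#' \[0, 1\] after every step.  The initial transient is discarded.
#'
#' @param c a max-normalized [connectome()].
#' @param p [dmf_params()].
#' @param duration total simulated time (s), transient included.
#' @param dt integration step (ms).
#' @param seed integer master seed.
#' @param transient initial time discarded (s).
#' @param init initial gating vector; default: the lowest stable fixed point
#'   of the isolated node, replicated.
#' @param store_dt sampling step of the returned trace (ms; default `dt`).
#' @param noise_dt noise bucket length (ms); must be a multiple of `dt`.
#' @return a `neural_trace`: list with `values` (time x region matrix of
#'   `S`), `dt` (ms, sampling step of `values`), `transient_discarded` (ms).
#' @export
simulate_dmf <- function(c, p = dmf_params(), duration, dt = 0.1, seed,
                         transient = 10, init = NULL, store_dt = dt,
                         noise_dt = 1, fic = FALSE) {
  check_sim_args(c, duration, dt, transient, noise_dt)
  if (is.null(init)) init <- rep(low_stable_root(p), n_regions(c))
  if (length(init) != n_regions(c))
    stop("init has wrong length", call. = FALSE)
  out <- .dmf_core_cpp(c$weights, unclass(p), unclass(hemodynamic_params()),
                       duration, dt, transient, 1, as.integer(seed),
                       as.numeric(init), noise_dt, store_dt, FALSE, 1L,
                       fic_bias(c, p, fic))
  structure(list(values = out$neural, dt = store_dt,
                 transient_discarded = transient * 1000),
            class = "neural_trace")
}

#' Balloon-Windkessel BOLD transform
#'
#' Integrates the hemodynamic cascade per region at the neural sampling step
#' (piecewise-constant input, state starting from the resting point
#' `(s, f, v, q) = (0, 1, 1, 1)`) and samples the BOLD percent signal change
#' at `TR`.
#'
#' @param n a `neural_trace` from [simulate_dmf()], or a plain time x region
#'   matrix with attribute-free sampling given via `dt_ms`.
#' @param h [hemodynamic_params()].
#' @param TR output sampling period (s); must be >= the neural step.
#' @param dt_ms neural sampling step when `n` is a plain matrix.
#' @return a `bold_trace`: list with `values` (time x region, percent signal
#'   change) and `TR` (s).
#' @export
balloon_windkessel <- function(n, h = hemodynamic_params(), TR = 1,
                               dt_ms = NULL) {
  if (inherits(n, "neural_trace")) {
    vals <- n$values; dt_ms <- n$dt
  } else {
    vals <- as.matrix(n)
    if (is.null(dt_ms)) stop("dt_ms required for a plain matrix", call. = FALSE)
  }
  if (TR * 1000 < dt_ms)
    stop("TR (", TR, " s) smaller than the neural step (", dt_ms, " ms)",
         call. = FALSE)
  bold <- .bw_core_cpp(vals, dt_ms, TR, unclass(h))
  structure(list(values = bold, TR = TR), class = "bold_trace")
}

#' Simulate resting-state BOLD on a connectome
#'
#' One-pass convenience wrapper: reduced Wong-Wang network dynamics
#' ([simulate_dmf()]) and the Balloon-Windkessel cascade are integrated
#' together at the neural step and only the TR-sampled BOLD is stored, so
#' long sessions need no intermediate neural storage.  The first `transient`
#' seconds (neural and hemodynamic settling) are discarded.
#'
#' @inheritParams simulate_dmf
#' @param h [hemodynamic_params()].
#' @param TR BOLD sampling period (s).
#' @return a `bold_trace` with `floor((duration - transient) / TR)` samples.
#' @export
simulate_bold <- function(c, p = dmf_params(), h = hemodynamic_params(),
                          duration, TR = 1, dt = 0.1, seed, transient = 10,
                          init = NULL, noise_dt = 1, fic = FALSE) {
  check_sim_args(c, duration, dt, transient, noise_dt)
  if (TR * 1000 < dt) stop("TR smaller than dt", call. = FALSE)
  if (is.null(init)) init <- rep(low_stable_root(p), n_regions(c))
  bw_every <- max(1L, as.integer(round(1 / dt)))  # 1 ms hemodynamic subgrid
  out <- .dmf_core_cpp(c$weights, unclass(p), unclass(h),
                       duration, dt, transient, TR, as.integer(seed),
                       as.numeric(init), noise_dt, 0, TRUE, bw_every,
                       fic_bias(c, p, fic))
  vals <- out$bold
  colnames(vals) <- paste0(c$regions$acronym, "_", c$regions$hemisphere)
  structure(list(values = vals, TR = TR), class = "bold_trace")
}

#' Critical global coupling of the linearized network
#'
#' Linearizes the gating dynamics around the low-activity fixed point
#' (exact under homeostatic input compensation, see [simulate_bold()]):
#' the Jacobian is `lambda0 I + kappa G t(W)` with
#' `lambda0 = -1/tau_s - gamma H(x0) + (1 - S0) gamma H'(x0) w J_N` and
#' `kappa = (1 - S0) gamma H'(x0) J_N`, so the low state loses stability
#' when `G` reaches `-lambda0 / (kappa * perron(W))` with `perron(W)` the
#' leading eigenvalue of the weight matrix.  Resting-state simulations are
#' run at a fixed fraction of this value, where connectome-shaped
#' fluctuations are amplified but the operating point remains stable; using
#' each connectome's own critical value makes operating points comparable
#' across connectomes of different size, density and weight scale.
#'
#' @param c a max-normalized [connectome()].
#' @param p [dmf_params()] (its `G` is ignored).
#' @return the critical coupling `G_c` (dimensionless).
#' @export
critical_coupling <- function(c, p = dmf_params()) {
  stopifnot(inherits(c, "connectome"))
  S0 <- low_stable_root(p)
  x0 <- p$w * p$J_N * S0 + p$I_0
  eps <- 1e-6
  Hp <- (transfer_rate(x0 + eps, p) - transfer_rate(x0 - eps, p)) / (2 * eps)
  lambda0 <- -1000 / p$tau_s - p$gamma * transfer_rate(x0, p) +
    (1 - S0) * p$gamma * Hp * p$w * p$J_N
  kappa <- (1 - S0) * p$gamma * Hp * p$J_N
  per <- max(Re(eigen(c$weights, only.values = TRUE)$values))
  if (per <= 0 || lambda0 >= 0)
    stop("no positive critical coupling at these parameters", call. = FALSE)
  -lambda0 / (kappa * per)
}

## Homeostatic input compensation (a reduced stand-in for local feedback
## inhibition control): subtracts each region's mean network input at the
## low-activity reference state, so the resting operating point stays at
## the isolated node's low stable root for any coupling G while the
## fluctuation coupling (the Jacobian) keeps the full directed structure.
fic_bias <- function(c, p, fic) {
  n <- n_regions(c)
  if (!isTRUE(fic) || p$G == 0) return(numeric(n))
  s_ref <- low_stable_root(p)
  -p$G * p$J_N * as.numeric(colSums(c$weights)) * s_ref
}

check_sim_args <- function(c, duration, dt, transient, noise_dt) {
  stopifnot(inherits(c, "connectome"))
  if (max(c$weights) > 1 + 1e-9)
    stop("connectome must be max-normalized before simulation ",
         "(see normalize_weights)", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (duration <= transient)
    stop("duration must exceed the transient (", transient, " s)",
         call. = FALSE)
  k <- noise_dt / dt
  if (abs(k - round(k)) > 1e-9 || k < 1 - 1e-9)
    stop("noise_dt must be a positive integer multiple of dt", call. = FALSE)
  invisible(TRUE)
}

low_stable_root <- function(p) {
  fp <- find_fixed_points(p)
  st <- fp$S[fp$stable]
  if (length(st) == 0) stop("no stable fixed point at these parameters",
                            call. = FALSE)
  min(st)
}

#' @export
print.neural_trace <- function(x, ...) {
  cat(sprintf("<neural_trace> %d samples x %d regions, dt = %g ms\n",
              nrow(x$values), ncol(x$values), x$dt))
  invisible(x)
}

#' @export
print.bold_trace <- function(x, ...) {
  cat(sprintf("<bold_trace> %d samples x %d regions, TR = %g s\n",
              nrow(x$values), ncol(x$values), x$TR))
  invisible(x)
}
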