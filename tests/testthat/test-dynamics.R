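test_that("transfer function handles the removable singularity analytically", {
  p <- dmf_params()
  ## at a*x = b the limit is 1/d
  expect_equal(transfer_rate(p$b / p$a, p), 1 / p$d, tolerance = 1e-9)
  ## large input: H(x) - (a x - b) -> 0
  expect_lt(abs(transfer_rate(2, p) - (p$a * 2 - p$b)), 1e-10)
  ## extended-precision oracle at x = 0.5 via Rmpfr-free high precision:
  ## the formula is stable here, so evaluate it directly in double
  h <- p$a * 0.5 - p$b
  expect_equal(transfer_rate(0.5, p), h / (1 - exp(-p$d * h)),
               tolerance = 1e-14)
  ## continuity across the singularity
  eps <- 1e-9
  lo <- transfer_rate(p$b / p$a - eps, p)
  hi <- transfer_rate(p$b / p$a + eps, p)
  expect_lt(abs(hi - lo), 1e-5)
})

test_that("drift matches a brute-force loop and its forced signs", {
  p <- dmf_params(G = 0.3)
  c <- normalize_weights(rand_connectome(3, seed = 1), "max")
  S <- runif(6, 0, 1)
  drift <- dmf_drift(S, c, p)
  for (i in 1:6) {
    coup <- 0
    for (j in 1:6) coup <- coup + c$weights[j, i] * S[j]
    x <- p$w * p$J_N * S[i] + p$G * p$J_N * coup + p$I_0
    ref <- -S[i] / (p$tau_s / 1000) +
      (1 - S[i]) * p$gamma * transfer_rate(x, p)
    expect_equal(drift[i], ref, tolerance = 1e-14)
  }
  ## S = 0, G = 0: positive drift gamma*H(I_0) everywhere
  p0 <- dmf_params(G = 0)
  d0 <- dmf_drift(rep(0, 6), c, p0)
  expect_true(all(d0 > 0))
  expect_equal(d0, rep(p0$gamma * transfer_rate(p0$I_0, p0), 6))
})

test_that("the default node is bistable and roots satisfy the drift", {
  fp <- find_fixed_points()
  expect_gte(sum(fp$stable), 2)
  expect_equal(sum(!fp$stable), 1)
  for (r in fp$S) expect_lt(abs(dmf_drift(r, NULL, dmf_params())), 1e-10)
  ## weak-recurrence configuration: single stable low root
  fp_mono <- find_fixed_points(dmf_params(w = 0.6))
  expect_equal(nrow(fp_mono), 1)
  expect_true(fp_mono$stable)
  expect_lt(fp_mono$S, 0.2)
})

test_that("noise-free simulation from a stable root stays put; seeded runs
           are bit-identical; bistable basins separate", {
  c <- normalize_weights(rand_connectome(2, seed = 2), "max")
  fp <- find_fixed_points()
  stable <- fp$S[fp$stable]; unstable <- fp$S[!fp$stable][1]
  p0 <- dmf_params(G = 0, sigma = 0)
  nt <- simulate_dmf(c, p0, duration = 12, dt = 0.1, seed = 1, transient = 0,
                     init = rep(min(stable), 4), store_dt = 100)
  expect_lt(max(abs(nt$values - min(stable))), 1e-8)

  ## determinism contract
  p <- dmf_params(G = 0.2)
  a <- simulate_dmf(c, p, duration = 5, dt = 0.5, seed = 42, transient = 1)
  b <- simulate_dmf(c, p, duration = 5, dt = 0.5, seed = 42, transient = 1)
  expect_identical(a$values, b$values)

  ## noise-free trajectories on either side of the unstable root converge
  ## to the two distinct stable roots
  lo <- simulate_dmf(c, p0, duration = 30, dt = 0.1, seed = 1, transient = 0,
                     init = rep(unstable - 0.02, 4), store_dt = 1000)
  hi <- simulate_dmf(c, p0, duration = 30, dt = 0.1, seed = 1, transient = 0,
                     init = rep(unstable + 0.02, 4), store_dt = 1000)
  expect_equal(unname(tail(lo$values, 1)[1, 1]), min(stable), tolerance = 1e-6)
  expect_equal(unname(tail(hi$values, 1)[1, 1]), max(stable), tolerance = 1e-6)
})

test_that("gating stays in [0, 1] and uncoupled regions are independent", {
  c <- normalize_weights(rand_connectome(3, seed = 3), "max")
  p <- dmf_params(G = 0.4, sigma = 0.1)
  nt <- simulate_dmf(c, p, duration = 20, dt = 0.5, seed = 7, transient = 0,
                     store_dt = 10)
  expect_true(all(nt$values >= 0 & nt$values <= 1))

  ## G = 0: the 6-region run equals independent per-region runs because
  ## noise streams are counter-based per region
  p0 <- dmf_params(G = 0, sigma = 0.02)
  full <- simulate_dmf(c, p0, duration = 10, dt = 0.5, seed = 11,
                       transient = 0, store_dt = 10)
  sub <- connectome(c$weights[1:2, 1:2] * 0, region_table(1),
                    directed = FALSE)
  two <- simulate_dmf(sub, p0, duration = 10, dt = 0.5, seed = 11,
                      transient = 0, store_dt = 10)
  expect_identical(full$values[, 1:2], two$values)
})

test_that("refining dt leaves the fixed noise path's FC nearly unchanged", {
  c <- normalize_weights(rand_connectome(3, seed = 4), "max")
  p <- dmf_params(w = 0.6)
  p$G <- 0.7 * critical_coupling(c, p)
  f <- function(dt) {
    bt <- simulate_bold(c, p, duration = 90, TR = 1, dt = dt, seed = 5,
                        transient = 30, fic = TRUE)
    upper_vec(static_fc(bt$values))
  }
  fc1 <- f(1); fc2 <- f(0.5)
  expect_lt(sqrt(mean((fc1 - fc2)^2)), 0.01)
})

test_that("directed coupling matters: W and t(W) give different FC", {
  c <- normalize_weights(rand_connectome(3, seed = 5), "max")
  ct <- connectome(t(c$weights), c$regions, lengths = c$lengths,
                   directed = TRUE)
  p <- dmf_params(w = 0.6)
  p$G <- 0.85 * critical_coupling(c, p)
  f <- function(cc) upper_vec(static_fc(simulate_bold(cc, p, duration = 120,
    TR = 1, dt = 1, seed = 9, transient = 30, fic = TRUE)$values))
  expect_gt(sqrt(mean((f(c) - f(ct))^2)), 0.05)
})

test_that("resting hemodynamics are silent and the transform matches an
           adaptive integrator", {
  h <- hemodynamic_params()
  zero <- matrix(0, 2000, 2)
  bw <- balloon_windkessel(zero, h, TR = 1, dt_ms = 10)
  expect_true(all(bw$values == 0))

  ## impulse input: positive transient relaxing back toward baseline,
  ## matching deSolve's adaptive stiff integrator within 1e-4 of the peak
  skip_if_not_installed("deSolve")
  dt_ms <- 1
  tmax <- 30
  u <- function(t) ifelse(t >= 1 & t < 2, 0.5, 0)
  times <- seq(0, tmax, by = dt_ms / 1000)
  neural <- matrix(u(times[-length(times)]), ncol = 1)
  bw2 <- balloon_windkessel(neural, h, TR = 0.5, dt_ms = dt_ms)
  rhs <- function(t, y, parms) {
    s <- y[1]; f <- y[2]; v <- y[3]; q <- y[4]
    E <- 1 - (1 - h$rho)^(1 / f)
    list(c(u(t) - h$kappa * s - h$gamma_h * (f - 1),
           s,
           (f - v^(1 / h$alpha)) / h$tau,
           (f * E / h$rho - q * v^(1 / h$alpha - 1)) / h$tau))
  }
  sol <- deSolve::lsoda(c(s = 0, f = 1, v = 1, q = 1), seq(0, tmax, by = 0.5),
                        rhs, NULL, rtol = 1e-10, atol = 1e-12)
  bold_ref <- 100 * h$V0 * (h$k1 * (1 - sol[, "q"]) +
                            h$k2 * (1 - sol[, "q"] / sol[, "v"]) +
                            h$k3 * (1 - sol[, "v"]))
  bold_ref <- bold_ref[-1]  # integrator output starts at t = 0
  got <- bw2$values[, 1]
  expect_gt(max(got), 0)                      # positive transient
  expect_lt(abs(tail(got, 1)), max(got) / 5)  # returns toward baseline
  expect_lt(max(abs(got - bold_ref)) / max(abs(bold_ref)), 1e-4)
})

test_that("critical coupling marks the stability boundary of the low state", {
  c <- normalize_weights(rand_connectome(4, seed = 6), "max")
  p <- dmf_params(w = 0.6, sigma = 0)
  gc <- critical_coupling(c, p)
  s0 <- min(find_fixed_points(p)$S)
  run <- function(G) {
    pp <- p; pp$G <- G
    nt <- simulate_dmf(c, pp, duration = 60, dt = 0.5, seed = 1,
                       transient = 0, init = rep(s0 + 1e-4, 8),
                       store_dt = 1000, fic = TRUE)
    max(abs(tail(nt$values, 1) - s0))
  }
  expect_lt(run(0.8 * gc), 0.01)  # below: relaxes back to the fixed point
  expect_gt(run(1.2 * gc), 0.05)  # above: departs
})
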