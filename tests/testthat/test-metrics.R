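test_that("global signal regression leaves residuals orthogonal to the mean", {
  set.seed(1)
  x <- matrix(rnorm(200), 50, 4)
  r <- global_signal_regress(x)
  g <- rowMeans(x)
  for (j in 1:4) expect_lt(abs(cor(r[, j], g)), 1e-12)
  ## identical regions regress to ~0
  same <- cbind(g, g, g)
  expect_lt(max(abs(global_signal_regress(same))), 1e-10)
  expect_error(global_signal_regress(matrix(1, 10, 3)), "constant")
})

test_that("static_fc equals the covariance/SD formula", {
  set.seed(2)
  x <- matrix(rnorm(250), 50, 5)
  fc <- static_fc(x)
  for (i in 1:5) for (j in 1:5) {
    ref <- sum((x[, i] - mean(x[, i])) * (x[, j] - mean(x[, j]))) /
      sqrt(sum((x[, i] - mean(x[, i]))^2) * sum((x[, j] - mean(x[, j]))^2))
    expect_equal(fc[i, j], ref, tolerance = 1e-12)
  }
  dup <- cbind(x, x[, 1])
  expect_equal(static_fc(dup)[1, 6], 1)
  flip <- cbind(x, -x[, 1])
  expect_equal(static_fc(flip)[1, 6], -1)
  bad <- x; bad[, 3] <- 2
  expect_error(static_fc(bad), "region 3")
})

test_that("predictive power is upper-triangle correlation, diagonal-blind", {
  set.seed(3)
  a <- static_fc(matrix(rnorm(200), 50, 4))
  b <- static_fc(matrix(rnorm(200), 50, 4))
  ## enumeration oracle over the 6 links of a 4-region FC
  va <- c(a[1, 2], a[1, 3], a[1, 4], a[2, 3], a[2, 4], a[3, 4])
  vb <- c(b[1, 2], b[1, 3], b[1, 4], b[2, 3], b[2, 4], b[3, 4])
  expect_equal(predictive_power(a, b), cor(va, vb), tolerance = 1e-12)
  expect_equal(predictive_power(a, a), 1)
  ## diagonal changes are ignored; symmetry in arguments; affine invariance
  a2 <- a; diag(a2) <- 0
  expect_equal(predictive_power(a2, b), predictive_power(a, b))
  expect_equal(predictive_power(b, a), predictive_power(a, b))
  expect_equal(predictive_power(0.5 * a + 0.1, b), predictive_power(a, b),
               tolerance = 1e-12)
  expect_error(predictive_power(a, b[1:3, 1:3]), "mismatch")
})

test_that("fcd window count and values match a double-loop reference", {
  set.seed(4)
  x <- matrix(rnorm(100 * 4), 100, 4)
  out <- fcd(x, window = 20, step = 10)
  expect_equal(length(out$windows), 9)  # floor((100-20)/10)+1
  expect_equal(dim(out$values), c(9, 9))
  expect_true(all(diag(out$values) == 1))
  expect_equal(out$values, t(out$values))
  ## brute-force reference
  ref <- matrix(NA, 9, 9)
  for (u in 1:9) for (v in 1:9) {
    su <- (u - 1) * 10 + 1; sv <- (v - 1) * 10 + 1
    fu <- upper_vec(cor(x[su:(su + 19), ])); fv <- upper_vec(cor(x[sv:(sv + 19), ]))
    ref[u, v] <- cor(fu, fv)
  }
  diag(ref) <- 1
  expect_equal(out$values, ref, tolerance = 1e-12)
  ## periodic signal with window = period: all windows identical
  per <- matrix(rnorm(20 * 3), 20, 3)[rep(1:20, 5), ]
  outp <- fcd(per, window = 20, step = 20)
  expect_true(all(abs(outp$values - 1) < 1e-10))
  expect_error(fcd(x, window = 2), "3 samples")
})

test_that("fmc correlates windowed link series", {
  set.seed(5)
  x <- matrix(rnorm(120 * 5), 120, 5)
  out <- fmc(x, window = 30, step = 15)
  nl <- 10
  expect_equal(dim(out$values), c(nl, nl))
  ## brute-force reference for two links
  starts <- seq(1, 120 - 30 + 1, by = 15)
  s1 <- sapply(starts, function(s) cor(x[s:(s + 29), 1], x[s:(s + 29), 2]))
  s2 <- sapply(starts, function(s) cor(x[s:(s + 29), 1], x[s:(s + 29), 3]))
  expect_equal(out$values[1, 2], cor(s1, s2), tolerance = 1e-12)
  ## subset contract
  sub <- fmc(x, window = 30, step = 15, links = c(2, 5, 7))
  expect_equal(dim(sub$values), c(3, 3))
  expect_equal(sub$values[1, 2], out$values[2, 5], tolerance = 1e-12)
  ## duplicated link series give correlation 1
  xx <- cbind(x[, 1:2], x[, 1:2])
  dup <- fmc(xx, window = 30, step = 15, links = c(1, 6))
  expect_equal(dup$values[1, 2], 1, tolerance = 1e-10)
})

test_that("session similarity pair counts follow the combinatorics", {
  set.seed(6)
  fcs <- lapply(1:6, function(i) static_fc(matrix(rnorm(120), 30, 4)))
  ss <- session_similarity(fcs, subjects = c(1, 1, 2, 2, 3, 3))
  expect_equal(length(ss$intersession), 3 * choose(2, 2 + 0))  # n * C(s,2)
  expect_equal(length(ss$intersubject), choose(3, 2) * 2 * 2)  # C(n,2) * s^2
  same <- session_similarity(list(fcs[[1]], fcs[[1]], fcs[[1]], fcs[[1]]),
                             subjects = c(1, 1, 2, 2))
  expect_true(all(abs(same$intersession - 1) < 1e-12))
  expect_true(all(abs(same$intersubject - 1) < 1e-12))
})

test_that("fc lateralization distance matches the hand-computed norm", {
  c <- rand_connectome(3, seed = 7)
  reg <- c$regions
  set.seed(7)
  fc <- static_fc(matrix(rnorm(50 * 6), 50, 6))
  out <- fc_lateralization(fc, reg)
  expect_equal(nrow(out), 3)
  left <- which(reg$hemisphere == "L"); hm <- reg$homotope
  l <- left[1]; r <- hm[l]
  others <- setdiff(left, l)
  d_ref <- sqrt(sum((fc[l, others] - fc[r, hm[others]])^2))
  expect_equal(out$distance[1], d_ref, tolerance = 1e-12)
  expect_equal(out$LI, 1 / (1 + out$distance))
  ## perfectly mirrored FC: build by copying right block onto left
  fcm <- fc
  fcm[left, left] <- fc[hm[left], hm[left]]
  fcm[left, hm[left]] <- fc[hm[left], left]
  outm <- fc_lateralization(fcm, reg)
  expect_true(all(outm$distance < 1e-12))
  expect_true(all(outm$LI == 1 / (1 + outm$distance)))
})

test_that("scan_coupling scores every grid point and picks the argmax", {
  c <- normalize_weights(rand_connectome(4, seed = 8), "max")
  p <- dmf_params(w = 0.6)
  gc <- critical_coupling(c, p)
  sessions <- make_sessions(c, 2, within_p(p, 0.8 * gc), duration = 40,
                            TR = 1, dt = 1, seed = 3, transient = 20)
  sc <- scan_coupling(c, sessions, p, grid = c(0.4, 0.8) * gc,
                      duration = 60, TR = 1, dt = 1, seed = 5)
  expect_s3_class(sc, "coupling_scan")
  expect_equal(nrow(sc$results), 2 * 2)
  mean_pp <- tapply(sc$results$pp, sc$results$coupling_G, mean)
  expect_equal(sc$G_star, as.numeric(names(mean_pp))[which.max(mean_pp)])
  ## single-value grid: G* is that value
  one <- scan_coupling(c, sessions, p, grid = 0.5 * gc,
                       duration = 60, TR = 1, dt = 1, seed = 5)
  expect_equal(one$G_star, 0.5 * gc)
  expect_error(scan_coupling(c, sessions, p, grid = numeric(0)), "empty")
})
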