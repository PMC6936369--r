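test_that("average_group equals the loop-computed mean of normalized weights", {
  cs <- lapply(1:3, function(s) rand_connectome(3, seed = s))
  avg <- average_group(cs)
  ref <- Reduce(`+`, lapply(cs, function(c) c$weights / max(c$weights))) / 3
  expect_equal(avg$weights, ref)

  ## k identical connectomes average to the normalized original
  same <- average_group(list(cs[[1]], cs[[1]], cs[[1]]))
  expect_equal(same$weights, cs[[1]]$weights / max(cs[[1]]$weights))

  ## with a zero matrix the average halves the normalized weights
  z <- connectome(matrix(0, 6, 6), cs[[1]]$regions)
  half <- average_group(list(cs[[1]], z))
  expect_equal(half$weights, cs[[1]]$weights / max(cs[[1]]$weights) / 2)

  expect_error(average_group(list(cs[[1]])), "two connectomes")
})

test_that("filter_by_union_mask keeps exactly the union support", {
  ref <- rand_connectome(4, seed = 1, density = 0.9)
  masks <- lapply(2:3, function(s) symmetrize(rand_connectome(4, seed = s,
                                                              density = 0.4)))
  out <- filter_by_union_mask(ref, masks)
  sup <- Reduce(`|`, lapply(masks, function(m) m$weights != 0))
  sup <- sup | t(sup)
  expect_true(all(out$weights[!sup] == 0))
  expect_equal(out$weights[sup], ref$weights[sup])
  expect_equal(attr(out, "retained_fraction"),
               sum(ref$weights != 0 & sup) / sum(ref$weights != 0))
  expect_lte(edge_density(out), edge_density(ref))

  full <- connectome(1 - diag(8), ref$regions)
  expect_equal(filter_by_union_mask(ref, list(full))$weights, ref$weights)
  none <- connectome(matrix(0, 8, 8), ref$regions)
  out0 <- filter_by_union_mask(ref, list(none))
  expect_equal(sum(out0$weights), 0)
  expect_equal(attr(out0, "retained_fraction"), 0)
  expect_error(filter_by_union_mask(ref, list()), "empty")
})

test_that("symmetrize averages directions, conserves weight, is idempotent", {
  reg <- region_table(1)
  w <- matrix(c(0, 2, 4, 0), 2, 2, byrow = TRUE)
  s <- symmetrize(connectome(w, reg))
  expect_equal(s$weights, matrix(c(0, 3, 3, 0), 2, 2))
  expect_false(s$directed)

  c <- rand_connectome(4, seed = 11)
  s2 <- symmetrize(c)
  expect_identical(s2$weights, t(s2$weights))
  expect_equal(sum(s2$weights), sum(c$weights))
  expect_equal(symmetrize(s2)$weights, s2$weights)
  expect_gte(edge_density(s2), edge_density(c))
})

test_that("asymmetrize repartitions pair sums by reference ratios", {
  ref <- rand_connectome(3, seed = 2)
  sym <- symmetrize(ref)
  out <- asymmetrize(sym, ref)
  n <- nrow(out$weights)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    expect_equal(out$weights[i, j] + out$weights[j, i],
                 sym$weights[i, j] + sym$weights[j, i], tolerance = 1e-12)
    r <- ref$weights[i, j] + ref$weights[j, i]
    if (r > 0)
      expect_equal(out$weights[i, j],
                   (sym$weights[i, j] + sym$weights[j, i]) *
                     ref$weights[i, j] / r, tolerance = 1e-12)
  }
  ## symmetric reference leaves a symmetric input unchanged
  out2 <- asymmetrize(sym, connectome(sym$weights, sym$regions,
                                      directed = TRUE))
  expect_equal(out2$weights, sym$weights)
  ## unidirectional reference sends the whole pair sum one way
  w <- matrix(0, 6, 6); w[1, 2] <- 5
  uni <- connectome(w, ref$regions, directed = TRUE)
  out3 <- asymmetrize(sym, uni)
  expect_equal(out3$weights[1, 2], sym$weights[1, 2] + sym$weights[2, 1])
  expect_equal(out3$weights[2, 1], 0)
  expect_error(asymmetrize(ref, ref), "not symmetric")
})

test_that("hybridize replaces exactly one row and column and is idempotent", {
  base <- normalize_weights(rand_connectome(4, seed = 3), "max")
  ref <- normalize_weights(rand_connectome(4, seed = 4), "max")
  r <- 5L
  h <- hybridize(base, ref, r)
  diff_mask <- h$weights != base$weights
  touched <- row(diff_mask) == r | col(diff_mask) == r
  expect_true(all(!diff_mask[!touched]))
  expect_lte(sum(diff_mask), 2 * nrow(base$weights) - 1)
  expect_equal(h$weights[r, -r], ref$weights[r, -r])
  expect_equal(h$weights[-r, r], ref$weights[-r, r])
  expect_equal(hybridize(h, ref, r)$weights, h$weights)
  expect_equal(hybridize(base, base, r)$weights, base$weights)
  expect_error(hybridize(base, ref, 99), "out of range")

  ## restricted mode only overwrites positions already nonzero in base
  h2 <- hybridize(base, ref, r, full_profile = FALSE)
  untouched <- base$weights[r, ] == 0
  expect_equal(h2$weights[r, untouched], base$weights[r, untouched])
})

test_that("mirror_left_from_right maps the right blocks onto the left", {
  c <- rand_connectome(4, seed = 6)
  reg <- c$regions
  m <- mirror_left_from_right(c)
  left <- which(reg$hemisphere == "L"); hm <- reg$homotope
  rl <- hm[left]
  expect_equal(m$weights[left, left], c$weights[rl, rl])
  expect_equal(m$weights[left, rl], c$weights[rl, left])
  ## right-seeded rows unchanged
  right <- which(reg$hemisphere == "R")
  expect_equal(m$weights[right, ], c$weights[right, ])
  ## idempotent, and a fixed point once mirrored
  expect_equal(mirror_left_from_right(m)$weights, m$weights)
})

test_that("weight similarity U behaves like a normalized rank statistic", {
  a <- normalize_weights(rand_connectome(4, seed = 8, density = 0.9), "max")
  expect_equal(weight_similarity_U(a, a), 0.5)

  ## complete separation on common support
  b <- connectome(a$weights * 1e-4, a$regions, lengths = a$lengths,
                  directed = TRUE)
  expect_equal(weight_similarity_U(a, b), 1)

  ## enumeration oracle on the {1,3} vs {2,4} example
  mw <- mann_whitney_u(c(1, 3), c(2, 4))
  expect_equal(mw$U, 1)
  expect_equal(mw$normalized_U, 0.25)
})
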