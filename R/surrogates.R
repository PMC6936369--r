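#' Group-average connectome
#'
#' Elementwise mean of the max-normalized weight matrices of a cohort, the
#' analogue of averaging individual diffusion-MRI connectomes into a group
#' connectome.  Weights are max-normalized first because different subjects'
#' streamline counts are not on a common scale.  Lengths are averaged over
#' the connectomes that carry them.
#'
#' @param cs list of at least two [connectome()]s on the same region table.
#' @return a [connectome()] labelled `"group-average"`.
#' @export
average_group <- function(cs) {
  if (!is.list(cs) || length(cs) < 2L)
    stop("need at least two connectomes", call. = FALSE)
  for (c in cs[-1]) check_same_regions(cs[[1]], c)
  ws <- lapply(cs, function(c) {
    if (all(c$weights == 0)) c$weights
    else normalize_weights(c, "max")$weights
  })
  w <- Reduce(`+`, ws) / length(ws)
  lens <- Filter(Negate(is.null), lapply(cs, `[[`, "lengths"))
  len <- if (length(lens)) Reduce(`+`, lens) / length(lens) else NULL
  connectome(w, cs[[1]]$regions, lengths = len, directed = NA,
             label = "group-average")
}

#' Filter a connectome by the union support of other connectomes
#'
#' Keeps entry (i, j) of `reference` iff at least one mask source has a
#' nonzero entry at (i, j) or (j, i); all other entries are zeroed.  This is
#' how a dense directed tracer-like connectome is restricted to the
#' connections that a set of (symmetric) diffusion-MRI reconstructions was
#' able to see, turning undetected connections into false negatives while
#' keeping directionality on the surviving ones.
#'
#' @param reference the [connectome()] to filter.
#' @param mask_sources nonempty list of [connectome()]s on the same regions.
#' @return the filtered [connectome()]; the fraction of reference edges
#'   retained is attached as attribute `"retained_fraction"`.
#' @export
filter_by_union_mask <- function(reference, mask_sources) {
  stopifnot(inherits(reference, "connectome"))
  if (!is.list(mask_sources) || length(mask_sources) == 0L)
    stop("empty mask source list", call. = FALSE)
  for (m in mask_sources) check_same_regions(reference, m)
  sup <- Reduce(`|`, lapply(mask_sources, function(m) m$weights != 0))
  sup <- sup | t(sup)
  w <- reference$weights
  n_before <- sum(w != 0)
  w[!sup] <- 0
  out <- connectome(w, reference$regions, lengths = reference$lengths,
                    directed = reference$directed,
                    label = paste0(reference$label, "-filtered"))
  attr(out, "retained_fraction") <-
    if (n_before > 0) sum(w != 0) / n_before else 0
  out
}

#' Symmetrize a connectome
#'
#' Replaces the weights by `(W + t(W)) / 2`, discarding all directionality
#' information while preserving the total weight.  Where only one direction
#' of a pair existed this creates a spurious reciprocal (false positive)
#' connection at half strength.
#'
#' @param c a [connectome()].
#' @return an undirected [connectome()].
#' @export
symmetrize <- function(c) {
  stopifnot(inherits(c, "connectome"))
  w <- (c$weights + t(c$weights)) / 2
  w <- (w + t(w)) / 2  # force exact bitwise symmetry
  connectome(w, c$regions, lengths = c$lengths, directed = FALSE,
             label = paste0(c$label, "-sym"))
}

#' Asymmetrize a symmetric connectome using a directed reference
#'
#' Repartitions each unordered pair's total weight between the two
#' directions in the proportions found in a directed reference: writing
#' `s = A[i,j] + A[j,i]`, for pairs with `s > 0` the output is
#' `W'[i,j] = (W[i,j] + W[j,i]) * A[i,j] / s` (and symmetrically), so
#' pairwise sums are conserved.  Pairs with no reference information
#' (`s = 0`) keep their symmetric values.  Recovering directions from a
#' symmetric matrix is ill-posed; this rule is one defensible choice and the
#' reference ratios are the only information used.
#'
#' @param sym a symmetric [connectome()].
#' @param reference a directed [connectome()] on the same regions.
#' @return a directed [connectome()].
#' @export
asymmetrize <- function(sym, reference) {
  stopifnot(inherits(sym, "connectome"), inherits(reference, "connectome"))
  check_same_regions(sym, reference)
  w <- sym$weights
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-12)))
    stop("`sym` is not symmetric", call. = FALSE)
  a <- reference$weights
  r <- a + t(a)
  pairsum <- w + t(w)
  out <- w
  idx <- r > 0
  out[idx] <- pairsum[idx] * a[idx] / r[idx]
  connectome(out, sym$regions, lengths = sym$lengths, directed = NA,
             label = paste0(sym$label, "-asym"))
}

#' Hybridize one region's connection profile from a reference connectome
#'
#' Replaces row `region` and column `region` of `base` (all incoming and
#' outgoing connections of that region) with the corresponding row and
#' column of `reference`, leaving every other entry untouched.  Both inputs
#' should be max-normalized so the transplanted weights are commensurable.
#' With the default `full_profile = TRUE` the full reference profile is
#' transplanted, importing reference connections absent from `base`; with
#' `full_profile = FALSE` only positions already nonzero in `base` are
#' overwritten.
#'
#' @param base the [connectome()] to refine.
#' @param reference the donor [connectome()] on the same regions.
#' @param region region index (1-based) whose profile is replaced.
#' @param full_profile replace the full row/column (default) or only
#'   base-supported positions.
#' @return a [connectome()]; idempotent for fixed `(reference, region)`.
#' @export
hybridize <- function(base, reference, region, full_profile = TRUE) {
  stopifnot(inherits(base, "connectome"), inherits(reference, "connectome"))
  check_same_regions(base, reference)
  n <- n_regions(base)
  region <- as.integer(region)
  if (is.na(region) || region < 1L || region > n)
    stop("region index out of range [1, ", n, "]", call. = FALSE)
  w <- base$weights
  if (full_profile) {
    w[region, ] <- reference$weights[region, ]
    w[, region] <- reference$weights[, region]
  } else {
    ri <- w[region, ] != 0
    ci <- w[, region] != 0
    w[region, ri] <- reference$weights[region, ri]
    w[ci, region] <- reference$weights[ci, region]
  }
  w[region, region] <- 0
  connectome(w, base$regions, lengths = base$lengths, directed = NA,
             label = paste0(base$label, "-hybrid"))
}

#' Rebuild the left hemisphere as a mirror image of the right
#'
#' Emulates the construction used for tracer-based connectomes when
#' injections exist only in one hemisphere: for homotopic pairs
#' `l <-> r`, left intrahemispheric connections are rebuilt from the right
#' ones (`W'[l_i, l_j] = W[r_i, r_j]`) and left-seeded contralateral
#' connections are mirrored (`W'[l_i, r_j] = W[r_i, l_j]`).  Rows seeded in
#' the right hemisphere are unchanged.  Idempotent.
#'
#' @param c a [connectome()] whose region table has a complete homotope map.
#' @return the mirrored [connectome()].
#' @export
mirror_left_from_right <- function(c) {
  stopifnot(inherits(c, "connectome"))
  reg <- c$regions
  left <- which(reg$hemisphere == "L")
  hm <- reg$homotope
  if (any(is.na(hm[left])) || any(reg$hemisphere[hm[left]] != "R"))
    stop("incomplete homotope mapping", call. = FALSE)
  w <- c$weights
  rl <- hm[left]                     # right homotope of each left region
  w[left, left] <- c$weights[rl, rl]
  w[left, rl] <- c$weights[rl, left]
  diag(w) <- 0
  connectome(w, reg, lengths = c$lengths, directed = NA,
             label = paste0(c$label, "-mirrored"))
}

#' Normalized Mann-Whitney U similarity between two weight distributions
#'
#' Compares the nonzero weights of two max-normalized connectomes on their
#' common support (entries nonzero in both) with the Mann-Whitney statistic,
#' normalized to \[0, 1\] by `n_a * n_b`.  A value of 0.5 means the two
#' weight distributions are indistinguishable; values near 0 or 1 mean one
#' connectome's weights are systematically smaller or larger.
#'
#' @param a,b max-normalized [connectome()]s on the same regions.
#' @return normalized U in \[0, 1\] (orientation: `P(weight_a > weight_b)`
#'   with ties counted half).
#' @export
weight_similarity_U <- function(a, b) {
  stopifnot(inherits(a, "connectome"), inherits(b, "connectome"))
  check_same_regions(a, b)
  sup <- a$weights != 0 & b$weights != 0
  if (!any(sup)) stop("empty common support", call. = FALSE)
  mann_whitney_u(a$weights[sup], b$weights[sup])$normalized_U
}
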