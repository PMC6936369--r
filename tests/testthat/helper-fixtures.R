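## Small deterministic fixtures shared across the test files.

## Random directed connectome on a bihemispheric region table.
rand_connectome <- function(n_per_hemisphere = 3, seed = 1, density = 0.7,
                            lengths = TRUE) {
  set.seed(seed)
  n <- 2 * n_per_hemisphere
  cen <- cbind(runif(n, -5, 5), runif(n, 0, 8), runif(n, 0, 5))
  reg <- region_table(n_per_hemisphere, centroids = cen)
  w <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < density)
  diag(w) <- 0
  len <- if (lengths) as.matrix(dist(cen)) else NULL
  connectome(w, reg, lengths = len, directed = TRUE, label = "fixture")
}

## Tiny config for generator/experiment tests: everything scaled down so a
## full cohort pipeline runs in seconds.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_per_hemisphere = 6L, n_subjects = 2L, n_sessions = 2L,
         session_duration = 60, dt = 1),
    list(...))
  do.call(synth_config, args)
}

upper_vec <- function(m) m[upper.tri(m)]

within_p <- function(p, G) { p$G <- G; p }
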