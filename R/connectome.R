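#' Build a region table
#'
#' A region table describes the parcellation a connectome lives on: one row
#' per region with an Allen-style acronym, a hemisphere label, the index of
#' the homotopic (mirror-image) region in the other hemisphere, and an
#' optional 3D centroid in millimetres.
#'
#' The table is stored with left-hemisphere regions first, then their right
#' homotopes in the same order, so `homotope` is the involution
#' `c((n+1):2n, 1:n)` by default.
#'
#' @param n_per_hemisphere number of regions per hemisphere.
#' @param acronyms character vector of length `n_per_hemisphere` with the
#'   per-hemisphere acronyms (the table gets `<acr>` for both hemispheres,
#'   disambiguated by the `hemisphere` column). Defaults to `"R01"...`.
#' @param centroids optional `2*n_per_hemisphere` x 3 numeric matrix of
#'   region centroids (mm), rows ordered as the table.
#' @return a `data.frame` with columns `acronym`, `hemisphere` (`"L"`/`"R"`),
#'   `homotope` (integer index), and `x`, `y`, `z` (may be `NA`).
#' @export
region_table <- function(n_per_hemisphere, acronyms = NULL, centroids = NULL) {
  n <- as.integer(n_per_hemisphere)
  if (is.na(n) || n < 1L) stop("n_per_hemisphere must be >= 1", call. = FALSE)
  if (is.null(acronyms))
    acronyms <- sprintf("R%02d", seq_len(n))
  if (length(acronyms) != n || anyDuplicated(acronyms))
    stop("acronyms must be ", n, " unique strings", call. = FALSE)
  tab <- data.frame(
    acronym = rep(acronyms, 2L),
    hemisphere = rep(c("L", "R"), each = n),
    homotope = c(seq_len(n) + n, seq_len(n)),
    x = NA_real_, y = NA_real_, z = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    if (nrow(centroids) != 2L * n || ncol(centroids) != 3L)
      stop("centroids must be a ", 2L * n, " x 3 matrix", call. = FALSE)
    tab[, c("x", "y", "z")] <- centroids
  }
  validate_region_table(tab)
  tab
}

validate_region_table <- function(regions) {
  req <- c("acronym", "hemisphere", "homotope")
  if (!all(req %in% names(regions)))
    stop("region table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!all(regions$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'", call. = FALSE)
  nL <- sum(regions$hemisphere == "L")
  nR <- sum(regions$hemisphere == "R")
  if (nL != nR)
    stop("unequal hemisphere sizes: ", nL, " L vs ", nR, " R", call. = FALSE)
  for (h in c("L", "R")) {
    acr <- regions$acronym[regions$hemisphere == h]
    if (anyDuplicated(acr))
      stop("duplicate acronym within hemisphere ", h, ": ",
           acr[duplicated(acr)][1], call. = FALSE)
  }
  hm <- regions$homotope
  n <- nrow(regions)
  if (any(is.na(hm)) || any(hm < 1L) || any(hm > n))
    stop("homotope indices out of range", call. = FALSE)
  if (!identical(as.integer(hm[hm]), seq_len(n)))
    stop("homotope mapping is not an involution", call. = FALSE)
  if (any(regions$hemisphere[hm] == regions$hemisphere))
    stop("homotope mapping must cross hemispheres", call. = FALSE)
  invisible(regions)
}

#' Construct a structural connectome
#'
#' A connectome is a directed weighted region-by-region matrix of connection
#' strengths, with optional symmetric tract lengths and a region table.  The
#' weight convention is source-to-target: `weights[i, j]` is the strength of
#' the projection from region `i` to region `j` (tracer-injection
#' semantics).
#'
#' @param weights N x N nonnegative numeric matrix with zero diagonal.
#' @param regions region table (see [region_table()]) with N rows.
#' @param lengths optional N x N symmetric nonnegative matrix of tract
#'   lengths (mm), zero diagonal.
#' @param directed logical; if `NA` (default) inferred from exact equality of
#'   `weights` with its transpose (any asymmetry implies directed).
#' @param label provenance tag, e.g. `"tracer"` or `"dmri-det"`.
#' @return an object of class `connectome`.
#' @export
connectome <- function(weights, regions, lengths = NULL, directed = NA,
                       label = "") {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  dimnames(weights) <- NULL
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop("weights must be square, got ", n, " x ", ncol(weights),
         call. = FALSE)
  if (nrow(regions) != n)
    stop("region table has ", nrow(regions), " rows but weights are ",
         n, " x ", n, call. = FALSE)
  validate_region_table(regions)
  bad <- which(weights < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative weight at (%d, %d): %g", bad[1, 1], bad[1, 2],
                 weights[bad[1, 1], bad[1, 2]]), call. = FALSE)
  if (any(diag(weights) != 0))
    stop("weights must have a zero diagonal (first offending region: ",
         which(diag(weights) != 0)[1], ")", call. = FALSE)
  if (!is.null(lengths)) {
    lengths <- as.matrix(lengths)
    storage.mode(lengths) <- "double"
    dimnames(lengths) <- NULL
    if (nrow(lengths) != n || ncol(lengths) != n)
      stop("lengths must be ", n, " x ", n, call. = FALSE)
    if (any(lengths < 0)) stop("negative tract length", call. = FALSE)
    if (!isTRUE(all.equal(lengths, t(lengths), tolerance = 0)))
      stop("lengths must be exactly symmetric", call. = FALSE)
    if (any(diag(lengths) != 0))
      stop("lengths must have a zero diagonal", call. = FALSE)
  }
  if (is.na(directed)) directed <- !identical(weights, t(weights))
  if (!directed && !identical(weights, t(weights)))
    stop("directed = FALSE but weights differ from their transpose",
         call. = FALSE)
  dimnames(weights) <- NULL
  if (!is.null(lengths)) dimnames(lengths) <- NULL
  structure(
    list(weights = weights, lengths = lengths, regions = regions,
         directed = isTRUE(directed), label = as.character(label)),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  cat(sprintf(
    "<connectome> %d regions (%s), %s, density %.3f%s%s\n",
    n, paste(range(table(x$regions$hemisphere)), collapse = "+"),
    if (x$directed) "directed" else "undirected",
    edge_density(x),
    if (is.null(x$lengths)) ", no lengths" else "",
    if (nzchar(x$label)) paste0(", label '", x$label, "'") else ""
  ))
  invisible(x)
}

n_regions <- function(c) nrow(c$weights)

#' Connection density
#'
#' Fraction of off-diagonal entries that are nonzero.
#'
#' @param c a [connectome()].
#' @return a fraction in \[0, 1\].
#' @export
edge_density <- function(c) {
  stopifnot(inherits(c, "connectome"))
  n <- n_regions(c)
  (sum(c$weights != 0)) / (n * (n - 1))
}

#' Mean connection length
#'
#' Unweighted mean of tract lengths over the entries carrying a nonzero
#' weight.  Invariant under any rescaling of the weights.
#'
#' @param c a [connectome()] with lengths present.
#' @return mean length in mm.
#' @export
mean_connection_length <- function(c) {
  stopifnot(inherits(c, "connectome"))
  if (is.null(c$lengths))
    stop("connectome has no tract lengths", call. = FALSE)
  sup <- c$weights > 0
  if (!any(sup)) stop("connectome has no connections", call. = FALSE)
  mean(c$lengths[sup])
}

#' Normalize connection weights
#'
#' Rescales all weights by a single positive factor so that either the
#' maximum entry is 1 (`"max"`, the convention used before simulating or
#' mixing connectomes from incommensurable sources) or the mean of the
#' nonzero entries is 1 (`"mean"`).  The zero pattern is unchanged.
#'
#' @param c a [connectome()] with at least one nonzero weight.
#' @param mode `"max"` or `"mean"`.
#' @return a rescaled [connectome()].
#' @export
normalize_weights <- function(c, mode = c("max", "mean")) {
  stopifnot(inherits(c, "connectome"))
  mode <- match.arg(mode)
  w <- c$weights
  nz <- w[w > 0]
  if (length(nz) == 0) stop("all-zero weight matrix", call. = FALSE)
  s <- if (mode == "max") max(nz) else mean(nz)
  c$weights <- w / s
  c
}

#' Read a connectome from disk
#'
#' Accepts either a directory or a connectivity zip containing
#' `weights.txt` (whitespace-delimited floats, one row per line), optional
#' `tract_lengths.txt`, optional `centres.txt` (acronym x y z) and a
#' `regions.tsv` with columns `acronym`, `hemisphere`, `homotope`, `x`, `y`,
#' `z`.  An optional `meta.tsv` (written by [write_connectome()]) carries
#' `directed` and `label`; without it directedness is inferred from exact
#' matrix symmetry.
#'
#' @param path directory or `.zip` file.
#' @return a validated [connectome()].
#' @export
read_connectome <- function(path) {
  if (!file.exists(path)) stop("no such path: ", path, call. = FALSE)
  dir <- path
  if (!dir.exists(path)) {
    dir <- tempfile("conn_unzip_")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    unzip(path, exdir = dir)
    ## tolerate a single top-level folder inside the zip
    entries <- list.files(dir, full.names = TRUE)
    if (length(entries) == 1L && dir.exists(entries))
      dir <- entries
  }
  wfile <- file.path(dir, "weights.txt")
  if (!file.exists(wfile)) stop("missing weights.txt in ", path, call. = FALSE)
  weights <- as.matrix(read.table(wfile, header = FALSE))
  rfile <- file.path(dir, "regions.tsv")
  cfile <- file.path(dir, "centres.txt")
  if (file.exists(rfile)) {
    regions <- read.delim(rfile, stringsAsFactors = FALSE)
  } else if (file.exists(cfile)) {
    ## centres.txt alone: infer L/R from acronym suffix is not possible, so
    ## require an even split in file order (left half then right half).
    cen <- read.table(cfile, header = FALSE, stringsAsFactors = FALSE)
    n <- nrow(cen) / 2L
    regions <- region_table(n, acronyms = cen[[1]][seq_len(n)],
                            centroids = as.matrix(cen[, 2:4]))
  } else stop("missing regions.tsv (or centres.txt) in ", path, call. = FALSE)
  lfile <- file.path(dir, "tract_lengths.txt")
  lengths <- if (file.exists(lfile))
    as.matrix(read.table(lfile, header = FALSE)) else NULL
  directed <- NA
  label <- ""
  mfile <- file.path(dir, "meta.tsv")
  if (file.exists(mfile)) {
    meta <- read.delim(mfile, stringsAsFactors = FALSE)
    directed <- as.logical(meta$directed[1])
    label <- as.character(meta$label[1])
  }
  connectome(weights, regions, lengths = lengths, directed = directed,
             label = label)
}

#' Write a connectome to disk
#'
#' Writes the plain-text connectivity layout read by [read_connectome()]
#' into a directory: `weights.txt`, `tract_lengths.txt` (only when lengths
#' are present), `centres.txt`, `regions.tsv` and `meta.tsv`.  Matrices are
#' written with 17 significant digits so a read/write round trip is exact.
#'
#' @param c a [connectome()].
#' @param path target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_connectome <- function(c, path) {
  stopifnot(inherits(c, "connectome"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)
  write_mat <- function(m, f) {
    txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
    writeLines(txt, file.path(path, f))
  }
  write_mat(c$weights, "weights.txt")
  if (!is.null(c$lengths)) write_mat(c$lengths, "tract_lengths.txt")
  cen <- data.frame(acronym = c$regions$acronym,
                    x = c$regions$x, y = c$regions$y, z = c$regions$z)
  write.table(cen, file.path(path, "centres.txt"), sep = " ",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(c$regions, file.path(path, "regions.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(data.frame(directed = c$directed, label = c$label),
              file.path(path, "meta.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

## shared precondition helper for binary connectome ops
check_same_regions <- function(a, b) {
  if (!identical(dim(a$weights), dim(b$weights)) ||
      !identical(a$regions$acronym, b$regions$acronym) ||
      !identical(a$regions$hemisphere, b$regions$hemisphere))
    stop("connectomes have mismatched region tables", call. = FALSE)
  invisible(TRUE)
}
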