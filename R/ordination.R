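## Ordination of delimitation methods: the pairwise match-ratio similarity
## matrix is transformed to distances and embedded by principal coordinate
## analysis (metric multidimensional scaling on the Gower-centered matrix).

#' Transform a similarity matrix to a distance matrix
#'
#' `d = 1 - s` by default; `sqrt(1 - s)` (which is metric for
#' match-ratio-like similarities) behind `transform = "sqrt"`.
#'
#' @param S symmetric similarity matrix, entries in `[0, 1]`, unit
#'   diagonal.
#' @param transform `"one_minus"` (default) or `"sqrt"`.
#' @return Validated distance matrix.
#' @export
similarity_to_distance <- function(S, transform = c("one_minus", "sqrt")) {
  transform <- match.arg(transform)
  dm_assert(is.matrix(S) && nrow(S) == ncol(S), "similarity must be square")
  if (any(S < 0 | S > 1))
    dm_stop("similarity entries must lie in [0, 1]", "input_error")
  dm_assert(all(abs(diag(S) - 1) < 1e-12), "similarity diagonal must be 1")
  D <- 1 - S
  if (transform == "sqrt") D <- sqrt(D)
  validate_distance_matrix(D)
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: eigendecomposition of the Gower-centered
#' matrix `-1/2 J D^2 J`; coordinates are eigenvectors scaled by the
#' square root of their (positive) eigenvalues. Negative eigenvalues are
#' reported and their axes dropped; `correction = "cailliez"` applies the
#' Cailliez additive constant instead. Axis signs are fixed by making the
#' first non-zero coordinate of each axis positive.
#'
#' @param D symmetric distance matrix with zero diagonal, `n >= 3`.
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return Object of class `pcoa_result`: `points` (n x k coordinates,
#'   k = number of retained positive axes), `eigenvalues` (all n, sorted
#'   descending), `positive_eigenvalues`, `proportion_explained` (over the
#'   positive spectrum), `negative_magnitude`.
#' @export
pcoa <- function(D, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  D <- validate_distance_matrix(D)
  n <- nrow(D)
  if (n < 3) dm_stop("PCoA needs at least 3 points", "ordination_error")
  ## cmdscale warns when asked for more axes than there are positive
  ## eigenvalues; the spectrum is post-processed here, so that is expected
  cmd <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D), k = n - 1, eig = TRUE,
                    add = correction == "cailliez"))
  eig <- sort(cmd$eig, decreasing = TRUE)
  tol <- max(abs(eig), 1e-300) * 1e-9
  pos <- cmd$eig > tol
  k <- min(sum(pos), ncol(cmd$points))
  pts <- cmd$points[, seq_len(k), drop = FALSE]
  if (k > 0) {
    colnames(pts) <- sprintf("Axis%d", seq_len(k))
    ## reproducible axis orientation
    for (j in seq_len(k)) {
      nz <- which(abs(pts[, j]) > tol)
      if (length(nz) && pts[nz[1], j] < 0) pts[, j] <- -pts[, j]
    }
  }
  pe <- if (k > 0) cmd$eig[pos] / sum(cmd$eig[pos]) else numeric(0)
  structure(list(points = pts,
                 eigenvalues = eig,
                 positive_eigenvalues = cmd$eig[pos],
                 proportion_explained = pe,
                 negative_magnitude = sum(abs(eig[eig < -tol])),
                 correction = correction),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- ncol(x$points)
  cat(sprintf("PCoA: %d points, %d positive axes\n", nrow(x$points), k))
  if (k > 0)
    cat(sprintf("  proportion explained (axes 1..%d): %s\n",
                min(k, 3),
                paste(sprintf("%.3f", utils::head(x$proportion_explained, 3)),
                      collapse = ", ")))
  if (x$negative_magnitude > 0)
    cat(sprintf("  dropped negative-eigenvalue magnitude: %.3g\n",
                x$negative_magnitude))
  invisible(x)
}

#' Ordinate delimitation methods by pairwise match ratio
#'
#' Pipeline composition: [pairwise_similarity()] then
#' [similarity_to_distance()] then [pcoa()]; one point per method, with
#' the reference partition included as a point when supplied among
#' `partitions`.
#'
#' @param partitions named list of at least three `partition`s (the
#'   reference may be one of them).
#' @param transform passed to [similarity_to_distance()].
#' @param correction passed to [pcoa()].
#' @param strict passed to [pairwise_similarity()].
#' @return A `pcoa_result`.
#' @export
ordinate_methods <- function(partitions, transform = "one_minus",
                             correction = "none", strict = FALSE) {
  dm_assert(length(partitions) >= 3, "need at least three partitions",
            "ordination_error")
  S <- pairwise_similarity(partitions, strict)
  pcoa(similarity_to_distance(S, transform), correction)
}
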