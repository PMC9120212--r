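## Pairwise distances under the uncorrected (p) and Jukes-Cantor (JC69)
## models. Each IUPAC code is held as a 4-bit mask over {A,C,G,T}; two sites
## are comparable when both masks are non-zero (i.e. neither is '-'/'?'),
## and they differ when the masks share no bit -- so ambiguity codes that
## are compatible with the other base (R vs A, N vs anything) count as a
## match. This is deliberately conservative toward lumping; pass
## `ambiguity = "missing"` to treat ambiguity codes as missing data instead.

IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L,
                "-" = 0L, "?" = 0L)

encode_alignment <- function(aln, ambiguity = c("match", "missing")) {
  ambiguity <- match.arg(ambiguity)
  mask <- IUPAC_MASK
  if (ambiguity == "missing")
    mask[!names(mask) %in% c("A", "C", "G", "T", "U")] <- 0L
  m <- matrix(mask[as.vector(unclass(aln))], nrow = nrow(aln),
              dimnames = list(rownames(aln), NULL))
  storage.mode(m) <- "integer"
  m
}

#' Uncorrected pairwise distance between two aligned sequences
#'
#' Proportion of differing sites among comparable sites. Gaps (`-`) and
#' missing data (`?`) are excluded; IUPAC ambiguity codes compatible with
#' the other base count as matches.
#'
#' @param a,b sequence strings or single-character vectors of equal length.
#' @param deletion `"pairwise"` (default) uses all sites comparable for this
#'   pair; `"complete"` is identical for a single pair of sequences and is
#'   applied alignment-wide in [distance_matrix()].
#' @param ambiguity `"match"` (default) or `"missing"`.
#' @return Proportion of differing sites, in `[0, 1]`.
#' @export
p_distance <- function(a, b, deletion = c("pairwise", "complete"),
                       ambiguity = c("match", "missing")) {
  deletion <- match.arg(deletion)
  aln <- as_alignment(c(a = paste(a, collapse = ""),
                        b = paste(b, collapse = "")))
  e <- encode_alignment(aln, ambiguity)
  p_dist_masks(e[1, ], e[2, ], "a/b")
}

p_dist_masks <- function(x, y, pair) {
  comp <- x > 0L & y > 0L
  n <- sum(comp)
  if (n == 0L)
    dm_stop(sprintf("no comparable sites for pair %s", pair),
            "undefined_distance_error")
  sum(bitwAnd(x[comp], y[comp]) == 0L) / n
}

#' Jukes-Cantor (JC69) correction of a p distance
#'
#' `d = -(3/4) log(1 - (4/3) p)`, expected substitutions per site. Defined
#' for `p < 0.75`; at or beyond that boundary the pair is saturated and a
#' `saturation_error` is raised.
#'
#' @param p proportion of differing sites.
#' @return Corrected distance (substitutions/site), always `>= p`.
#' @export
jc69_distance <- function(p) {
  dm_assert(all(p >= 0), "negative p distance")
  if (any(p >= 0.75))
    dm_stop(sprintf("JC69 saturation: p = %s >= 0.75",
                    paste(format(p[p >= 0.75]), collapse = ", ")),
            "saturation_error")
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln a `barcode_alignment` with at least two records.
#' @param model `"p"` (uncorrected) or `"jc69"`.
#' @param deletion `"pairwise"` (default) or `"complete"` (drop every site
#'   with missing data in any record before computing distances).
#' @param ambiguity `"match"` (default) or `"missing"`.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
distance_matrix <- function(aln, model = c("p", "jc69"),
                            deletion = c("pairwise", "complete"),
                            ambiguity = c("match", "missing")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  dm_assert(nrow(aln) >= 2, "need at least two sequences")
  e <- encode_alignment(aln, ambiguity)
  if (deletion == "complete") {
    keep <- colSums(e == 0L) == 0L
    dm_assert(any(keep), "complete deletion removes every site",
              "undefined_distance_error")
    e <- e[, keep, drop = FALSE]
  }
  n <- nrow(e)
  ids <- rownames(e)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      p <- p_dist_masks(e[i, ], e[j, ], sprintf("%s/%s", ids[i], ids[j]))
      d <- if (model == "jc69") {
        tryCatch(jc69_distance(p), saturation_error = function(err)
          dm_stop(sprintf("saturated pair %s/%s (p = %g)", ids[i], ids[j], p),
                  "saturation_error"))
      } else p
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}

#' Absolute nucleotide differences between all sequence pairs
#'
#' Step counts (number of differing comparable sites) used by the
#' statistical-parsimony delimiter; missing sites are excluded pairwise.
#'
#' @param aln a `barcode_alignment`.
#' @param ambiguity `"match"` (default) or `"missing"`.
#' @return Symmetric integer matrix of pairwise differences.
#' @export
step_matrix <- function(aln, ambiguity = c("match", "missing")) {
  e <- encode_alignment(aln, ambiguity)
  n <- nrow(e)
  ids <- rownames(e)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      comp <- e[i, ] > 0L & e[j, ] > 0L
      m[i, j] <- m[j, i] <-
        sum(bitwAnd(e[i, comp], e[j, comp]) == 0L)
    }
  }
  m
}
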