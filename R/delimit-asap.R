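## Ranked hierarchical partitioning: every single-linkage merge level is a
## candidate partition, scored by a probability of panmixia (small when the
## partition separates real structure) and a relative gap width (large when
## the next merge is far above); the two ranks are averaged into the final
## score, lower is better. The panmixia probability is a seeded Monte-Carlo
## permutation test with the same contract as the coalescent-derived
## original: small under structure, large under panmixia.

#' Single-linkage merge levels of a distance matrix
#'
#' @param D validated distance matrix, `n >= 2`.
#' @return List with one element per distinct merge height (ties
#'   coalesced): `height` and `partition` (the partition produced by all
#'   merges up to and including that height). Partitions are nested and the
#'   last one is the single block.
#' @export
dendrogram_levels <- function(D) {
  D <- validate_distance_matrix(D)
  n <- nrow(D)
  dm_assert(n >= 2, "need at least two specimens")
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  heights <- sort(unique(hc$height))
  lapply(heights, function(h) {
    ## partition after all merges at heights <= h: components under
    ## edges d <= h (single-linkage clusters at that height)
    list(height = h,
         partition = component_partition(D, h, "MOTU", strict = FALSE))
  })
}

#' Monte-Carlo probability of panmixia for a partition
#'
#' Statistic: mean between-block distance minus mean within-block
#' distance. The p value is the permutation probability of a statistic at
#' least as extreme under random relabeling, `(1 + n_extreme) / (R + 1)`.
#' Partitions with no between-block or no within-block pairs (one block,
#' or all blocks singletons) have p = 1 by convention.
#'
#' @param D validated distance matrix.
#' @param partition a `partition` on `D`'s ids.
#' @param R number of permutations (>= 1).
#' @return Probability in `(0, 1]`.
#' @export
panmixia_pval <- function(D, partition, R = 999) {
  dm_assert(R >= 1, "R must be >= 1", "config_error")
  ids <- rownames(D)
  dm_assert(setequal(ids, names(partition)),
            "partition must cover the matrix ids")
  lab <- unclass(partition)[ids]
  ut <- upper.tri(D)
  dvec <- D[ut]
  stat_for <- function(l) {
    same <- outer(l, l, "==")[ut]
    nw <- sum(same)
    nb <- length(dvec) - nw
    if (nw == 0L || nb == 0L) return(NA_real_)
    sum(dvec[!same]) / nb - sum(dvec[same]) / nw
  }
  obs <- stat_for(lab)
  if (is.na(obs)) return(1)
  extreme <- 0L
  for (r in seq_len(R)) {
    s <- stat_for(sample(lab))
    if (!is.na(s) && s >= obs - 1e-12) extreme <- extreme + 1L
  }
  (1 + extreme) / (R + 1)
}

#' Relative gap width at a merge height
#'
#' `w = (next height - height) / height`; the last level (and any level
#' tied with its successor, or a non-positive height) has `w = 0`.
#'
#' @param heights sorted distinct merge heights.
#' @param i index of the level.
#' @return Non-negative relative width.
#' @export
relative_gap_width <- function(heights, i) {
  if (i >= length(heights)) return(0)
  h <- heights[i]
  if (h <= 0) return(0)
  max(0, (heights[i + 1L] - h) / h)
}

#' Ranked hierarchical-partitioning delimitation
#'
#' Scores every single-linkage merge level: `rank_p` = 1 for the smallest
#' panmixia probability, `rank_w` = 1 for the largest relative gap width
#' (ties get the minimum rank), and the score is their mean. Candidates
#' are returned sorted by ascending score, ties broken by fewer blocks and
#' then lower threshold.
#'
#' @param D validated distance matrix, `n >= 3` for a meaningful ranking.
#' @param R permutations for the panmixia test.
#' @param seed integer seed fixing the entire ranked list.
#' @return Object of class `asap_result`: list of candidates, each with
#'   `threshold`, `partition`, `n_motu`, `p_val`, `w`, `rank_p`, `rank_w`,
#'   `score`; plus `best` and `second` (the rank-1 and rank-2 partitions).
#' @export
asap_delimit <- function(D, R = 999, seed = 1) {
  D <- validate_distance_matrix(D)
  levels <- dendrogram_levels(D)
  heights <- vapply(levels, `[[`, 0, "height")
  with_seed(seed, {
    p_val <- vapply(seq_along(levels), function(i)
      panmixia_pval(D, levels[[i]]$partition, R), 0)
    w <- vapply(seq_along(levels), function(i)
      relative_gap_width(heights, i), 0)
    rank_p <- rank(p_val, ties.method = "min")
    rank_w <- rank(-w, ties.method = "min")
    score <- (rank_p + rank_w) / 2
    nb <- vapply(levels, function(l) n_blocks(l$partition), 0L)
    ord <- order(score, nb, heights)
    cands <- lapply(ord, function(i) {
      list(threshold = heights[i], partition = levels[[i]]$partition,
           n_motu = nb[i], p_val = p_val[i], w = w[i],
           rank_p = as.integer(rank_p[i]), rank_w = as.integer(rank_w[i]),
           score = score[i])
    })
    structure(list(candidates = cands,
                   best = cands[[1]]$partition,
                   second = if (length(cands) >= 2) cands[[2]]$partition),
              class = "asap_result")
  })
}

#' @export
print.asap_result <- function(x, ...) {
  cat(sprintf("ranked hierarchical partitioning: %d candidate levels\n",
              length(x$candidates)))
  top <- utils::head(x$candidates, 5)
  for (c in top)
    cat(sprintf("  score %5.1f  n_motu %3d  threshold %.5f  p %.4g  w %.3g\n",
                c$score, c$n_motu, c$threshold, c$p_val, c$w))
  invisible(x)
}
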