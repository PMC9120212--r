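## Partition congruence: exact-match counting, the taxonomic match ratio
## 2 N_match / (N_mol + N_morph), split/lump classification of reference
## species, universal-match counting across methods, and the pairwise
## method-similarity matrix.

## shared-domain policy: specimens missing from either partition are
## dropped with a warning (strict = TRUE errors instead)
shared_domain <- function(p_a, p_b, strict = FALSE) {
  ids_a <- names(p_a); ids_b <- names(p_b)
  common <- intersect(ids_a, ids_b)
  if (length(common) == 0)
    dm_stop("partitions have disjoint specimen domains",
            "domain_mismatch_error")
  dropped <- setdiff(union(ids_a, ids_b), common)
  if (length(dropped)) {
    if (strict)
      dm_stop(sprintf("partitions disagree on specimens: %s",
                      paste(sort(dropped), collapse = ", ")),
              "domain_mismatch_error")
    warning(sprintf("dropping %d specimen(s) absent from one partition: %s",
                    length(dropped), paste(sort(dropped), collapse = ", ")),
            call. = FALSE)
  }
  list(a = as_partition(unclass(p_a)[common]),
       b = as_partition(unclass(p_b)[common]))
}

#' Number of exact block matches between two partitions
#'
#' A match is a specimen set that appears as a block in both partitions
#' (all individuals, exact set equality).
#'
#' @param p_a,p_b `partition` objects over the same specimen set (specimens
#'   present in only one are dropped with a warning unless `strict`).
#' @param strict error instead of dropping mismatched specimens.
#' @return Integer match count.
#' @export
match_count <- function(p_a, p_b, strict = FALSE) {
  d <- shared_domain(p_a, p_b, strict)
  length(intersect(block_keys(d$a), block_keys(d$b)))
}

#' Taxonomic match ratio between two partitions
#'
#' `2 * N_match / (N_a + N_b)`: 1 when the partitions are identical, 0
#' when no block matches exactly.
#'
#' @inheritParams match_count
#' @return Ratio in `[0, 1]` at full precision (round for tables with
#'   [round2()] or [trunc2()]).
#' @export
match_ratio <- function(p_a, p_b, strict = FALSE) {
  d <- shared_domain(p_a, p_b, strict)
  2 * match_count(d$a, d$b) / (n_blocks(d$a) + n_blocks(d$b))
}

#' Match ratio from published-style count tables
#'
#' Computes `2 * n_match / (n_mol + n_morph)` per method from counts, as
#' printed in congruence tables.
#'
#' @param n_match integer vector of exact-match counts per method.
#' @param n_mol integer vector of MOTU counts per method.
#' @param n_morph single reference (morphospecies) block count.
#' @return Numeric vector of match ratios, named like `n_match`.
#' @export
match_ratio_from_counts <- function(n_match, n_mol, n_morph) {
  dm_assert(length(n_match) == length(n_mol),
            "n_match and n_mol must have equal length")
  dm_assert(all(n_match >= 0) && all(n_mol >= 1) && n_morph >= 1,
            "counts must be positive")
  dm_assert(all(n_match <= pmin(n_mol, n_morph)),
            "n_match cannot exceed min(n_mol, n_morph)")
  stats::setNames(2 * n_match / (n_mol + n_morph), names(n_match))
}

#' Classify reference blocks as match, split, lump, or mixed
#'
#' For each reference block B against the MOTU partition:
#' `match` -- one MOTU equals B exactly; `split` -- B occupies two or more
#' MOTUs, each fully inside B; `lump` -- B occupies exactly one MOTU that
#' strictly contains B; `mixed` -- B occupies two or more MOTUs of which at
#' least one also holds non-B specimens.
#'
#' @param p_ref reference (e.g. morphospecies) `partition`.
#' @param p_motu MOTU `partition`.
#' @param strict error on domain mismatch instead of dropping.
#' @return Named character vector: reference block label -> status.
#' @export
classify_reference_blocks <- function(p_ref, p_motu, strict = FALSE) {
  d <- shared_domain(p_ref, p_motu, strict)
  ref_blocks <- partition_blocks(d$a)
  motu_of <- unclass(d$b)
  vapply(ref_blocks, function(B) {
    motus <- unique(motu_of[B])
    sizes_in_ref <- table(motu_of[B])
    motu_sizes <- table(motu_of)[names(sizes_in_ref)]
    pure <- sizes_in_ref == motu_sizes      # MOTU entirely inside B?
    if (length(motus) == 1L) {
      if (pure[[1]]) "match" else "lump"
    } else {
      if (all(pure)) "split" else "mixed"
    }
  }, "")
}

#' Reference blocks matched exactly by every method
#'
#' @param p_ref reference `partition`.
#' @param motu_partitions non-empty named list of MOTU `partition`s.
#' @param strict error on domain mismatch instead of dropping.
#' @return Integer count of reference blocks that are blocks of every
#'   method's partition.
#' @export
universal_match_count <- function(p_ref, motu_partitions, strict = FALSE) {
  dm_assert(length(motu_partitions) >= 1, "no method partitions given",
            "config_error")
  keys <- block_keys(p_ref)
  for (p in motu_partitions) {
    d <- shared_domain(p_ref, p, strict)
    keys <- intersect(keys, block_keys(d$b))
  }
  length(keys)
}

#' Pairwise match-ratio similarity matrix of delimitation methods
#'
#' @param partitions named list of at least two `partition`s over a shared
#'   specimen domain (a reference partition may be included as one entry).
#' @param strict error on domain mismatch instead of dropping.
#' @return Symmetric numeric matrix of match ratios with unit diagonal.
#' @export
pairwise_similarity <- function(partitions, strict = FALSE) {
  dm_assert(length(partitions) >= 2, "need at least two partitions")
  nms <- names(partitions)
  dm_assert(!is.null(nms) && all(nzchar(nms)) && !anyDuplicated(nms),
            "partitions must be uniquely named")
  k <- length(partitions)
  m <- diag(1, k)
  dimnames(m) <- list(nms, nms)
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    m[i, j] <- m[j, i] <-
      match_ratio(partitions[[i]], partitions[[j]], strict)
  }
  m
}

#' Full congruence summary of one MOTU partition against a reference
#'
#' @param p_ref reference `partition`.
#' @param p_motu MOTU `partition`.
#' @param strict error on domain mismatch instead of dropping.
#' @return Object of class `congruence`: `n_match`, `n_ref`, `n_motu`,
#'   `match_ratio`, and `per_label` status vector.
#' @export
congruence <- function(p_ref, p_motu, strict = FALSE) {
  d <- shared_domain(p_ref, p_motu, strict)
  nm <- match_count(d$a, d$b)
  structure(list(
    n_match = nm,
    n_ref = n_blocks(d$a),
    n_motu = n_blocks(d$b),
    match_ratio = 2 * nm / (n_blocks(d$a) + n_blocks(d$b)),
    per_label = classify_reference_blocks(d$a, d$b)),
    class = "congruence")
}

#' @export
print.congruence <- function(x, ...) {
  cat(sprintf(
    "partition congruence: N_match = %d, N_ref = %d, N_motu = %d\n",
    x$n_match, x$n_ref, x$n_motu))
  cat(sprintf("  match ratio = %.4f (table form %.2f)\n",
              x$match_ratio, round2(x$match_ratio)))
  print(table(factor(x$per_label,
                     levels = c("match", "split", "lump", "mixed"))))
  invisible(x)
}
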