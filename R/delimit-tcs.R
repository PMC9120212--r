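## Statistical-parsimony delimitation: haplotypes are connected when their
## step count does not exceed the 95% parsimony connection limit; connected
## networks are read as MOTUs. Only the components matter for delimitation,
## so networks are built by transitive closure on pairwise step counts
## rather than by estimating full network topology.

#' Collapse an alignment to unique haplotypes
#'
#' Sequences identical under the missing-data policy are merged. With
#' `missing_tolerant = TRUE` (default) two sequences merge when they are
#' compatible at every site where both are non-missing, and at least one
#' is non-missing somewhere; the representative keeps the more complete
#' residue at each site.
#'
#' @param aln a `barcode_alignment`.
#' @param missing_tolerant merge sequences that differ only at `-`/`?`
#'   sites.
#' @return List with `haplotypes` (named character vector of sequence
#'   strings) and `membership` (named list: haplotype -> specimen ids).
#' @export
collapse_haplotypes <- function(aln, missing_tolerant = TRUE) {
  s <- alignment_strings(aln)
  ids <- names(s)
  if (!missing_tolerant) {
    grp <- match(s, unique(s))
  } else {
    e <- encode_alignment(aln)
    n <- nrow(e)
    grp <- integer(n)
    reps <- list()          # per group: current merged mask vector
    for (i in seq_len(n)) {
      placed <- FALSE
      for (g in seq_along(reps)) {
        r <- reps[[g]]
        both <- r > 0L & e[i, ] > 0L
        if (all(bitwAnd(r[both], e[i, both]) != 0L)) {
          ## compatible: merge, preferring the defined residue
          merged <- r
          merged[r == 0L] <- e[i, r == 0L]
          reps[[g]] <- merged
          grp[i] <- g
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        reps[[length(reps) + 1L]] <- e[i, ]
        grp[i] <- length(reps)
      }
    }
  }
  members <- split(ids, grp)
  hap_ids <- sprintf("H%d", seq_along(members))
  haps <- stats::setNames(s[vapply(members, `[[`, "", 1L)], hap_ids)
  names(members) <- hap_ids
  list(haplotypes = haps, membership = members)
}

## probability that a site showing a difference experienced exactly one
## substitution, given Poisson(lambda) substitutions under JC69 dynamics
single_step_prob <- function(lambda) {
  n <- 1:100
  p_diff_given_n <- 0.75 * (1 - (-1 / 3)^n)
  w <- stats::dpois(n, lambda) * p_diff_given_n
  w[1] / sum(w)
}

#' Parsimony probability for j observed differences
#'
#' Estimated probability that all `j` observed differences between two
#' sequences of length `seq_length` involve no superimposed substitutions.
#' Convention used: the per-site divergence is the JC69 correction of
#' `p = j / seq_length`; the number of substitutions at a site is Poisson
#' with that mean, and a site in a different state after n substitutions
#' has probability 3/4 (1 - (-1/3)^n); the parsimony probability is then
#' P(single substitution | difference)^j.
#'
#' @param j non-negative integer count of observed differences.
#' @param seq_length alignment length in sites.
#' @return Probability in `[0, 1]`; 0 once `j/seq_length` saturates.
#' @export
parsimony_probability <- function(j, seq_length) {
  dm_assert(seq_length >= 1, "seq_length must be >= 1")
  if (j == 0) return(1)
  p <- j / seq_length
  if (p >= 0.75) return(0)
  lambda <- jc69_distance(p)
  single_step_prob(lambda)^j
}

#' Statistical-parsimony connection limit
#'
#' Largest number of steps `j` such that the estimated probability that
#' `j` observed differences are non-homoplastic is at least `confidence`.
#'
#' @param seq_length alignment length in sites.
#' @param confidence connection probability, default 0.95.
#' @return Integer step limit.
#' @export
connection_limit <- function(seq_length, confidence = 0.95) {
  dm_assert(seq_length >= 1, "seq_length must be >= 1")
  dm_assert(confidence > 0 && confidence < 1,
            "confidence must lie in (0, 1)")
  j <- 0L
  jmax <- floor(0.74 * seq_length)
  while (j < jmax && parsimony_probability(j + 1L, seq_length) >= confidence)
    j <- j + 1L
  j
}

#' Statistical-parsimony (TCS-style) delimitation
#'
#' Haplotypes are collapsed, pairwise step counts computed (missing sites
#' excluded), and haplotypes connected whenever their step count is at most
#' the connection limit; connection is transitive, and the connected
#' components are the MOTUs. Specimens inherit their haplotype's block.
#'
#' @param aln a `barcode_alignment`.
#' @param confidence connection probability, default 0.95.
#' @param max_steps optional explicit step limit overriding the
#'   confidence-derived one (`Inf` gives one block; 0 gives one block per
#'   haplotype).
#' @return A `partition`.
#' @export
tcs_delimit <- function(aln, confidence = 0.95, max_steps = NULL) {
  hap <- collapse_haplotypes(aln)
  if (is.null(max_steps))
    max_steps <- connection_limit(ncol(aln), confidence)
  reps <- as_alignment(hap$haplotypes)
  steps <- step_matrix(reps)
  hp <- component_partition(steps, max_steps + 1, "NET") # edges: steps <= limit
  lab <- character(0)
  for (h in names(hap$membership))
    lab[hap$membership[[h]]] <- unclass(hp)[[h]]
  as_partition(lab[rownames(aln)])
}
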