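# Independent oracles and fixture builders used across the test files.
# These deliberately re-derive results with different code paths than the
# package (brute-force searches, explicit loops) so the tests are not
# self-confirming.

# brute-force connected components of the graph with edge iff d < thr
# (<= thr when strict = FALSE); returns a list of sorted id vectors
brute_components <- function(D, thr, strict = TRUE) {
  ids <- rownames(D)
  n <- length(ids)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      hit <- if (strict) D[i, j] < thr else D[i, j] <= thr
      if (i != j && hit && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(ids, comp), sort))
}

# set-of-blocks comparison helpers
blocks_of <- function(p) unname(partition_blocks(p))
same_blocks <- function(a, b) {
  ka <- sort(vapply(a, paste, "", collapse = "|"))
  kb <- sort(vapply(b, paste, "", collapse = "|"))
  identical(ka, kb)
}
partitions_equal <- function(p, q) same_blocks(blocks_of(p), blocks_of(q))

# brute-force exact-match count by quadratic block comparison
brute_match_count <- function(p_a, p_b) {
  ba <- blocks_of(p_a); bb <- blocks_of(p_b)
  n <- 0L
  for (x in ba) for (y in bb) if (length(x) == length(y) && all(x == y))
    n <- n + 1L
  n
}

# independent per-site p distance on two character strings
brute_p_distance <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  amb <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  ncomp <- 0L; ndiff <- 0L
  for (i in seq_along(x)) {
    if (x[i] %in% c("-", "?") || y[i] %in% c("-", "?")) next
    ncomp <- ncomp + 1L
    if (length(intersect(amb[[x[i]]], amb[[y[i]]])) == 0L) ndiff <- ndiff + 1L
  }
  ndiff / ncomp
}

# small labeled symmetric matrix from an upper-triangle spec
dist_fixture <- function(ids, fill) {
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  k <- 0L
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    k <- k + 1L
    D[i, j] <- D[j, i] <- fill[k]
  }
  D
}

# two-cluster distance matrix with prescribed within/between values
two_group_matrix <- function(within = 0.005, between = 0.10,
                             sizes = c(3, 3)) {
  ids <- c(sprintf("a%d", seq_len(sizes[1])), sprintf("b%d", seq_len(sizes[2])))
  grp <- rep(1:2, sizes)
  n <- length(ids)
  D <- matrix(between, n, n, dimnames = list(ids, ids))
  D[grp == 1, grp == 1] <- within
  D[grp == 2, grp == 2] <- within
  diag(D) <- 0
  D
}

# random partition of ids into at most k blocks (for property tests)
random_partition <- function(ids, k) {
  as_partition(stats::setNames(sprintf("B%d", sample(k, length(ids),
                                                     replace = TRUE)), ids))
}

# rooted two-species tree: two coalescent clades on long stems
two_species_tree <- function(n1 = 4, n2 = 4, within = 0.01, stem = 0.3) {
  t1 <- ape::rcoal(n1, tip.label = sprintf("a%d", seq_len(n1)))
  t2 <- ape::rcoal(n2, tip.label = sprintf("b%d", seq_len(n2)))
  t1$edge.length <- t1$edge.length * (within / max(ape::node.depth.edgelength(t1)))
  t2$edge.length <- t2$edge.length * (within / max(ape::node.depth.edgelength(t2)))
  nw <- sprintf("(%s:%g,%s:%g);",
                sub(";$", "", ape::write.tree(t1)), stem,
                sub(";$", "", ape::write.tree(t2)), stem)
  ape::read.tree(text = nw)
}

# ABGD fixture: cluster A (two tight subclusters, cross ~0.06) whose
# internal gap is masked globally by cluster B, an 11-point cluster whose
# 55 internal distances form an exact arithmetic ladder 0.0002..0.0650
abgd_masking_matrix <- function() {
  ids <- c(sprintf("p%d", 1:4), sprintf("q%d", 1:11))
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[1:4, 5:15] <- 0.25 + outer(1:4, 1:11) * 1e-5
  D[5:15, 1:4] <- t(D[1:4, 5:15])
  D[1, 2] <- D[2, 1] <- 0.0010
  D[3, 4] <- D[4, 3] <- 0.0011
  cross <- c(0.0595, 0.05955, 0.0596, 0.05965)
  k <- 0L
  for (i in 1:2) for (j in 3:4) {
    k <- k + 1L
    D[i, j] <- D[j, i] <- cross[k]
  }
  ladder <- 0.0002 + 0.0012 * (0:54)
  k <- 0L
  for (i in 5:14) for (j in seq.int(i + 1, 15)) {
    k <- k + 1L
    D[i, j] <- D[j, i] <- ladder[k]
  }
  validate_distance_matrix(D)
}
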