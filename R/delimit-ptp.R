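## Poisson tree processes delimitation. Branches are classified into a
## between-species (speciation) class and within-species class(es); each
## class has exponentially distributed branch lengths, so with the rate
## profiled at its ML value (lambda-hat = n / sum(b)) a class of n branches
## contributes n log(n / sum b) - n to the log likelihood. A delimitation
## is a set of species-root nodes whose subtrees partition the tips:
## every edge on the root-to-species-root paths is a speciation edge,
## every edge strictly inside a species subtree is a within edge.
## Single-rate mode shares one within rate; multi-rate mode gives each
## species its own within rate and is compared on AIC so that extra rate
## parameters must pay for themselves.

BRLEN_FLOOR <- 1e-9  # identical haplotypes yield zero branches; keep rates finite

## --- small tree utilities on ape "phylo" objects -------------------------

tree_index <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode)
  edge_of <- integer(nnode)              # edge row whose child is the node
  children <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    parent[c] <- p
    edge_of[c] <- e
    children[[p]] <- c(children[[p]], c)
  }
  lens <- pmax(tree$edge.length, BRLEN_FLOOR)
  root <- ntip + 1L
  list(ntip = ntip, nnode = nnode, root = root, parent = parent,
       edge_of = edge_of, children = children, lens = lens)
}

## tips under each node, as list of integer vectors
tips_under <- function(ix) {
  out <- vector("list", ix$nnode)
  for (t in seq_len(ix$ntip)) out[[t]] <- t
  ## postorder: process nodes in decreasing order works for ape's cladewise
  ## numbering only sometimes; do an explicit recursion instead
  rec <- function(v) {
    if (v <= ix$ntip) return(out[[v]])
    kids <- ix$children[[v]]
    out[[v]] <<- sort(unlist(lapply(kids, rec)))
    out[[v]]
  }
  rec(ix$root)
  out
}

## all edges (rows) in the subtree rooted at node, excluding the node's own
## incoming edge
edges_below <- function(ix, node) {
  res <- integer(0)
  stack <- ix$children[[node]]
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    res <- c(res, ix$edge_of[v])
    if (v > ix$ntip) stack <- c(stack, ix$children[[v]])
  }
  res
}

## --- likelihood -----------------------------------------------------------

#' Log-likelihood contribution of one exponential rate class
#'
#' With the rate at its maximum-likelihood value `n / sum(b)`, a class of
#' `n` branches of total length `sum(b)` contributes
#' `n * log(n / sum(b)) - n`.
#'
#' @param lengths branch lengths of the class (may be empty).
#' @return The profiled log-likelihood contribution (0 for an empty class).
#' @export
rate_class_loglik <- function(lengths) {
  n <- length(lengths)
  if (n == 0L) return(0)
  s <- sum(pmax(lengths, BRLEN_FLOOR))
  n * log(n / s) - n
}

## classify edges for a species-root set: TRUE = speciation
edge_is_speciation <- function(ix, species_roots) {
  spec <- rep(FALSE, nrow_edges <- length(ix$lens))
  for (s in species_roots) {
    v <- s
    while (v != ix$root) {
      spec[ix$edge_of[v]] <- TRUE
      v <- ix$parent[v]
    }
  }
  spec
}

ptp_objective <- function(ix, species_roots, mode) {
  spec <- edge_is_speciation(ix, species_roots)
  ll_spec <- rate_class_loglik(ix$lens[spec])
  if (mode == "single") {
    ll <- ll_spec + rate_class_loglik(ix$lens[!spec])
    list(loglik = ll, objective = ll)
  } else {
    k <- as.integer(any(spec))
    ll <- ll_spec
    for (s in species_roots) {
      e <- edges_below(ix, s)
      if (length(e)) {
        ll <- ll + rate_class_loglik(ix$lens[e])
        k <- k + 1L
      }
    }
    list(loglik = ll, objective = ll - k)  # AIC/2 penalty per free rate
  }
}

#' Poisson tree processes log-likelihood of a delimitation
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @param species_roots integer node numbers (ape convention) whose
#'   subtrees are the species; they must be an antichain covering all tips.
#' @param mode `"single"` (one shared within-species rate) or `"multi"`
#'   (one rate per species).
#' @return Log likelihood with all rates profiled at their ML values.
#' @export
ptp_loglik <- function(tree, species_roots, mode = c("single", "multi")) {
  mode <- match.arg(mode)
  ix <- tree_index(validate_tree(tree))
  tu <- tips_under(ix)
  covered <- sort(unlist(tu[species_roots]))
  dm_assert(identical(covered, seq_len(ix$ntip)),
            "species subtrees must be disjoint and cover all tips")
  ptp_objective(ix, species_roots, mode)$loglik
}

## enumerate every antichain of nodes covering all tips (species-root sets)
enumerate_species_roots <- function(ix, node = ix$root) {
  if (node <= ix$ntip) return(list(node))
  kids <- lapply(ix$children[[node]], function(k)
    enumerate_species_roots(ix, k))
  combos <- Reduce(function(acc, lst) {
    out <- vector("list", length(acc) * length(lst))
    i <- 0L
    for (a in acc) for (b in lst) { i <- i + 1L; out[[i]] <- c(a, b) }
    out
  }, kids)
  c(list(node), combos)
}

## Exact single-rate search by dynamic programming. With one speciation
## and one within class the profiled log-likelihood depends on a
## delimitation only through k (number of speciation edges) and s (their
## total length):
##   f(k, s) = k log(k/s) - k + (N-k) log((N-k)/(T-s)) - (N-k),
## which is convex in s for fixed k, so over the achievable set the
## maximum sits at the smallest or largest achievable s. Both extremes
## (and one delimitation attaining each) are computed for every k by a
## knapsack-style DP over the tree, giving the exact argmax in polynomial
## time for trees of any size.
ptp_dp_single <- function(ix) {
  smin <- vector("list", ix$nnode)   # per node: vector over k (index k+1)
  smax <- vector("list", ix$nnode)
  bpmin <- vector("list", ix$nnode)  # backpointers: per child stage,
  bpmax <- vector("list", ix$nnode)  #   2 x (k+1) matrix of (i, j)
  rec <- function(v) {
    if (v <= ix$ntip) {
      smin[[v]] <<- 0; smax[[v]] <<- 0
      return(invisible())
    }
    kids <- ix$children[[v]]
    for (c in kids) rec(c)
    accmin <- 0; accmax <- 0
    stages_min <- vector("list", length(kids))
    stages_max <- vector("list", length(kids))
    for (ci in seq_along(kids)) {
      c <- kids[ci]
      l <- ix$lens[ix$edge_of[c]]
      lm <- smin[[c]]; lx <- smax[[c]]
      nk <- length(accmin) + length(lm)
      newmin <- rep(Inf, nk); newmax <- rep(-Inf, nk)
      bmn <- matrix(NA_integer_, 2, nk); bmx <- matrix(NA_integer_, 2, nk)
      for (i in seq_along(accmin)) {
        if (!is.finite(accmin[i]) && !is.finite(accmax[i])) next
        for (j in seq_along(lm)) {
          k1 <- i + j          # index of k = (i-1) + 1 + (j-1), plus 1
          v1 <- accmin[i] + l + lm[j]
          if (v1 < newmin[k1]) { newmin[k1] <- v1; bmn[, k1] <- c(i, j) }
          v2 <- accmax[i] + l + lx[j]
          if (v2 > newmax[k1]) { newmax[k1] <- v2; bmx[, k1] <- c(i, j) }
        }
      }
      accmin <- newmin; accmax <- newmax
      stages_min[[ci]] <- bmn; stages_max[[ci]] <- bmx
    }
    accmin[1] <- 0; accmax[1] <- 0    # k = 0: v itself is a species root
    smin[[v]] <<- accmin; smax[[v]] <<- accmax
    bpmin[[v]] <<- stages_min; bpmax[[v]] <<- stages_max
    invisible()
  }
  rec(ix$root)

  N <- length(ix$lens); Ttot <- sum(ix$lens)
  f <- function(k, s) {
    a <- if (k > 0) k * log(k / s) - k else 0
    nw <- N - k; sw <- Ttot - s
    b <- if (nw > 0) nw * log(nw / max(sw, BRLEN_FLOOR)) - nw else 0
    a + b
  }
  root_min <- smin[[ix$root]]; root_max <- smax[[ix$root]]
  best <- -Inf; best_k <- 0L; best_side <- "min"
  for (k1 in seq_along(root_min)) {
    k <- k1 - 1L
    if (is.finite(root_min[k1])) {
      val <- f(k, root_min[k1])
      if (val > best + 1e-12) { best <- val; best_k <- k; best_side <- "min" }
    }
    if (is.finite(root_max[k1])) {
      val <- f(k, root_max[k1])
      if (val > best + 1e-12) { best <- val; best_k <- k; best_side <- "max" }
    }
  }
  ## backtrack one delimitation attaining (best_k, best_side)
  collect <- function(v, k, side) {
    if (k == 0L) return(v)
    kids <- ix$children[[v]]
    stages <- if (side == "min") bpmin[[v]] else bpmax[[v]]
    out <- integer(0)
    k1 <- k + 1L
    for (ci in rev(seq_along(kids))) {
      bp <- stages[[ci]][, k1]
      i <- bp[1]; j <- bp[2]
      out <- c(out, collect(kids[ci], j - 1L, side))
      k1 <- i
    }
    out
  }
  collect(ix$root, best_k, best_side)
}

## greedy root-to-tip search with a split/merge local-exchange pass
## (used for the multi-rate mode on large trees)
greedy_species_roots <- function(ix, mode) {
  obj <- function(S) ptp_objective(ix, S, mode)$objective
  refine <- function(S) {
    repeat {
      cur <- obj(S)
      best <- NULL; best_val <- cur + 1e-10
      ## splits: replace an internal species root by its children
      for (i in seq_along(S)) {
        s <- S[i]
        if (s > ix$ntip) {
          cand <- c(S[-i], ix$children[[s]])
          v <- obj(cand)
          if (v > best_val) { best <- cand; best_val <- v }
        }
      }
      ## merges: if every child of a node is a species root, lump them
      parents <- unique(ix$parent[S])
      parents <- parents[parents != 0L]
      for (p in parents) {
        kids <- ix$children[[p]]
        if (all(kids %in% S)) {
          cand <- c(setdiff(S, kids), p)
          v <- obj(cand)
          if (v > best_val) { best <- cand; best_val <- v }
        }
      }
      if (is.null(best)) return(S)
      S <- best
    }
  }
  cand <- list(refine(ix$root),                 # coarse start
               refine(seq_len(ix$ntip)))        # fine start
  vals <- vapply(cand, obj, 0)
  cand[[which.max(vals)]]
}

#' Maximum-likelihood Poisson tree processes delimitation
#'
#' Trees with at most `exact_max_tips` tips are solved by enumerating
#' every valid species-root set. Larger trees use the scalable search
#' (`method = "fast"`): in single-rate mode a dynamic program over
#' (speciation-edge count, total speciation length) that is provably
#' exact; in multi-rate mode a greedy best-split search from both a
#' one-species and an all-tips start with a split/merge exchange pass.
#' The result never scores below the one-species or the tips-as-species
#' baseline.
#'
#' @param tree rooted `phylo` tree with branch lengths, >= 2 tips.
#' @param mode `"single"` or `"multi"` (multi-rate, AIC-penalised).
#' @param outgroup optional tip label pruned before delimitation.
#' @param method `"auto"` (enumeration up to `exact_max_tips`, then
#'   `"fast"`), `"exact"` (always enumerate), or `"fast"`.
#' @param exact_max_tips exhaustive-search size limit under `"auto"`.
#' @return Object of class `ptp_fit`.
#' @export
ptp_ml_search <- function(tree, mode = c("single", "multi"), outgroup = NULL,
                          method = c("auto", "exact", "fast"),
                          exact_max_tips = 12) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  tree <- validate_tree(tree)
  if (!ape::is.rooted(tree))
    dm_stop("tree is unrooted: root it (e.g. on an outgroup) before PTP",
            "input_error")
  if (!is.null(outgroup)) {
    dm_assert(outgroup %in% tree$tip.label,
              sprintf("outgroup '%s' is not a tip", outgroup))
    tree <- ape::drop.tip(tree, outgroup)
    dm_assert(length(tree$tip.label) >= 2, "fewer than 2 tips after pruning")
  }
  dm_assert(length(tree$tip.label) >= 2, "need at least 2 tips")
  dm_assert(!is.null(tree$edge.length), "tree has no branch lengths")
  ix <- tree_index(tree)
  if (method == "auto")
    method <- if (ix$ntip <= exact_max_tips) "exact" else "fast"
  if (method == "exact") {
    cands <- enumerate_species_roots(ix)
    vals <- vapply(cands, function(S) ptp_objective(ix, S, mode)$objective, 0)
    S <- cands[[which.max(vals)]]
  } else if (mode == "single") {
    S <- ptp_dp_single(ix)
  } else {
    S <- greedy_species_roots(ix, mode)
    ## never report below the trivial baselines
    base <- list(S, ix$root, seq_len(ix$ntip))
    vals <- vapply(base, function(b) ptp_objective(ix, b, mode)$objective, 0)
    S <- base[[which.max(vals)]]
  }
  res <- ptp_objective(ix, S, mode)
  spec <- edge_is_speciation(ix, S)
  structure(list(tree = tree, mode = mode, method = method,
                 species_roots = sort(as.integer(S)),
                 n_species = length(S),
                 loglik = res$loglik, objective = res$objective,
                 lambda_speciation =
                   if (any(spec)) sum(spec) / sum(ix$lens[spec]) else NA_real_,
                 lambda_within =
                   if (any(!spec)) sum(!spec) / sum(ix$lens[!spec])
                   else NA_real_),
            class = "ptp_fit")
}

#' @export
print.ptp_fit <- function(x, ...) {
  cat(sprintf("Poisson tree processes delimitation (%s-rate, %s search)\n",
              x$mode, x$method))
  cat(sprintf("  %d tips -> %d species;  log-likelihood %.4f\n",
              length(x$tree$tip.label), x$n_species, x$loglik))
  if (!is.na(x$lambda_speciation))
    cat(sprintf("  speciation rate %.3g;  within rate %.3g\n",
                x$lambda_speciation, x$lambda_within))
  invisible(x)
}

#' Convert a PTP delimitation to a partition
#'
#' @param fit a `ptp_fit`.
#' @return A `partition`: one block per species subtree.
#' @export
delimitation_to_partition <- function(fit) {
  ix <- tree_index(fit$tree)
  tu <- tips_under(ix)
  lab <- character(ix$ntip)
  for (k in seq_along(fit$species_roots))
    lab[tu[[fit$species_roots[k]]]] <- sprintf("SP%d", k)
  as_partition(stats::setNames(lab, fit$tree$tip.label))
}

#' Count of valid species-root sets of a tree
#'
#' Antichain recursion: `c(leaf) = 1`, `c(node) = 1 + prod(c(children))`.
#'
#' @param tree rooted `phylo` tree.
#' @return Integer count of delimitations the exact search enumerates.
#' @export
count_delimitations <- function(tree) {
  ix <- tree_index(validate_tree(tree))
  rec <- function(v) {
    if (v <= ix$ntip) return(1)
    1 + prod(vapply(ix$children[[v]], rec, 0))
  }
  rec(ix$root)
}
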