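test_that("rate-class contributions match the closed form", {
  ## lambda-hat = 1 in both cases
  expect_equal(rate_class_loglik(c(0.5, 1.5)), -2)
  expect_equal(rate_class_loglik(1), -1)
  expect_equal(rate_class_loglik(numeric(0)), 0)
  ## splitting a class into parts with the same mean leaves the sum
  ## unchanged
  expect_equal(rate_class_loglik(c(2, 2, 4, 4)),
               rate_class_loglik(c(2, 4)) + rate_class_loglik(c(4, 2)))
})

test_that("delimitation log-likelihood sums its edge classes", {
  tr <- ape::read.tree(text = "((a:1,b:1):2,(c:1,d:1):2);")
  root <- 5L  # ape numbering: tips 1..4, root 5, clades 6 and 7
  ## one species: all six edges in the within class
  expect_equal(ptp_loglik(tr, root), rate_class_loglik(c(1, 1, 1, 1, 2, 2)))
  ## two species at the clade roots: clade stems are speciation edges
  expect_equal(ptp_loglik(tr, c(6L, 7L)),
               rate_class_loglik(c(2, 2)) + rate_class_loglik(rep(1, 4)))
  ## every tip a species: all edges speciation
  expect_equal(ptp_loglik(tr, 1:4), rate_class_loglik(c(1, 1, 1, 1, 2, 2)))
  ## invalid sets are rejected
  expect_error(ptp_loglik(tr, c(6L)), class = "delimatch_error")
})

test_that("the candidate count follows the antichain recursion", {
  expect_equal(count_delimitations(ape::read.tree(text = "(a:1,b:1);")), 2)
  expect_equal(count_delimitations(
    ape::read.tree(text = "((a:1,b:1):1,c:1);")), 3)
  expect_equal(count_delimitations(
    ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")), 5)
  expect_equal(count_delimitations(
    ape::read.tree(text = "(((a:1,b:1):1,c:1):1,d:1);")), 4)
  ## caterpillar of 5: c = 1 + c(4) = 5
  expect_equal(count_delimitations(
    ape::read.tree(text = "((((a:1,b:1):1,c:1):1,d:1):1,e:1);")), 5)
  set.seed(1)
  tr <- ape::rtree(8)
  expect_equal(length(enumerate_species_roots(delimatch:::tree_index(tr))),
               count_delimitations(tr))
})

test_that("exact search recovers a simulated two-species delimitation", {
  set.seed(121)
  tr <- two_species_tree(n1 = 4, n2 = 4, within = 0.01, stem = 0.4)
  fit <- ptp_ml_search(tr, method = "exact")
  part <- delimitation_to_partition(fit)
  expect_equal(fit$n_species, 2L)
  expect_true(same_blocks(blocks_of(part),
                          list(sprintf("a%d", 1:4), sprintf("b%d", 1:4))))
  ## better than both baselines
  ix <- delimatch:::tree_index(tr)
  expect_gte(fit$loglik, ptp_loglik(tr, ix$root))
  expect_gte(fit$loglik, ptp_loglik(tr, seq_len(8)))
})

test_that("a two-tip tree picks the better of its two candidates", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.3);")
  fit <- ptp_ml_search(tr)
  cands <- list(3L, c(1L, 2L))
  lls <- vapply(cands, function(s) ptp_loglik(tr, s), 0)
  expect_equal(fit$loglik, max(lls))
})

test_that("the scalable single-rate search equals exhaustive enumeration", {
  set.seed(131)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n, br = function(k) rexp(k, 10))
    fe <- ptp_ml_search(tr, method = "exact")
    ff <- ptp_ml_search(tr, method = "fast")
    expect_equal(ff$loglik, fe$loglik, tolerance = 1e-9)
  }
})

test_that("rescaling branch lengths never changes the argmax delimitation", {
  set.seed(141)
  for (rep in 1:5) {
    tr <- ape::rtree(9, br = function(k) rexp(k, 5) + 0.01)
    f1 <- ptp_ml_search(tr, method = "exact")
    tr2 <- tr
    tr2$edge.length <- tr$edge.length * 7
    f2 <- ptp_ml_search(tr2, method = "exact")
    expect_identical(f1$species_roots, f2$species_roots)
    ## loglik shifts by -(number of edges) * log(c)
    expect_equal(f2$loglik, f1$loglik - nrow(tr$edge) * log(7),
                 tolerance = 1e-8)
  }
})

test_that("trivial conversions and input validation behave", {
  tr <- two_species_tree(3, 3, 0.01, 0.3)
  ix <- delimatch:::tree_index(tr)
  fit1 <- ptp_ml_search(tr)
  expect_equal(n_blocks(delimitation_to_partition(fit1)), fit1$n_species)

  ## unrooted input is refused with advice
  unr <- ape::unroot(ape::rtree(5))
  expect_error(ptp_ml_search(unr), class = "input_error")

  ## outgroup pruning
  tr2 <- ape::read.tree(text = "(((a:0.01,b:0.01):0.3,(c:0.01,d:0.01):0.3):0.5,out:0.8);")
  fit2 <- ptp_ml_search(tr2, outgroup = "out")
  expect_false("out" %in% names(delimitation_to_partition(fit2)))

  ## zero-length branches do not crash the likelihood
  tr3 <- ape::read.tree(text = "((a:0,b:0):0.2,(c:0.01,d:0.01):0.2);")
  expect_true(is.finite(ptp_ml_search(tr3)$loglik))
})

test_that("multi-rate mode penalises free rates and still covers all tips", {
  set.seed(151)
  tr <- two_species_tree(4, 4, 0.01, 0.4)
  fit <- ptp_ml_search(tr, mode = "multi", method = "exact")
  part <- delimitation_to_partition(fit)
  expect_setequal(names(part), tr$tip.label)
  ## the AIC-penalised objective is below the raw loglik when >1 class
  expect_lte(fit$objective, fit$loglik)
})
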