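mk_part <- function(...) {
  x <- c(...)
  as_partition(x)
}

test_that("exact-match counting agrees with the brute-force block oracle", {
  pa <- mk_part(a = "1", b = "1", c = "2", d = "2", e = "3", f = "3")
  pb <- mk_part(a = "x", b = "x", c = "y", d = "y", e = "y", f = "y")
  expect_equal(match_count(pa, pb), 1L)
  expect_equal(match_count(pa, pb), brute_match_count(pa, pb))

  expect_equal(match_count(pa, pa), 3L)

  singles <- as_partition(stats::setNames(letters[1:6], names(pa)))
  onebig <- as_partition(stats::setNames(rep("Z", 6), names(pa)))
  expect_equal(match_count(singles, onebig), 0L)

  pz <- mk_part(q = "1", r = "1")
  expect_error(match_count(pa, pz), class = "domain_mismatch_error")
})

test_that("match ratio follows 2 N_match / (N_a + N_b)", {
  pa <- mk_part(a = "1", b = "1", c = "2", d = "2", e = "3", f = "3")
  pb <- mk_part(a = "x", b = "x", c = "y", d = "y", e = "y", f = "y")
  expect_equal(match_ratio(pa, pb), 0.4)   # 2*1/(3+2)
  expect_equal(match_ratio(pa, pa), 1)
  expect_equal(match_ratio(pa, pb), match_ratio(pb, pa))

  ## count-table form reproduces a published-style column: 33 matches,
  ## 53 MOTUs, 45 reference species -> 0.67 at two decimals
  r <- match_ratio_from_counts(33, 53, 45)
  expect_equal(round2(r), 0.67)
  expect_error(match_ratio_from_counts(46, 50, 45), class = "delimatch_error")
})

test_that("reference blocks classify as match, split, lump or mixed", {
  ref <- mk_part(a = "R1", b = "R1", c = "R1")
  motu <- mk_part(a = "M1", b = "M1", c = "M2")
  expect_equal(unname(classify_reference_blocks(ref, motu)["R1"]), "split")

  ref2 <- mk_part(a = "R1", b = "R1", c = "R2", d = "R2")
  motu2 <- mk_part(a = "M", b = "M", c = "M", d = "M")
  st2 <- classify_reference_blocks(ref2, motu2)
  expect_equal(unname(st2[c("R1", "R2")]), c("lump", "lump"))

  ref3 <- mk_part(a = "R1", b = "R1", c = "R1", d = "R2", e = "R2")
  motu3 <- mk_part(a = "M1", b = "M1", c = "M2", d = "M2", e = "M2")
  st3 <- classify_reference_blocks(ref3, motu3)
  expect_equal(unname(st3["R1"]), "mixed")
  expect_equal(unname(st3["R2"]), "lump")

  idn <- classify_reference_blocks(ref2, mk_part(a = "A", b = "A",
                                                 c = "B", d = "B"))
  expect_true(all(idn == "match"))
})

test_that("statuses are exhaustive and all-match is equivalent to ratio 1", {
  set.seed(161)
  ids <- sprintf("s%d", 1:12)
  for (rep in 1:20) {
    pr <- random_partition(ids, 4)
    pm <- random_partition(ids, 5)
    st <- classify_reference_blocks(pr, pm)
    expect_setequal(names(st), unique(unclass(pr)))
    expect_true(all(st %in% c("match", "split", "lump", "mixed")))
    if (all(st == "match")) expect_equal(match_ratio(pr, pm), 1)
    if (match_ratio(pr, pm) == 1) expect_true(all(st == "match"))
    expect_equal(match_count(pr, pm), brute_match_count(pr, pm))
  }
})

test_that("refining a block cannot raise the match count faster than N_a", {
  set.seed(171)
  ids <- sprintf("s%d", 1:10)
  for (rep in 1:20) {
    pa <- random_partition(ids, 3)
    pb <- random_partition(ids, 3)
    ## split the largest block of pa in two
    bl <- partition_blocks(pa)
    big <- bl[[which.max(lengths(bl))]]
    if (length(big) < 2) next
    pa2 <- unclass(pa)
    pa2[big[1]] <- "NEWBLOCK"
    pa2 <- as_partition(pa2)
    dn <- match_count(pa2, pb) - match_count(pa, pb)
    da <- n_blocks(pa2) - n_blocks(pa)
    expect_lte(dn, da + 1)  # can gain at most one match per new block plus repair
  }
})

test_that("universal matches count reference blocks shared by every method", {
  ref <- mk_part(a = "R1", b = "R1", c = "R2", d = "R2", e = "R3", f = "R4")
  same <- as_partition(stats::setNames(unclass(ref), names(ref)))
  expect_equal(universal_match_count(ref, list(m1 = same)), 4L)

  singles <- as_partition(stats::setNames(letters[1:6], names(ref)))
  expect_equal(universal_match_count(ref, list(a = same, b = singles)), 2L)

  ## three methods sharing exactly two of four reference blocks
  m1 <- mk_part(a = "1", b = "1", c = "2", d = "2", e = "3", f = "3")
  m2 <- mk_part(a = "1", b = "1", c = "2", d = "2", e = "5", f = "6")
  m3 <- mk_part(a = "1", b = "1", c = "2", d = "2", e = "7", f = "7")
  expect_equal(universal_match_count(ref, list(m1, m2, m3)), 2L)

  expect_error(universal_match_count(ref, list()), class = "config_error")
})

test_that("the similarity matrix is symmetric with unit diagonal", {
  p1 <- mk_part(a = "1", b = "1", c = "2", d = "2")
  p2 <- mk_part(a = "x", b = "x", c = "y", d = "z")
  p3 <- mk_part(a = "q", b = "q", c = "q", d = "q")
  S <- pairwise_similarity(list(one = p1, two = p2, three = p3))
  expect_equal(S, t(S))
  expect_true(all(diag(S) == 1))
  expect_equal(S["one", "two"], 2 * 1 / (2 + 3))
  expect_equal(S["one", "three"], 0)
  expect_equal(S["two", "three"], 0)

  Sid <- pairwise_similarity(list(a = p1, b = p1))
  expect_true(all(Sid == 1))
})

test_that("specimens missing from one partition are dropped with a warning", {
  ref <- mk_part(a = "R1", b = "R1", c = "R2")
  motu <- mk_part(a = "M1", b = "M1", c = "M2", d = "M3")
  expect_warning(r <- match_ratio(ref, motu), "dropping")
  expect_equal(r, 1)
  expect_error(match_ratio(ref, motu, strict = TRUE),
               class = "domain_mismatch_error")
})

test_that("the congruence summary bundles counts, ratio and statuses", {
  ref <- mk_part(a = "R1", b = "R1", c = "R2", d = "R2")
  motu <- mk_part(a = "M1", b = "M1", c = "M2", d = "M3")
  cg <- congruence(ref, motu)
  expect_s3_class(cg, "congruence")
  expect_equal(cg$n_match, 1L)
  expect_equal(cg$n_ref, 2L)
  expect_equal(cg$n_motu, 3L)
  expect_equal(cg$match_ratio, 0.4)
  expect_equal(unname(cg$per_label), c("match", "split"))
})
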