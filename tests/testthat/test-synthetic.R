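test_that("community simulation is deterministic and internally consistent", {
  cfg <- community_config(n_species = 4, n_per_species = 3, seed = 7)
  c1 <- simulate_community(cfg)
  c2 <- simulate_community(cfg)
  expect_identical(unclass(c1$alignment), unclass(c2$alignment))
  expect_identical(unclass(c1$true_partition), unclass(c2$true_partition))
  expect_identical(ape::write.tree(c1$genealogy), ape::write.tree(c2$genealogy))

  ## shared specimen ids across alignment, partition and genealogy
  expect_setequal(rownames(c1$alignment), names(c1$true_partition))
  expect_setequal(c1$genealogy$tip.label, names(c1$true_partition))
  expect_equal(n_blocks(c1$true_partition), 4L)
  expect_equal(ncol(c1$alignment), 658L)

  c3 <- simulate_community(community_config(4, 3, seed = 8))
  expect_false(identical(unclass(c1$alignment), unclass(c3$alignment)))
})

test_that("impossible configurations are refused before simulation", {
  expect_error(community_config(5, 4, theta = 0.2, gap_factor = 5, seed = 1),
               class = "config_error")
  expect_error(community_config(3, 4, n_recent_pairs = 2, seed = 1),
               class = "config_error")
  expect_error(community_config(0, 4, seed = 1), class = "config_error")
  expect_error(community_config(5, 4), class = "config_error") # seed mandatory
})

test_that("a clean community has the promised barcode gap", {
  com <- simulate_community(community_config(5, 4, theta = 0.005,
                                             gap_factor = 10, seed = 3))
  D <- distance_matrix(com$alignment)
  lab <- unclass(com$true_partition)[rownames(D)]
  same <- outer(lab, lab, "==")
  ut <- upper.tri(D)
  expect_lt(max(D[ut & same]), min(D[ut & !same]))
  ## the standard 2.2% threshold sits inside the gap here
  expect_true(partitions_equal(single_linkage_delimit(D, 0.022),
                               com$true_partition))
})

test_that("introgressed specimens move next to their donor species", {
  com <- simulate_community(community_config(5, 4, seed = 11))
  set.seed(99)
  com2 <- inject_introgression(com, "species01", "species02", 1)
  ev <- com2$event_log[[length(com2$event_log)]]
  expect_equal(ev$type, "introgression")
  moved <- ev$specimens[1]
  D <- distance_matrix(com2$alignment)
  nn <- names(which.min(D[moved, setdiff(rownames(D), moved)]))
  expect_equal(unname(unclass(com2$true_partition)[nn]), "species01")
  ## labels unchanged
  expect_identical(unclass(com2$true_partition), unclass(com$true_partition))
  ## n = 0 leaves the community untouched
  com0 <- inject_introgression(com, "species01", "species02", 0)
  expect_identical(unclass(com0$alignment), unclass(com$alignment))
  expect_error(inject_introgression(com, "speciesXX", "species02", 1),
               class = "input_error")
})

test_that("an introgressed recipient is flagged by distance-based congruence", {
  cfg <- community_config(5, 4, n_introgression = 1, seed = 13)
  com <- simulate_community(cfg)
  ev <- Filter(function(e) e$type == "introgression", com$event_log)[[1]]
  D <- distance_matrix(com$alignment)
  st <- classify_reference_blocks(com$true_partition,
                                  single_linkage_delimit(D, 0.022))
  expect_true(st[[ev$recipient]] %in% c("mixed", "lump", "split"))
})

test_that("recent species pairs share near-zero mitochondrial divergence", {
  cfg <- community_config(6, 3, n_recent_pairs = 1, seed = 17)
  com <- simulate_community(cfg)
  ev <- Filter(function(e) e$type == "recent_pair", com$event_log)[[1]]
  D <- distance_matrix(com$alignment)
  bl <- partition_blocks(com$true_partition)
  cross <- D[bl[[ev$species[1]]], bl[[ev$species[2]]]]
  ## within usual intraspecific divergence, far below the barcode gap
  expect_lt(max(cross), 0.022)
  p <- single_linkage_delimit(D, 0.022)
  st <- classify_reference_blocks(com$true_partition, p)
  expect_true(all(st[ev$species] == "lump"))
})

test_that("geographic splits produce two within-species haplogroups", {
  cfg <- community_config(5, 6, n_geo_splits = 1, seed = 19)
  com <- simulate_community(cfg)
  ev <- Filter(function(e) e$type == "geo_split", com$event_log)[[1]]
  D <- distance_matrix(com$alignment)
  ids <- ev$specimens
  sub <- D[ids, ids]
  ## haplogroup structure: the largest within-species distance is well
  ## above theta but below the between-species gap
  expect_gt(max(sub), 2 * 0.005)
  expect_lt(max(sub), 0.05)
})

test_that("partition pairs round-trip their requested congruence counts", {
  set.seed(211)
  for (rep in 1:50) {
    n <- sample(8:40, 1)
    nm <- sample(0:3, 1)
    ns <- sample(0:2, 1)
    nl <- sample(0:2, 1)
    if (nm + 2 * ns + 2 * nl == 0) next
    need <- nm + 2 * ns + 2 * nl
    if (need > n) next
    pp <- make_partition_pair(n, nm, ns, nl, seed = rep)
    expect_equal(match_count(pp$ref, pp$motu), nm)
    expect_equal(brute_match_count(pp$ref, pp$motu), nm)
    st <- classify_reference_blocks(pp$ref, pp$motu)
    expect_equal(sum(st == "split"), ns)
    expect_equal(sum(st == "lump"), 2 * nl)
    expect_equal(sum(st == "match"), nm)
  }

  ## a published-style column reproduced on a synthetic pair: 45 reference
  ## blocks, 53 MOTUs, 33 exact matches -> ratio 0.67
  pp <- make_partition_pair(140, n_match = 33, n_split_events = 8,
                            n_lump_events = 2, seed = 5, split_ways = 2)
  ## splits add 8 extra MOTUs over the 37 non-match ref blocks
  expect_equal(n_blocks(pp$ref), 33 + 8 + 4)
  expect_equal(match_count(pp$ref, pp$motu), 33)

  ## identical request: everything matches, ratio 1
  ppid <- make_partition_pair(10, 4, 0, 0, seed = 2)
  expect_equal(match_ratio(ppid$ref, ppid$motu), 1)

  ## infeasible requests name the violated bound
  expect_error(make_partition_pair(5, 2, 1, 1, seed = 1),
               class = "config_error")
  expect_error(make_partition_pair(6, 0, 0, 0, seed = 1),
               class = "config_error")
})
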