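## Seeded generator of barcode communities with known species boundaries.
## Species sit on a random coalescent species genealogy whose minimum
## between-species divergence is pinned to gap_factor * theta; each species
## carries a random coalescent subtree rescaled so the expected within-
## species pairwise distance is theta. Sequences evolve along the genealogy
## under JC69 (matching the in-pipeline distance models). Discordance is
## injected as haplotype-level events after the baseline simulation:
## introgressed specimens take mutated copies of donor haplotypes; "recent
## pairs" are two species labels drawn from one genetic cluster (near-zero
## mtDNA divergence, distinct morphology); geographic splits give one
## species two divergent haplogroups.

#' Configuration of a synthetic barcode community
#'
#' @param n_species number of (morpho)species labels.
#' @param n_per_species specimens per species: a single count or a
#'   `c(min, max)` range sampled per species.
#' @param seq_length alignment length in sites (default 658, a standard
#'   barcode fragment).
#' @param theta expected within-species pairwise distance
#'   (substitutions/site).
#' @param gap_factor ratio of the minimum between-species divergence to
#'   `theta`; the barcode gap. Values >= 5 give a clean gap; 0 < values
#'   near 1 deliberately destroy it.
#' @param n_introgression haplotype-transfer events applied after the
#'   baseline simulation (one specimen each).
#' @param n_recent_pairs species pairs with near-zero mtDNA divergence but
#'   distinct labels.
#' @param n_geo_splits species given two divergent geographic haplogroups.
#' @param geo_divergence divergence between haplogroups (default
#'   `3 * theta`).
#' @param seed integer seed; mandatory, fixes the whole community.
#' @return A list of class `community_config`.
#' @export
community_config <- function(n_species, n_per_species = 4, seq_length = 658,
                             theta = 0.005, gap_factor = 10,
                             n_introgression = 0, n_recent_pairs = 0,
                             n_geo_splits = 0, geo_divergence = 3 * theta,
                             seed) {
  dm_assert(!missing(seed) && is.numeric(seed) && length(seed) == 1,
            "seed is mandatory", "config_error")
  dm_assert(n_species >= 1, "n_species must be >= 1", "config_error")
  dm_assert(all(n_per_species >= 1) && length(n_per_species) <= 2,
            "n_per_species must be a count or c(min, max)", "config_error")
  dm_assert(seq_length >= 1, "seq_length must be >= 1", "config_error")
  dm_assert(theta > 0 && gap_factor > 0, "theta and gap_factor must be > 0",
            "config_error")
  dm_assert(n_introgression >= 0 && n_recent_pairs >= 0 && n_geo_splits >= 0,
            "event counts must be >= 0", "config_error")
  if (gap_factor * theta >= 0.5)
    dm_stop(paste("unattainable barcode gap: gap_factor * theta =",
                  gap_factor * theta, ">= 0.5 saturates JC69 distances"),
            "config_error")
  dm_assert(2 * n_recent_pairs <= n_species,
            "n_recent_pairs needs 2 species each", "config_error")
  dm_assert(n_geo_splits <= n_species - 2 * n_recent_pairs,
            "too many geographic splits for the available species",
            "config_error")
  structure(list(n_species = as.integer(n_species),
                 n_per_species = as.integer(n_per_species),
                 seq_length = as.integer(seq_length), theta = theta,
                 gap_factor = gap_factor,
                 n_introgression = as.integer(n_introgression),
                 n_recent_pairs = as.integer(n_recent_pairs),
                 n_geo_splits = as.integer(n_geo_splits),
                 geo_divergence = geo_divergence,
                 seed = as.integer(seed)),
            class = "community_config")
}

## random coalescent subtree over the given tip labels, rescaled so the
## mean pairwise path length is `mean_dist`; returns rootless newick text
coalescent_newick <- function(labels, mean_dist) {
  m <- length(labels)
  if (m == 1) return(labels)
  sub <- ape::rcoal(m, tip.label = labels)
  coph <- ape::cophenetic.phylo(sub)
  mp <- mean(coph[upper.tri(coph)])
  sub$edge.length <- sub$edge.length * (mean_dist / mp)
  sub("\\);$", ")", sub(";$", "", ape::write.tree(sub)))
}

#' Simulate a barcode community with known species boundaries
#'
#' @param cfg a [community_config()].
#' @return Object of class `synthetic_community`: `alignment`
#'   (`barcode_alignment`), `true_partition` (`partition` of morphospecies
#'   labels), `genealogy` (rooted `phylo` over the specimens), `event_log`
#'   (list of injected events), `config`.
#' @export
simulate_community <- function(cfg) {
  dm_assert(inherits(cfg, "community_config"), "cfg must be a community_config")
  with_seed(cfg$seed, {
    nsp <- cfg$n_species
    sizes <- if (length(cfg$n_per_species) == 1)
      rep(cfg$n_per_species, nsp)
    else sample(seq(cfg$n_per_species[1], cfg$n_per_species[2]), nsp,
                replace = TRUE)
    spec_ids <- lapply(seq_len(nsp), function(s)
      sprintf("sp%02d_%d", s, seq_len(sizes[s])))
    labels <- rep(sprintf("species%02d", seq_len(nsp)), sizes)
    names(labels) <- unlist(spec_ids)
    event_log <- list()

    ## genetic units: a recent pair shares one unit (the last species are
    ## paired up so indexing stays deterministic)
    units <- as.list(seq_len(nsp - 2 * cfg$n_recent_pairs))
    if (cfg$n_recent_pairs > 0) {
      for (r in seq_len(cfg$n_recent_pairs)) {
        a <- nsp - 2 * cfg$n_recent_pairs + 2 * r - 1L
        b <- a + 1L
        units <- c(units, list(c(a, b)))
        event_log <- c(event_log, list(list(
          type = "recent_pair",
          species = sprintf("species%02d", c(a, b)),
          specimens = c(spec_ids[[a]], spec_ids[[b]]))))
      }
    }
    geo_species <- integer(0)
    if (cfg$n_geo_splits > 0) {
      eligible <- which(seq_len(nsp) <= nsp - 2 * cfg$n_recent_pairs &
                          sizes >= 2)
      dm_assert(length(eligible) >= cfg$n_geo_splits,
                "not enough species of size >= 2 for geographic splits",
                "config_error")
      geo_species <- sort(sample(eligible, cfg$n_geo_splits))
    }

    ## per-unit subtree newick
    unit_nwk <- vapply(seq_along(units), function(u) {
      sp <- units[[u]]
      ids <- unlist(spec_ids[sp])
      if (length(sp) == 1 && sp %in% geo_species) {
        half <- ceiling(length(ids) / 2)
        g1 <- coalescent_newick(ids[seq_len(half)], cfg$theta)
        g2 <- coalescent_newick(ids[-seq_len(half)], cfg$theta)
        event_log <<- c(event_log, list(list(
          type = "geo_split", species = sprintf("species%02d", sp),
          specimens = ids, divergence = cfg$geo_divergence)))
        sprintf("(%s:%g,%s:%g)", g1, cfg$geo_divergence / 2,
                g2, cfg$geo_divergence / 2)
      } else {
        coalescent_newick(ids, cfg$theta)
      }
    }, "")

    ## species genealogy: pure-birth (Yule) topology, uniformly stretched
    ## so the shallowest between-unit divergence equals gap_factor * theta
    if (length(units) == 1) {
      nwk <- if (grepl("^\\(", unit_nwk[1])) paste0(unit_nwk[1], ";")
             else sprintf("(%s:0);", unit_nwk[1])
    } else {
      nu <- length(units)
      ut <- ape::rphylo(nu, birth = 1, death = 0)
      ut$tip.label <- sprintf("unitzz%dzz", seq_len(nu))
      coph <- ape::cophenetic.phylo(ut)
      ut$edge.length <- ut$edge.length *
        (cfg$gap_factor * cfg$theta / min(coph[upper.tri(coph)]))
      nwk <- ape::write.tree(ut)
      for (u in seq_along(units))
        nwk <- sub(sprintf("unitzz%dzz:", u),
                   sprintf("%s:", unit_nwk[u]), nwk, fixed = TRUE)
    }
    genealogy <- validate_tree(ape::read.tree(text = nwk))

    ## sequences along the genealogy under JC69 (equal rates/frequencies)
    sim <- phangorn::simSeq(genealogy, l = cfg$seq_length, type = "DNA")
    m <- toupper(as.character(sim))
    aln <- as_alignment(m[names(labels), , drop = FALSE])

    community <- structure(list(alignment = aln,
                                true_partition = as_partition(labels),
                                genealogy = genealogy,
                                event_log = event_log,
                                config = cfg),
                           class = "synthetic_community")
    if (cfg$n_introgression > 0) {
      dm_assert(nsp >= 2, "introgression needs >= 2 species", "config_error")
      for (e in seq_len(cfg$n_introgression)) {
        pair <- sample(nsp, 2)
        community <- inject_introgression(
          community,
          donor_species = sprintf("species%02d", pair[1]),
          recipient_species = sprintf("species%02d", pair[2]),
          n_specimens = 1)
      }
    }
    community
  })
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf(
    "synthetic barcode community: %d specimens, %d species, %d sites\n",
    nrow(x$alignment), n_blocks(x$true_partition), ncol(x$alignment)))
  if (length(x$event_log))
    cat(sprintf("  injected events: %s\n",
                paste(vapply(x$event_log, `[[`, "", "type"), collapse = ", ")))
  invisible(x)
}

#' Inject an introgression event into a community
#'
#' Selected recipient specimens take mutated copies of randomly chosen
#' donor haplotypes (each site flipped with probability `theta`, so the
#' copies sit within usual intraspecific divergence of the donor). True
#' partition labels are unchanged; the event is logged. Uses the current
#' RNG state: seed the caller for reproducibility.
#'
#' @param community a `synthetic_community`.
#' @param donor_species,recipient_species species labels of the true
#'   partition.
#' @param n_specimens how many recipient specimens to replace
#'   (`<=` recipient size; 0 leaves the community unchanged).
#' @return The modified `synthetic_community`.
#' @export
inject_introgression <- function(community, donor_species, recipient_species,
                                 n_specimens = 1) {
  p <- community$true_partition
  blocks <- partition_blocks(p)
  for (s in c(donor_species, recipient_species))
    if (!s %in% names(blocks))
      dm_stop(sprintf("unknown species label '%s'", s), "input_error")
  dm_assert(donor_species != recipient_species,
            "donor and recipient must differ")
  recip <- blocks[[recipient_species]]
  dm_assert(n_specimens <= length(recip),
            "n_specimens exceeds recipient species size")
  if (n_specimens == 0) return(community)
  theta <- community$config$theta
  chosen <- sample(recip, n_specimens)
  donors <- sample(blocks[[donor_species]], n_specimens, replace = TRUE)
  aln <- unclass(community$alignment)
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_specimens)) {
    seqd <- aln[donors[k], ]
    flip <- which(stats::runif(length(seqd)) < theta & seqd %in% bases)
    for (site in flip)
      seqd[site] <- sample(setdiff(bases, seqd[site]), 1)
    aln[chosen[k], ] <- seqd
  }
  community$alignment <- as_alignment(aln)
  community$event_log <- c(community$event_log, list(list(
    type = "introgression", donor = donor_species,
    recipient = recipient_species, specimens = sort(chosen),
    donors = donors)))
  community
}

#' Construct a partition pair with exact congruence counts
#'
#' Builds a reference partition and a MOTU partition over `domain_size`
#' specimens such that [match_count()] returns exactly `n_match`,
#' [classify_reference_blocks()] reports exactly `n_split_events` split
#' labels and `lump_size * n_lump_events` lumped labels, and everything
#' else is a match. Construction is deterministic given `seed`.
#'
#' @param domain_size number of specimens.
#' @param n_match number of exactly matching blocks.
#' @param n_split_events reference blocks split into `split_ways` MOTUs.
#' @param n_lump_events MOTUs each merging `lump_size` reference blocks.
#' @param seed integer seed.
#' @param split_ways MOTUs per split event (>= 2).
#' @param lump_size reference blocks per lump event (>= 2).
#' @return List with `ref` and `motu` (`partition`s) and `requested`.
#' @export
make_partition_pair <- function(domain_size, n_match, n_split_events,
                                n_lump_events, seed, split_ways = 2,
                                lump_size = 2) {
  dm_assert(split_ways >= 2 && lump_size >= 2,
            "split_ways and lump_size must be >= 2", "config_error")
  dm_assert(n_match >= 0 && n_split_events >= 0 && n_lump_events >= 0,
            "counts must be >= 0", "config_error")
  need <- n_match + split_ways * n_split_events + lump_size * n_lump_events
  if (domain_size < need)
    dm_stop(sprintf(
      "infeasible request: %d matches + %d splits x %d + %d lumps x %d need %d specimens, domain has %d",
      n_match, n_split_events, split_ways, n_lump_events, lump_size,
      need, domain_size), "config_error")
  if (need == 0 && domain_size > 0)
    dm_stop("no blocks requested but domain is non-empty", "config_error")
  with_seed(seed, {
    ids <- sample(sprintf("t%03d", seq_len(domain_size)))
    ref <- character(0); motu <- character(0)
    take <- function(n) {
      out <- ids[seq_len(n)]; ids <<- ids[-seq_len(n)]; out
    }
    slots <- list()   # each: list(type, ref_labels, motu_labels)
    ri <- 0L; mi <- 0L
    for (k in seq_len(n_match)) {
      ri <- ri + 1L; mi <- mi + 1L
      x <- take(1)
      ref[x] <- sprintf("R%d", ri); motu[x] <- sprintf("M%d", mi)
      slots[[length(slots) + 1L]] <-
        list(type = "match", ref = sprintf("R%d", ri),
             motu = sprintf("M%d", mi))
    }
    for (k in seq_len(n_split_events)) {
      ri <- ri + 1L
      mls <- sprintf("M%d", mi + seq_len(split_ways)); mi <- mi + split_ways
      x <- take(split_ways)
      ref[x] <- sprintf("R%d", ri)
      motu[x] <- mls
      slots[[length(slots) + 1L]] <-
        list(type = "split", ref = sprintf("R%d", ri), motu = mls)
    }
    for (k in seq_len(n_lump_events)) {
      mi <- mi + 1L
      rls <- sprintf("R%d", ri + seq_len(lump_size)); ri <- ri + lump_size
      x <- take(lump_size)
      ref[x] <- rls
      motu[x] <- sprintf("M%d", mi)
      slots[[length(slots) + 1L]] <-
        list(type = "lump", ref = rls, motu = sprintf("M%d", mi))
    }
    ## distribute leftovers without changing any status
    while (length(ids)) {
      sl <- slots[[sample(length(slots), 1)]]
      x <- take(1)
      ref[x] <- if (length(sl$ref) == 1) sl$ref else sample(sl$ref, 1)
      motu[x] <- if (length(sl$motu) == 1) sl$motu else sample(sl$motu, 1)
    }
    list(ref = as_partition(ref), motu = as_partition(motu),
         requested = list(n_match = n_match,
                          n_split_events = n_split_events,
                          n_lump_events = n_lump_events,
                          split_ways = split_ways, lump_size = lump_size))
  })
}
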