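# delimatch

Single-locus species delimitation engines and partition congruence
statistics for DNA barcode data.

DNA barcoding sorts specimens into molecular operational taxonomic units
(MOTUs) and treats them as putative species. In species-rich, poorly known
groups — tropical chafer radiations are a canonical example — the MOTUs a
study reports depend heavily on *which* delimitation algorithm was run,
and none of them is guaranteed to coincide with the morphospecies a
taxonomist recognises from, say, male genital morphology. `delimatch`
implements the whole comparison workshop in one package:

* **Delimitation engines** (all de novo, single locus):
  * fixed-threshold single-linkage clustering (`single_linkage_delimit`),
    the stated proxy for BIN assignment at the 2.2% seed threshold;
  * statistical-parsimony networks at the 95% connection limit
    (`tcs_delimit`, `connection_limit`);
  * barcode-gap discovery over a geometric grid of prior intraspecific
    divergences, with recursive refinement (`abgd_delimit`);
  * ranked hierarchical partitioning scoring every single-linkage merge
    level by a panmixia probability and a relative gap width
    (`asap_delimit`);
  * Poisson tree processes maximum-likelihood delimitation on a rooted
    tree, single-rate and AIC-penalised multi-rate (`ptp_ml_search`), with
    an exhaustive search for small trees and a provably exact dynamic
    program for single-rate mode on trees of any size.
* **Congruence statistics**: the taxonomic match ratio

  ```
  match ratio = 2 * N_match / (N_mol + N_morph)
  ```

  where `N_match` counts specimen sets that appear as a block in both
  partitions (exact matches, all individuals), `N_mol` is the number of
  MOTUs and `N_morph` the number of reference (morpho)species. Plus
  per-species classification into match / split / lump / mixed
  (`classify_reference_blocks`), universal-match counting across methods
  (`universal_match_count`), and the pairwise method-similarity matrix
  (`pairwise_similarity`).
* **Ordination**: `1 - s` (or `sqrt(1 - s)`) transform and principal
  coordinate analysis of the method-similarity matrix
  (`ordinate_methods`, `pcoa`).
* **Synthetic communities**: a seeded simulator of 658-bp barcode
  alignments with known species boundaries, a controllable barcode gap,
  and injectable discordance — introgression, recent divergence with
  distinct morphology, geographic haplogroup splits
  (`simulate_community`, `inject_introgression`) — plus exact-count
  congruence fixtures (`make_partition_pair`).
* **Pipeline**: `run_pipeline()` orchestrates simulate/load → distances →
  all engines → congruence table → similarity matrix → PCoA, writing TSV
  and JSON reports.

## Worked example

Simulate a 5-species community (4 specimens each, within-species
diversity 0.005 substitutions/site, a ten-fold barcode gap) in which two
"species" labels share one mitochondrial cluster — the classic recently
diverged pair whose genitalia disagree with their barcodes — and compare
four engines against the true morphospecies partition:

```r
library(delimatch)

com <- simulate_community(community_config(n_species = 5, n_per_species = 4,
                                           theta = 0.005, gap_factor = 10,
                                           n_recent_pairs = 1, seed = 42))
D <- distance_matrix(com$alignment, model = "p")
motus <- list(
  threshold = single_linkage_delimit(D, 0.022),
  tcs       = tcs_delimit(com$alignment),
  asap      = asap_delimit(D, R = 999, seed = 42)$best,
  ptp       = delimitation_to_partition(ptp_ml_search(com$genealogy)))
for (m in names(motus)) {
  cg <- congruence(com$true_partition, motus[[m]])
  cat(sprintf("%-9s N_match=%2d N_MOTU=%2d match ratio=%.2f\n",
              m, cg$n_match, cg$n_motu, round2(cg$match_ratio)))
}
```

```
threshold N_match= 3 N_MOTU= 4 match ratio=0.67
tcs       N_match= 2 N_MOTU= 5 match ratio=0.40
asap      N_match= 3 N_MOTU= 4 match ratio=0.67
ptp       N_match= 0 N_MOTU=11 match ratio=0.00
```

No engine recovers the 5 true species: the distance-based methods lump
the recent pair into one MOTU (4 MOTUs, 3 of which match), and the
tree-based PTP run oversplits deep within-species lineages. The
per-species view and the method ordination:

```r
print(congruence(com$true_partition, motus$threshold))
ord <- ordinate_methods(c(list(morphology = com$true_partition), motus))
round(ord$points[, 1:2], 3)
```

```
partition congruence: N_match = 3, N_ref = 5, N_motu = 4
  match ratio = 0.6667 (table form 0.67)

match split  lump mixed
    3     0     2     0

            Axis1  Axis2
morphology  0.248  0.287
threshold   0.262 -0.058
tcs        -0.041 -0.240
asap        0.262 -0.058
ptp        -0.730  0.069
```

The two lumped labels are exactly the injected recent pair; threshold and
ranked-partition clustering produce identical MOTUs and plot on the same
point, while the oversplitting PTP run sits far from morphology on the
first axis.

For published-style count tables there is a bypass that pins the
arithmetic without sequence data:

```r
report_from_counts(n_match = c(TCS = 33, BIN = 30),
                   n_motu = c(53, 61), n_morph = 45)
#>   method n_match n_motu n_morph match_ratio ratio_2dp ratio_trunc
#> 1    TCS      33     53      45   0.6734694      0.67        0.67
#> 2    BIN      30     61      45   0.5660377      0.57        0.57
```

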