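## End-to-end orchestration: simulate/load -> distances -> delimit (all
## requested engines) -> congruence vs the reference -> similarity matrix
## and ordination, with every table written as TSV and structured results
## as JSON. A bypass report generator turns published-style count tables
## directly into match-ratio tables so the table arithmetic can be pinned
## without any sequence data.

#' Match-ratio report from a count table
#'
#' @param n_match named integer vector: exact matches per method.
#' @param n_motu integer vector: MOTUs per method (same order).
#' @param n_morph reference block count.
#' @return Data frame with one row per method: `n_match`, `n_motu`,
#'   `match_ratio` (full precision), `ratio_2dp` (half-even rounding) and
#'   `ratio_trunc` (truncation) -- both table conventions occur in
#'   published congruence tables.
#' @export
report_from_counts <- function(n_match, n_motu, n_morph) {
  r <- match_ratio_from_counts(n_match, n_motu, n_morph)
  data.frame(method = if (is.null(names(n_match)))
    sprintf("method%d", seq_along(n_match)) else names(n_match),
    n_match = as.integer(n_match),
    n_motu = as.integer(n_motu),
    n_morph = as.integer(n_morph),
    match_ratio = unname(r),
    ratio_2dp = unname(round2(r)),
    ratio_trunc = unname(trunc2(r)),
    row.names = NULL)
}

default_methods <- c("threshold", "tcs", "abgd", "asap", "ptp")

## run one engine, returning a named list of partitions it contributes
run_engine <- function(method, aln, D, tree, params, seed) {
  switch(method,
    threshold = list(threshold = single_linkage_delimit(
      D, threshold = params$threshold %||% 0.022)),
    tcs = list(tcs = tcs_delimit(
      aln, confidence = params$confidence %||% 0.95)),
    abgd = {
      res <- abgd_delimit(D, params$abgd_config %||% abgd_config())
      counts <- vapply(res$results, `[[`, 0L, "n_motu")
      modal <- which(counts == names(sort(-table(counts)))[1])[1]
      list(abgd = res$results[[modal]]$partition)
    },
    asap = {
      res <- asap_delimit(D, R = params$permutations %||% 999, seed = seed)
      out <- list(asap_1st = res$best)
      if (!is.null(res$second)) out$asap_2nd <- res$second
      out
    },
    ptp = {
      dm_assert(!is.null(tree), "PTP requires a tree", "config_error")
      fit <- ptp_ml_search(tree, mode = params$ptp_mode %||% "single",
                           outgroup = params$outgroup)
      list(ptp = delimitation_to_partition(fit))
    },
    dm_stop(sprintf("unknown delimitation method '%s'", method),
            "config_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full delimitation-and-congruence pipeline
#'
#' @param cfg list describing the run:
#'   * `simulation` -- a [community_config()]; or `alignment`, `reference`
#'     and optionally `tree`, `matrix` as file paths;
#'   * `methods` -- subset of `"threshold"`, `"tcs"`, `"abgd"`, `"asap"`,
#'     `"ptp"` (default: all that the inputs support);
#'   * `params` -- optional per-method parameter list (`threshold`,
#'     `confidence`, `abgd_config`, `permutations`, `ptp_mode`,
#'     `outgroup`, `distance_model`);
#'   * `seed` -- mandatory when simulation or ASAP permutations are used;
#'   * `intersect` -- restrict analysis to the specimen ids shared by all
#'     inputs instead of failing on a mismatch.
#' @param out_dir output directory; created if needed. Per-method
#'   partitions, a count/ratio table, a per-species status table, the
#'   method-similarity matrix, PCoA coordinates and a JSON summary are
#'   written there.
#' @return The report as a list (invisibly): `partitions`, `table`,
#'   `status`, `similarity`, `pcoa`, `universal_matches`, `log`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  dm_assert(is.list(cfg), "cfg must be a list", "config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- cfg$params %||% list()
  tree <- NULL
  if (!is.null(cfg$simulation)) {
    community <- simulate_community(cfg$simulation)
    aln <- community$alignment
    ref <- community$true_partition
    tree <- community$genealogy
    write_fasta(aln, file.path(out_dir, "alignment.fasta"))
    write_partition(ref, file.path(out_dir, "true_partition.tsv"))
    write_newick(tree, file.path(out_dir, "genealogy.nwk"))
    jsonlite::write_json(community$event_log,
                         file.path(out_dir, "event_log.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    dm_assert(!is.null(cfg$alignment) && !is.null(cfg$reference),
              "cfg needs either a simulation or alignment + reference paths",
              "config_error")
    aln <- read_fasta(cfg$alignment)
    ref <- read_partition(cfg$reference)
    if (!is.null(cfg$tree)) tree <- read_newick(cfg$tree)
    sets <- list(alignment = rownames(aln), reference = names(ref))
    if (!is.null(tree)) sets$tree <- tree$tip.label
    ids <- reconcile_ids(sets, intersect = isTRUE(cfg$intersect))
    aln <- as_alignment(unclass(aln)[ids, , drop = FALSE])
    ref <- as_partition(unclass(ref)[ids])
    if (!is.null(tree) && length(setdiff(tree$tip.label, ids)))
      tree <- ape::drop.tip(tree, setdiff(tree$tip.label, ids))
  }
  methods <- cfg$methods %||%
    setdiff(default_methods, if (is.null(tree)) "ptp" else character(0))
  dm_assert(length(methods) >= 1, "no delimitation method enabled",
            "config_error")
  seed <- cfg$seed
  if ("asap" %in% methods)
    dm_assert(!is.null(seed), "seed required for ASAP permutations",
              "config_error")
  D <- if (!is.null(cfg$matrix)) read_matrix(cfg$matrix)
       else distance_matrix(aln, model = params$distance_model %||% "p")

  partitions <- list()
  for (m in methods) {
    res <- tryCatch(run_engine(m, aln, D, tree, params, seed %||% 1L),
                    delimatch_error = function(e)
                      dm_stop(sprintf("stage '%s' failed: %s", m,
                                      conditionMessage(e)), "pipeline_error"))
    partitions <- c(partitions, res)
  }
  for (nm in names(partitions))
    write_partition(partitions[[nm]],
                    file.path(out_dir, sprintf("partition_%s.tsv", nm)))

  cong <- lapply(partitions, function(p) congruence(ref, p))
  tab <- report_from_counts(
    stats::setNames(vapply(cong, `[[`, 0L, "n_match"), names(cong)),
    vapply(cong, `[[`, 0L, "n_motu"),
    n_blocks(ref))
  utils::write.table(tab, file.path(out_dir, "match_ratio_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  status <- do.call(cbind, lapply(cong, `[[`, "per_label"))
  utils::write.table(
    data.frame(reference_block = rownames(status), status,
               check.names = FALSE),
    file.path(out_dir, "per_species_status.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  um <- universal_match_count(ref, partitions)
  all_parts <- c(list(reference = ref), partitions)
  S <- pairwise_similarity(all_parts)
  write_matrix(similarity_to_distance(S),
               file.path(out_dir, "method_distance.tsv"))
  ord <- if (length(all_parts) >= 3) ordinate_methods(all_parts) else NULL
  if (!is.null(ord) && ncol(ord$points) > 0)
    utils::write.table(
      data.frame(method = rownames(ord$points), ord$points,
                 check.names = FALSE),
      file.path(out_dir, "pcoa_coordinates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)

  log <- list(package_version = as.character(utils::packageVersion("delimatch")),
              seed = seed, methods = methods,
              n_specimens = length(ref), n_reference_blocks = n_blocks(ref),
              universal_matches = um,
              input_digest = lapply(partitions, function(p)
                sum(utf8ToInt(paste(block_keys(p), collapse = "")))))
  jsonlite::write_json(
    list(table = tab, universal_matches = um,
         similarity = as.data.frame(S), log = log),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(partitions = partitions, table = tab, status = status,
                 similarity = S, pcoa = ord, universal_matches = um,
                 log = log))
}
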