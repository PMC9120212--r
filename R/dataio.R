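## Central data containers and on-disk formats.
##
## Conventions used throughout the package:
##  * Alignment  -- character matrix (specimens x sites) of single upper-case
##                  IUPAC nucleotide codes plus '-' and '?', rownames = ids;
##                  class "barcode_alignment".
##  * Partition  -- named character vector, names = specimen ids, values =
##                  block labels; class "partition".
##  * Distance   -- plain numeric matrix, symmetric, zero diagonal, dimnames
##                  = specimen ids.
##  * Tree       -- ape "phylo", rooted, tip labels = specimen ids.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?")

#' Construct a barcode alignment
#'
#' @param seqs named character vector of equal-length sequence strings
#'   (IUPAC nucleotide codes, `-` for gaps, `?` for missing), or a character
#'   matrix of single characters with rownames.
#' @return A `barcode_alignment`: character matrix, specimens in rows.
#' @export
as_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    dm_assert(is.character(seqs) && length(seqs) >= 1,
              "sequences must be a non-empty character vector")
    ids <- names(seqs)
    dm_assert(!is.null(ids) && all(nzchar(ids)),
              "every sequence must carry a non-empty specimen id")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      dm_stop(sprintf("ragged alignment: sequence lengths %s",
                      paste(unique(lens), collapse = ", ")),
              "alignment_error")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- ids
  }
  dm_assert(!anyDuplicated(rownames(m)), "duplicate specimen ids")
  bad <- setdiff(unique(as.vector(m)), IUPAC_CHARS)
  if (length(bad))
    dm_stop(sprintf("illegal characters in alignment: %s",
                    paste(bad, collapse = " ")), "input_error")
  dm_assert(ncol(m) >= 1, "alignment has zero sites", "alignment_error")
  structure(m, class = c("barcode_alignment", class(m)))
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf("barcode alignment: %d specimens x %d sites\n",
              nrow(x), ncol(x)))
  invisible(x)
}

alignment_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1L, paste, collapse = ""),
                  rownames(aln))
}

#' Read a FASTA alignment
#'
#' The token before the first whitespace in each header is the specimen id.
#' All sequences must share one length; the alphabet is restricted to IUPAC
#' nucleotide codes plus `-` and `?`.
#'
#' @param path path to a FASTA file.
#' @return A [as_alignment()] object.
#' @export
read_fasta <- function(path) {
  dm_assert(file.exists(path), sprintf("file not found: %s", path))
  ## seqtype = "AA" keeps every character verbatim so that our own
  ## IUPAC-nucleotide validation sees the raw file content
  recs <- seqinr::read.fasta(path, as.string = TRUE, seqtype = "AA",
                             forceDNAtolower = FALSE)
  dm_assert(length(recs) > 0, "empty FASTA file", "input_error")
  ids <- names(recs)
  if (anyDuplicated(ids))
    dm_stop(sprintf("duplicate specimen ids in FASTA: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "input_error")
  seqs <- vapply(recs, as.character, "")
  as_alignment(stats::setNames(gsub("\\s", "", seqs), ids))
}

#' Write a FASTA alignment
#'
#' @param aln a `barcode_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  s <- alignment_strings(aln)
  writeLines(paste0(">", names(s), "\n", s), path)
  invisible(path)
}

#' Construct a partition of specimens into blocks
#'
#' @param x named character vector: names are specimen ids, values block
#'   labels.
#' @return A `partition` object.
#' @export
as_partition <- function(x) {
  ids <- names(x)
  dm_assert(!is.null(ids) && all(nzchar(ids)), "specimen ids required")
  dm_assert(!anyDuplicated(ids), "duplicate specimen ids in partition")
  x <- as.character(x)
  dm_assert(all(!is.na(x) & nzchar(x)), "empty block label")
  structure(stats::setNames(x, ids), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d specimens in %d blocks\n",
              length(x), n_blocks(x)))
  invisible(x)
}

#' Blocks of a partition
#'
#' @param p a `partition`.
#' @return Named list of sorted specimen-id vectors, one per block.
#' @export
partition_blocks <- function(p) {
  lapply(split(names(p), unname(unclass(p))), sort)
}

#' Number of blocks in a partition
#' @param p a `partition`.
#' @return Integer block count.
#' @export
n_blocks <- function(p) length(unique(unclass(p)))

## canonical block keys: a block is identified by its (sorted) member set
block_keys <- function(p) {
  vapply(partition_blocks(p), paste, "", collapse = "\r")
}

#' Read a specimen partition from a two-column TSV
#'
#' Columns are specimen id and block label. A header row is recognised (and
#' skipped) when the first field is one of `specimen`, `specimen_id`, `id`.
#'
#' @param path path to the TSV file.
#' @return A `partition`.
#' @export
read_partition <- function(path) {
  dm_assert(file.exists(path), sprintf("file not found: %s", path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           blank.lines.skip = TRUE)
  dm_assert(ncol(tab) >= 2, "partition file needs two tab-separated columns")
  if (tolower(tab[1, 1]) %in% c("specimen", "specimen_id", "id"))
    tab <- tab[-1, , drop = FALSE]
  dm_assert(nrow(tab) > 0, "empty partition file")
  if (anyDuplicated(tab[[1]]))
    dm_stop(sprintf("duplicate specimen rows: %s",
                    paste(unique(tab[[1]][duplicated(tab[[1]])]),
                          collapse = ", ")), "input_error")
  as_partition(stats::setNames(tab[[2]], tab[[1]]))
}

#' Write a partition as a two-column TSV
#'
#' @param p a `partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(p, path) {
  ord <- order(names(p))
  utils::write.table(
    data.frame(specimen_id = names(p)[ord], label = unclass(p)[ord]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate (and canonicalise) a pairwise distance matrix
#'
#' @param m square numeric matrix with specimen-id dimnames.
#' @param tol symmetry tolerance; larger deviations are an input error.
#' @return The matrix, exactly symmetrised, diagonal set to zero.
#' @export
validate_distance_matrix <- function(m, tol = 1e-8) {
  dm_assert(is.matrix(m) && is.numeric(m) && nrow(m) == ncol(m),
            "distance matrix must be square and numeric")
  ids <- rownames(m)
  dm_assert(!is.null(ids) && all(nzchar(ids)) && !anyDuplicated(ids),
            "distance matrix needs unique specimen-id dimnames")
  if (!is.null(colnames(m)))
    dm_assert(identical(colnames(m), ids),
              "row and column ids of distance matrix disagree")
  asym <- max(abs(m - t(m)))
  if (asym > tol)
    dm_stop(sprintf("asymmetric distance matrix (max |d_ij - d_ji| = %g)",
                    asym), "input_error")
  dm_assert(all(m >= -tol), "negative distances")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  colnames(m) <- ids
  m
}

#' Read a pairwise distance matrix
#'
#' Auto-detects the dialect: if the first whitespace-separated token of the
#' file is numeric the file is PHYLIP-style (count line, then
#' `label d1 d2 ...` rows, square or lower-triangle); otherwise it is a
#' labeled TSV with an id header row and an id first column.
#'
#' @param path path to the matrix file.
#' @return Validated symmetric numeric matrix.
#' @export
read_matrix <- function(path) {
  dm_assert(file.exists(path), sprintf("file not found: %s", path))
  first <- scan(path, what = "character", n = 1, quiet = TRUE)
  if (!is.na(suppressWarnings(as.numeric(first)))) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    n <- as.integer(first)
    rows <- strsplit(trimws(lines[-1]), "\\s+")
    dm_assert(length(rows) == n, "PHYLIP matrix: row count != header count")
    ids <- vapply(rows, `[[`, "", 1L)
    vals <- lapply(rows, function(r) as.numeric(r[-1]))
    nv <- lengths(vals)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    if (all(nv == n)) {
      for (i in seq_len(n)) m[i, ] <- vals[[i]]
    } else if (all(nv == seq_len(n) - 1L)) {   # lower triangle
      for (i in seq_len(n)) if (i > 1) {
        m[i, seq_len(i - 1L)] <- vals[[i]]
        m[seq_len(i - 1L), i] <- vals[[i]]
      }
    } else {
      dm_stop("unrecognised PHYLIP matrix shape", "input_error")
    }
    dm_assert(!anyNA(m), "non-numeric entries in distance matrix")
    validate_distance_matrix(m)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             row.names = 1, check.names = FALSE, quote = "")
    m <- as.matrix(tab)
    validate_distance_matrix(m)
  }
}

#' Write a distance matrix as labeled TSV
#'
#' @param m symmetric numeric matrix with id dimnames.
#' @param path output path.
#' @param digits significant digits written.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, digits = 12) {
  m <- validate_distance_matrix(m)
  out <- format(m, digits = digits, trim = TRUE, scientific = FALSE)
  df <- data.frame(id = rownames(m), out, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted tree in Newick format
#'
#' @param path path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object, validated: labeled unique
#'   tips, non-negative branch lengths.
#' @export
read_newick <- function(path) {
  dm_assert(file.exists(path), sprintf("file not found: %s", path))
  tr <- ape::read.tree(path)
  dm_assert(inherits(tr, "phylo"), "could not parse Newick tree")
  validate_tree(tr)
}

validate_tree <- function(tr) {
  dm_assert(inherits(tr, "phylo"), "not a phylo tree")
  if (any(is.na(tr$tip.label)) || any(!nzchar(tr$tip.label)))
    dm_stop("unlabeled tip in tree", "input_error")
  dm_assert(!anyDuplicated(tr$tip.label), "duplicate tip labels in tree")
  if (!is.null(tr$edge.length))
    dm_assert(all(tr$edge.length >= 0), "negative branch length")
  tr
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Reconcile specimen-id sets across inputs
#'
#' Specimen ids are the join key across alignment, tree, matrix and
#' partition files. Mismatched id sets are fatal by default and reported as
#' set differences; with `intersect = TRUE` analysis is restricted to the
#' common subset.
#'
#' @param id_sets named list of character vectors of specimen ids.
#' @param intersect if `TRUE`, return the common subset instead of erroring.
#' @return Character vector of ids usable by all inputs.
#' @export
reconcile_ids <- function(id_sets, intersect = FALSE) {
  dm_assert(length(id_sets) >= 1, "no id sets given")
  common <- Reduce(base::intersect, id_sets)
  full <- Reduce(base::union, id_sets)
  if (length(common) == length(full)) return(sort(common))
  if (intersect) {
    dm_assert(length(common) > 0, "no specimens shared by all inputs")
    return(sort(common))
  }
  diffs <- vapply(names(id_sets), function(nm) {
    missing <- setdiff(full, id_sets[[nm]])
    if (length(missing) == 0) "" else
      sprintf("%s lacks: %s", nm, paste(sort(missing), collapse = ", "))
  }, "")
  dm_stop(paste(c("specimen id sets disagree;",
                  diffs[nzchar(diffs)],
                  "(use intersect = TRUE to analyse the common subset)"),
                collapse = " "), "input_error")
}
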