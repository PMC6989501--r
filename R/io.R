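# Single file dialect everywhere: tab-delimited, UTF-8, '.' decimal.
# Samples are rows, ASVs are columns.

DIET_LEVELS <- c("low-carb", "low-fat")
SEX_LEVELS <- c("F", "M")
WINDOW_LEVELS <- c("BL", "W10")

#' Validate an ASV count table
#'
#' A count table is an integer matrix with unique sample identifiers as row
#' names and unique ASV identifiers as column names; all entries are
#' non-negative integers and every sample has at least one positive count.
#'
#' @param counts numeric matrix, samples in rows, ASVs in columns.
#' @return the validated matrix (storage mode integer), invisibly usable.
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count table must be a non-empty matrix (no samples)", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table must carry sample row names and ASV column names",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate ASV identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "count table cell (%s, %s) is not a non-negative integer",
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]),
      call. = FALSE)
  empty <- rownames(counts)[rowSums(counts) == 0]
  if (length(empty) > 0L)
    stop("samples with no positive counts: ", paste(empty, collapse = ", "),
         call. = FALSE)
  storage.mode(counts) <- "integer"
  counts
}

#' Read an ASV count table from TSV
#'
#' Expects a header row of ASV identifiers and a first column of sample
#' identifiers. Cells must be non-negative integers; anything else is a
#' format error naming the offending sample and ASV.
#'
#' @param path path to a tab-delimited file.
#' @return validated integer matrix (samples x ASVs).
#' @export
read_count_table <- function(path) {
  if (file.size(path) == 0)
    stop("no samples: '", path, "' is empty", call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("no samples in '", path, "'", call. = FALSE)
  samples <- df[[1L]]
  asvs <- colnames(df)[-1L]
  num <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(samples, asvs))
  nonnum <- which(is.na(num) & !is.na(as.matrix(df[-1L])), arr.ind = TRUE)
  if (nrow(nonnum) > 0L)
    stop(sprintf("count table cell (%s, %s) is not numeric",
                 samples[nonnum[1L, 1L]], asvs[nonnum[1L, 2L]]),
         call. = FALSE)
  validate_count_table(num)
}

#' Write an ASV count table to TSV
#'
#' @param counts validated count table matrix.
#' @param path output path.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_count_table(counts)
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from Newick
#'
#' The tree must be rooted and carry branch lengths (all non-negative). When
#' a count table is supplied the tip labels are cross-checked against its ASV
#' identifiers: any symmetric difference raises a warning, and tips absent
#' from the table can be pruned on request.
#'
#' @param path path to a Newick file.
#' @param counts optional count table to cross-check tips against.
#' @param prune if `TRUE`, drop tips absent from `counts`.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path, counts = NULL, prune = FALSE) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick in '", path, "'",
                          call. = FALSE)
  validate_tree(tree)
  if (!is.null(counts)) {
    extra <- setdiff(tree$tip.label, colnames(counts))
    missing <- setdiff(colnames(counts), tree$tip.label)
    if (length(extra) + length(missing) > 0L)
      warning("tree/table tip mismatch; only in tree: {",
              paste(extra, collapse = ", "), "}; only in table: {",
              paste(missing, collapse = ", "), "}", call. = FALSE)
    if (prune && length(extra) > 0L)
      tree <- ape::drop.tip(tree, extra)
  }
  tree
}

#' Validate a rooted tree with branch lengths
#'
#' @param tree an [ape::phylo] object.
#' @return the tree, invisibly.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("tree has negative or non-finite branch lengths", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("tree is not rooted", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels", call. = FALSE)
  invisible(tree)
}

#' Write a tree to Newick
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read and join sample- and subject-level metadata
#'
#' Sample metadata needs columns `sample_id`, `subject_id`, `window`
#' (`BL`/`W10`), `day_offset`, `lane`. Subject metadata needs `subject_id`,
#' `diet` (`low-carb`/`low-fat`), `sex` (`F`/`M`), `weight_loss_pct_12mo`,
#' and restricted-component dietary recall columns
#' `restricted_pct_bl`, `restricted_pct_3m`, `restricted_pct_6m`,
#' `restricted_pct_12m` (percent of total kcal from the diet's restricted
#' macronutrient at baseline and on-diet recalls). Every sample's subject
#' must exist; orphans are an error.
#'
#' @param sample_path TSV of per-sample records.
#' @param subject_path TSV of per-subject records.
#' @return a list with elements `samples` and `subjects` (data frames),
#'   class `cohort_metadata`.
#' @export
read_metadata <- function(sample_path, subject_path) {
  samples <- utils::read.delim(sample_path, check.names = FALSE,
                               stringsAsFactors = FALSE,
                               colClasses = c(sample_id = "character",
                                              subject_id = "character",
                                              lane = "character"))
  subjects <- utils::read.delim(subject_path, check.names = FALSE,
                                stringsAsFactors = FALSE,
                                colClasses = c(subject_id = "character"))
  validate_metadata(samples, subjects)
}

#' Validate joined cohort metadata
#' @param samples per-sample data frame.
#' @param subjects per-subject data frame.
#' @return `cohort_metadata` list.
#' @export
validate_metadata <- function(samples, subjects) {
  need_s <- c("sample_id", "subject_id", "window", "day_offset", "lane")
  need_u <- c("subject_id", "diet", "sex", "weight_loss_pct_12mo",
              "restricted_pct_bl", "restricted_pct_3m",
              "restricted_pct_6m", "restricted_pct_12m")
  miss <- setdiff(need_s, colnames(samples))
  if (length(miss)) stop("sample metadata missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(need_u, colnames(subjects))
  if (length(miss)) stop("subject metadata missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id", call. = FALSE)
  if (!all(samples$window %in% WINDOW_LEVELS))
    stop("unknown window level (expected BL/W10)", call. = FALSE)
  if (any(is.na(subjects$diet)) || !all(subjects$diet %in% DIET_LEVELS))
    stop("unknown or missing diet level (expected low-carb/low-fat)",
         call. = FALSE)
  if (any(is.na(subjects$sex)) || !all(subjects$sex %in% SEX_LEVELS))
    stop("unknown or missing sex level (expected F/M)", call. = FALSE)
  if (any(!nzchar(samples$lane)) || any(is.na(samples$lane)))
    stop("lane must be non-empty for every sample", call. = FALSE)
  orphan <- setdiff(samples$subject_id, subjects$subject_id)
  if (length(orphan) > 0L) {
    bad <- samples$sample_id[samples$subject_id %in% orphan]
    stop("samples reference unknown subjects: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  macro <- subjects[, need_u[5:8]]
  if (any(macro < 0 | macro > 100, na.rm = TRUE))
    stop("macronutrient percentages must lie in [0, 100]", call. = FALSE)
  structure(list(samples = samples, subjects = subjects),
            class = "cohort_metadata")
}

#' Write cohort metadata to two TSV files
#' @param metadata a `cohort_metadata` list.
#' @param sample_path,subject_path output paths.
#' @export
write_metadata <- function(metadata, sample_path, subject_path) {
  utils::write.table(metadata$samples, sample_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(metadata$subjects, subject_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(sample_path, subject_path))
}

#' Read an ASV taxonomy table
#'
#' TSV with columns `asv_id` and `genus` (empty string encodes a missing
#' genus assignment, never the literal "NA"). When a count table is given,
#' every table ASV must be present.
#'
#' @param path TSV path.
#' @param counts optional count table for cross-checking.
#' @return data frame with `asv_id`, `genus` (and any extra rank columns).
#' @export
read_taxonomy <- function(path, counts = NULL) {
  tax <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  if (!all(c("asv_id", "genus") %in% colnames(tax)))
    stop("taxonomy needs columns asv_id and genus", call. = FALSE)
  if (anyDuplicated(tax$asv_id)) stop("duplicate asv_id in taxonomy",
                                      call. = FALSE)
  if (!is.null(counts)) {
    miss <- setdiff(colnames(counts), tax$asv_id)
    if (length(miss) > 0L)
      stop("taxonomy missing ASVs present in count table: ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  tax
}

#' Write a taxonomy table to TSV
#' @param taxonomy data frame with `asv_id`, `genus`.
#' @param path output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
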