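#' Cluster ASVs by cutting the phylogenetic tree at a height
#'
#' Maximum-likelihood amplicon trees are not ultrametric, so "cutting at
#' height h" is realized as average-linkage agglomerative clustering on the
#' patristic (tip-to-tip path length) distance matrix, cut at merge height
#' h. Average linkage is monotone, so partitions at increasing h form a
#' refinement hierarchy. Cluster identifiers are assigned deterministically
#' in order of each cluster's lexicographically first member.
#'
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param h cut height in substitutions per site; `h = 0.1` corresponds to
#'   roughly genus-level groups for V4 16S amplicons.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list of class `cluster_assignment` with `assignment` (named
#'   character vector, ASV -> cluster id), `h`, and `summary` (per-cluster
#'   member count and median within-cluster patristic distance).
#' @export
cut_tree <- function(tree, h, linkage = "average") {
  validate_tree(tree)
  if (!is.numeric(h) || length(h) != 1L || h < 0)
    stop("cut height h must be a single non-negative number", call. = FALSE)
  tips <- tree$tip.label
  if (length(tips) < 2L) {
    assignment <- stats::setNames(rep("cl1", length(tips)), tips)
    pat <- matrix(0, 1, 1, dimnames = list(tips, tips))
  } else {
    pat <- stats::cophenetic(tree)
    pat <- pat[order(rownames(pat)), order(colnames(pat))]
    hc <- stats::hclust(stats::as.dist(pat), method = linkage)
    cl <- stats::cutree(hc, h = h)
    # relabel clusters by order of first (lexicographic) member
    first_seen <- cl[!duplicated(cl)]
    relabel <- stats::setNames(paste0("cl", seq_along(first_seen)),
                               as.character(first_seen))
    assignment <- stats::setNames(relabel[as.character(cl)], names(cl))
    assignment <- assignment[tips]
  }
  summary <- do.call(rbind, lapply(split(names(assignment), assignment),
                                   function(members) {
    med <- if (length(members) > 1L)
      stats::median(pat[members, members][lower.tri(pat[members, members])])
    else 0
    data.frame(cluster_id = assignment[members[1L]],
               n_members = length(members),
               median_patristic = med, stringsAsFactors = FALSE)
  }))
  summary <- summary[order(as.integer(sub("^cl", "", summary$cluster_id))), ]
  rownames(summary) <- NULL
  structure(list(assignment = assignment, h = h, linkage = linkage,
                 summary = summary),
            class = "cluster_assignment")
}

#' Convert a median base-pair difference to percent sequence identity
#'
#' For amplicons of a fixed length, a median pairwise difference of d bases
#' corresponds to \eqn{100 (L - d) / L} percent identity, reported to one
#' decimal. A median 7.5 bp difference over 233 bp amplicons, for instance,
#' is 96.8% identity -- in the range used to delimit genera.
#'
#' @param median_bp_diff median pairwise base differences between cluster
#'   members.
#' @param seq_len amplicon length in bases.
#' @return percent identity, rounded to one decimal place.
#' @export
height_to_identity <- function(median_bp_diff, seq_len) {
  if (seq_len <= 0) stop("seq_len must be positive", call. = FALSE)
  if (median_bp_diff < 0 || median_bp_diff > seq_len)
    stop("median_bp_diff must lie in [0, seq_len]", call. = FALSE)
  round(100 * (seq_len - median_bp_diff) / seq_len, 1L)
}

#' Aggregate an ASV count table by cluster
#'
#' Sums columns within each cluster; per-sample totals are conserved
#' exactly. Every ASV in the table must be assigned.
#'
#' @param counts count table (samples x ASVs).
#' @param clusters a `cluster_assignment` from [cut_tree()] (or any named
#'   vector ASV -> cluster id).
#' @return count table with one column per cluster.
#' @export
aggregate_by_cluster <- function(counts, clusters) {
  counts <- validate_count_table(counts)
  assignment <- if (inherits(clusters, "cluster_assignment"))
    clusters$assignment else clusters
  unassigned <- setdiff(colnames(counts), names(assignment))
  if (length(unassigned) > 0L)
    stop("unassigned ASVs: ", paste(utils::head(unassigned, 5L),
                                    collapse = ", "), call. = FALSE)
  cl <- assignment[colnames(counts)]
  groups <- split(seq_len(ncol(counts)), cl)
  # keep first-appearance order of cluster ids
  groups <- groups[unique(cl)]
  agg <- vapply(groups, function(idx)
    rowSums(counts[, idx, drop = FALSE]), numeric(nrow(counts)))
  agg <- matrix(agg, nrow = nrow(counts),
                dimnames = list(rownames(counts), names(groups)))
  validate_count_table(agg)
}

#' Subject-level prevalence filter
#'
#' Retains features detected (count > 0 in at least one of the subject's
#' samples) in at least `ceiling(min_frac * n_subjects)` of the subjects on
#' the given diet. Prevalence is defined per subject, not per sample,
#' because replicate samples would otherwise inflate it.
#'
#' @param counts count table.
#' @param metadata `cohort_metadata` object.
#' @param diet_level diet arm whose subjects define prevalence.
#' @param min_frac minimum fraction of subjects (default 0.10).
#' @return character vector of retained feature ids.
#' @export
prevalence_filter <- function(counts, metadata, diet_level,
                              min_frac = 0.10) {
  counts <- validate_count_table(counts)
  su <- metadata$subjects
  on_diet <- su$subject_id[su$diet == diet_level]
  if (length(on_diet) == 0L)
    stop("no subjects on diet '", diet_level, "'", call. = FALSE)
  sm <- metadata$samples
  sm <- sm[sm$subject_id %in% on_diet &
             sm$sample_id %in% rownames(counts), , drop = FALSE]
  present <- vapply(split(sm$sample_id, sm$subject_id), function(ids)
    colSums(counts[ids, , drop = FALSE] > 0) > 0,
    logical(ncol(counts)))
  present <- matrix(present, nrow = ncol(counts))
  n_detect <- rowSums(present)
  threshold <- ceiling(min_frac * length(on_diet))
  colnames(counts)[n_detect >= threshold]
}
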