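#' Consecutive sample pairs within a window
#'
#' "Consecutive" means successive in collection order (sorted by day
#' offset), not calendar-adjacent: subjects whose samples are several days
#' apart still contribute, but a three-sample series contributes only the
#' pairs (1,2) and (2,3), never (1,3).
#'
#' @param sample_ids sample identifiers, sorted by day offset.
#' @return list of length-2 character vectors; empty when fewer than two
#'   samples.
#' @export
consecutive_pairs <- function(sample_ids) {
  n <- length(sample_ids)
  if (n < 2L) return(list())
  lapply(seq_len(n - 1L), function(i) sample_ids[c(i, i + 1L)])
}

#' Daily plasticity of one subject within one window
#'
#' Mean pairwise beta-diversity over the subject's consecutive sample pairs
#' in the window. Subjects with fewer than two samples yield NA (excluded,
#' as in cohorts where only most subjects provide replicate days).
#'
#' @param sample_ids the subject's samples in the window, sorted by day.
#' @param dm distance matrix (square, sample ids as dimnames).
#' @return list with `value` (mean distance, NA if not computable) and
#'   `n_pairs`.
#' @export
daily_plasticity <- function(sample_ids, dm) {
  pairs <- consecutive_pairs(sample_ids)
  if (length(pairs) == 0L) return(list(value = NA_real_, n_pairs = 0L))
  d <- vapply(pairs, function(p) dm[p[1L], p[2L]], numeric(1))
  list(value = mean(d), n_pairs = length(d))
}

#' Cross-period plasticity of one subject
#'
#' Mean beta-diversity over the full bipartite set of (pre-diet, 10-week)
#' sample pairs. NA when either window has no samples.
#'
#' @param bl_ids pre-diet (BL) sample ids.
#' @param w10_ids 10-week (W10) sample ids.
#' @param dm distance matrix.
#' @return list with `value` and `n_pairs` (= |BL| * |W10|).
#' @export
cross_period_plasticity <- function(bl_ids, w10_ids, dm) {
  if (length(bl_ids) == 0L || length(w10_ids) == 0L)
    return(list(value = NA_real_, n_pairs = 0L))
  d <- dm[bl_ids, w10_ids, drop = FALSE]
  list(value = mean(d), n_pairs = length(d))
}

#' Per-subject plasticity table
#'
#' One row per subject x pairing x metric where computable. Pairings are
#' `BLvBL` and `W10vW10` (daily plasticity from consecutive pairs within
#' the window) and `BLvW10` (mean over all pre-diet x 10-week pairs). Each
#' subject contributes a single averaged value per row; downstream group
#' tests operate on these subject means.
#'
#' @param counts count table (samples x ASVs).
#' @param metadata `cohort_metadata` object.
#' @param metrics character vector of metric names (see [distance_matrix()]).
#' @param scale count scale for the abundance-based metrics; plasticity
#'   defaults to per-sample proportions.
#' @param tree tree, required when UniFrac metrics are requested.
#' @return data frame with `subject_id`, `pairing`, `metric`, `value`,
#'   `n_pairs`.
#' @export
plasticity_table <- function(counts, metadata,
                             metrics = c("bray", "jaccard", "jsd",
                                         "uunifrac", "wunifrac"),
                             scale = "proportion", tree = NULL) {
  counts <- validate_count_table(counts)
  sm <- metadata$samples
  sm <- sm[sm$sample_id %in% rownames(counts), , drop = FALSE]
  sm <- sm[order(sm$subject_id, sm$window, sm$day_offset), , drop = FALSE]
  subjects <- unique(sm$subject_id)
  out <- list()
  for (metric in metrics) {
    dm <- distance_matrix(counts, metric = metric, scale = scale,
                          tree = tree)
    for (subj in subjects) {
      bl <- sm$sample_id[sm$subject_id == subj & sm$window == "BL"]
      w10 <- sm$sample_id[sm$subject_id == subj & sm$window == "W10"]
      rows <- list(
        BLvBL = daily_plasticity(bl, dm),
        W10vW10 = daily_plasticity(w10, dm),
        BLvW10 = cross_period_plasticity(bl, w10, dm))
      for (pairing in names(rows)) {
        r <- rows[[pairing]]
        if (!is.na(r$value))
          out[[length(out) + 1L]] <- data.frame(
            subject_id = subj, pairing = pairing, metric = metric,
            value = r$value, n_pairs = r$n_pairs,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(subject_id = character(), pairing = character(),
                      metric = character(), value = numeric(),
                      n_pairs = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Compare plasticity between two outcome groups
#'
#' Two-sided Wilcoxon rank-sum test on per-subject plasticity values for
#' one diet, pairing and metric, comparing e.g. unsuccessful (US) against
#' very successful (VS) subjects.
#'
#' @param pt plasticity table from [plasticity_table()].
#' @param groups named character vector, subject id -> group label; only
#'   subjects carrying one of the two `levels` enter the test.
#' @param diet named character vector, subject id -> diet; the test is run
#'   within `diet_level` only. Use `NULL` to skip diet filtering.
#' @param diet_level diet arm to test within.
#' @param pairing,metric which plasticity rows to use.
#' @param levels the two group labels to compare, in (x, y) order.
#' @return list with `statistic` (rank-sum U), `p_value`, `n` per group.
#' @export
compare_plasticity_groups <- function(pt, groups, diet = NULL,
                                      diet_level = NULL,
                                      pairing = "BLvBL", metric = "bray",
                                      levels = c("US", "VS")) {
  rows <- pt[pt$pairing == pairing & pt$metric == metric, , drop = FALSE]
  if (!is.null(diet) && !is.null(diet_level))
    rows <- rows[diet[rows$subject_id] == diet_level, , drop = FALSE]
  g <- groups[rows$subject_id]
  x <- rows$value[!is.na(g) & g == levels[1L]]
  y <- rows$value[!is.na(g) & g == levels[2L]]
  if (length(x) == 0L || length(y) == 0L)
    stop("a comparison group is empty", call. = FALSE)
  res <- wilcoxon_rank_sum(x, y)
  list(statistic = res$statistic, p_value = res$p_value,
       n = c(length(x), length(y)))
}

#' Correlate plasticity with a subject-level covariate
#'
#' Spearman rank correlation between per-subject plasticity and a covariate
#' (e.g. dietary change), optionally restricted to a diet arm and/or sex
#' subgroup. Requires at least 3 paired observations after filtering.
#'
#' @param pt plasticity table.
#' @param covariate named numeric vector, subject id -> value.
#' @param subjects subject data frame (for diet/sex filters); may be `NULL`
#'   when no filters are requested.
#' @param diet_level,sex_level optional filters.
#' @inheritParams compare_plasticity_groups
#' @return list with `rho`, `p_value`, `n`; NA with a warning when fewer
#'   than 3 pairs remain.
#' @export
correlate_plasticity <- function(pt, covariate, subjects = NULL,
                                 diet_level = NULL, sex_level = NULL,
                                 pairing = "BLvBL", metric = "bray") {
  rows <- pt[pt$pairing == pairing & pt$metric == metric, , drop = FALSE]
  keep <- rows$subject_id
  if (!is.null(subjects)) {
    if (!is.null(diet_level))
      keep <- intersect(keep,
                        subjects$subject_id[subjects$diet == diet_level])
    if (!is.null(sex_level))
      keep <- intersect(keep,
                        subjects$subject_id[subjects$sex == sex_level])
  }
  rows <- rows[rows$subject_id %in% keep, , drop = FALSE]
  y <- covariate[rows$subject_id]
  ok <- !is.na(y) & !is.na(rows$value)
  if (sum(ok) < 3L) {
    warning("fewer than 3 paired observations; correlation not computed",
            call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  res <- spearman_cor(rows$value[ok], y[ok])
  list(rho = res$rho, p_value = res$p_value, n = sum(ok))
}

#' Within- versus between-subject community distances
#'
#' Splits all pairwise distances among the samples of a window into
#' within-subject and between-subject sets and compares them with a
#' two-sided Wilcoxon rank-sum test. With strong subject individuality the
#' within-subject distribution sits well below the between-subject one.
#'
#' @param dm distance matrix over the window's samples.
#' @param metadata `cohort_metadata` object.
#' @param window `"BL"` or `"W10"`.
#' @return list with `intra` and `inter` distance vectors and `p_value`.
#' @export
intra_inter_comparison <- function(dm, metadata, window = "BL") {
  sm <- metadata$samples
  sm <- sm[sm$window == window & sm$sample_id %in% rownames(dm), ,
           drop = FALSE]
  if (length(unique(sm$subject_id)) < 2L)
    stop("need at least 2 subjects with samples in the window",
         call. = FALSE)
  ids <- sm$sample_id
  subj <- sm$subject_id
  n <- length(ids)
  intra <- numeric(0)
  inter <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- dm[ids[i], ids[j]]
      if (subj[i] == subj[j]) intra <- c(intra, d) else inter <- c(inter, d)
    }
  }
  p <- if (length(intra) > 0L && length(inter) > 0L)
    wilcoxon_rank_sum(intra, inter)$p_value else NA_real_
  list(intra = intra, inter = inter, p_value = p)
}
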