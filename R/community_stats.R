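#' Prevotella/Bacteroides ratio per sample and subject
#'
#' Per sample, P is the summed count of all Prevotella-genus ASVs and B the
#' summed count of Bacteroides-genus ASVs. Because roughly half of
#' real-world subjects carry no detectable Prevotella, a pseudocount of 1
#' is substituted for P exactly when P = 0 (never added unconditionally).
#' Samples with B = 0 have an undefined ratio and are excluded with a
#' warning. The subject-level value is the mean ratio over the subject's
#' pre-diet (BL) samples. Ratios are computed on raw genus count sums; the
#' library size cancels in the ratio except through the pseudocount.
#'
#' @param counts count table (samples x ASVs).
#' @param taxonomy taxonomy data frame (`asv_id`, `genus`).
#' @param metadata `cohort_metadata` object (defines subjects and the BL
#'   window).
#' @return list of class `pb_result` with `per_sample` (data frame:
#'   `sample_id`, `prevotella`, `bacteroides`, `ratio`) and `per_subject`
#'   (data frame: `subject_id`, `mean_ratio`, `n_samples`).
#' @export
pb_ratio <- function(counts, taxonomy, metadata) {
  counts <- validate_count_table(counts)
  p_asvs <- intersect(taxonomy$asv_id[grepl("Prevotella", taxonomy$genus)],
                      colnames(counts))
  b_asvs <- intersect(taxonomy$asv_id[grepl("Bacteroides", taxonomy$genus)],
                      colnames(counts))
  if (length(p_asvs) == 0L || length(b_asvs) == 0L)
    stop("taxonomy must label Prevotella and Bacteroides genera",
         call. = FALSE)
  P <- rowSums(counts[, p_asvs, drop = FALSE])
  B <- rowSums(counts[, b_asvs, drop = FALSE])
  P[P == 0] <- 1   # pseudocount only on zero Prevotella
  ratio <- ifelse(B > 0, P / B, NA_real_)
  excluded <- rownames(counts)[B == 0]
  if (length(excluded) > 0L)
    warning("samples with zero Bacteroides excluded from P/B: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  per_sample <- data.frame(sample_id = rownames(counts),
                           prevotella = P, bacteroides = B, ratio = ratio,
                           stringsAsFactors = FALSE, row.names = NULL)
  sm <- metadata$samples
  bl <- sm[sm$window == "BL" & sm$sample_id %in% rownames(counts), ,
           drop = FALSE]
  r <- stats::setNames(ratio, rownames(counts))[bl$sample_id]
  per_subject <- do.call(rbind, lapply(split(seq_len(nrow(bl)),
                                             bl$subject_id), function(i) {
    v <- r[i]
    v <- v[!is.na(v)]
    data.frame(subject_id = bl$subject_id[i[1L]],
               mean_ratio = if (length(v)) mean(v) else NA_real_,
               n_samples = length(v), stringsAsFactors = FALSE)
  }))
  rownames(per_subject) <- NULL
  structure(list(per_sample = per_sample, per_subject = per_subject),
            class = "pb_result")
}

#' Dichotomize subjects at a P/B ratio cutoff
#'
#' Subjects with mean pre-diet P/B ratio at or above the cutoff are classed
#' `"high"`, below it `"low"`. The default cutoff 0.003 suits cohorts with
#' low Prevotella prevalence (the classical 0.01 threshold assumes higher
#' carriage).
#'
#' @param pb a `pb_result` from [pb_ratio()].
#' @param cutoff ratio cutoff.
#' @return named character vector subject id -> `"high"`/`"low"`.
#' @export
classify_pb <- function(pb, cutoff = 0.003) {
  cls <- ifelse(pb$per_subject$mean_ratio >= cutoff, "high", "low")
  stats::setNames(cls, pb$per_subject$subject_id)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: eigendecomposition of the
#' double-centered \eqn{-D^2/2}, coordinates scaled by the square root of
#' the eigenvalues. Negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis) are dropped and their count
#' reported.
#'
#' @param dm square symmetric distance matrix (>= 3 samples).
#' @param n_axes number of axes to retain.
#' @return list of class `ordination_result` with `coordinates` (samples x
#'   axes), `eigenvalues` (positive, non-increasing), `prop_explained`,
#'   `n_negative_eig`.
#' @export
pcoa_ordination <- function(dm, n_axes = 2) {
  if (nrow(dm) < 3L) stop("PCoA needs at least 3 samples", call. = FALSE)
  fit <- stats::cmdscale(stats::as.dist(dm), k = min(n_axes, nrow(dm) - 1L),
                         eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > sqrt(.Machine$double.eps)]
  k <- min(n_axes, length(pos), ncol(fit$points))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = pos[seq_len(k)],
                 prop_explained = pos[seq_len(k)] / sum(pos),
                 n_negative_eig = sum(eig < -sqrt(.Machine$double.eps))),
            class = "ordination_result")
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  lev <- unique(groups)
  a <- length(lev)
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (g in lev) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  list(f = f, r2 = ss_between / ss_total)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared distances into between- and
#' within-group components (Anderson's partition) and tests the pseudo-F
#' by permuting group labels. The p-value is
#' \eqn{(1 + \#\{F^{perm} \ge F\}) / (n_{perm} + 1)}.
#' By default labels are permuted at the sample level; for repeated-measures
#' designs `strata` (sample id -> subject) permutes whole subjects instead,
#' keeping each subject's samples together.
#'
#' @param dm square distance matrix.
#' @param groups group label per sample (in `dm` row order, or named by
#'   sample id).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param strata optional vector of subject ids (same order as `groups`)
#'   for whole-subject label permutation.
#' @return list of class `permanova_result` with `pseudo_f`, `r2`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1, strata = NULL) {
  if (!is.null(names(groups))) groups <- groups[rownames(dm)]
  groups <- as.character(groups)
  n <- nrow(dm)
  if (length(groups) != n) stop("groups length must match dm", call. = FALSE)
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes == 1L))
    warning("group(s) with a single member contribute no within-group df",
            call. = FALSE)
  d2 <- dm^2
  obs <- permanova_f(d2, groups)
  set.seed(seed)
  exceed <- 0L
  if (is.null(strata)) {
    for (b in seq_len(n_perm)) {
      fp <- permanova_f(d2, sample(groups))$f
      if (fp >= obs$f) exceed <- exceed + 1L
    }
  } else {
    strata <- as.character(strata)
    subj <- unique(strata)
    subj_group <- groups[match(subj, strata)]
    for (b in seq_len(n_perm)) {
      perm <- stats::setNames(sample(subj_group), subj)
      fp <- permanova_f(d2, unname(perm[strata]))$f
      if (fp >= obs$f) exceed <- exceed + 1L
    }
  }
  structure(list(pseudo_f = obs$f, r2 = obs$r2,
                 p_value = (1 + exceed) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "permanova_result")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most
#' `exact_threshold` and there are no ties; otherwise the normal
#' approximation with tie and continuity correction. Small plasticity group
#' sizes make exactness affordable.
#'
#' @param x,y numeric samples, both non-empty.
#' @param exact_threshold combined-size limit for the exact test.
#' @return list with `statistic` (rank-sum U of `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_threshold = 20) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y)) <= exact_threshold && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Spearman rank correlation with two-sided p-value
#'
#' Pearson correlation of (average) ranks. The p-value is exact for n of
#' at most 10 without ties and the t approximation otherwise. Constant
#' input yields NA with a warning.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  use_exact <- n <= 10
  res <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = use_exact,
                    alternative = "two.sided"))
  list(rho = unname(res$estimate), p_value = res$p.value, n = n)
}
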