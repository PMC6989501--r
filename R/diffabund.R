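#' Poscounts size factors for sparse count tables
#'
#' Median-of-positive-ratios normalization suited to sparse tables. For
#' each feature positive in at least one sample, the reference is the
#' geometric mean of its positive counts; each sample's factor is the
#' median, over features where the sample is positive, of count/reference.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts count table (samples x features), every sample with at
#'   least one positive count.
#' @return named numeric vector of positive size factors (one per sample).
#' @export
poscounts_size_factors <- function(counts) {
  counts <- validate_count_table(counts)
  x <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  pos <- x > 0
  keep <- colSums(pos) > 0
  x <- x[, keep, drop = FALSE]
  pos <- pos[, keep, drop = FALSE]
  logx <- log(x)
  logx[!pos] <- NA
  ref <- exp(colMeans(logx, na.rm = TRUE))
  sf <- vapply(seq_len(nrow(x)), function(j) {
    r <- x[j, ] / ref
    stats::median(r[pos[j, ]])
  }, numeric(1))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, rownames(counts))
}

#' Asinh-voom: precision weights from a mean-variance trend
#'
#' A voom-style precision-weighting scheme in which the usual log-CPM
#' transform is replaced by the inverse hyperbolic sine of size-factor
#' normalized counts (defined at zero, variance-stabilizing for
#' overdispersed 16S counts). Per feature, ordinary least squares against
#' the design yields residual standard deviations; a lowess trend of
#' sqrt(residual SD) on mean transformed abundance is interpolated at each
#' observation's fitted value (clamped at the trend endpoints) and
#' inverted to fourth-power weights.
#'
#' @param counts count table (samples x features).
#' @param size_factors per-sample size factors (default: poscounts).
#' @param design model matrix (samples x coefficients), full rank.
#' @param lowess_f lowess span (default 0.5).
#' @param lowess_iter robustifying iterations (default 3).
#' @return list of class `voom_fit` with `y` (features x samples asinh
#'   matrix), `weights` (same shape, strictly positive), `trend` (lowess
#'   x/y), `size_factors`, `design`.
#' @export
voom_asinh <- function(counts, size_factors = NULL, design,
                       lowess_f = 0.5, lowess_iter = 3) {
  counts <- validate_count_table(counts)
  if (is.null(size_factors)) size_factors <- poscounts_size_factors(counts)
  check_design(design, nrow(counts))
  y <- t(asinh_transform(sweep(matrix(as.numeric(counts), nrow(counts),
                                      ncol(counts),
                                      dimnames = dimnames(counts)),
                               1L, size_factors, "/")))
  n <- ncol(y)   # samples
  p <- ncol(design)
  fit <- stats::lm.fit(design, t(y))
  res <- as.matrix(fit$residuals)
  df <- n - fit$rank
  if (df < 1L) stop("design leaves no residual degrees of freedom",
                    call. = FALSE)
  sd_res <- sqrt(colSums(res^2) / df)
  mean_y <- rowMeans(y)
  lo <- stats::lowess(mean_y, sqrt(sd_res), f = lowess_f,
                      iter = lowess_iter)
  fitted <- t(as.matrix(fit$fitted.values))   # features x samples
  pred <- matrix(stats::approx(lo$x, lo$y, xout = as.vector(fitted),
                               rule = 2, ties = mean)$y,
                 nrow(y), n, dimnames = dimnames(y))
  pred <- pmax(pred, 1e-4)   # guard against zero-variance features
  w <- pred^-4
  structure(list(y = y, weights = w, trend = lo,
                 size_factors = size_factors, design = design),
            class = "voom_fit")
}

check_design <- function(design, n_samples) {
  if (!is.matrix(design) || nrow(design) != n_samples)
    stop("design must be a matrix with one row per sample", call. = FALSE)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  invisible(NULL)
}

#' Consensus within-block correlation
#'
#' Estimates, per feature, the intra-block (within-subject) correlation of
#' a compound-symmetry covariance model from the ordinary least-squares
#' residuals. Because residuals are projected through \eqn{I - H} (H the
#' design's hat matrix), raw within-block cross-products are attenuated;
#' the estimator solves the exact pair of moment equations
#' \deqn{E[r'Qr] = \sigma^2(-tr(QH) + \rho\, tr((Q(I-H))^2)),\quad
#'       E[r'r] = \sigma^2(n - p - \rho\, tr(QH))}
#' (Q the within-block pair indicator) for \eqn{\rho} feature by feature.
#' The consensus is the tanh of the 10%-trimmed mean of the per-feature
#' atanh correlations, clipped to (-0.99, 0.99). Returns 0 with a warning
#' when every block is a singleton.
#'
#' @param vf a `voom_fit`.
#' @param block vector of block (subject) identifiers, one per sample.
#' @return consensus correlation (scalar).
#' @export
consensus_correlation <- function(vf, block) {
  y <- vf$y
  design <- vf$design
  n <- ncol(y)
  block <- as.character(block)
  if (length(block) != n)
    stop("block must have one entry per sample", call. = FALSE)
  sizes <- table(block)
  if (all(sizes == 1L)) {
    warning("all blocks are singletons; consensus correlation set to 0",
            call. = FALSE)
    return(0)
  }
  fit <- stats::lm.fit(design, t(y))
  res <- as.matrix(fit$residuals)        # samples x features
  nu <- n - fit$rank
  Q <- matrix(0, n, n)
  for (b in names(sizes)[sizes > 1L]) {
    idx <- which(block == b)
    Q[idx, idx] <- 1
    diag(Q)[idx] <- 0
  }
  H <- design %*% solve(crossprod(design), t(design))
  QM <- Q %*% (diag(n) - H)
  t1 <- sum(diag(Q %*% H))
  t2 <- sum(QM * t(QM))                  # tr((Q(I-H))^2)
  a <- colSums(res * (Q %*% res))        # r' Q r per feature
  b2 <- colSums(res^2)                   # r' r per feature
  rho_g <- (a * nu + b2 * t1) / (b2 * t2 + a * t1)
  rho_g <- pmin(pmax(rho_g, -0.99), 0.99)
  z <- atanh(rho_g)
  tanh(min(max(mean(z, trim = 0.10), atanh(-0.99)), atanh(0.99)))
}

# Inverse of the trigamma function by Newton iteration.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50L)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

# Empirical-Bayes hyperparameters (d0, s0^2) by moment matching on log s^2.
# Falls back to d0 = Inf (pooled variance) when the trigamma equation has
# no positive solution.
estimate_var_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(d0 = Inf, s0sq = mean(s2[ok])))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    warning("variance-prior moment matching did not converge; ",
            "using d0 = Inf (pooled variance)", call. = FALSE)
    return(list(d0 = Inf, s0sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

# Block-diagonal inverse square root of a compound-symmetry correlation
# matrix, cached by block size.
cs_whitener <- function(block, rho) {
  block <- as.character(block)
  sizes <- table(block)
  cache <- list()
  get_A <- function(k) {
    key <- as.character(k)
    if (is.null(cache[[key]])) {
      R <- matrix(rho, k, k)
      diag(R) <- 1
      es <- eigen(R, symmetric = TRUE)
      if (any(es$values <= 0))
        stop("compound-symmetry correlation not positive definite at rho = ",
             rho, call. = FALSE)
      cache[[key]] <<- es$vectors %*% diag(1 / sqrt(es$values), k) %*%
        t(es$vectors)
    }
    cache[[key]]
  }
  n <- length(block)
  A <- matrix(0, n, n)
  for (b in names(sizes)) {
    idx <- which(block == b)
    A[idx, idx] <- get_A(length(idx))
  }
  A
}

#' Moderated differential-abundance fit
#'
#' Per feature, generalized least squares with compound-symmetry
#' within-block correlation `rho` and the voom observation weights;
#' residual variances are then shrunk toward an empirical-Bayes prior
#' (d0, s0^2) estimated by moment matching on log variances, giving
#' posterior variances \eqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)}
#' and moderated t statistics on \eqn{d + d_0} degrees of freedom.
#'
#' @param vf a `voom_fit`.
#' @param block subject identifier per sample (`NULL` for independent
#'   samples).
#' @param rho consensus within-block correlation (see
#'   [consensus_correlation()]).
#' @param contrasts numeric matrix (coefficients x contrasts) of contrast
#'   vectors; column names label the contrasts.
#' @param use_weights set `FALSE` to fit with flat weights.
#' @param prior_df optional fixed prior degrees of freedom d0, bypassing
#'   the empirical-Bayes estimate: `0` gives the unmoderated per-feature
#'   fit, `Inf` fully pools the variances.
#' @return list of class `da_fit` with per-contrast data frames
#'   (`feature_id`, `logFC`, `t`, `p_value`, `mean_abundance`) in
#'   `$contrasts`, plus `d0`, `s0sq`, `df_residual`, `rho`.
#' @export
fit_moderated <- function(vf, block = NULL, rho = 0, contrasts,
                          use_weights = TRUE, prior_df = NULL) {
  y <- vf$y
  design <- vf$design
  n <- ncol(y)
  p <- ncol(design)
  if (!is.matrix(contrasts)) contrasts <- matrix(contrasts, ncol = 1L)
  if (nrow(contrasts) != p)
    stop("contrast rows must match design coefficients", call. = FALSE)
  if (is.null(colnames(contrasts)))
    colnames(contrasts) <- paste0("contrast", seq_len(ncol(contrasts)))
  A <- if (!is.null(block) && rho != 0) cs_whitener(block, rho)
       else diag(n)
  w <- if (use_weights) vf$weights else matrix(1, nrow(y), n)
  G <- nrow(y)
  est <- matrix(NA_real_, G, ncol(contrasts))
  usd <- matrix(NA_real_, G, ncol(contrasts))
  s2 <- numeric(G)
  df <- NA_integer_
  for (g in seq_len(G)) {
    sw <- sqrt(w[g, ])
    zt <- A %*% (sw * y[g, ])
    Xt <- A %*% (sw * design)
    qf <- qr(Xt)
    if (qf$rank < p)
      stop("design became rank deficient after weighting", call. = FALSE)
    beta <- qr.coef(qf, zt)
    resid <- zt - Xt %*% beta
    dfr <- n - qf$rank
    s2[g] <- sum(resid^2) / dfr
    xtxi <- chol2inv(chol(crossprod(Xt)))
    for (k in seq_len(ncol(contrasts))) {
      L <- contrasts[, k]
      est[g, k] <- sum(L * beta)
      usd[g, k] <- sqrt(drop(t(L) %*% xtxi %*% L))
    }
    df <- dfr
  }
  if (is.null(prior_df)) {
    prior <- estimate_var_prior(s2, df)
    d0 <- prior$d0
    s0sq <- prior$s0sq
  } else {
    d0 <- prior_df
    s0sq <- mean(s2)
  }
  if (is.finite(d0)) {
    s2_post <- (d0 * s0sq + df * s2) / (d0 + df)
    df_total <- df + d0
  } else {
    s2_post <- rep(s0sq, G)
    df_total <- Inf
  }
  out <- lapply(seq_len(ncol(contrasts)), function(k) {
    tt <- est[, k] / (usd[, k] * sqrt(s2_post))
    data.frame(feature_id = rownames(y),
               logFC = est[, k], t = tt,
               p_value = 2 * stats::pt(-abs(tt), df = df_total),
               mean_abundance = rowMeans(y),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(out) <- colnames(contrasts)
  structure(list(contrasts = out, d0 = d0, s0sq = s0sq,
                 df_residual = df, rho = rho, s2 = s2),
            class = "da_fit")
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up false-discovery-rate adjustment (monotonicity enforced), with a
#' logical flag for adjusted p at or below `alpha`.
#'
#' @param pvals raw p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with `adjusted` and `significant`.
#' @export
bh_adjust <- function(pvals, alpha = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, significant = adj <= alpha)
}

#' Full differential-abundance pipeline
#'
#' Pre-diet samples from both diets are fit jointly (shared variance
#' moderation, higher power); testing is per diet through contrasts. The
#' stages are: per-diet subject-level prevalence filter, poscounts size
#' factors, asinh-voom weights, consensus within-subject correlation,
#' moderated GLS fit with a diet x outcome cell-means design plus a
#' sequencing-lane fixed effect, per-diet contrasts (VS - US in categorical
#' mode; the per-diet weight-loss slope in continuous mode) and
#' Benjamini-Hochberg adjustment within each contrast restricted to that
#' diet's retained features.
#'
#' @param counts count table (samples x ASVs), pre-diet samples only are
#'   used.
#' @param metadata `cohort_metadata` object.
#' @param phenotypes phenotype table from [phenotype_table()].
#' @param mode `"categorical"` (VS vs US contrast; MS samples stay in the
#'   design) or `"continuous"` (percent weight loss at 12 months).
#' @param level `"asv"` or `"cluster"` (requires `tree`; clusters from
#'   [cut_tree()] at height `h`).
#' @param tree tree for `level = "cluster"`.
#' @param h tree-cut height (default 0.1).
#' @param alpha FDR level.
#' @param min_frac prevalence-filter fraction (default 0.10).
#' @return list of class `da_result`: per-diet data frames with `logFC`
#'   (VS minus US on the asinh scale, positive = more abundant in VS),
#'   `t`, `p_value`, `adj_p`, `significant`; attributes `rho`, `d0`,
#'   `s0sq`.
#' @export
run_da <- function(counts, metadata, phenotypes,
                   mode = c("categorical", "continuous"),
                   level = c("asv", "cluster"), tree = NULL, h = 0.1,
                   alpha = 0.05, min_frac = 0.10) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  counts <- validate_count_table(counts)
  if (level == "cluster") {
    if (is.null(tree)) stop("cluster level requires a tree", call. = FALSE)
    counts <- aggregate_by_cluster(counts, cut_tree(tree, h))
  }
  sm <- metadata$samples
  bl <- sm[sm$window == "BL" & sm$sample_id %in% rownames(counts), ,
           drop = FALSE]
  counts <- counts[bl$sample_id, , drop = FALSE]
  diets <- DIET_LEVELS
  retained <- lapply(diets, function(d)
    prevalence_filter(counts, metadata, d, min_frac = min_frac))
  names(retained) <- diets
  union_feat <- unique(unlist(retained))
  if (length(union_feat) == 0L)
    stop("no features pass the prevalence filter", call. = FALSE)
  counts <- counts[, union_feat, drop = FALSE]
  ph <- phenotypes[match(bl$subject_id, phenotypes$subject_id), ]
  lane <- factor(bl$lane)
  if (mode == "categorical") {
    cell <- factor(paste(ph$diet, ph$success, sep = "."),
                   levels = as.vector(outer(diets, c("US", "MS", "VS"),
                                            paste, sep = ".")))
    cell <- droplevels(cell)
    X <- stats::model.matrix(~ 0 + cell)
    colnames(X) <- levels(cell)
  } else {
    dietf <- factor(ph$diet, levels = diets)
    X <- stats::model.matrix(~ 0 + dietf + dietf:ph$weight_loss_pct_12mo)
    colnames(X) <- c(diets, paste0(diets, ".wl"))
  }
  if (nlevels(lane) > 1L) {
    Xl <- stats::model.matrix(~ lane)[, -1L, drop = FALSE]
    X <- cbind(X, Xl)
  }
  check_design(X, nrow(counts))
  sf <- poscounts_size_factors(counts)
  vf <- voom_asinh(counts, sf, X)
  rho <- consensus_correlation(vf, bl$subject_id)
  contr <- matrix(0, ncol(X), length(diets),
                  dimnames = list(colnames(X), diets))
  for (d in diets) {
    if (mode == "categorical") {
      vs <- paste0(d, ".VS"); us <- paste0(d, ".US")
      if (!all(c(vs, us) %in% colnames(X)))
        stop("contrast not estimable: no ", vs, " or ", us, " samples",
             call. = FALSE)
      contr[vs, d] <- 1
      contr[us, d] <- -1
    } else {
      contr[paste0(d, ".wl"), d] <- 1
    }
  }
  fit <- fit_moderated(vf, block = bl$subject_id, rho = rho,
                       contrasts = contr)
  out <- lapply(diets, function(d) {
    tab <- fit$contrasts[[d]]
    tab <- tab[tab$feature_id %in% retained[[d]], , drop = FALSE]
    adj <- bh_adjust(tab$p_value, alpha = alpha)
    tab$adj_p <- adj$adjusted
    tab$significant <- adj$significant
    rownames(tab) <- NULL
    tab
  })
  names(out) <- diets
  structure(out, class = "da_result", rho = rho, d0 = fit$d0,
            s0sq = fit$s0sq, mode = mode, level = level, alpha = alpha)
}
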