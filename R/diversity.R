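#' Inverse hyperbolic sine transform
#'
#' Elementwise \eqn{\mathrm{asinh}(x) = \log(x + \sqrt{1 + x^2})}. Unlike a
#' log transform it is defined at zero (asinh(0) = 0), which is the reason
#' it is used as the variance-stabilizing transform for sparse count data
#' throughout this package.
#'
#' @param x non-negative numeric vector or matrix.
#' @return transformed object of the same shape.
#' @export
asinh_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE))
    stop("asinh_transform expects non-negative input", call. = FALSE)
  asinh(x)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{d = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)}, bounded in [0, 1].
#'
#' @param u,v non-negative numeric vectors of equal length.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(u, v) {
  check_pair(u, v)
  sum(abs(u - v)) / sum(u + v)
}

#' Jaccard dissimilarity (presence/absence) between two abundance vectors
#'
#' Vectors are binarized internally (presence means count > 0);
#' \eqn{d = 1 - |A \cap B| / |A \cup B|}.
#'
#' @inheritParams bray_curtis
#' @return dissimilarity in [0, 1].
#' @export
jaccard_dissimilarity <- function(u, v) {
  check_pair(u, v)
  a <- u > 0
  b <- v > 0
  1 - sum(a & b) / sum(a | b)
}

#' Jensen-Shannon divergence between two abundance vectors
#'
#' Vectors are normalized to proportions internally. The divergence is
#' computed in log base 2 so that it is bounded in [0, 1]; the divergence
#' itself (not its square root) is returned.
#'
#' @inheritParams bray_curtis
#' @return divergence in [0, 1].
#' @export
jensen_shannon <- function(u, v) {
  check_pair(u, v)
  p <- u / sum(u)
  q <- v / sum(v)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log2(a[i]) - log2(b[i])))
  }
  (kl(p, m) + kl(q, m)) / 2
}

check_pair <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors must have equal length", call. = FALSE)
  if (any(u < 0) || any(v < 0))
    stop("abundance vectors must be non-negative", call. = FALSE)
  if (sum(u) == 0 || sum(v) == 0)
    stop("abundance vector with no positive entry", call. = FALSE)
  invisible(NULL)
}

# Edge x tip incidence of a rooted tree, in the tree's postorder edge order.
# Row b is TRUE at the tips descending from branch b. Returned with the
# matching branch lengths so callers never mix edge orderings.
edge_tip_incidence <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  M <- matrix(FALSE, ne, nt, dimnames = list(NULL, tree$tip.label))
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- i
  for (e in seq_len(ne)) {
    child <- tree$edge[e, 2L]
    parent <- tree$edge[e, 1L]
    M[e, desc[[child]]] <- TRUE
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  list(incidence = M, lengths = tree$edge.length,
       tip_labels = tree$tip.label)
}

#' UniFrac distance between two samples
#'
#' Unweighted UniFrac is the fraction of branch length unique to one of the
#' two samples among branch length leading to any observed tip. Weighted
#' UniFrac is the normalized variant, bounded in [0, 1]:
#' \eqn{\sum_b L_b |p_{Ab} - p_{Bb}| / \sum_b L_b (p_{Ab} + p_{Bb})} with
#' branch weights \eqn{p_{\cdot b}} the proportion of a sample's reads
#' descending from branch b.
#'
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param u,v abundance vectors named by (or ordered as) the tree's tips.
#' @param weighted logical; `TRUE` for normalized weighted UniFrac.
#' @return distance in [0, 1].
#' @export
unifrac <- function(tree, u, v, weighted = FALSE) {
  validate_tree(tree)
  inc <- edge_tip_incidence(tree)
  u <- align_to_tips(u, inc$tip_labels)
  v <- align_to_tips(v, inc$tip_labels)
  check_pair(u, v)
  if (weighted) {
    bu <- as.vector(inc$incidence %*% (u / sum(u)))
    bv <- as.vector(inc$incidence %*% (v / sum(v)))
    sum(inc$lengths * abs(bu - bv)) / sum(inc$lengths * (bu + bv))
  } else {
    au <- as.vector(inc$incidence %*% (u > 0)) > 0
    av <- as.vector(inc$incidence %*% (v > 0)) > 0
    sum(inc$lengths * xor(au, av)) / sum(inc$lengths * (au | av))
  }
}

align_to_tips <- function(x, tips) {
  if (!is.null(names(x))) {
    miss <- setdiff(tips, names(x))
    extra <- setdiff(names(x), tips)
    if (length(miss) || length(extra))
      stop("abundance names do not match tree tips", call. = FALSE)
    x <- x[tips]
  } else if (length(x) != length(tips)) {
    stop("abundance vector length does not match number of tips",
         call. = FALSE)
  }
  as.numeric(x)
}

#' All pairwise beta-diversity distances for a count table
#'
#' @param counts count table (samples x ASVs).
#' @param metric one of `"bray"`, `"jaccard"`, `"jsd"`, `"uunifrac"`,
#'   `"wunifrac"`.
#' @param scale `"proportion"` (per-sample relative abundances, the default
#'   used for plasticity) or `"asinh_normalized"` (asinh of size-factor
#'   normalized counts, as used for ordination). Presence/absence metrics
#'   are unaffected by the choice.
#' @param tree rooted tree, required for the UniFrac metrics.
#' @param size_factors optional per-sample size factors for the
#'   `asinh_normalized` scale; computed with [poscounts_size_factors()]
#'   when absent.
#' @return symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames and the metric name in `attr(, "metric")`.
#' @export
distance_matrix <- function(counts, metric = c("bray", "jaccard", "jsd",
                                               "uunifrac", "wunifrac"),
                            scale = c("proportion", "asinh_normalized"),
                            tree = NULL, size_factors = NULL) {
  metric <- match.arg(metric)
  scale <- match.arg(scale)
  counts <- validate_count_table(counts)
  n <- nrow(counts)
  x <- matrix(as.numeric(counts), n, ncol(counts),
              dimnames = dimnames(counts))
  if (scale == "proportion") {
    x <- x / rowSums(x)
  } else {
    if (is.null(size_factors)) size_factors <- poscounts_size_factors(counts)
    x <- asinh_transform(x / size_factors)
  }
  ids <- rownames(counts)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (metric %in% c("uunifrac", "wunifrac")) {
    if (is.null(tree)) stop("UniFrac metrics require a tree", call. = FALSE)
    validate_tree(tree)
    inc <- edge_tip_incidence(tree)
    if (!setequal(inc$tip_labels, colnames(counts)))
      stop("tree tips do not match count table ASVs", call. = FALSE)
    L <- inc$lengths
    # raw counts drive presence and branch proportions (scale-invariant)
    raw <- matrix(as.numeric(counts), n, ncol(counts),
                  dimnames = dimnames(counts))
    B <- raw[, inc$tip_labels, drop = FALSE] %*% t(inc$incidence) # n x edges
    if (metric == "uunifrac") {
      P <- (B > 0) + 0
      LP <- sweep(P, 2L, L, "*")
      shared <- LP %*% t(P)                 # sum L * (a AND b)
      tot <- rowSums(LP)
      num <- outer(tot, tot, "+") - 2 * shared
      den <- outer(tot, tot, "+") - shared
      D <- num / den
      diag(D) <- 0
      dimnames(D) <- list(ids, ids)
    } else {
      Bp <- B / rowSums(raw)
      for (i in seq_len(n - 1L)) {
        j <- (i + 1L):n
        dif <- abs(Bp[j, , drop = FALSE] -
                     rep(Bp[i, ], each = length(j)))
        sm <- Bp[j, , drop = FALSE] + rep(Bp[i, ], each = length(j))
        D[i, j] <- D[j, i] <- (dif %*% L) / (sm %*% L)
      }
    }
  } else if (metric == "bray") {
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      xi <- rep(x[i, ], each = length(j))
      num <- rowSums(abs(x[j, , drop = FALSE] - xi))
      den <- rowSums(x[j, , drop = FALSE] + xi)
      D[i, j] <- D[j, i] <- num / den
    }
  } else if (metric == "jaccard") {
    P <- (x > 0) + 0
    shared <- P %*% t(P)
    tot <- rowSums(P)
    union <- outer(tot, tot, "+") - shared
    D <- 1 - shared / union
    diag(D) <- 0
    dimnames(D) <- list(ids, ids)
  } else { # jsd
    p <- x / rowSums(x)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        D[i, j] <- D[j, i] <- jensen_shannon(p[i, ], p[j, ])
      }
    }
  }
  attr(D, "metric") <- metric
  attr(D, "scale") <- scale
  D
}

#' Expected phylogenetic diversity under rarefaction
#'
#' Expectation of Faith's phylogenetic diversity when a sample of total
#' depth N is subsampled without replacement to depth m:
#' \deqn{E[PD_m] = \sum_b L_b \left(1 - \binom{N - n_b}{m} /
#'   \binom{N}{m}\right)}
#' where \eqn{n_b} is the number of reads descending from branch b. Computed
#' with log-binomial coefficients for numerical stability. Interpolation
#' only: m may not exceed N.
#'
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param counts tip abundance vector (named by tips or in tip order).
#' @param m rarefaction depth (positive integer, at most `sum(counts)`).
#' @return expected phylogenetic diversity in branch-length units.
#' @export
expected_pd_rarefied <- function(tree, counts, m) {
  validate_tree(tree)
  inc <- edge_tip_incidence(tree)
  counts <- align_to_tips(counts, inc$tip_labels)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  N <- sum(counts)
  if (m > N) stop("rarefaction depth m exceeds sample depth N ",
                  "(interpolation only)", call. = FALSE)
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  nb <- as.vector(inc$incidence %*% counts)
  p_in <- 1 - exp(lchoose(N - nb, m) - lchoose(N, m))
  sum(inc$lengths * p_in)
}

#' Per-sample rarefied phylogenetic alpha-diversity
#'
#' Expected phylogenetic diversity at an interpolated depth of `m` reads for
#' every sample. Samples shallower than `m` are reported as `NA` with a
#' warning (no extrapolation).
#'
#' @param counts count table (samples x ASVs).
#' @param tree rooted tree over the table's ASVs.
#' @param m rarefaction depth; the default (11000) matches a minimum
#'   post-filter library size typical of daily stool 16S libraries.
#' @return data frame with `sample_id`, `pd` and the depth `m` used.
#' @export
alpha_table <- function(counts, tree, m = 11000) {
  counts <- validate_count_table(counts)
  depths <- rowSums(counts)
  shallow <- rownames(counts)[depths < m]
  if (length(shallow) > 0L)
    warning("samples below rarefaction depth reported as NA: ",
            paste(shallow, collapse = ", "), call. = FALSE)
  inc <- edge_tip_incidence(tree)
  if (!setequal(inc$tip_labels, colnames(counts)))
    stop("tree tips do not match count table ASVs", call. = FALSE)
  B <- counts[, inc$tip_labels, drop = FALSE] %*% t(inc$incidence)
  pd <- vapply(seq_len(nrow(counts)), function(i) {
    N <- depths[i]
    if (N < m) return(NA_real_)
    p_in <- 1 - exp(lchoose(N - B[i, ], m) - lchoose(N, m))
    sum(inc$lengths * p_in)
  }, numeric(1))
  data.frame(sample_id = rownames(counts), pd = pd, m = m,
             stringsAsFactors = FALSE)
}
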