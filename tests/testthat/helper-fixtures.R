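# Shared fixtures, built in code.

# 3-tip tree with patristic d(A,B) = 0.05, d(A,C) = d(B,C) = 0.5
tree3 <- function() {
  ape::read.tree(text = "(C:0.25,(A:0.025,B:0.025):0.225);")
}

# 2-tip tree with unit-length tip branches
tree2 <- function() {
  ape::read.tree(text = "(A:1,B:1);")
}

# tiny hand-built count table
tiny_counts <- function() {
  m <- matrix(c(6L, 2L,
                2L, 2L,
                0L, 5L), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("ASV_1", "ASV_2")))
  m
}

# metadata for a 2-subject, 2-window mini cohort (3 BL days + 2 W10 days)
mini_metadata <- function() {
  samples <- data.frame(
    sample_id = c("a1", "a2", "a3", "a4", "a5", "b1", "b2"),
    subject_id = c("A", "A", "A", "A", "A", "B", "B"),
    window = c("BL", "BL", "BL", "W10", "W10", "BL", "BL"),
    day_offset = c(1L, 2L, 3L, 1L, 2L, 1L, 2L),
    lane = "L1", stringsAsFactors = FALSE)
  subjects <- data.frame(
    subject_id = c("A", "B"), diet = c("low-carb", "low-fat"),
    sex = c("F", "M"), weight_loss_pct_12mo = c(12, 1),
    restricted_pct_bl = c(40, 35),
    restricted_pct_3m = c(20, 10), restricted_pct_6m = c(22, 12),
    restricted_pct_12m = c(24, 14), stringsAsFactors = FALSE)
  validate_metadata(samples, subjects)
}

# named square distance matrix from a vector of pairwise values
dm_from_pairs <- function(ids, pairs) {
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (p in pairs) D[p[[1]], p[[2]]] <- D[p[[2]], p[[1]]] <- p[[3]]
  D
}

# Procrustes error after optimal translation + rotation/reflection
procrustes_error <- function(X, Y) {
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  sum((X %*% R - Y)^2)
}
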