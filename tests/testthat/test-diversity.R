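test_that("asinh transform matches its closed form and is monotone", {
  expect_equal(asinh_transform(0), 0)
  expect_equal(asinh_transform(100), log(100 + sqrt(1 + 100^2)))
  expect_equal(asinh_transform(100), 5.29834, tolerance = 1e-5)
  x <- seq(0, 50, by = 0.5)
  expect_true(all(diff(asinh_transform(x)) > 0))
  expect_error(asinh_transform(-1), "non-negative")
})

test_that("pairwise metrics match hand-computed values and axioms", {
  u <- c(6, 2); v <- c(2, 2)
  expect_equal(bray_curtis(u, v), 4 / 12)
  expect_equal(bray_curtis(u, u), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 3)), 1)

  a <- c(1, 1, 1, 0); b <- c(0, 2, 5, 9)  # supports {1,2,3} vs {2,3,4}
  expect_equal(jaccard_dissimilarity(a, b), 0.5)
  expect_equal(jaccard_dissimilarity(a, 2 * a), 0)
  expect_equal(jaccard_dissimilarity(c(1, 0), c(0, 1)), 1)

  expect_equal(jensen_shannon(c(1, 0), c(0, 1)), 1)
  expect_equal(jensen_shannon(c(3, 1), c(3, 1)), 0)
  p <- c(0.2, 0.5, 0.3); q <- c(0.6, 0.1, 0.3)
  expect_equal(jensen_shannon(p, q), jensen_shannon(q, p))
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "no positive")
})

test_that("metric axioms hold for all five metrics on random samples", {
  fx <- fixture_small()
  counts <- fx$counts[1:8, , drop = FALSE]
  for (metric in c("bray", "jaccard", "jsd", "uunifrac", "wunifrac")) {
    D <- distance_matrix(counts, metric, tree = fx$tree)
    expect_equal(D, t(D), info = metric)
    expect_true(all(diag(D) == 0), info = metric)
    expect_true(all(D >= 0 & D <= 1 + 1e-12), info = metric)
  }
})

test_that("unifrac matches hand cases and is abundance-scale invariant", {
  tr <- tree2()
  expect_equal(unifrac(tr, c(A = 3, B = 0), c(A = 0, B = 5)), 1)
  expect_equal(unifrac(tr, c(A = 3, B = 0), c(A = 0, B = 5),
                       weighted = TRUE), 1)
  expect_equal(unifrac(tr, c(A = 1, B = 1), c(A = 1, B = 1)), 0)
  expect_equal(unifrac(tr, c(A = 1, B = 1), c(A = 1, B = 1),
                       weighted = TRUE), 0)
  u <- c(A = 2, B = 1, C = 0); v <- c(A = 0, B = 3, C = 1)
  tr3 <- tree3()
  expect_equal(unifrac(tr3, u, v), unifrac(tr3, 10 * u, v))
  # hand evaluation on the 3-tip tree: unique branches A (0.025) and
  # C (0.25); all branches observed (0.025+0.025+0.225+0.25)
  expect_equal(unifrac(tr3, u, v), (0.025 + 0.25) / 0.525)
})

test_that("unifrac agrees with the phyloseq implementation", {
  skip_if_not_installed("phyloseq")
  fx <- fixture_small()
  counts <- fx$counts[1:6, , drop = FALSE]
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(t(counts), taxa_are_rows = TRUE),
    phyloseq::phy_tree(fx$tree))
  for (w in c(FALSE, TRUE)) {
    ref <- as.matrix(phyloseq::UniFrac(ps, weighted = w, normalized = TRUE))
    metric <- if (w) "wunifrac" else "uunifrac"
    D <- distance_matrix(counts, metric, tree = fx$tree)
    expect_equal(D[rownames(ref), colnames(ref)], ref,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("distance_matrix is consistent with the pairwise calls", {
  counts <- tiny_counts()
  D <- distance_matrix(counts, "bray", scale = "proportion")
  p <- counts / rowSums(counts)
  expect_equal(D["s1", "s2"], bray_curtis(p["s1", ], p["s2", ]))
  expect_equal(D["s1", "s3"], bray_curtis(p["s1", ], p["s3", ]))
  # permuting samples permutes the matrix consistently
  D2 <- distance_matrix(counts[c(3, 1, 2), ], "bray")
  expect_equal(D2[rownames(D), colnames(D)], D, ignore_attr = TRUE)
  expect_error(distance_matrix(counts, "uunifrac"), "tree")
})

test_that("bray and jaccard agree with vegan on the fixture", {
  skip_if_not_installed("vegan")
  fx <- fixture_small()
  counts <- fx$counts[1:10, , drop = FALSE]
  p <- counts / rowSums(counts)
  expect_equal(distance_matrix(counts, "bray"),
               as.matrix(vegan::vegdist(p, "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(distance_matrix(counts, "jaccard"),
               as.matrix(vegan::vegdist(counts > 0, "jaccard")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("bray-curtis on proportions ignores library-size scaling", {
  counts <- tiny_counts()
  scaled <- counts
  scaled[1, ] <- scaled[1, ] * 7L
  expect_equal(distance_matrix(counts, "bray"),
               distance_matrix(scaled, "bray"), ignore_attr = TRUE)
})

test_that("expected rarefied PD matches enumeration and subsampling", {
  tr <- tree2()
  # m = 1 with counts (1,1): both singleton subsamples span one unit branch
  expect_equal(expected_pd_rarefied(tr, c(A = 1, B = 1), 1), 1.0)
  # m = N recovers Faith's PD of the observed branches
  expect_equal(expected_pd_rarefied(tr, c(A = 3, B = 2), 5), 2.0)
  expect_error(expected_pd_rarefied(tr, c(A = 1, B = 1), 3),
               "interpolation")

  # Monte-Carlo oracle on a 10-tip tree
  set.seed(7)
  tr10 <- ape::rcoal(10, tip.label = paste0("t", 1:10))
  counts <- stats::setNames(rpois(10, 8) + 1L, tr10$tip.label)
  m <- 12
  inc_pd <- function(kept) {
    # Faith's PD of a multiset of tip draws via the package's full-depth call
    tab <- table(factor(kept, levels = tr10$tip.label))
    expected_pd_rarefied(tr10, stats::setNames(as.integer(tab),
                                               tr10$tip.label), sum(tab))
  }
  pool <- rep(tr10$tip.label, counts)
  draws <- replicate(1000, inc_pd(sample(pool, m)))
  mc <- mean(draws); se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(expected_pd_rarefied(tr10, counts, m) - mc), 3 * se)
})

test_that("expected rarefied PD is non-decreasing in depth", {
  set.seed(3)
  tr <- ape::rcoal(8, tip.label = paste0("t", 1:8))
  counts <- stats::setNames(rpois(8, 20) + 1L, tr$tip.label)
  vals <- vapply(seq(1, sum(counts), length.out = 10), function(m)
    expected_pd_rarefied(tr, counts, floor(m)), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("alpha_table flags shallow samples and bounds PD", {
  fx <- fixture_small()
  total_bl <- sum(fx$tree$edge.length)
  at <- alpha_table(fx$counts, fx$tree, m = 500)
  expect_true(all(is.finite(at$pd)))
  expect_true(all(at$pd <= total_bl))
  # identical count vectors give identical PD
  c2 <- fx$counts[c(1, 1), , drop = FALSE]
  rownames(c2) <- c("x", "y")
  at2 <- alpha_table(c2, fx$tree, m = 400)
  expect_equal(at2$pd[1], at2$pd[2])
  expect_warning(alpha_table(fx$counts, fx$tree, m = 10^7), "below")
})
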