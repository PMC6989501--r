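test_that("consecutive pairs follow collection order, never skipping", {
  expect_equal(consecutive_pairs(c("a", "b", "c")),
               list(c("a", "b"), c("b", "c")))
  expect_equal(consecutive_pairs(c("a", "b")), list(c("a", "b")))
  expect_equal(consecutive_pairs("a"), list())
})

test_that("daily plasticity averages consecutive pairs only", {
  dm <- dm_from_pairs(c("a", "b", "c"),
                      list(list("a", "b", 0.3), list("b", "c", 0.5),
                           list("a", "c", 0.9)))
  r <- daily_plasticity(c("a", "b", "c"), dm)
  expect_equal(r$value, 0.4)   # (0.3 + 0.5)/2; d(a,c) = 0.9 ignored
  expect_equal(r$n_pairs, 2L)
  expect_equal(daily_plasticity(c("a", "b"), dm)$value, 0.3)
  expect_true(is.na(daily_plasticity("a", dm)$value))
  # invariant to the value stored for non-consecutive pairs
  dm2 <- dm; dm2["a", "c"] <- dm2["c", "a"] <- 0.123
  expect_equal(daily_plasticity(c("a", "b", "c"), dm2)$value, 0.4)
})

test_that("cross-period plasticity is the bipartite mean", {
  dm <- dm_from_pairs(c("a", "b", "c"),
                      list(list("a", "c", 0.2), list("b", "c", 0.4)))
  r <- cross_period_plasticity(c("a", "b"), "c", dm)
  expect_equal(r$value, 0.3)
  expect_equal(r$n_pairs, 2L)
  ids <- paste0("s", 1:6)
  dm6 <- matrix(0.5, 6, 6, dimnames = list(ids, ids)); diag(dm6) <- 0
  r <- cross_period_plasticity(ids[1:3], ids[4:6], dm6)
  expect_equal(r$n_pairs, 9L)
  expect_equal(r$value, 0.5)
  expect_true(is.na(cross_period_plasticity(character(0), "c", dm)$value))
})

test_that("plasticity table covers subjects, pairings and hand values", {
  md <- mini_metadata()
  ids <- md$samples$sample_id
  counts <- matrix(rpois(7 * 5, 40) + 1L, 7, 5,
                   dimnames = list(ids, paste0("ASV_", 1:5)))
  pt <- plasticity_table(counts, md, metrics = "bray")
  # subject A: all three pairings; subject B: BLvBL only
  expect_setequal(pt$pairing[pt$subject_id == "A"],
                  c("BLvBL", "W10vW10", "BLvW10"))
  expect_equal(pt$pairing[pt$subject_id == "B"], "BLvBL")
  dm <- distance_matrix(counts, "bray")
  expect_equal(pt$value[pt$subject_id == "A" & pt$pairing == "BLvBL"],
               (dm["a1", "a2"] + dm["a2", "a3"]) / 2)
  expect_equal(pt$value[pt$subject_id == "A" & pt$pairing == "BLvW10"],
               mean(dm[c("a1", "a2", "a3"), c("a4", "a5")]))
  expect_equal(pt$n_pairs[pt$subject_id == "A" & pt$pairing == "BLvW10"],
               6L)
  # deterministic
  expect_identical(pt, plasticity_table(counts, md, metrics = "bray"))
})

test_that("every fixture subject has a BLvBL row", {
  fx <- fixture_small()
  pt <- plasticity_table(fx$counts, fx$metadata, metrics = "bray")
  expect_setequal(pt$subject_id[pt$pairing == "BLvBL"],
                  fx$metadata$subjects$subject_id)
})

test_that("group comparison is an exact rank-sum test on subject means", {
  pt <- data.frame(subject_id = c("s1", "s2", "s3", "s4"),
                   pairing = "BLvBL", metric = "bray",
                   value = c(0.1, 0.2, 0.8, 0.9), n_pairs = 2L,
                   stringsAsFactors = FALSE)
  groups <- c(s1 = "US", s2 = "US", s3 = "VS", s4 = "VS")
  r <- compare_plasticity_groups(pt, groups)
  expect_equal(r$p_value, 2 / choose(4, 2))   # exact enumeration
  # relabeling invariance
  r2 <- compare_plasticity_groups(pt, groups, levels = c("VS", "US"))
  expect_equal(r$p_value, r2$p_value)
  # identical multisets give p = 1
  pt$value <- c(0.3, 0.6, 0.3, 0.6)
  expect_equal(compare_plasticity_groups(pt, groups)$p_value, 1)
  expect_error(compare_plasticity_groups(pt, c(s1 = "US", s2 = "US",
                                               s3 = "US", s4 = "US")),
               "empty")
})

test_that("plasticity-covariate correlation matches rank arithmetic", {
  pt <- data.frame(subject_id = c("s1", "s2", "s3"), pairing = "BLvBL",
                   metric = "bray", value = c(1, 2, 3), n_pairs = 2L,
                   stringsAsFactors = FALSE)
  expect_equal(correlate_plasticity(pt, c(s1 = 2, s2 = 1, s3 = 3))$rho,
               0.5)
  expect_equal(correlate_plasticity(pt, c(s1 = 1, s2 = 2, s3 = 3))$rho, 1)
  expect_equal(correlate_plasticity(pt, c(s1 = -1, s2 = -2, s3 = -3))$rho,
               -1)
  expect_warning(
    r <- correlate_plasticity(pt, c(s1 = 1, s2 = 2, s3 = NA)),
    "fewer than 3")
  expect_true(is.na(r$rho))
})

test_that("intra/inter comparison books pairs combinatorially", {
  md <- mini_metadata()
  ids <- md$samples$sample_id
  n <- length(ids)
  dm <- matrix(0.4, n, n, dimnames = list(ids, ids)); diag(dm) <- 0
  cmp <- intra_inter_comparison(dm, md, window = "BL")
  # BL: subject A has 3 samples (3 intra pairs), B has 2 (1 intra pair);
  # 5 choose 2 = 10 total pairs -> 6 inter
  expect_equal(length(cmp$intra), 4L)
  expect_equal(length(cmp$inter), 6L)
  # all-identical samples give all-zero distributions
  dm0 <- dm * 0
  cmp0 <- intra_inter_comparison(dm0, md, window = "BL")
  expect_true(all(cmp0$intra == 0) && all(cmp0$inter == 0))
})

test_that("plasticity recovers the true turnover ordering across subjects", {
  cfg <- sim_config(n_subjects_per_diet = 10, n_taxa = 100,
                    depth_log_mean = log(10000), depth_log_sd = 0,
                    sigma_plasticity = seq(0.1, 1.0, length.out = 20),
                    n_lanes = 2, seed = 31)
  b <- simulate_cohort(cfg)
  pt <- plasticity_table(b$counts, b$metadata, metrics = "bray")
  bl <- pt[pt$pairing == "BLvBL", ]
  est <- stats::setNames(bl$value, bl$subject_id)
  truth <- b$truth$sigma_plasticity[names(est)]
  expect_gt(spearman_cor(truth, est)$rho, 0.8)
})

test_that("a simulated diet shift makes cross-period exceed daily
           plasticity", {
  cfg <- sim_config(n_subjects_per_diet = 8, n_taxa = 80,
                    depth_log_mean = log(8000), depth_log_sd = 0,
                    delta_diet_shift = 2, n_lanes = 1, seed = 17)
  b <- simulate_cohort(cfg)
  pt <- plasticity_table(b$counts, b$metadata, metrics = "bray")
  cross <- mean(pt$value[pt$pairing == "BLvW10"])
  daily <- mean(pt$value[pt$pairing %in% c("BLvBL", "W10vW10")])
  expect_gt(cross, daily)
})
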