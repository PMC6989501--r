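#' Simulate a random rooted phylogeny over ASV tips
#'
#' Random coalescent topology with the tips labelled `ASV_1..ASV_n`; all
#' branch lengths are positive and the tree is rooted and binary
#' (2n - 2 edges).
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed RNG seed.
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(n_taxa, seed = 1) {
  if (n_taxa < 2L) stop("need at least 2 taxa", call. = FALSE)
  set.seed(seed)
  ape::rcoal(n_taxa, tip.label = paste0("ASV_", seq_len(n_taxa)))
}

#' Simulation configuration for a two-arm longitudinal cohort
#'
#' Defaults emulate a two-arm diet-intervention discovery cohort: ~32
#' subjects per arm sampled on three consecutive days pre-diet (BL) and
#' again at 10 weeks (W10), a sparse table of ~1,000 ASVs, per-sample
#' sequencing depth log-normal around 73,000 +/- 33,000 reads, and 7
#' sequencing lanes.
#'
#' @param n_subjects_per_diet subjects per diet arm.
#' @param n_taxa number of ASVs.
#' @param days_per_window daily samples per subject per window.
#' @param depth_log_mean,depth_log_sd log-normal library-size parameters
#'   (defaults give mean ~73,700, SD ~33,400 reads).
#' @param base_concentration symmetric Dirichlet concentration of the
#'   global mean composition (small values give realistic sparsity).
#' @param sigma_subject SD of the per-taxon subject offset on the log
#'   scale (inter-individual variation).
#' @param sigma_plasticity per-subject daily turnover SD on the log scale;
#'   scalar, or a vector with one value per subject (low-carb arm first).
#' @param delta_diet_shift magnitude of the BL to W10 log-composition
#'   shift along a fixed per-diet direction, scaled per subject by dietary
#'   change relative to the arm mean.
#' @param n_da_taxa,da_effect number and asinh-scale magnitude of taxa
#'   whose pre-diet abundance differs between very-successful (VS) and
#'   unsuccessful (US) subjects. Differential taxa are drawn from taxa
#'   abundant enough for a log shift to equal an asinh shift.
#' @param n_lanes,lane_bias_sd number of sequencing lanes and SD of the
#'   per-lane multiplicative (log-scale) taxon bias.
#' @param frac_prevotella,frac_bacteroides fraction of taxa labelled with
#'   those genera in the taxonomy.
#' @param prevotella_carrier_prob probability a subject carries Prevotella
#'   at all (about half of real-world subjects have none detected).
#' @param seed RNG seed; one global stream drives the whole simulation.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects_per_diet = 32, n_taxa = 1000,
                       days_per_window = 3,
                       depth_log_mean = 11.11, depth_log_sd = 0.43,
                       base_concentration = 0.5,
                       sigma_subject = 0.8, sigma_plasticity = 0.5,
                       delta_diet_shift = 1.0,
                       n_da_taxa = 0, da_effect = 0,
                       n_lanes = 7, lane_bias_sd = 0.1,
                       frac_prevotella = 0.02, frac_bacteroides = 0.05,
                       prevotella_carrier_prob = 0.5, seed = 1) {
  cfg <- list(n_subjects_per_diet = n_subjects_per_diet, n_taxa = n_taxa,
              days_per_window = days_per_window,
              depth_log_mean = depth_log_mean,
              depth_log_sd = depth_log_sd,
              base_concentration = base_concentration,
              sigma_subject = sigma_subject,
              sigma_plasticity = sigma_plasticity,
              delta_diet_shift = delta_diet_shift,
              n_da_taxa = n_da_taxa, da_effect = da_effect,
              n_lanes = n_lanes, lane_bias_sd = lane_bias_sd,
              frac_prevotella = frac_prevotella,
              frac_bacteroides = frac_bacteroides,
              prevotella_carrier_prob = prevotella_carrier_prob,
              seed = seed)
  n_subj <- 2L * n_subjects_per_diet
  sds <- c(depth_log_sd, sigma_subject, lane_bias_sd, cfg$sigma_plasticity)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (any(c(frac_prevotella, frac_bacteroides,
            prevotella_carrier_prob) < 0) ||
      any(c(frac_prevotella, frac_bacteroides,
            prevotella_carrier_prob) > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (n_da_taxa > n_taxa) stop("n_da_taxa exceeds n_taxa", call. = FALSE)
  if (!length(cfg$sigma_plasticity) %in% c(1L, n_subj))
    stop("sigma_plasticity must be scalar or one value per subject",
         call. = FALSE)
  if (!is.finite(exp(depth_log_mean)) || exp(depth_log_mean) < 1)
    stop("infeasible sequencing depth", call. = FALSE)
  if (n_taxa < 2L || n_subjects_per_diet < 1L || days_per_window < 1L ||
      n_lanes < 1L)
    stop("infeasible configuration", call. = FALSE)
  structure(cfg, class = "sim_config")
}

softmax_log <- function(eta) {
  m <- max(eta[is.finite(eta)])
  x <- exp(eta - m)
  x / sum(x)
}

#' Simulate a longitudinal two-arm cohort
#'
#' Generative model, in order: (1) a global mean composition p from a
#' symmetric Dirichlet; (2) each subject's baseline log-composition is
#' log p plus an i.i.d. Normal(0, sigma_subject^2) per-taxon offset, plus
#' the differential-abundance shift for its success category; (3) each
#' sampling day adds an exchangeable Normal(0, sigma_plasticity^2)
#' per-taxon perturbation around the subject centroid (a subject-level
#' trait, not a random walk); (4) W10 samples add a shift of magnitude
#' `delta_diet_shift` along a fixed unit direction per diet, scaled by the
#' subject's dietary change relative to the arm mean; (5) a per-lane
#' multiplicative taxon bias acts on the log scale before (6) counts are
#' drawn Multinomial(depth, softmax(eta)) with log-normal depths. Subject
#' weight loss is drawn per arm so that all of US/MS/VS occur, and
#' restricted-component dietary recalls are drawn consistently with the
#' arm (carbs restricted on low-carb, fat on low-fat).
#'
#' @param config a [sim_config()].
#' @return list with `counts`, `metadata` (`cohort_metadata`), `tree`,
#'   `taxonomy`, `truth` (per-subject true plasticity SDs, differential
#'   taxa with signed effects, per-subject shift magnitudes, lane bias
#'   matrix), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nt <- config$n_taxa
  nspd <- config$n_subjects_per_diet
  n_subj <- 2L * nspd
  taxa <- paste0("ASV_", seq_len(nt))

  tree <- ape::rcoal(nt, tip.label = taxa)

  # taxonomy: disjoint Prevotella and Bacteroides label sets
  n_prev <- max(1L, round(config$frac_prevotella * nt))
  n_bact <- max(1L, round(config$frac_bacteroides * nt))
  special <- sample(nt, n_prev + n_bact)
  prev_idx <- special[seq_len(n_prev)]
  bact_idx <- special[n_prev + seq_len(n_bact)]
  genus <- rep("", nt)
  genus[prev_idx] <- "Prevotella"
  genus[bact_idx] <- "Bacteroides"
  taxonomy <- data.frame(asv_id = taxa, genus = genus,
                         stringsAsFactors = FALSE)

  # global composition
  g <- stats::rgamma(nt, shape = config$base_concentration)
  g[g == 0] <- .Machine$double.xmin
  p_global <- g / sum(g)
  log_p <- log(p_global)

  # subjects
  diet <- rep(DIET_LEVELS, each = nspd)
  subj_ids <- sprintf("S%03d", seq_len(n_subj))
  sex <- ifelse(stats::runif(n_subj) < 0.6, "F", "M")
  wl_mean <- ifelse(diet == "low-carb", 8.4, 6.3)
  wl <- numeric(n_subj)
  for (d in DIET_LEVELS) {
    idx <- which(diet == d)
    for (try in seq_len(100L)) {
      draw <- stats::rnorm(length(idx), wl_mean[idx], 7.7)
      if (all(c("US", "MS", "VS") %in% classify_success(draw))) break
    }
    wl[idx] <- draw
  }
  success <- classify_success(wl)

  # dietary recalls for the restricted component (percent of kcal)
  base_mean <- ifelse(diet == "low-carb", 44.6, 36.8)
  base_sd <- ifelse(diet == "low-carb", 7.6, 6.5)
  ondiet_mean <- rbind(`low-carb` = c(17.6, 22.1, 27.3),
                       `low-fat` = c(21.4, 25.6, 28.6))
  rest_bl <- pmin(pmax(stats::rnorm(n_subj, base_mean, base_sd), 5), 95)
  rest_on <- t(vapply(seq_len(n_subj), function(s)
    pmin(pmax(stats::rnorm(3L, ondiet_mean[diet[s], ], 6), 1), 95),
    numeric(3L)))
  change <- rest_bl - rowMeans(rest_on)

  # per-diet unit shift direction and per-subject shift scale
  v_diet <- lapply(DIET_LEVELS, function(d) {
    z <- stats::rnorm(nt)
    z / sqrt(sum(z^2))
  })
  names(v_diet) <- DIET_LEVELS
  shift_scale <- numeric(n_subj)
  for (d in DIET_LEVELS) {
    idx <- which(diet == d)
    mc <- mean(change[idx])
    shift_scale[idx] <- if (abs(mc) < 1e-8) 1 else change[idx] / mc
  }

  # differential taxa: only taxa abundant enough that a log shift is an
  # asinh shift (expected count >= 20 at the median depth)
  da_idx <- integer(0)
  da_sign <- integer(0)
  if (config$n_da_taxa > 0L) {
    med_depth <- exp(config$depth_log_mean)
    eligible <- setdiff(which(p_global * med_depth >= 20), prev_idx)
    if (length(eligible) < config$n_da_taxa)
      eligible <- setdiff(order(p_global, decreasing = TRUE), prev_idx)
    da_idx <- sort(sample(eligible, config$n_da_taxa))
    da_sign <- sample(c(-1L, 1L), config$n_da_taxa, replace = TRUE)
  }
  da_score <- c(US = 0, MS = 0.5, VS = 1)[success]

  sigma_pl <- rep(config$sigma_plasticity, length.out = n_subj)
  carrier <- stats::runif(n_subj) < config$prevotella_carrier_prob
  lane_ids <- paste0("L", seq_len(config$n_lanes))
  lane_bias <- matrix(stats::rnorm(config$n_lanes * nt, 0,
                                   config$lane_bias_sd),
                      config$n_lanes, nt,
                      dimnames = list(lane_ids, taxa))

  # subject baseline log-compositions
  baseline <- matrix(0, n_subj, nt, dimnames = list(subj_ids, taxa))
  for (s in seq_len(n_subj)) {
    eta <- log_p + stats::rnorm(nt, 0, config$sigma_subject)
    if (length(da_idx))
      eta[da_idx] <- eta[da_idx] + da_score[s] * da_sign * config$da_effect
    if (!carrier[s]) eta[prev_idx] <- -Inf
    baseline[s, ] <- eta
  }

  n_samples <- n_subj * 2L * config$days_per_window
  counts <- matrix(0L, n_samples, nt, dimnames = list(NULL, taxa))
  meta <- vector("list", n_samples)
  k <- 0L
  for (s in seq_len(n_subj)) {
    for (win in WINDOW_LEVELS) {
      for (day in seq_len(config$days_per_window)) {
        k <- k + 1L
        eta <- baseline[s, ] + stats::rnorm(nt, 0, sigma_pl[s])
        if (win == "W10")
          eta <- eta + config$delta_diet_shift * shift_scale[s] *
            v_diet[[diet[s]]]
        lane <- sample(lane_ids, 1L)
        eta <- eta + lane_bias[lane, ]
        depth <- max(1L, round(stats::rlnorm(1L, config$depth_log_mean,
                                             config$depth_log_sd)))
        counts[k, ] <- stats::rmultinom(1L, depth, softmax_log(eta))[, 1L]
        meta[[k]] <- data.frame(
          sample_id = sprintf("%s_%s_d%d", subj_ids[s], win, day),
          subject_id = subj_ids[s], window = win, day_offset = day,
          lane = lane, stringsAsFactors = FALSE)
      }
    }
  }
  samples <- do.call(rbind, meta)
  rownames(counts) <- samples$sample_id
  # drop taxa never observed (keeps the table valid and realistic)
  observed <- colSums(counts) > 0
  counts <- counts[, observed, drop = FALSE]
  taxonomy <- taxonomy[observed, , drop = FALSE]
  tree_obs <- if (sum(observed) < nt)
    ape::drop.tip(tree, taxa[!observed]) else tree

  subjects <- data.frame(
    subject_id = subj_ids, diet = diet, sex = sex,
    weight_loss_pct_12mo = wl,
    restricted_pct_bl = rest_bl,
    restricted_pct_3m = rest_on[, 1L],
    restricted_pct_6m = rest_on[, 2L],
    restricted_pct_12m = rest_on[, 3L],
    stringsAsFactors = FALSE)
  metadata <- validate_metadata(samples, subjects)
  truth <- list(
    sigma_plasticity = stats::setNames(sigma_pl, subj_ids),
    da_taxa = if (length(da_idx))
      data.frame(asv_id = taxa[da_idx],
                 effect = da_sign * config$da_effect,
                 stringsAsFactors = FALSE)
      else data.frame(asv_id = character(), effect = numeric(),
                      stringsAsFactors = FALSE),
    shift_magnitude = stats::setNames(
      config$delta_diet_shift * shift_scale, subj_ids),
    lane_bias = lane_bias,
    prevotella_carrier = stats::setNames(carrier, subj_ids))
  list(counts = validate_count_table(counts), metadata = metadata,
       tree = tree_obs, taxonomy = taxonomy, truth = truth,
       config = config)
}

#' Deterministic small fixture cohort
#'
#' A tiny bundle (6 subjects per diet, 40 taxa, depth ~2,000, 2 lanes)
#' regenerated deterministically for tests and examples. Every subject has
#' three BL samples by construction.
#'
#' @return the [simulate_cohort()] bundle.
#' @export
fixture_small <- function() {
  simulate_cohort(sim_config(
    n_subjects_per_diet = 6, n_taxa = 40, days_per_window = 3,
    depth_log_mean = log(2000), depth_log_sd = 0.1,
    n_lanes = 2, seed = 42))
}
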