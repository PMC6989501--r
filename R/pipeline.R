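#' Default pipeline configuration
#'
#' @param outdir output directory.
#' @param sim list of arguments for [sim_config()] (the synthetic cohort
#'   to analyse).
#' @param metric beta-diversity metric for plasticity and ordination.
#' @param scale count scale for plasticity distances.
#' @param alpha_depth rarefaction depth for phylogenetic alpha-diversity.
#' @param cluster_height tree-cut height for ASV clustering.
#' @param da_mode,da_level,da_alpha differential-abundance settings.
#' @param pb_cutoff P/B ratio dichotomization cutoff.
#' @param n_perm PERMANOVA permutations.
#' @param seed pipeline seed (PERMANOVA permutations).
#' @return config list.
#' @export
pipeline_config <- function(outdir, sim = list(), metric = "bray",
                            scale = "proportion", alpha_depth = 11000,
                            cluster_height = 0.1,
                            da_mode = "categorical", da_level = "asv",
                            da_alpha = 0.05, pb_cutoff = 0.003,
                            n_perm = 999, seed = 1) {
  list(outdir = outdir, sim = sim, metric = metric, scale = scale,
       alpha_depth = alpha_depth, cluster_height = cluster_height,
       da_mode = da_mode, da_level = da_level, da_alpha = da_alpha,
       pb_cutoff = pb_cutoff, n_perm = n_perm, seed = seed)
}

validate_pipeline_config <- function(config) {
  need <- c("outdir", "metric", "scale", "alpha_depth", "cluster_height",
            "da_mode", "da_level", "da_alpha", "pb_cutoff", "n_perm",
            "seed")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("pipeline config missing fields: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!config$metric %in% c("bray", "jaccard", "jsd", "uunifrac",
                            "wunifrac"))
    stop("unknown metric '", config$metric, "'", call. = FALSE)
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Orchestrates: simulate -> phenotypes -> alpha-diversity -> plasticity ->
#' clustering -> differential abundance -> community statistics
#' (P/B ratio, ordination, PERMANOVA), writing every stage's output under
#' `config$outdir` together with a manifest (config echo, package version,
#' per-stage wall time and output file checksums). Reruns with the same
#' config are identical for all deterministic stages. A stage failure
#' aborts with the stage named; earlier outputs are retained.
#'
#' @param config a [pipeline_config()] list, or the path of a YAML file
#'   holding one.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages[[name]] <<- list(
      files = basename(files),
      md5 = unname(tools::md5sum(files)),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    files
  }

  bundle <- NULL
  run_stage("simulate", function() {
    bundle <<- simulate_cohort(do.call(sim_config, config$sim))
    f <- file.path(outdir, c("counts.tsv", "tree.nwk", "taxonomy.tsv",
                             "samples.tsv", "subjects.tsv", "truth.json"))
    write_count_table(bundle$counts, f[1L])
    write_tree(bundle$tree, f[2L])
    write_taxonomy(bundle$taxonomy, f[3L])
    write_metadata(bundle$metadata, f[4L], f[5L])
    jsonlite::write_json(list(
      sigma_plasticity = as.list(bundle$truth$sigma_plasticity),
      da_taxa = bundle$truth$da_taxa,
      shift_magnitude = as.list(bundle$truth$shift_magnitude)),
      f[6L], auto_unbox = TRUE, digits = NA)
    f
  })

  phen <- NULL
  run_stage("phenotypes", function() {
    phen <<- phenotype_table(bundle$metadata)
    f <- file.path(outdir, "phenotypes.tsv")
    utils::write.table(phen, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  })

  run_stage("alpha", function() {
    at <- suppressWarnings(
      alpha_table(bundle$counts, bundle$tree, m = config$alpha_depth))
    f <- file.path(outdir, "alpha.tsv")
    utils::write.table(at, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })

  pt <- NULL
  run_stage("plasticity", function() {
    pt <<- plasticity_table(bundle$counts, bundle$metadata,
                            metrics = config$metric, scale = config$scale,
                            tree = bundle$tree)
    f <- file.path(outdir, "plasticity.tsv")
    utils::write.table(pt, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })

  run_stage("cluster", function() {
    ca <- cut_tree(bundle$tree, config$cluster_height)
    agg <- aggregate_by_cluster(bundle$counts, ca)
    f <- file.path(outdir, c("clusters.tsv", "cluster_counts.tsv"))
    utils::write.table(
      data.frame(asv_id = names(ca$assignment),
                 cluster_id = unname(ca$assignment),
                 stringsAsFactors = FALSE),
      f[1L], sep = "\t", quote = FALSE, row.names = FALSE)
    write_count_table(agg, f[2L])
    f
  })

  run_stage("da", function() {
    da <- run_da(bundle$counts, bundle$metadata, phen,
                 mode = config$da_mode, level = config$da_level,
                 tree = bundle$tree, h = config$cluster_height,
                 alpha = config$da_alpha)
    f <- file.path(outdir, paste0("da_", gsub("-", "", names(da)), ".tsv"))
    for (i in seq_along(da))
      utils::write.table(da[[i]], f[i], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    f
  })

  run_stage("community", function() {
    pb <- pb_ratio(bundle$counts, bundle$taxonomy, bundle$metadata)
    pb$per_subject$class <- classify_pb(pb, config$pb_cutoff)[
      pb$per_subject$subject_id]
    sm <- bundle$metadata$samples
    bl <- sm$sample_id[sm$window == "BL"]
    dm <- distance_matrix(bundle$counts[bl, , drop = FALSE],
                          metric = config$metric,
                          scale = "asinh_normalized", tree = bundle$tree)
    ord <- pcoa_ordination(dm, n_axes = 2)
    groups <- phen$success[match(sm$subject_id[match(bl, sm$sample_id)],
                                 phen$subject_id)]
    pmv <- permanova(dm, groups, n_perm = config$n_perm,
                     seed = config$seed)
    f <- file.path(outdir, c("pb.tsv", "ordination.tsv", "permanova.json"))
    utils::write.table(pb$per_subject, f[1L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = rownames(ord$coordinates),
                 ord$coordinates, stringsAsFactors = FALSE),
      f[2L], sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(pmv), f[3L], auto_unbox = TRUE,
                         digits = NA)
    f
  })

  manifest <- list(
    package = "plasticome",
    version = as.character(utils::packageVersion("plasticome")),
    config = config[setdiff(names(config), "outdir")],
    stages = stages)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
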