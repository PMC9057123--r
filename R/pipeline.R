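# End-to-end orchestration: synthetic trial (or user point clouds) ->
# terrain -> detection -> traits -> genetics, with every intermediate
# artifact written to the output directory and a machine-readable manifest.
# All defaults are the field-standard values used throughout the package
# (0.5 m rasters, 2.6 m minimum tree height, 5 m maximum crown diameter,
# heritability coefficient 2.5, selection ratios 10/20/30%).

#' Pipeline configuration
#'
#' A validated list of every tunable parameter of the pipeline, with a schema
#' version so configurations round-trip losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param preset optional fixture preset (`"tiny"`, `"easy"`, `"paperlike"`)
#'   supplying design, architecture and rendering defaults; `NULL` for a
#'   fully manual configuration.
#' @param n_sites,n_blocks_per_site,n_families,spacing_x,spacing_y trial
#'   layout (see [trial_design()]).
#' @param survival fraction of planted trees alive.
#' @param density point density (points per m^2); see [density_presets].
#' @param noise_sd vertical point noise SD (m).
#' @param res raster resolution (m).
#' @param min_height minimum detectable tree height (m).
#' @param max_crown_diameter maximum crown diameter (m).
#' @param knn_k,knn_power DTM interpolation parameters.
#' @param cloth_resolution,rigidness,csf_threshold ground-filter parameters.
#' @param gam_k spline basis size of the DBH model.
#' @param h2_coefficient heritability relationship coefficient.
#' @param ratios selection ratios.
#' @param n_ground_truth number of trees measured on the ground (DBH model
#'   training set).
#' @param seed integer seed driving every random stage.
#' @param arch a [genetic_architecture()]; default architecture if `NULL`.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = NULL,
                            n_sites = 2, n_blocks_per_site = 14,
                            n_families = 20, spacing_x = 2, spacing_y = 3,
                            survival = 1, density = 100, noise_sd = 0.05,
                            res = 0.5, min_height = 2.6,
                            max_crown_diameter = 5,
                            knn_k = 10, knn_power = 2,
                            cloth_resolution = 0.5, rigidness = 2,
                            csf_threshold = 0.5,
                            gam_k = 10, h2_coefficient = 2.5,
                            ratios = c(0.1, 0.2, 0.3),
                            n_ground_truth = 100, seed = 1, arch = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("tiny", "easy", "paperlike"))
    pp <- preset_params(preset)
    for (nm in names(pp)) assign(nm, pp[[nm]])
  }
  cfg <- list(
    schema_version = 1L, preset = preset,
    n_sites = n_sites, n_blocks_per_site = n_blocks_per_site,
    n_families = n_families, spacing_x = spacing_x, spacing_y = spacing_y,
    survival = survival, density = density, noise_sd = noise_sd,
    res = res, min_height = min_height,
    max_crown_diameter = max_crown_diameter,
    knn_k = knn_k, knn_power = knn_power,
    cloth_resolution = cloth_resolution, rigidness = rigidness,
    csf_threshold = csf_threshold,
    gam_k = gam_k, h2_coefficient = h2_coefficient, ratios = ratios,
    n_ground_truth = n_ground_truth, seed = as.integer(seed),
    arch = if (is.null(arch)) genetic_architecture() else arch)
  stopifnot(cfg$res > 0, cfg$density > 0, cfg$min_height >= 0,
            all(cfg$ratios > 0), all(cfg$ratios <= 1))
  class(cfg) <- "pipeline_config"
  cfg
}

preset_params <- function(preset) {
  switch(preset,
    # 9-tree smoke fixture: runs the geometry stages in well under a second
    tiny = list(n_sites = 1, n_blocks_per_site = 3, n_families = 3,
                spacing_x = 2, spacing_y = 3, survival = 1,
                density = 100, noise_sd = 0, n_ground_truth = 9),
    # separable crowns, noise-free: apex spacing exceeds the detection
    # window radius so every planted tree must be found
    easy = list(n_sites = 1, n_blocks_per_site = 4, n_families = 20,
                spacing_x = 7, spacing_y = 7, survival = 1,
                density = 100, noise_sd = 0, n_ground_truth = 40,
                arch = genetic_architecture(
                  mean = c(height = 9, dbh = 14, crown_diameter = 2.8),
                  var_family = c(height = 0.3, dbh = 1.2,
                                 crown_diameter = 0.02),
                  var_block = c(height = 0.3, dbh = 1.2,
                                crown_diameter = 0.02),
                  var_residual = c(height = 1.4, dbh = 5.6,
                                   crown_diameter = 0.12))),
    # the full two-site, 20-family, 14-blocks-per-site trial at the lowest
    # emulated flight density, with realistic mortality
    paperlike = list(n_sites = 2, n_blocks_per_site = 14, n_families = 20,
                     spacing_x = 2, spacing_y = 3, survival = 0.92,
                     density = density_presets[["low"]], noise_sd = 0.05,
                     n_ground_truth = 100))
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$arch <- list(mean = as.list(x$arch$mean),
                 var_family = as.list(x$arch$var_family),
                 var_block = as.list(x$arch$var_block),
                 var_residual = as.list(x$arch$var_residual),
                 cor_family = apply(x$arch$cor_family, 1, as.list,
                                    simplify = FALSE))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$schema_version) || x$schema_version != 1L)
    stop("unsupported pipeline config schema: ", path)
  cm <- do.call(rbind, lapply(x$arch$cor_family, function(r)
    unlist(r, use.names = TRUE)))
  rownames(cm) <- colnames(cm)
  arch <- genetic_architecture(mean = unlist(x$arch$mean),
                               var_family = unlist(x$arch$var_family),
                               var_block = unlist(x$arch$var_block),
                               var_residual = unlist(x$arch$var_residual),
                               cor_family = cm)
  pipeline_config(preset = NULL,
    n_sites = x$n_sites, n_blocks_per_site = x$n_blocks_per_site,
    n_families = x$n_families, spacing_x = x$spacing_x,
    spacing_y = x$spacing_y, survival = x$survival, density = x$density,
    noise_sd = x$noise_sd, res = x$res, min_height = x$min_height,
    max_crown_diameter = x$max_crown_diameter, knn_k = x$knn_k,
    knn_power = x$knn_power, cloth_resolution = x$cloth_resolution,
    rigidness = x$rigidness, csf_threshold = x$csf_threshold,
    gam_k = x$gam_k, h2_coefficient = x$h2_coefficient,
    ratios = unlist(x$ratios), n_ground_truth = x$n_ground_truth,
    seed = x$seed, arch = arch)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline from a configuration
#'
#' Simulates the trial, renders one point cloud per site, classifies ground,
#' builds DTM/DSM/CHM, detects and segments trees, matches them to planted
#' positions, fits the DBH model on the ground-truth subset, computes
#' biomass, estimates variance components, heritabilities, genetic
#' correlations and genetic gains, and writes every table plus a
#' machine-readable run manifest to `out_dir`. Identical configuration and
#' seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param write_clouds also write the rendered point clouds as XYZ CSV
#'   (large; default `FALSE`).
#' @return an object of class `canopygain_run`: list with `trees`
#'   (per-tree trait table), `validation`, `genetics`
#'   (a [summarize_genetics()] result), `detection` (per-site counts),
#'   `dbh_model`, `manifest_path`.
#' @export
run_pipeline <- function(config, out_dir, write_clouds = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)

  design <- trial_design(config$n_sites, config$n_blocks_per_site,
                         config$n_families, config$spacing_x,
                         config$spacing_y)
  trees <- stage("synth", simulate_trial(design, config$arch,
                                         seed = config$seed,
                                         survival = config$survival))
  write_true_trees(trees, pth("trees_true.csv"))

  detection <- list(); metrics_all <- list()
  for (s in seq_len(config$n_sites)) {
    ts <- trees[trees$site == s, ]
    syn <- stage("synth", render_point_cloud(
      ts, density = config$density, noise_sd = config$noise_sd,
      seed = config$seed + 1000L + s))
    if (write_clouds) write_xyz(syn$cloud, pth(sprintf("cloud_site%d.csv", s)))

    lab <- stage("terrain", classify_ground(
      syn$cloud, cloth_resolution = config$cloth_resolution,
      rigidness = config$rigidness, threshold = config$csf_threshold))
    ext <- cloud_extent(lab)
    dtm <- stage("terrain", interpolate_dtm(
      lab, res = config$res, k = config$knn_k, power = config$knn_power,
      extent = ext))
    dsm <- stage("terrain", build_dsm(lab, res = config$res, grid = dtm))
    chm <- stage("terrain", build_chm(dsm, dtm))
    write_ascii_grid(dtm, pth(sprintf("dtm_site%d.asc", s)))
    write_ascii_grid(chm, pth(sprintf("chm_site%d.asc", s)))

    tops <- stage("detect", detect_treetops(chm,
                                            min_height = config$min_height))
    segs <- stage("detect", segment_crowns(
      chm, tops, max_crown_diameter = config$max_crown_diameter,
      min_height = config$min_height))
    met <- stage("detect", crown_metrics(segs, chm))
    matched <- stage("detect", suppressMessages(match_treetops(met, ts)))
    utils::write.csv(
      data.frame(tree_id = tops$tree_id, x = tops$x, y = tops$y,
                 height_m = tops$H),
      pth(sprintf("treetops_site%d.csv", s)), row.names = FALSE,
      quote = FALSE)
    write_crowns_geojson(met, pth(sprintf("crowns_site%d.geojson", s)))
    utils::write.csv(
      data.frame(tree_id = matched$planted_id, site = matched$site,
                 block = matched$block, family = matched$family,
                 H_m = matched$H, CA_m2 = matched$CA),
      pth(sprintf("crown_metrics_site%d.csv", s)), row.names = FALSE,
      quote = FALSE)
    detection[[s]] <- data.frame(site = s, planted = nrow(ts),
                                 detected = nrow(tops),
                                 matched = nrow(matched))
    metrics_all[[s]] <- matched
  }
  detection <- do.call(rbind, detection)
  utils::write.csv(detection, pth("detection_counts.csv"),
                   row.names = FALSE, quote = FALSE)

  met <- do.call(rbind, metrics_all)
  # per-tree trait table in field column convention
  tab <- data.frame(tree_id = met$planted_id, site = met$site,
                    block = met$block, family = met$family,
                    UAV_H = met$H, UAV_CA = met$CA)
  truth <- trees[match(tab$tree_id, trees$tree_id), ]
  tab$GT_H <- truth$true_height
  tab$GT_DBH <- truth$true_dbh

  # ground-truth campaign: measure n_ground_truth trees for DBH training
  n_gt <- min(config$n_ground_truth, nrow(tab))
  gt_idx <- with_seed(config$seed + 2000L,
                      sort(sample.int(nrow(tab), n_gt)))
  train <- data.frame(H = tab$UAV_H[gt_idx], CA = tab$UAV_CA[gt_idx],
                      DBH = tab$GT_DBH[gt_idx])
  model <- stage("traits", fit_dbh_model(train, k = config$gam_k))
  save_dbh_model(model, pth("dbh_model.json"))
  tab$PRE_DBH <- stage("traits",
                       suppressWarnings(predict_dbh(model, tab$UAV_H,
                                                    tab$UAV_CA)))
  tab$UAV_AGB <- agb(tab$PRE_DBH, tab$UAV_H)
  tab$UAV_BGB <- bgb(tab$PRE_DBH)
  # ground-truth biomass from measured DBH and height via the same allometry
  tab$GT_AGB <- NA_real_; tab$GT_BGB <- NA_real_
  tab$GT_AGB[gt_idx] <- agb(tab$GT_DBH[gt_idx], tab$GT_H[gt_idx])
  tab$GT_BGB[gt_idx] <- bgb(tab$GT_DBH[gt_idx])
  utils::write.csv(tab, pth("tree_traits.csv"), row.names = FALSE,
                   quote = FALSE)

  val <- stage("traits", {
    g <- tab[gt_idx, ]
    rbind(
      data.frame(quantity = "H",
                 as.data.frame(validate_predictions(g$UAV_H, g$GT_H))),
      data.frame(quantity = "DBH",
                 as.data.frame(validate_predictions(g$PRE_DBH, g$GT_DBH))),
      data.frame(quantity = "AGB",
                 as.data.frame(validate_predictions(g$UAV_AGB, g$GT_AGB))),
      data.frame(quantity = "BGB",
                 as.data.frame(validate_predictions(g$UAV_BGB, g$GT_BGB))))
  })
  utils::write.csv(val, pth("validation.csv"), row.names = FALSE,
                   quote = FALSE)

  # trait means +/- SD per site (summary-table layout)
  tcols <- c("UAV_H", "UAV_CA", "PRE_DBH", "UAV_AGB", "UAV_BGB")
  mt <- do.call(rbind, lapply(tcols, function(tc) {
    a <- aggregate(tab[[tc]], list(site = tab$site),
                   function(v) c(mean = mean(v), sd = stats::sd(v)))
    data.frame(trait = tc, site = a$site, mean = a$x[, "mean"],
               sd = a$x[, "sd"])
  }))
  utils::write.csv(mt, pth("trait_means.csv"), row.names = FALSE,
                   quote = FALSE)

  gen <- stage("genetics", summarize_genetics(
    tab, traits = tcols[tcols != "UAV_CA"], ratios = config$ratios,
    coefficient = config$h2_coefficient))
  write_genetic_summary(gen, pth("genetics"))
  utils::write.csv(
    data.frame(family = rownames(gen$breeding_values),
               gen$breeding_values, check.names = FALSE),
    pth("breeding_values.csv"), row.names = FALSE, quote = FALSE)

  manifest <- list(
    tool = "canopygain",
    version = as.character(utils::packageVersion("canopygain")),
    seed = config$seed,
    config = jsonlite::fromJSON(jsonlite::toJSON(
      unclass(config)[setdiff(names(unclass(config)), "arch")],
      auto_unbox = TRUE, digits = NA)),
    architecture = list(mean = as.list(config$arch$mean),
                        var_family = as.list(config$arch$var_family),
                        var_block = as.list(config$arch$var_block),
                        var_residual = as.list(config$arch$var_residual)),
    outputs = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  structure(list(trees = tab, validation = val, genetics = gen,
                 detection = detection, dbh_model = model,
                 out_dir = out_dir,
                 manifest_path = pth("manifest.json")),
            class = "canopygain_run")
}

#' @export
print.canopygain_run <- function(x, ...) {
  cat("canopygain pipeline run\n")
  cat(sprintf("  detection: %d/%d trees matched\n",
              sum(x$detection$matched), sum(x$detection$planted)))
  cat("  validation (ground-truth subset):\n")
  print(x$validation, row.names = FALSE)
  cat("  pooled heritabilities:\n")
  print(x$genetics$h2[x$genetics$h2$site == "pooled", ], row.names = FALSE)
  cat(sprintf("  artifacts in %s\n", x$out_dir))
  invisible(x)
}

#' Generate a named fixture bundle on disk
#'
#' Presets: `"tiny"` (9 trees, seconds), `"easy"` (80 trees, separable
#' crowns, noise-free) and `"paperlike"` (two sites, 20 families, 560
#' planted trees, survey-density point cloud). Writes the true-tree table,
#' one XYZ CSV cloud per site and the generating configuration; regeneration
#' with the same seed is byte-identical.
#'
#' @param preset `"tiny"`, `"easy"` or `"paperlike"`.
#' @param seed integer seed.
#' @param dir output directory.
#' @return list with `config`, `trees`, and the written `paths`.
#' @export
make_fixtures <- function(preset = c("tiny", "easy", "paperlike"), seed = 1,
                          dir = tempfile("fixtures_")) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- pipeline_config(preset = preset, seed = seed)
  design <- trial_design(cfg$n_sites, cfg$n_blocks_per_site, cfg$n_families,
                         cfg$spacing_x, cfg$spacing_y)
  trees <- simulate_trial(design, cfg$arch, seed = seed,
                          survival = cfg$survival)
  paths <- character()
  p <- file.path(dir, "trees_true.csv")
  write_true_trees(trees, p); paths <- c(paths, p)
  for (s in seq_len(cfg$n_sites)) {
    syn <- render_point_cloud(trees[trees$site == s, ],
                              density = cfg$density,
                              noise_sd = cfg$noise_sd,
                              seed = seed + 1000L + s)
    p <- file.path(dir, sprintf("cloud_site%d.csv", s))
    write_xyz(syn$cloud, p); paths <- c(paths, p)
  }
  p <- file.path(dir, "config.yaml")
  write_pipeline_config(cfg, p); paths <- c(paths, p)
  list(config = cfg, trees = trees, paths = paths)
}
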