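# End-to-end orchestration: simulate (or load) a cohort, preprocess, derive
# the pattern(s) at the final timepoint, run LOOCV, project longitudinally,
# summarize regionally, and write all artifacts.

#' Validate a pipeline configuration
#'
#' @param config Named list (or path to a YAML/JSON file) with fields:
#'   `out` (output directory, required), `seed` (integer, default 1),
#'   `mode` (`"pdsp"`, `"pdmp"` or `"both"`, default `"both"`), `fwhm`
#'   (default 1.6), `training_timepoint` (default `"w9"`),
#'   `predominance_ratio` (default 2), `simulate` (logical; default `TRUE`
#'   when no `images` path is given) plus optional `phantom` sub-list
#'   (generator arguments), or `images`/`mask` paths (with optional `atlas`)
#'   for on-disk data, and optional fixed `C`, `kernel_scale`, `epsilon`.
#' @return The completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("`config` must be a list or a YAML/JSON path",
                             call. = FALSE)
  if (is.null(config$out))
    stop("config field `out` (output directory) is missing", call. = FALSE)
  config$seed <- as.integer(config$seed %||% 1L)
  config$mode <- match.arg(config$mode %||% "both",
                           c("both", "pdsp", "pdmp"))
  config$fwhm <- config$fwhm %||% 1.6
  config$training_timepoint <- config$training_timepoint %||% "w9"
  config$predominance_ratio <- config$predominance_ratio %||% 2
  config$simulate <- config$simulate %||% is.null(config$images)
  if (!config$simulate) {
    for (fld in c("images", "mask")) {
      if (is.null(config[[fld]]))
        stop("config field `", fld, "` is missing", call. = FALSE)
      if (!file.exists(config[[fld]]))
        stop("config field `", fld, "`: path '", config[[fld]],
             "' does not exist", call. = FALSE)
    }
  }
  config
}

#' Run the full pattern-derivation pipeline
#'
#' Executes simulate (or load) -> preprocess -> hyperparameter search and
#' pattern derivation at the final timepoint (classification for the
#' disease-specific pattern, motor-score regression for the motor pattern)
#' -> leave-one-out cross-validation -> longitudinal projection with
#' Wilcoxon tests -> regional weighting tables, and writes every artifact
#' (pattern NIfTI + provenance JSON, score CSV, regional TSVs, summary and
#' manifest JSON) under `config$out`. Deterministic for a fixed seed.
#'
#' @param config See [validate_config()].
#' @return Invisibly, a list with the cohort/feature matrix, fitted
#'   patterns, LOOCV reports, longitudinal results and regional tables.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (config$simulate) {
    ph <- config$phantom %||% list()
    atlas <- build_phantom_atlas(
      grid_dims = ph$grid_dims %||% c(32L, 32L, 32L),
      n_regions = ph$n_regions %||% 15L,
      seed = ph$atlas_seed %||% config$seed,
      voxel_size = ph$voxel_size %||% c(1, 1, 1))
    effects <- ph$region_effects %||%
      default_region_effects(ph$amplitude %||% 0.1)
    truth <- make_ground_truth_pattern(atlas, effects)
    args <- list(atlas = atlas, truth = truth, seed = config$seed)
    for (nm in intersect(names(ph),
                         c("n_pd", "n_control", "timepoints", "schedule",
                           "baseline_mean", "subject_sd", "voxel_noise_sd",
                           "psf_fwhm", "motor_params")))
      args[[nm]] <- ph[[nm]]
    cohort <- do.call(generate_cohort, args)
  } else {
    cohort <- read_cohort(dirname(config$mask))
  }

  fm <- feature_matrix(cohort, fwhm = config$fwhm)
  train_tp <- config$training_timepoint
  modes <- switch(config$mode, both = c("pdsp", "pdmp"),
                  pdsp = "pdsp", pdmp = "pdmp")
  results <- list(cohort = cohort, features = fm, config = config)
  summary_json <- list(seed = config$seed, mode = config$mode,
                       training_timepoint = train_tp)

  for (nm in modes) {
    svm_mode <- if (nm == "pdsp") "classification" else "regression"
    pat <- metabolic_pattern(fm, timepoint = train_tp, mode = svm_mode,
                             C = config$C, kernel_scale = config$kernel_scale,
                             epsilon = config$epsilon, seed = config$seed)
    h <- pat$hyperparameters
    lo <- loocv_pattern(fm, timepoint = train_tp, mode = svm_mode,
                        C = h$C, kernel_scale = h$kernel_scale,
                        epsilon = h$epsilon)
    proj <- longitudinal_projection(pat, fm, loocv = lo)
    results[[nm]] <- list(pattern = pat, loocv = lo, projection = proj)

    # artifacts
    vol <- coef(pat, as_volume = TRUE)
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = pat$voxel_size),
                       file.path(out_dir, paste0(nm, "_pattern.nii.gz")))
    jsonlite::write_json(
      list(mode = svm_mode, timepoint = train_tp, C = h$C,
           kernel_scale = h$kernel_scale, epsilon = h$epsilon,
           sign_flipped = pat$sign_flipped,
           n_components = pat$basis$K,
           reference = proj$reference[c("mu", "sigma", "n")]),
      file.path(out_dir, paste0(nm, "_provenance.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(proj$scores,
                     file.path(out_dir, paste0(nm, "_scores.csv")),
                     row.names = FALSE)
    if (!is.null(cohort$atlas)) {
      utils::write.table(
        region_weighting(pat, cohort$atlas,
                         predominance_ratio = config$predominance_ratio),
        file.path(out_dir, paste0(nm, "_region_weighting.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary_json[[nm]] <- list(
      hyperparameters = list(C = h$C, kernel_scale = h$kernel_scale,
                             epsilon = h$epsilon),
      accuracy_pd = lo$accuracy_pd,
      accuracy_control = lo$accuracy_control,
      wilcoxon = stats::setNames(as.list(proj$tests$p),
                                 proj$tests$timepoint))
  }

  if (length(modes) == 2L && !is.null(cohort$atlas)) {
    utils::write.table(
      pattern_region_correlation(results$pdsp$pattern,
                                 results$pdmp$pattern, cohort$atlas),
      file.path(out_dir, "region_correlation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    sa <- results$pdsp$projection$scores
    sb <- results$pdmp$projection$scores
    key <- paste(sa$subject_id, sa$timepoint)
    m <- match(key, paste(sb$subject_id, sb$timepoint))
    pooled <- vapply(unique(sa$timepoint), function(tp) {
      sel <- sa$timepoint == tp
      score_correlation(sa$z[sel], sb$z[m][sel])
    }, numeric(1))
    summary_json$pdsp_pdmp_score_correlation <- as.list(pooled)
    results$score_correlation <- pooled
  }

  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("mbpattern")),
                   seed = config$seed,
                   config_hash = digest_config(config),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

# stable hash of the configuration (serialization + md5, no extra deps)
digest_config <- function(config) {
  config$out <- NULL
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeBin(serialize(config[order(names(config))], NULL, version = 2L), tf)
  unname(tools::md5sum(tf))
}
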