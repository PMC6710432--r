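# Synthetic longitudinal rat-brain PET phantom: an ellipsoidal "brain"
# parcellated into contiguous regions, a planted regional covariance pattern
# of relative hyper-/hypometabolism, and cylinder-test-like motor scores.

#' Default parcel names of the 15-region phantom atlas
#'
#' Generic rat-brain parcel labels used purely to make the regional output
#' tables readable; the phantom parcels themselves are random contiguous
#' partitions, not anatomy.
#' @export
phantom_region_names <- c(
  "cingulate cortex", "entorhinal cortex", "insular cortex",
  "medial prefrontal cortex", "motor cortex", "orbitofrontal cortex",
  "somatosensory cortex", "visual cortex", "cerebellum", "striatum",
  "thalamus", "hippocampus", "midbrain", "pons", "medulla")

#' Build a synthetic brain atlas and mask
#'
#' An ellipsoidal brain mask is placed in the grid and partitioned into
#' `n_regions` contiguous parcels by nearest-seed-point assignment of the
#' mask voxels (a Voronoi partition restricted to the mask). Deterministic
#' for a fixed seed.
#'
#' @param grid_dims Integer length-3 grid dimensions, each >= 16.
#' @param n_regions Number of parcels, between 2 and 30.
#' @param seed Integer RNG seed.
#' @param voxel_size Voxel edge lengths in mm (default 1 mm isotropic).
#' @param region_names Optional character vector of length `n_regions`;
#'   defaults to [phantom_region_names] when `n_regions == 15`, otherwise
#'   `region_01`, `region_02`, ...
#' @return Object of class `atlas_volume`: list with `labels` (3D integer
#'   array, 0 = background), `label_table` (data frame `region_id`,
#'   `region_name`), `mask` (3D 0/1 array) and `voxel_size`.
#' @export
build_phantom_atlas <- function(grid_dims = c(32L, 32L, 32L),
                                n_regions = 15L, seed = 1L,
                                voxel_size = c(1, 1, 1),
                                region_names = NULL) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 16L))
    stop("`grid_dims` must be three integers >= 16", call. = FALSE)
  if (n_regions < 2L || n_regions > 30L)
    stop("`n_regions` must be between 2 and 30", call. = FALSE)
  centre <- (grid_dims + 1) / 2
  semi <- grid_dims / 2 - 2
  co <- as.matrix(expand.grid(x = seq_len(grid_dims[1L]),
                              y = seq_len(grid_dims[2L]),
                              z = seq_len(grid_dims[3L])))
  r2 <- ((co[, 1L] - centre[1L]) / semi[1L])^2 +
    ((co[, 2L] - centre[2L]) / semi[2L])^2 +
    ((co[, 3L] - centre[3L]) / semi[3L])^2
  inside <- which(r2 <= 1)
  if (length(inside) < n_regions)
    stop(sprintf("mask has %d voxels, fewer than n_regions = %d",
                 length(inside), n_regions), call. = FALSE)
  mask <- array(0L, grid_dims)
  mask[inside] <- 1L
  seeds_idx <- with_seed(seed, sample(inside, n_regions))
  sc <- co[seeds_idx, , drop = FALSE]
  # nearest seed (Euclidean in voxel units); ties resolved to the lowest id
  pts <- co[inside, , drop = FALSE]
  d2 <- outer(rowSums(pts^2), rowSums(sc^2), "+") - 2 * pts %*% t(sc)
  assign_id <- max.col(-d2, ties.method = "first")
  labels <- array(0L, grid_dims)
  labels[inside] <- assign_id
  if (length(unique(assign_id)) < n_regions)
    stop("degenerate partition: some regions are empty", call. = FALSE)
  region_names <- region_names %||%
    (if (n_regions == 15L) phantom_region_names
     else sprintf("region_%02d", seq_len(n_regions)))
  if (length(region_names) != n_regions)
    stop("`region_names` must have length `n_regions`", call. = FALSE)
  structure(list(labels = labels,
                 label_table = data.frame(region_id = seq_len(n_regions),
                                          region_name = region_names,
                                          stringsAsFactors = FALSE),
                 mask = mask, voxel_size = voxel_size),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat(sprintf("phantom atlas: %s grid, %d regions, %d mask voxels\n",
              paste(dim(x$labels), collapse = "x"),
              nrow(x$label_table), sum(x$mask)))
  invisible(x)
}

#' Planted ground-truth pattern from regional effect amplitudes
#'
#' Every voxel of a region receives that region's signed relative amplitude
#' (positive = planted hypermetabolism, negative = hypometabolism); unlisted
#' regions and background get 0.
#'
#' @param atlas An `atlas_volume`.
#' @param region_effects Named numeric vector: names are region ids, values
#'   are signed amplitudes (fractional uptake change at full effect).
#' @return Object of class `truth_pattern`: list with `map` (3D array),
#'   `values` (masked vector in the shared voxel order) and `mask_index`.
#' @export
make_ground_truth_pattern <- function(atlas, region_effects) {
  stopifnot(inherits(atlas, "atlas_volume"))
  map <- array(0, dim(atlas$labels))
  if (length(region_effects)) {
    ids <- as.integer(names(region_effects))
    if (any(is.na(ids)))
      stop("`region_effects` must be named by region id", call. = FALSE)
    unknown <- setdiff(ids, atlas$label_table$region_id)
    if (length(unknown))
      stop("unknown region id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (i in seq_along(ids))
      map[atlas$labels == ids[i]] <- region_effects[[i]]
  }
  mask_index <- which(atlas$mask != 0)
  structure(list(map = map, values = map[mask_index],
                 mask_index = mask_index,
                 region_effects = region_effects),
            class = "truth_pattern")
}

#' Default regional effect amplitudes for the 15-region phantom
#'
#' Mirrors a plausible hyper-/hypometabolic layout: nine regions planted
#' positive, five negative, one (somatosensory cortex) left at zero.
#'
#' @param amplitude Magnitude of the planted relative effect (default 0.1,
#'   i.e. a 10 percent regional uptake change at full expression).
#' @return Named numeric vector of region-id -> amplitude.
#' @export
default_region_effects <- function(amplitude = 0.1) {
  pos <- c(1, 4, 5, 6, 8, 10, 13, 14, 15)   # cortices, striatum, brainstem
  neg <- c(2, 3, 9, 11, 12)                 # entorhinal/insular, cerebellum,
                                            # thalamus, hippocampus
  stats::setNames(c(rep(amplitude, length(pos)),
                    rep(-amplitude, length(neg))),
                  c(pos, neg))
}

#' Default longitudinal effect schedule
#'
#' Per-timepoint multiplier on the planted amplitude: no effect at baseline
#' and week 3, ramp at week 4, near-complete at week 6 and complete/stable at
#' week 9 — the timeline of progressive dopaminergic degeneration the phantom
#' emulates.
#' @return Named numeric vector over `baseline, w3, w4, w6, w9`.
#' @export
default_effect_schedule <- function() {
  c(baseline = 0, w3 = 0, w4 = 0.6, w6 = 0.9, w9 = 1.0)
}

validate_schedule <- function(schedule, timepoints) {
  if (is.null(names(schedule)) || any(!nzchar(names(schedule))))
    stop("`schedule` must be a named vector of timepoint multipliers",
         call. = FALSE)
  miss <- setdiff(timepoints, names(schedule))
  if (length(miss))
    stop("schedule does not cover timepoint(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (schedule[[1L]] != 0)
    stop("schedule must start at 0 (no effect at baseline)", call. = FALSE)
  if (any(diff(schedule) < 0))
    stop("schedule multipliers must be non-decreasing", call. = FALSE)
  if (max(schedule) > 1)
    stop("schedule multipliers must not exceed 1", call. = FALSE)
  schedule[timepoints]
}

#' Generate a synthetic longitudinal PET cohort
#'
#' Simulates one scan per subject per timepoint. A control scan is a
#' subject-scaled uniform uptake within the brain mask plus i.i.d. voxel
#' noise, blurred by the scanner's point-spread function; a patient scan is
#' additionally multiplied voxelwise by `1 + schedule[t] * truth`. Because
#' the downstream preprocessing L2-normalizes every scan, only this relative
#' regional modulation — not the global scale — carries signal, matching a
#' covariance-pattern analysis. Motor scores emulate the cylinder test
#' (percent impaired-forelimb use): symmetric (~50%) controls, and patients
#' declining with the effect schedule.
#'
#' @param atlas An `atlas_volume`.
#' @param truth A `truth_pattern` from [make_ground_truth_pattern()].
#' @param n_pd,n_control Group sizes (default 10 and 8).
#' @param timepoints Timepoint labels (default the five scan sessions).
#' @param schedule Named per-timepoint effect multipliers; see
#'   [default_effect_schedule()].
#' @param baseline_mean Mean masked uptake in arbitrary units (default 100).
#' @param subject_sd SD of the subject-level multiplicative scale
#'   (default 0.1).
#' @param voxel_noise_sd SD of additive i.i.d. voxel noise (default 5).
#' @param psf_fwhm Scanner point-spread FWHM in mm applied to the simulated
#'   images (default 1.35).
#' @param motor_params List with `healthy_mean` (default 50), `slope`
#'   (score drop at full effect, default 30) and `sd` (default 5).
#' @param seed Integer RNG seed; cohorts are bit-identical for equal seeds.
#' @return Object of class `pet_cohort`: list with `images` (named list of
#'   3D arrays), `meta` (data frame: `subject_id`, `group`, `timepoint`,
#'   `motor_score`, `image`), `atlas`, `mask`, `voxel_size`, `truth`,
#'   `schedule`, `params`, `seed`.
#' @export
generate_cohort <- function(atlas, truth, n_pd = 10L, n_control = 8L,
                            timepoints = c("baseline", "w3", "w4", "w6",
                                           "w9"),
                            schedule = default_effect_schedule(),
                            baseline_mean = 100, subject_sd = 0.1,
                            voxel_noise_sd = 5, psf_fwhm = 1.35,
                            motor_params = list(healthy_mean = 50,
                                                slope = 30, sd = 5),
                            seed = 1L) {
  stopifnot(inherits(atlas, "atlas_volume"), inherits(truth, "truth_pattern"))
  if (n_pd < 1L || n_control < 1L)
    stop("`n_pd` and `n_control` must be >= 1", call. = FALSE)
  if (baseline_mean <= 0 || subject_sd <= 0 || voxel_noise_sd <= 0 ||
      psf_fwhm <= 0)
    stop("scale parameters must be positive", call. = FALSE)
  s <- validate_schedule(schedule, timepoints)
  dims <- dim(atlas$labels)
  mask <- atlas$mask != 0
  subjects <- data.frame(
    subject_id = c(sprintf("PD%02d", seq_len(n_pd)),
                   sprintf("HC%02d", seq_len(n_control))),
    group = rep(c("PD", "control"), c(n_pd, n_control)),
    stringsAsFactors = FALSE)
  images <- list()
  meta <- NULL
  with_seed(seed, {
    for (i in seq_len(nrow(subjects))) {
      scale_i <- max(stats::rnorm(1, 0, subject_sd), -0.9)
      is_pd <- subjects$group[i] == "PD"
      for (tp in timepoints) {
        signal <- array(0, dims)
        base <- baseline_mean * (1 + scale_i)
        signal[mask] <- base
        if (is_pd)
          signal[mask] <- signal[mask] * (1 + s[[tp]] * truth$map[mask])
        img <- signal + array(stats::rnorm(prod(dims), 0, voxel_noise_sd),
                              dims)
        img <- smooth_gaussian(img, fwhm = psf_fwhm,
                               voxel_size = atlas$voxel_size)
        key <- paste(subjects$subject_id[i], tp, sep = "_")
        images[[key]] <- img
        motor <- if (is_pd) {
          motor_params$healthy_mean - motor_params$slope * s[[tp]] +
            stats::rnorm(1, 0, motor_params$sd)
        } else {
          motor_params$healthy_mean + stats::rnorm(1, 0, motor_params$sd)
        }
        meta <- rbind(meta, data.frame(
          subject_id = subjects$subject_id[i], group = subjects$group[i],
          timepoint = tp, motor_score = min(max(motor, 0), 100),
          image = key, stringsAsFactors = FALSE))
      }
    }
  })
  structure(list(images = images, meta = meta, atlas = atlas,
                 mask = array(as.numeric(mask), dims),
                 voxel_size = atlas$voxel_size, truth = truth,
                 schedule = s,
                 params = list(n_pd = n_pd, n_control = n_control,
                               baseline_mean = baseline_mean,
                               subject_sd = subject_sd,
                               voxel_noise_sd = voxel_noise_sd,
                               psf_fwhm = psf_fwhm,
                               motor_params = motor_params,
                               timepoints = timepoints),
                 seed = seed),
            class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf("synthetic PET cohort: %d PD + %d control, timepoints %s\n",
              x$params$n_pd, x$params$n_control,
              paste(x$params$timepoints, collapse = ", ")))
  cat(sprintf("  grid %s, %d mask voxels, seed %d\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask != 0),
              x$seed))
  invisible(x)
}

#' Write a cohort to disk (NIfTI volumes + tables)
#'
#' Writes one NIfTI volume per scan, the atlas and mask volumes, the label
#' table (TSV), the subject table (CSV) and a JSON manifest recording the
#' seed and all generator parameters.
#'
#' @param cohort A `pet_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pet_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pix <- cohort$voxel_size
  for (key in names(cohort$images)) {
    RNifti::writeNifti(RNifti::asNifti(cohort$images[[key]],
                                       pixdim = pix),
                       file.path(dir, paste0(key, ".nii.gz")))
  }
  RNifti::writeNifti(RNifti::asNifti(cohort$mask, pixdim = pix),
                     file.path(dir, "mask.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(cohort$atlas$labels * 1.0,
                                     pixdim = pix),
                     file.path(dir, "atlas.nii.gz"))
  utils::write.table(cohort$atlas$label_table,
                     file.path(dir, "atlas_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$meta, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  manifest <- list(seed = cohort$seed, params = cohort$params,
                   schedule = as.list(cohort$schedule),
                   region_effects =
                     as.list(cohort$truth$region_effects %||% list()))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()] (or assembled by hand)
#'
#' Expects `subjects.csv` (columns `subject_id`, `group`, `timepoint`,
#' `motor_score`, `image`), `mask.nii.gz`, optionally `atlas.nii.gz` +
#' `atlas_labels.tsv`, and one NIfTI per `image` entry.
#'
#' @param dir Directory to read.
#' @return A `pet_cohort` (without a ground-truth pattern).
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "subjects.csv"),
                          stringsAsFactors = FALSE)
  mask <- array(as.numeric(RNifti::readNifti(file.path(dir,
                                                       "mask.nii.gz"))),
                dim = dim(RNifti::readNifti(file.path(dir, "mask.nii.gz"))))
  vox <- RNifti::pixdim(RNifti::readNifti(file.path(dir, "mask.nii.gz")))
  images <- list()
  for (key in meta$image) {
    nii <- RNifti::readNifti(file.path(dir, paste0(key, ".nii.gz")))
    images[[key]] <- array(as.numeric(nii), dim = dim(nii))
  }
  atlas <- NULL
  if (file.exists(file.path(dir, "atlas.nii.gz"))) {
    lab_nii <- RNifti::readNifti(file.path(dir, "atlas.nii.gz"))
    labels <- array(as.integer(round(as.numeric(lab_nii))), dim(lab_nii))
    tab <- utils::read.delim(file.path(dir, "atlas_labels.tsv"),
                             stringsAsFactors = FALSE)
    atlas <- structure(list(labels = labels, label_table = tab,
                            mask = mask, voxel_size = vox[seq_len(3)]),
                       class = "atlas_volume")
  }
  structure(list(images = images, meta = meta, atlas = atlas, mask = mask,
                 voxel_size = vox[seq_len(3)], truth = NULL,
                 schedule = NULL,
                 params = list(timepoints = unique(meta$timepoint)),
                 seed = NA_integer_),
            class = "pet_cohort")
}
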