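#' Vectorize a masked 3D volume
#'
#' Extracts the voxels inside a binary mask as a vector using a fixed
#' column-major raster order. The returned index makes the operation
#' invertible via [devectorize()]; the same mask (hence the same order) must
#' be used for every scan and pattern in one analysis.
#'
#' @param image 3D numeric array.
#' @param mask 3D array of the same dimensions; voxels with nonzero mask value
#'   are retained.
#' @return List with `values` (numeric vector of length `D`), `mask_index`
#'   (integer linear indices into the array) and `dim`.
#' @export
vectorize_image <- function(image, mask) {
  stop_if_not_dim3(image); stop_if_not_dim3(mask, "mask")
  if (!identical(dim(image), dim(mask)))
    stop("`image` and `mask` dimensions differ", call. = FALSE)
  idx <- which(mask != 0)
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  list(values = as.numeric(image[idx]), mask_index = idx, dim = dim(image))
}

#' Restore a masked vector to a 3D volume
#'
#' @param values Numeric vector of masked voxel values.
#' @param mask_index Integer linear indices as produced by [vectorize_image()].
#' @param dim Integer length-3 array dimensions.
#' @param fill Value for voxels outside the mask (default 0).
#' @return 3D numeric array.
#' @export
devectorize <- function(values, mask_index, dim, fill = 0) {
  if (length(values) != length(mask_index))
    stop("`values` and `mask_index` lengths differ", call. = FALSE)
  out <- array(fill, dim)
  out[mask_index] <- values
  out
}

#' Demean and L2-normalize a masked intensity vector
#'
#' Produces the analysis-ready feature vector: the spatial mean over masked
#' voxels is subtracted and the result is divided by its L2 norm, so the
#' output has zero mean and unit sum of squares. Multiplying the input by any
#' positive constant leaves the output unchanged, which removes global-scale
#' (e.g. injected-dose) differences between scans.
#'
#' @param raw Numeric vector of masked voxel intensities (length >= 2).
#' @return Numeric vector with `sum(x) == 0` and `sum(x^2) == 1`.
#' @export
normalize_feature <- function(raw) {
  if (length(raw) < 2L) stop("feature vector needs length >= 2", call. = FALSE)
  if (any(!is.finite(raw))) stop("non-finite voxel intensities", call. = FALSE)
  centred <- raw - mean(raw)
  nrm <- sqrt(sum(centred^2))
  if (nrm < 1e-12 * max(1, sqrt(sum(raw^2))) || nrm == 0)
    stop("degenerate scan: zero variance over masked voxels", call. = FALSE)
  centred / nrm
}

#' Build the analysis data matrix from a set of co-registered scans
#'
#' Applies the preprocessing chain smooth -> mask -> vectorize -> demean ->
#' L2-normalize to every scan and stacks the resulting feature vectors as
#' rows, with subject metadata carried alongside. Rows are ordered by
#' (group, subject id, timepoint).
#'
#' @param x A `pet_cohort` (see [generate_cohort()]) or a named list of 3D
#'   arrays keyed by the `image` column of `meta`.
#' @param meta Data frame with columns `subject_id`, `group`, `timepoint`,
#'   `image` and optionally `motor_score`; ignored (taken from the cohort)
#'   when `x` is a `pet_cohort`.
#' @param mask 3D binary array; ignored for a `pet_cohort`.
#' @param fwhm Smoothing kernel FWHM in mm (default 1.6).
#' @param voxel_size Voxel edge lengths in mm.
#' @return Object of class `feature_matrix`: list with `X` (N x D matrix whose
#'   rows are feature vectors), `meta`, `mask_index`, `dim`, `voxel_size`,
#'   `fwhm`.
#' @export
feature_matrix <- function(x, meta = NULL, mask = NULL, fwhm = 1.6,
                           voxel_size = NULL) {
  if (inherits(x, "pet_cohort")) {
    images <- x$images
    meta <- x$meta
    mask <- x$mask
    voxel_size <- voxel_size %||% x$voxel_size
  } else {
    images <- x
  }
  voxel_size <- voxel_size %||% c(1, 1, 1)
  if (is.null(meta) || is.null(mask))
    stop("`meta` and `mask` are required unless `x` is a pet_cohort",
         call. = FALSE)
  req <- c("subject_id", "group", "timepoint", "image")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("`meta` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta <- meta[order(meta$group, meta$subject_id, meta$timepoint), ,
               drop = FALSE]
  rownames(meta) <- NULL
  ref <- vectorize_image(array(0, dim(mask)), mask)
  D <- length(ref$mask_index)
  X <- matrix(NA_real_, nrow(meta), D)
  for (i in seq_len(nrow(meta))) {
    img <- images[[meta$image[i]]]
    if (is.null(img))
      stop("image '", meta$image[i], "' not found", call. = FALSE)
    stop_if_not_dim3(img)
    if (!identical(dim(img), dim(mask)))
      stop("scan '", meta$image[i], "' dimensions do not match the mask",
           call. = FALSE)
    sm <- smooth_gaussian(img, fwhm = fwhm, voxel_size = voxel_size)
    X[i, ] <- normalize_feature(sm[ref$mask_index])
  }
  structure(list(X = X, meta = meta, mask_index = ref$mask_index,
                 dim = dim(mask), voxel_size = voxel_size, fwhm = fwhm),
            class = "feature_matrix")
}

#' Subset a feature matrix by timepoint (or arbitrary row filter)
#'
#' @param x A `feature_matrix`.
#' @param timepoint Timepoint label(s) to retain; `NULL` keeps all rows.
#' @param rows Optional logical or integer row selector applied after
#'   `timepoint`.
#' @return A `feature_matrix` with the selected rows.
#' @export
subset_rows <- function(x, timepoint = NULL, rows = NULL) {
  stopifnot(inherits(x, "feature_matrix"))
  keep <- rep(TRUE, nrow(x$meta))
  if (!is.null(timepoint)) keep <- keep & x$meta$timepoint %in% timepoint
  keep <- which(keep)
  if (!is.null(rows)) keep <- keep[rows]
  out <- x
  out$X <- x$X[keep, , drop = FALSE]
  out$meta <- x$meta[keep, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d scans x %d masked voxels (grid %s)\n",
              nrow(x$X), ncol(x$X), paste(x$dim, collapse = "x")))
  cat(sprintf("  groups: %s; timepoints: %s; smoothing FWHM %.3g mm\n",
              paste(names(table(x$meta$group)), table(x$meta$group),
                    sep = "=", collapse = ", "),
              paste(unique(x$meta$timepoint), collapse = ", "), x$fwhm))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$X)
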