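#' Regional positive/negative weighting of a pattern
#'
#' Summarizes a voxel-weight pattern over atlas regions. For region r,
#' `pos_pct = 100 * sum(p[v in r & p > 0]) / sum(|p|)` and
#' `neg_pct = 100 * sum(|p[v in r & p < 0]|) / sum(|p|)` — percentages of the
#' whole-pattern absolute weight, so summed over a full-coverage atlas the
#' two columns total 100. A region is called predominantly positive (`"+"`,
#' relative hypermetabolism) when `pos_pct >= ratio * neg_pct`, predominantly
#' negative (`"-"`) in the mirrored case, and mixed (`"/"`) otherwise.
#'
#' @param pattern A `metabolic_pattern` or a numeric voxel-weight vector in
#'   the atlas's masked-voxel order.
#' @param atlas An `atlas_volume` aligned to the pattern mask.
#' @param predominance_ratio Threshold ratio of the dominant to the
#'   subordinate weighting mass (default 2).
#' @return Data frame with `region_id`, `region_name`, `pos_pct`, `neg_pct`,
#'   `predominance`.
#' @export
region_weighting <- function(pattern, atlas, predominance_ratio = 2) {
  stopifnot(inherits(atlas, "atlas_volume"), predominance_ratio >= 1)
  p <- pattern_values(pattern, atlas)
  total <- sum(abs(p))
  if (total == 0) stop("all-zero pattern", call. = FALSE)
  lab <- atlas$labels[atlas$mask != 0]
  tab <- atlas$label_table
  out <- data.frame(region_id = tab$region_id,
                    region_name = tab$region_name,
                    pos_pct = NA_real_, neg_pct = NA_real_,
                    predominance = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    v <- p[lab == tab$region_id[i]]
    if (!length(v)) {
      warning("region ", tab$region_id[i], " is empty", call. = FALSE)
      out$pos_pct[i] <- 0; out$neg_pct[i] <- 0; out$predominance[i] <- "/"
      next
    }
    pos <- 100 * sum(v[v > 0]) / total
    neg <- 100 * sum(-v[v < 0]) / total
    out$pos_pct[i] <- pos
    out$neg_pct[i] <- neg
    out$predominance[i] <-
      if (pos == 0 && neg == 0) "/"
      else if (pos >= predominance_ratio * neg) "+"
      else if (neg >= predominance_ratio * pos) "-"
      else "/"
  }
  out
}

pattern_values <- function(pattern, atlas) {
  if (inherits(pattern, "metabolic_pattern")) {
    idx <- which(atlas$mask != 0)
    if (!identical(idx, pattern$mask_index))
      stop("atlas mask does not match the pattern mask", call. = FALSE)
    pattern$pattern
  } else {
    p <- as.numeric(pattern)
    if (length(p) != sum(atlas$mask != 0))
      stop("pattern length does not match the atlas mask", call. = FALSE)
    p
  }
}

#' Region-wise Pearson correlation between two patterns
#'
#' For each atlas region, the Pearson correlation of the two patterns' voxel
#' weights restricted to that region. Regions with fewer than `min_voxels`
#' voxels or zero variance in either pattern are reported as `NA`.
#'
#' @param p1,p2 `metabolic_pattern`s (or weight vectors) on the same mask.
#' @param atlas An `atlas_volume` aligned to the shared mask.
#' @param min_voxels Minimum region size (default 3).
#' @return Data frame with `region_id`, `region_name`, `n_voxels`, `r`.
#' @export
pattern_region_correlation <- function(p1, p2, atlas, min_voxels = 3L) {
  stopifnot(inherits(atlas, "atlas_volume"))
  v1 <- pattern_values(p1, atlas)
  v2 <- pattern_values(p2, atlas)
  lab <- atlas$labels[atlas$mask != 0]
  tab <- atlas$label_table
  out <- data.frame(region_id = tab$region_id,
                    region_name = tab$region_name,
                    n_voxels = NA_integer_, r = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    sel <- lab == tab$region_id[i]
    out$n_voxels[i] <- sum(sel)
    if (sum(sel) < min_voxels) next
    a <- v1[sel]; b <- v2[sel]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    out$r[i] <- stats::cor(a, b)
  }
  out
}

#' Pearson correlation between two aligned sets of expression scores
#'
#' Intended for pooled (patients and controls combined) scores of two
#' patterns over the same scans; affine-invariant, so raw scores and
#' Z-values give the same value.
#'
#' @param scores_a,scores_b Numeric score vectors over the same scans, in
#'   the same order.
#' @return Pearson correlation coefficient.
#' @export
score_correlation <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors differ in length", call. = FALSE)
  if (length(scores_a) < 3L)
    stop("need at least 3 score pairs", call. = FALSE)
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0)
    stop("zero variance in scores", call. = FALSE)
  stats::cor(scores_a, scores_b)
}
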