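# The image core: atlas-based refinement of vessel segmentations,
# topology-preserving 3-D thinning, exact anisotropic Euclidean distance
# transform, per-centerline-voxel radii, and the regional measurements.

#' Refine a vessel segmentation with a probabilistic atlas
#'
#' Removes every segmented voxel whose occurrence probability in the
#' probabilistic cerebrovascular atlas is strictly below `threshold`
#' (default 1%), cleaning noise-related over-segmentation. Nothing is ever
#' added: the operation is anti-extensive and idempotent. Voxels at exactly
#' the threshold survive.
#'
#' @param mask a [binary_volume()] vessel segmentation.
#' @param atlas a [probability_volume()] on the same grid.
#' @param threshold removal cut as a fraction (default 0.01).
#' @return A refined [binary_volume()].
#' @export
refine_segmentation <- function(mask, atlas, threshold = 0.01) {
  if (!inherits(mask, "binary_volume")) stop("`mask` must be a binary_volume")
  if (!inherits(atlas, "probability_volume"))
    stop("`atlas` must be a probability_volume")
  if (!same_grid(mask$grid, atlas$grid))
    stop_grid_mismatch(mask$grid, atlas$grid, "mask and atlas")
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  out <- mask$data
  out[atlas$data < threshold] <- 0L
  binary_volume(out, mask$grid)
}

#' Extract vessel centerlines by 3-D thinning
#'
#' Iterative topology-preserving thinning (26-connected foreground,
#' 6-connected background): in each iteration, border voxels from six
#' directional sub-passes are deleted only if they are simple points (local
#' foreground/background connectivity — and hence the Euler characteristic —
#' is preserved) and not line endpoints; deletion inside a sub-pass is
#' sequential with re-checking. Terminates when a full pass deletes nothing.
#' The result is a one-voxel-thin skeleton, a subset of the input
#' foreground, with the same number of 26-connected components. Thinning is
#' combinatorial and ignores anisotropic spacing; the radii attached later
#' are metric.
#'
#' @param mask a [binary_volume()]. An empty mask yields an empty
#'   centerline set.
#' @return A [centerline_set()] with radii unset (fill with
#'   [centerline_radii()]).
#' @export
skeletonize3d <- function(mask) {
  if (!inherits(mask, "binary_volume")) stop("`mask` must be a binary_volume")
  thin <- .thin_cpp(as.integer(mask$data), mask$grid$shape)
  idx <- which(array(thin, dim = mask$grid$shape) == 1L)
  centerline_set(arrayInd(idx, mask$grid$shape), mask$grid)
}

#' Exact anisotropic Euclidean distance transform
#'
#' For every foreground voxel, the exact Euclidean distance (mm, respecting
#' the anisotropic voxel spacing) to the nearest background voxel center;
#' background voxels map to 0. Computed with a separable lower-envelope
#' algorithm on squared distances, so the result is exact, not chamfer
#' approximated.
#'
#' @param mask a [binary_volume()] with at least one background voxel.
#' @return A 3-D numeric array of distances in mm, same shape as the mask.
#' @export
distance_transform <- function(mask) {
  if (!inherits(mask, "binary_volume")) stop("`mask` must be a binary_volume")
  if (all(mask$data == 1L))
    stop("all-foreground volume: no boundary exists to measure distance to")
  d <- .edt_cpp(as.integer(mask$data), mask$grid$shape, mask$grid$spacing)
  array(d, dim = mask$grid$shape)
}

#' Attach radii to centerline voxels
#'
#' The local vessel radius at each centerline voxel is the distance-map
#' value there: the distance to the nearest vessel boundary. No half-voxel
#' correction is applied; the voxel-center convention is documented and the
#' recovery tolerances account for it.
#'
#' @param centerline a [centerline_set()] from [skeletonize3d()].
#' @param dist distance array from [distance_transform()] of the same mask.
#' @return The centerline set with `radius_mm` filled.
#' @export
centerline_radii <- function(centerline, dist) {
  if (!inherits(centerline, "centerline_set"))
    stop("`centerline` must be a centerline_set")
  if (!identical(as.integer(dim(dist)), centerline$grid$shape))
    stop("distance map shape does not match the centerline grid")
  if (nrow(centerline$voxels) == 0) return(centerline)
  r <- dist[centerline_linear_index(centerline)]
  if (any(r <= 0))
    stop("centerline voxel with zero distance: centerline and distance map ",
         "come from inconsistent masks")
  centerline$radius_mm <- r
  centerline
}

label_id <- function(region, label) {
  if (is.character(label)) {
    if (!label %in% names(region$label_names))
      stop(sprintf("unknown region name '%s'", label))
    region$label_names[[label]]
  } else as.integer(label)
}

#' Artery density within a flow territory
#'
#' 100 x (segmented vessel voxels inside the territory) / (territory
#' voxels). The full segmentation volume is used, not the centerline.
#'
#' @param mask refined [binary_volume()] segmentation.
#' @param territories [label_volume()] of flow territories on the same grid.
#' @param label territory label (integer) or name.
#' @return Density in percent.
#' @export
territory_density <- function(mask, territories, label) {
  if (!same_grid(mask$grid, territories$grid))
    stop_grid_mismatch(mask$grid, territories$grid, "mask and territories")
  id <- label_id(territories, label)
  sel <- territories$data == id
  n_ter <- sum(sel)
  if (n_ter == 0) stop(sprintf("territory label %s is empty", label))
  100 * sum(mask$data[sel]) / n_ter
}

#' Mean centerline radius within a region
#'
#' Arithmetic mean of the per-centerline-voxel radii falling inside the
#' labelled region. Only centerline voxels enter the average, so large
#' arteries do not bias it through their cross-sectional bulk. A region
#' containing no centerline voxel yields `NA` (a logged missing value,
#' never a silent 0).
#'
#' @param centerline a radius-filled [centerline_set()].
#' @param region a [label_volume()] (flow territory or small artery mask).
#' @param label region label (integer) or name.
#' @return Mean radius in mm, or `NA_real_`.
#' @export
territory_mean_radius <- function(centerline, region, label) {
  if (!inherits(centerline, "centerline_set"))
    stop("`centerline` must be a centerline_set")
  if (!same_grid(centerline$grid, region$grid))
    stop_grid_mismatch(centerline$grid, region$grid, "centerline and region")
  if (all(is.na(centerline$radius_mm)) && nrow(centerline$voxels) > 0)
    stop("centerline radii are unset; run centerline_radii() first")
  id <- label_id(region, label)
  if (!any(region$data == id)) stop(sprintf("region label %s is empty", label))
  if (nrow(centerline$voxels) == 0) return(NA_real_)
  inlab <- region$data[centerline_linear_index(centerline)] == id
  if (!any(inlab)) {
    message(sprintf("no centerline voxels in region %s: recording NA", label))
    return(NA_real_)
  }
  mean(centerline$radius_mm[inlab])
}

#' @rdname territory_mean_radius
#' @export
artery_mean_radius <- territory_mean_radius

#' Intracranial volume from a mask
#'
#' Foreground voxel count times the voxel volume, in cm^3.
#'
#' @param icv_mask a [binary_volume()] intracranial mask (nonempty).
#' @return Volume in cm^3.
#' @export
intracranial_volume <- function(icv_mask) {
  if (!inherits(icv_mask, "binary_volume"))
    stop("`icv_mask` must be a binary_volume")
  n <- sum(icv_mask$data)
  if (n == 0) stop("empty intracranial mask")
  n * voxel_volume_mm3(icv_mask$grid) / 1000
}

#' Run the full regional morphometry on one subject
#'
#' Pipeline: atlas refinement of the segmentation, centerline extraction by
#' thinning, anisotropic distance transform, per-centerline radii, then the
#' 24 regional measurements (6 territory densities, 6 territory mean radii,
#' 12 artery-mask mean radii) and the intracranial volume. Territory labels
#' sharing a name after stripping a trailing `_proximal` / `_middle` /
#' `_distal` suffix are unioned before measurement. Deterministic.
#'
#' @param mask raw [binary_volume()] vessel segmentation.
#' @param atlas [probability_volume()] vessel atlas.
#' @param territories [label_volume()] of flow territories (6 after union).
#' @param artery_masks [label_volume()] of 12 small artery masks.
#' @param icv_mask [binary_volume()] intracranial mask.
#' @param threshold atlas refinement cut (fraction, default 0.01).
#' @return A one-row data.frame of class `regional_measurements` with the
#'   24 measurement columns ([measurement_names()]), `icv_cm3`, and a
#'   `qc_empty_refined` flag set when refinement removed every voxel (all
#'   measurements are then NA).
#' @export
extract_measurements <- function(mask, atlas, territories, artery_masks,
                                 icv_mask, threshold = 0.01) {
  for (v in list(atlas, territories, artery_masks, icv_mask))
    if (!same_grid(mask$grid, v$grid))
      stop_grid_mismatch(mask$grid, v$grid, "subject volumes")
  territories <- merge_territory_labels(territories)

  refined <- refine_segmentation(mask, atlas, threshold)
  mn <- measurement_names("all")
  out <- as.data.frame(as.list(setNames(rep(NA_real_, length(mn)), mn)))
  out$icv_cm3 <- intracranial_volume(icv_mask)
  out$qc_empty_refined <- FALSE
  if (sum(refined$data) == 0) {
    out$qc_empty_refined <- TRUE
    class(out) <- c("regional_measurements", class(out))
    return(out)
  }

  cl <- tryCatch(skeletonize3d(refined),
                 error = function(e) stop("skeletonization stage: ",
                                          conditionMessage(e)))
  dist <- tryCatch(distance_transform(refined),
                   error = function(e) stop("distance-transform stage: ",
                                            conditionMessage(e)))
  cl <- tryCatch(centerline_radii(cl, dist),
                 error = function(e) stop("radius stage: ",
                                          conditionMessage(e)))

  # a named region carrying no voxels in this subject (e.g. clipped by
  # registration) yields a missing measurement, not a failed subject
  soft_na <- function(expr, what) {
    tryCatch(suppressMessages(expr), error = function(e) {
      message(sprintf("%s: %s -> recording NA", what, conditionMessage(e)))
      NA_real_
    })
  }
  ter_map <- c(territory_ACA_L = "ACA_L", territory_ACA_R = "ACA_R",
               territory_MCA_L = "MCA_L", territory_MCA_R = "MCA_R",
               territory_PCA_L = "PCA_L", territory_PCA_R = "PCA_R")
  for (tn in names(ter_map)) {
    if (!tn %in% names(territories$label_names)) next
    out[[paste0("density_", ter_map[[tn]])]] <-
      soft_na(territory_density(refined, territories, tn), tn)
    out[[paste0("tradius_", ter_map[[tn]])]] <-
      soft_na(territory_mean_radius(cl, territories, tn), tn)
  }
  for (an in names(artery_masks$label_names)) {
    col <- paste0("aradius_", sub("^artery_", "", an))
    if (!col %in% mn) next
    out[[col]] <- soft_na(artery_mean_radius(cl, artery_masks, an), an)
  }
  class(out) <- c("regional_measurements", class(out))
  out
}

# union proximal/middle/distal sub-territories into single territory labels
merge_territory_labels <- function(territories) {
  nm <- names(territories$label_names)
  base <- sub("_(proximal|middle|distal)$", "", nm)
  if (identical(base, nm)) return(territories)
  ub <- unique(base)
  new_ids <- setNames(seq_along(ub), ub)
  dat <- array(0L, dim = territories$grid$shape)
  for (i in seq_along(nm)) {
    old <- territories$label_names[[i]]
    dat[territories$data == old] <- new_ids[[base[i]]]
  }
  label_volume(dat, territories$grid, new_ids)
}
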