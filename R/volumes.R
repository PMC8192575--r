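#' Voxel grid geometry
#'
#' A `grid_spec` describes the voxel lattice all volumes of one subject
#' share: the array dimensions and the physical voxel spacing in mm.
#' World coordinates of a voxel center are `(index - 1) * spacing + origin`
#' (1-based indices).
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel along each axis
#'   (all > 0). A scalar is recycled to an isotropic grid.
#' @param origin world position (mm) of the center of voxel (1,1,1).
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(c(64, 64, 40), spacing = 0.7)
#' @export
grid_spec <- function(shape, spacing = 1, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 integers >= 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive reals (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_grid_mismatch <- function(a, b, what) {
  stop(sprintf(
    "%s are not on the same grid: %s @ (%s) mm vs %s @ (%s) mm",
    what,
    paste(a$shape, collapse = "x"), paste(signif(a$spacing, 4), collapse = ", "),
    paste(b$shape, collapse = "x"), paste(signif(b$spacing, 4), collapse = ", ")))
}

new_volume <- function(data, grid, class) {
  if (!inherits(grid, "grid_spec")) stop("`grid` must be a grid_spec")
  data <- as.array(data)
  if (!identical(as.integer(dim(data)), grid$shape))
    stop(sprintf("data dim (%s) does not match grid shape (%s)",
                 paste(dim(data), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  structure(list(data = data, grid = grid), class = c(class, "vessel_volume"))
}

#' Binary, probability and label volumes
#'
#' Thin S3 containers pairing a 3-D array with its [grid_spec()].
#' `binary_volume` holds a segmentation mask in \{0,1\}; `probability_volume`
#' holds per-voxel occurrence probabilities in \[0,1\] (e.g. a probabilistic
#' cerebrovascular atlas); `label_volume` holds non-negative integer region
#' labels (0 = background) with a name per label, e.g. flow territories or
#' small main-artery masks.
#'
#' @param data 3-D array with dimensions matching `grid$shape`.
#' @param grid a [grid_spec()].
#' @param label_names named integer vector mapping region names to labels
#'   (label_volume only); every nonzero label present in `data` must be named.
#' @return An object of class `binary_volume`, `probability_volume` or
#'   `label_volume`.
#' @export
binary_volume <- function(data, grid) {
  storage.mode(data) <- "integer"
  if (any(is.na(data)) || any(data != 0L & data != 1L))
    stop("binary volume data must be 0/1")
  new_volume(data, grid, "binary_volume")
}

#' @rdname binary_volume
#' @export
probability_volume <- function(data, grid) {
  storage.mode(data) <- "double"
  if (any(is.na(data)) || any(data < 0 | data > 1))
    stop("probability volume data must lie in [0, 1]")
  new_volume(data, grid, "probability_volume")
}

#' @rdname binary_volume
#' @export
label_volume <- function(data, grid, label_names) {
  storage.mode(data) <- "integer"
  if (any(is.na(data)) || any(data < 0L))
    stop("label volume data must be non-negative integers")
  labs <- sort(unique(data[data > 0L]))
  if (missing(label_names))
    label_names <- setNames(labs, paste0("region_", labs))
  if (is.null(names(label_names)) || any(names(label_names) == ""))
    stop("`label_names` must be a named integer vector")
  if (!all(labs %in% label_names))
    stop(sprintf("unnamed labels present in data: %s",
                 paste(setdiff(labs, label_names), collapse = ", ")))
  v <- new_volume(data, grid, "label_volume")
  v$label_names <- label_names
  v
}

#' @export
print.vessel_volume <- function(x, ...) {
  cat(sprintf("<%s> ", class(x)[1]))
  print(x$grid)
  if (inherits(x, "binary_volume"))
    cat(sprintf("  foreground voxels: %d\n", sum(x$data)))
  if (!is.null(x$label_names))
    cat(sprintf("  labels: %s\n",
                paste(sprintf("%s=%d", names(x$label_names), x$label_names),
                      collapse = ", ")))
  invisible(x)
}

voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' Read and write volumes as NIfTI
#'
#' Volumes round-trip through NIfTI-1 with the voxel spacing in the pixdim
#' header fields. On read, any rotational part of the stored affine is
#' ignored with a warning (all inputs are assumed co-registered in subject
#' space); the translation is kept as the grid origin.
#'
#' @param vol a volume object ([binary_volume()] family).
#' @param path file path, conventionally `.nii.gz`.
#' @param kind one of "binary", "probability", "label": the volume class to
#'   construct on read.
#' @param label_names passed to [label_volume()] when `kind = "label"`.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   volume object.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data, internal = FALSE)
  RNifti::pixdim(img) <- vol$grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, kind = c("binary", "probability", "label"),
                        label_names) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  aff <- try(RNifti::xform(img), silent = TRUE)
  origin <- c(0, 0, 0)
  if (!inherits(aff, "try-error") && is.matrix(aff)) {
    rot <- aff[1:3, 1:3]
    if (max(abs(abs(rot) - diag(abs(diag(rot)))) ) > 1e-4)
      warning("NIfTI affine has a rotational part; ignoring rotation, ",
              "keeping spacing and translation only")
    origin <- aff[1:3, 4]
  }
  g <- grid_spec(dim(img)[1:3], spacing, origin)
  arr <- array(as.vector(img), dim = g$shape)
  switch(kind,
    binary = binary_volume(arr != 0, g),
    probability = probability_volume(arr, g),
    label = if (missing(label_names)) label_volume(round(arr), g)
            else label_volume(round(arr), g, label_names))
}

#' Centerline voxels with per-voxel radii
#'
#' The product of skeletonization plus radius lookup: a matrix of 1-based
#' voxel indices that lie on the one-voxel-thin vessel centerline, and for
#' each one the local vessel radius in mm (NA until filled by
#' [centerline_radii()]).
#'
#' @param voxels n x 3 integer matrix of 1-based voxel indices.
#' @param grid the [grid_spec()] the indices refer to.
#' @param radius_mm numeric vector of per-voxel radii in mm, or NA.
#' @return An object of class `centerline_set`.
#' @export
centerline_set <- function(voxels, grid, radius_mm = rep(NA_real_, nrow(voxels))) {
  voxels <- matrix(as.integer(voxels), ncol = 3,
                   dimnames = list(NULL, c("i", "j", "k")))
  if (anyDuplicated(voxels)) stop("duplicate centerline voxels")
  if (nrow(voxels) > 0 &&
      (any(voxels < 1L) || any(t(voxels) > grid$shape)))
    stop("centerline voxel indices outside the grid")
  if (length(radius_mm) != nrow(voxels))
    stop("radius_mm length must match the number of voxels")
  structure(list(voxels = voxels, grid = grid,
                 radius_mm = as.numeric(radius_mm)),
            class = "centerline_set")
}

#' @export
print.centerline_set <- function(x, ...) {
  cat(sprintf("<centerline_set> %d voxels", nrow(x$voxels)))
  if (!all(is.na(x$radius_mm)))
    cat(sprintf(", radius %.3g-%.3g mm",
                min(x$radius_mm, na.rm = TRUE), max(x$radius_mm, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @export
length.centerline_set <- function(x) nrow(x$voxels)

# linear (column-major) indices of centerline voxels in the grid array
centerline_linear_index <- function(cl) {
  v <- cl$voxels
  s <- cl$grid$shape
  (v[, 3] - 1L) * s[1] * s[2] + (v[, 2] - 1L) * s[1] + v[, 1]
}
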