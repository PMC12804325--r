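#' Define a voxel grid
#'
#' A `grid_spec` fixes the voxel lattice on which phantoms are rasterized:
#' the number of voxels per axis and the physical voxel spacing in mm.
#' Voxel centres are indexed from 0 and placed symmetrically about the grid
#' centre, so voxel `i` along an axis with `n` voxels and spacing `s` sits
#' at physical position `(i - (n - 1) / 2) * s` mm. Phantom solids are
#' centred at the origin of this coordinate system.
#'
#' @param shape integer vector of length 3; voxels along x, y, z (all >= 1)
#' @param spacing numeric vector of length 3; mm per voxel (all > 0).
#'   A scalar is recycled.
#' @return an object of class `grid_spec` with fields `shape` and `spacing`
#' @examples
#' g <- grid_spec(c(80, 80, 80), 1)
#' @export
grid_spec <- function(shape, spacing = 1) {
  shape <- as.integer(rep_len(shape, 3L))
  spacing <- as.numeric(rep_len(spacing, 3L))
  if (any(is.na(shape)) || any(shape < 1L))
    stop("grid shape entries must be integers >= 1", call. = FALSE)
  if (any(is.na(spacing)) || any(spacing <= 0))
    stop("grid spacing entries must be > 0", call. = FALSE)
  structure(list(shape = shape, spacing = spacing), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# physical voxel-centre coordinates (mm, grid-centred) along each axis
grid_axes <- function(grid) {
  lapply(1:3, function(a) {
    n <- grid$shape[a]
    (seq_len(n) - 1 - (n - 1) / 2) * grid$spacing[a]
  })
}

# physical half-extent of the grid per axis (mm from centre to last voxel centre)
grid_half_extent <- function(grid) (grid$shape - 1) / 2 * grid$spacing

#' Default simulation grid
#'
#' An 80 x 80 x 80 voxel grid at 1 mm isotropic spacing: large enough for a
#' 30-mm tumor with a 10-mm margin plus registration excursions of several
#' standard deviations and padding.
#'
#' @return a [grid_spec()]
#' @export
default_grid <- function() grid_spec(c(80L, 80L, 80L), 1)

#' Check that a grid can hold the largest phantom a parameter set can draw
#'
#' The grid must cover the maximum tumor diameter plus twice the maximum
#' margin, two two-sigma registration excursions, and 10 mm padding;
#' rarer, larger excursions are handled by the per-case redraw logic.
#'
#' @param grid a [grid_spec()]
#' @param params a [sim_params()] object
#' @return `TRUE` invisibly; errors if the grid is too small
#' @export
assert_grid_fits <- function(grid, params) {
  need <- max(params$tumor_range_mm) + 2 * max(0, max(params$margin_range_mm)) +
    2 * 2 * params$registration_sd_mm + 10
  ext <- grid$shape * grid$spacing
  if (min(ext) < need)
    stop(sprintf(
      "grid extent %.0f mm too small: need >= %.0f mm per axis for these parameters",
      min(ext), need), call. = FALSE)
  invisible(TRUE)
}

#' Construct a binary volume mask
#'
#' A `volume_mask` couples a logical voxel array with its [grid_spec()] and
#' a role label. Masks produced by the phantom generator additionally carry
#' the analytic solids (`geom`: one row per ellipsoid, columns
#' `cx, cy, cz, ax, ay, az` in mm) so that rigid translations can be
#' realized by re-rasterization at sub-voxel precision; operations that
#' destroy the analytic description drop it.
#'
#' @param voxels logical 3D array matching `grid$shape`
#' @param grid a [grid_spec()]
#' @param label one of `"tumor_true"`, `"tumor_imaged"`, `"ablation_true"`,
#'   `"ablation_imaged"`
#' @param geom optional numeric matrix of analytic solids (see Details)
#' @return an object of class `volume_mask`
#' @export
volume_mask <- function(voxels, grid,
                        label = c("tumor_true", "tumor_imaged",
                                  "ablation_true", "ablation_imaged"),
                        geom = NULL) {
  label <- match.arg(label)
  if (!is.logical(voxels)) storage.mode(voxels) <- "logical"
  if (!identical(dim(voxels), as.integer(grid$shape)))
    stop("voxel array dimensions do not match grid shape", call. = FALSE)
  structure(list(grid = grid, voxels = voxels, label = label, geom = geom),
            class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("<volume_mask:%s> %d foreground voxels on %d x %d x %d grid\n",
              x$label, sum(x$voxels),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

# count of foreground voxels
mask_volume <- function(mask) sum(mask$voxels)

# physical centroid (mm, grid-centred) of a non-empty mask
mask_centroid <- function(mask) {
  ax <- grid_axes(mask$grid)
  w <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty mask has no centroid", call. = FALSE)
  c(mean(ax[[1]][w[, 1]]), mean(ax[[2]][w[, 2]]), mean(ax[[3]][w[, 3]]))
}

# voxel-index bounding box of TRUE voxels, padded by `pad` voxels and
# clamped to the grid; returns list(lo, hi) or NULL for an empty mask
mask_bbox <- function(voxels, pad = 1L) {
  d <- dim(voxels)
  b <- cpp_bbox(as.vector(voxels), d)
  if (b[4] == 0L) return(NULL)
  list(lo = pmax(b[1:3] - pad, 1L), hi = pmin(b[4:6] + pad, d))
}

#' Rasterize a union of axis-aligned ellipsoids
#'
#' Low-level rasterizer used by the phantom generator and handy for
#' building test masks: a voxel is foreground iff its centre lies inside
#' any of the solids. Coordinates are physical mm relative to the grid
#' centre.
#'
#' @param grid a [grid_spec()]
#' @param centers numeric matrix (or length-3 vector) of solid centres
#' @param semiaxes numeric matrix (or length-3 vector) of semiaxes; equal
#'   semiaxes give a sphere of that radius
#' @return a logical 3D array of `grid$shape`
#' @export
rasterize_solids <- function(grid, centers, semiaxes) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  semiaxes <- matrix(as.numeric(semiaxes), ncol = 3)
  v <- cpp_rasterize_solids(grid$shape, grid$spacing, centers, semiaxes)
  array(v, dim = grid$shape)
}

# geometry matrix helper
solid_geom <- function(centers, semiaxes) {
  g <- cbind(matrix(centers, ncol = 3), matrix(semiaxes, ncol = 3))
  colnames(g) <- c("cx", "cy", "cz", "ax", "ay", "az")
  g
}

#' Export a mask as NIfTI
#'
#' Writes the binary mask as an integer NIfTI volume with the grid spacing
#' recorded in the header, for visual inspection in external viewers.
#'
#' @param mask a [volume_mask()]
#' @param path output file (`.nii` or `.nii.gz`)
#' @return the path, invisibly
#' @export
write_mask_nifti <- function(mask, path) {
  arr <- array(as.integer(mask$voxels), dim = mask$grid$shape)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- mask$grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file written by [write_mask_nifti()] or compatible
#' @param label role label for the resulting mask
#' @return a [volume_mask()] with spacing taken from the header
#' @export
read_mask_nifti <- function(path, label = "tumor_imaged") {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  arr <- as.array(img) > 0.5
  volume_mask(arr, grid_spec(dim(arr), sp[1:3]), label = label)
}
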