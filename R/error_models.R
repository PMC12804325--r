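#' Draw the random error realizations for one simulated case
#'
#' One draw per error source, using R's global random number generator:
#' \describe{
#'   \item{tissue shrinkage}{`Normal(shrinkage_mean, 0.05)`, clamped below
#'     at 0 (expansion is not physical); identically 0 when
#'     `shrinkage_mean = 0`}
#'   \item{satellite lesion}{presence `Bernoulli(satellite_prob)`; size
#'     (sphere radius) `Uniform(0.5, 2.5)` mm when present, else 0}
#'   \item{registration}{each image of the pair contributes an independent
#'     axis-aligned displacement with signed magnitude
#'     `Normal(0, registration_sd_mm)` along an axis chosen uniformly from
#'     X, Y, Z; under `registration_model = "single"` only the
#'     post-ablation image is displaced}
#'   \item{segmentation}{independent global boundary offsets for tumor and
#'     ablation masks; under the default composite model each offset is
#'     `Normal(0, seg_fixed_sd_mm)` (inter-observer component) plus
#'     `Uniform(-s, s)` with `s = seg_error_scale * segmentation_sd_mm`
#'     (bounded component scaling with the nominal error); under
#'     `seg_noise_model = "gaussian"` each offset is
#'     `Normal(0, segmentation_sd_mm)`}
#' }
#'
#' @param params a [sim_params()] object
#' @return an object of class `error_draws`
#' @examples
#' set.seed(7)
#' draw_errors(sim_params(registration_sd_mm = 3))
#' @export
draw_errors <- function(params) {
  e_shrink <- 0
  if (params$shrinkage_mean > 0)
    e_shrink <- min(max(rnorm(1, params$shrinkage_mean, 0.05), 0), 0.99)
  present <- rbinom(1, 1, params$satellite_prob) == 1
  d_sat <- if (present) runif(1, 0.5, 2.5) else 0
  paired <- !identical(params$registration_model, "single")
  seg_offset <- function() {
    if (identical(params$seg_noise_model, "gaussian"))
      return(rnorm(1, 0, params$segmentation_sd_mm))
    s <- params$seg_error_scale * params$segmentation_sd_mm
    rnorm(1, 0, params$seg_fixed_sd_mm) + if (s > 0) runif(1, -s, s) else 0
  }
  structure(list(
    e_shrinkage = e_shrink,
    p_satellite_draw = present,
    d_satellite = d_sat,
    e_mag = rnorm(1, 0, params$registration_sd_mm),
    e_dir = sample(c("x", "y", "z"), 1),
    e_mag_pre = if (paired) rnorm(1, 0, params$registration_sd_mm) else 0,
    e_dir_pre = sample(c("x", "y", "z"), 1),
    e_tumor_offset = seg_offset(),
    e_ablation_offset = seg_offset()
  ), class = "error_draws")
}

# net relative registration displacement vector (mm) of a draw
registration_vector <- function(draws) {
  v <- c(0, 0, 0)
  v[match(draws$e_dir, c("x", "y", "z"))] <- draws$e_mag
  v2 <- c(0, 0, 0)
  v2[match(draws$e_dir_pre, c("x", "y", "z"))] <- draws$e_mag_pre
  v - v2
}

#' Shift a mask rigidly to emulate registration error
#'
#' Image registration misaligns the post-ablation image against the
#' pre-ablation image; the model shifts the ablation zone by a signed
#' magnitude along a single axis while the tumor stays in place. Masks
#' carrying analytic solids are re-rasterized at the shifted centre, so
#' sub-voxel shifts are honoured; plain masks fall back to a roll by the
#' nearest whole number of voxels.
#'
#' @param ablation a [volume_mask()] (any mask can be shifted)
#' @param e_mag signed shift in mm
#' @param e_dir axis, one of `"x"`, `"y"`, `"z"` (or 1:3)
#' @return the shifted [volume_mask()]
#' @export
apply_registration_shift <- function(ablation, e_mag, e_dir = c("x", "y", "z")) {
  if (is.numeric(e_dir)) e_dir <- c("x", "y", "z")[e_dir]
  e_dir <- match.arg(e_dir)
  a <- match(e_dir, c("x", "y", "z"))
  if (e_mag == 0) return(ablation)
  off <- c(0, 0, 0)
  off[a] <- e_mag
  translate_mask(ablation, off)
}

# rigid translation by a physical offset vector (mm)
translate_mask <- function(mask, offset) {
  if (all(offset == 0)) return(mask)
  if (!is.null(mask$geom)) {
    g <- mask$geom
    g[, 1:3] <- g[, 1:3, drop = FALSE] +
      matrix(offset, nrow(g), 3, byrow = TRUE)
    # solids are clipped at the grid boundary (finite field of view); a
    # solid displaced completely outside the grid is a geometry error
    inner_ext <- abs(g[, 1:3, drop = FALSE]) - g[, 4:6, drop = FALSE]
    half <- grid_half_extent(mask$grid)
    live <- g[, 4] > 0 & g[, 5] > 0 & g[, 6] > 0
    if (any(live) &&
        all(apply(inner_ext[live, , drop = FALSE], 1,
                  function(e) any(e > half))))
      stop_geometry("shifted solid lies entirely outside the grid")
    vox <- rasterize_solids(mask$grid, g[, 1:3, drop = FALSE],
                            g[, 4:6, drop = FALSE])
    return(volume_mask(vox, mask$grid, label = mask$label, geom = g))
  }
  # voxel-roll fallback at whole-voxel precision; content rolled past the
  # boundary is clipped
  shift_vox <- round(offset / mask$grid$spacing)
  v <- mask$voxels
  d <- dim(v)
  out <- array(FALSE, d)
  src <- lapply(1:3, function(a) seq_len(d[a]) - shift_vox[a])
  ok <- lapply(1:3, function(a) src[[a]] >= 1 & src[[a]] <= d[a])
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    v[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  volume_mask(out, mask$grid, label = mask$label)
}

#' Displace a mask boundary to emulate segmentation error
#'
#' Observer or algorithmic contouring error is modeled as a global
#' boundary offset: the mask surface moves outward by `offset` mm
#' (inward if negative). The operation thresholds the signed Euclidean
#' distance field of the mask at `-offset`, which is morphological
#' dilation (or erosion) by a metric ball of radius `|offset|`, correct
#' under anisotropic spacing. Erosion may empty the mask; that is
#' permitted and the empty mask is returned.
#'
#' @param mask a [volume_mask()]
#' @param offset boundary displacement in mm (positive = outward)
#' @return the displaced [volume_mask()]; the analytic solid description
#'   is dropped
#' @export
apply_segmentation_noise <- function(mask, offset) {
  if (offset == 0) return(mask)
  v <- mask$voxels
  grid <- mask$grid
  bb <- mask_bbox(v, pad = as.integer(ceiling(
    max(0, offset) / min(grid$spacing))) + 2L)
  if (is.null(bb)) return(mask) # nothing contoured: empty stays empty
  sub <- v[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
           drop = FALSE]
  disp <- cpp_offset_mask(as.vector(sub), dim(sub), grid$spacing, offset)
  out <- array(FALSE, dim(v))
  out[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- disp
  volume_mask(out, grid, label = mask$label)
}

#' Resample a mask to a coarser slice thickness
#'
#' Clinical images are reconstructed with ~1 mm in-plane resolution but
#' 1-5 mm slice thickness cranio-caudally (the z axis here). New slice
#' centres are laid out symmetrically about the grid centre at the given
#' thickness; in-plane axes are untouched and the output grid has spacing
#' `(sx, sy, thickness)`. Two reconstructions are available:
#' \describe{
#'   \item{`"union"` (default)}{a slab is foreground wherever any thin
#'     slice within it is — thick-slab projection, the
#'     partial-volume-inclusive reconstruction a contour drawn on thick
#'     slices produces. It never un-covers structure that is present in
#'     the thin slices, which keeps slab quantization from fabricating
#'     spurious uncovered tumor at the poles.}
#'   \item{`"nearest"`}{each slab takes the single thin slice nearest its
#'     centre.}
#' }
#'
#' @param mask a [volume_mask()]
#' @param thickness slice thickness in mm, `>=` the current z spacing
#' @param method slab reconstruction, `"union"` or `"nearest"`
#' @return a [volume_mask()] on the resampled grid
#' @export
resample_slice_thickness <- function(mask, thickness,
                                     method = c("union", "nearest")) {
  method <- match.arg(method)
  sz <- mask$grid$spacing[3]
  if (thickness < sz)
    stop("slice thickness must be >= current z spacing", call. = FALSE)
  if (thickness == sz) return(mask)
  nz <- mask$grid$shape[3]
  nz_new <- max(1L, as.integer(floor(nz * sz / thickness)))
  zc <- (seq_len(nz_new) - 1 - (nz_new - 1) / 2) * thickness
  z0 <- (seq_len(nz) - 1 - (nz - 1) / 2) * sz
  grid_new <- grid_spec(c(mask$grid$shape[1:2], nz_new),
                        c(mask$grid$spacing[1:2], thickness))
  out <- array(FALSE, grid_new$shape)
  if (method == "nearest") {
    src <- round(zc / sz + (nz - 1) / 2) + 1
    src <- pmin(pmax(src, 1L), nz)
    out <- mask$voxels[, , src, drop = FALSE]
  } else {
    for (k in seq_len(nz_new)) {
      win <- which(abs(z0 - zc[k]) <= thickness / 2 + 1e-9)
      if (length(win))
        out[, , k] <- apply(mask$voxels[, , win, drop = FALSE], c(1, 2), any)
    }
  }
  volume_mask(out, grid_new, label = mask$label)
}
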