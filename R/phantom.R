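#' Sample the geometry of one simulated case
#'
#' Draws the tumor diameter and the target (nominal) minimum ablative
#' margin uniformly from the configured ranges, using R's global random
#' number generator. In ellipsoid mode the per-axis ratios are drawn
#' Uniform(0.8, 1.2) and applied to the common diameter.
#'
#' @param params a [sim_params()] object
#' @return an object of class `case_geometry` with fields `d_tumor`
#'   (mm), `margin_target` (mm, may be negative), `shape_kind`,
#'   `ellipsoid_axis_ratio`
#' @examples
#' set.seed(1)
#' sample_case(sim_params())
#' @export
sample_case <- function(params) {
  tr <- params$tumor_range_mm
  mr <- params$margin_range_mm
  if (tr[1] > tr[2] || mr[1] > mr[2])
    stop("invalid sampling range: lower bound exceeds upper bound",
         call. = FALSE)
  ratio <- c(1, 1, 1)
  if (identical(params$shape_kind, "ellipsoid"))
    ratio <- runif(3, 0.8, 1.2)
  structure(list(
    d_tumor = runif(1, tr[1], tr[2]),
    margin_target = runif(1, mr[1], mr[2]),
    shape_kind = params$shape_kind,
    ellipsoid_axis_ratio = ratio
  ), class = "case_geometry")
}

#' Rasterize the tumor / ablation-zone pair for one case
#'
#' The tumor is a solid of diameter `d_tumor` centred on the grid; the
#' ablation zone is concentric with every semiaxis enlarged by the target
#' margin, so that before any error is applied the margin is (up to voxel
#' quantization) `margin_target` everywhere on the surface. A negative
#' margin larger than the tumor radius clamps the ablation to an empty
#' mask. A voxel is foreground iff its centre lies inside the analytic
#' solid.
#'
#' @param geom a `case_geometry` from [sample_case()]
#' @param grid a [grid_spec()]
#' @return list with elements `tumor` and `ablation`, both [volume_mask()]s
#'   carrying their analytic solids
#' @export
rasterize_case <- function(geom, grid) {
  semi_t <- geom$d_tumor / 2 * geom$ellipsoid_axis_ratio
  semi_a <- semi_t + geom$margin_target
  if (max(semi_t) > min(grid_half_extent(grid)) ||
      max(semi_a) > min(grid_half_extent(grid)))
    stop_geometry("solid exceeds grid extent")
  ctr <- c(0, 0, 0)
  tumor <- volume_mask(rasterize_solids(grid, ctr, semi_t), grid,
                       label = "tumor_imaged",
                       geom = solid_geom(ctr, semi_t))
  semi_a_cl <- pmax(semi_a, 0)
  ablation <- volume_mask(rasterize_solids(grid, ctr, semi_a_cl), grid,
                          label = "ablation_imaged",
                          geom = solid_geom(ctr, semi_a_cl))
  list(tumor = tumor, ablation = ablation)
}

#' Contract a tumor mask by thermal tissue shrinkage
#'
#' Microwave ablation contracts tissue radially; the microscopic (true)
#' tumor is therefore smaller than the imaged one. All linear dimensions
#' are scaled by `1 - shrink_fraction` about the solid's own centre.
#' Masks carrying analytic solids are re-rasterized exactly; plain masks
#' are rescaled by nearest-neighbour resampling about their centroid.
#'
#' @param tumor a [volume_mask()]
#' @param shrink_fraction fraction in `[0, 1)`; draws below 0 must be
#'   clamped by the caller (see [draw_errors()])
#' @return the contracted [volume_mask()], labelled `tumor_true`
#' @export
apply_shrinkage <- function(tumor, shrink_fraction) {
  if (!is.finite(shrink_fraction) || shrink_fraction < 0 ||
      shrink_fraction >= 1)
    stop("shrink_fraction must lie in [0, 1)", call. = FALSE)
  if (shrink_fraction == 0) {
    out <- tumor
    out$label <- "tumor_true"
    return(out)
  }
  s <- 1 - shrink_fraction
  if (!is.null(tumor$geom)) {
    g <- tumor$geom
    ctr <- g[1, 1:3] # contract about the primary solid's centre
    ctr_m <- matrix(ctr, nrow(g), 3, byrow = TRUE)
    g[, 1:3] <- (g[, 1:3, drop = FALSE] - ctr_m) * s + ctr_m
    g[, 4:6] <- g[, 4:6, drop = FALSE] * s
    vox <- rasterize_solids(tumor$grid, g[, 1:3, drop = FALSE],
                            g[, 4:6, drop = FALSE])
    return(volume_mask(vox, tumor$grid, label = "tumor_true", geom = g))
  }
  # mask-only path: nearest-neighbour pullback about the centroid
  ctr <- mask_centroid(tumor)
  ax <- grid_axes(tumor$grid)
  idx <- lapply(1:3, function(a) {
    src <- ctr[a] + (ax[[a]] - ctr[a]) / s # position sampled in the source
    i <- round(src / tumor$grid$spacing[a] +
                 (tumor$grid$shape[a] - 1) / 2) + 1
    ifelse(i >= 1 & i <= tumor$grid$shape[a], i, NA_integer_)
  })
  vox <- array(FALSE, tumor$grid$shape)
  ok1 <- !is.na(idx[[1]]); ok2 <- !is.na(idx[[2]]); ok3 <- !is.na(idx[[3]])
  vox[ok1, ok2, ok3] <-
    tumor$voxels[idx[[1]][ok1], idx[[2]][ok2], idx[[3]][ok3]]
  volume_mask(vox, tumor$grid, label = "tumor_true")
}

#' Attach a microscopic satellite lesion to a tumor mask
#'
#' Satellite lesions are sub-resolution tumor deposits directly adjacent to
#' the main tumor, invisible on imaging but reducing the true margin. When
#' `present`, a solid sphere of radius `d_satellite` is placed tangent to
#' the tumor surface along a direction drawn uniformly on the unit sphere,
#' and unioned with the mask. The lesion therefore protrudes
#' `2 * d_satellite` mm beyond the original surface.
#'
#' @param tumor a [volume_mask()]
#' @param present logical; if `FALSE` the mask is returned unchanged
#' @param d_satellite satellite size (sphere radius) in mm, in `[0.5, 2.5]`
#'   when present
#' @return a [volume_mask()] labelled `tumor_true`
#' @export
add_satellite <- function(tumor, present, d_satellite) {
  out <- tumor
  out$label <- "tumor_true"
  if (!isTRUE(present)) return(out)
  if (!is.finite(d_satellite) || d_satellite <= 0)
    stop("d_satellite must be positive when a satellite is present",
         call. = FALSE)
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  if (!is.null(tumor$geom)) {
    g0 <- tumor$geom[1, , drop = FALSE]
    # radial extent of the (axis-aligned) ellipsoid along direction u
    r_u <- 1 / sqrt(sum((u / g0[1, 4:6])^2))
    ctr <- g0[1, 1:3] + u * (r_u + d_satellite)
  } else {
    ctr0 <- mask_centroid(tumor)
    step <- min(tumor$grid$spacing) / 4
    tmax <- max(grid_half_extent(tumor$grid)) * 2
    ts <- seq(0, tmax, by = step)
    inside <- vapply(ts, function(t) point_in_mask(tumor, ctr0 + t * u),
                     logical(1))
    r_u <- if (any(inside)) ts[max(which(inside))] else 0
    ctr <- ctr0 + u * (r_u + d_satellite)
  }
  if (any(abs(ctr) + d_satellite > grid_half_extent(tumor$grid)))
    stop_geometry("satellite lesion would leave the grid")
  sat <- rasterize_solids(tumor$grid, ctr, rep(d_satellite, 3))
  geom <- if (!is.null(tumor$geom))
    rbind(tumor$geom, solid_geom(ctr, rep(d_satellite, 3)))
  volume_mask(tumor$voxels | sat, tumor$grid, label = "tumor_true",
              geom = geom)
}

# is a physical point (mm, grid-centred) inside the mask?
point_in_mask <- function(mask, p) {
  i <- round(p / mask$grid$spacing + (mask$grid$shape - 1) / 2) + 1
  if (any(i < 1) || any(i > mask$grid$shape)) return(FALSE)
  mask$voxels[i[1], i[2], i[3]]
}

# condition class used for per-case geometry failures (triggers a redraw)
stop_geometry <- function(msg) {
  stop(structure(class = c("mamsim_geometry_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
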