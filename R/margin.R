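#' Signed Euclidean distance field of a binary mask
#'
#' Positive inside the mask (distance to the nearest background voxel
#' centre), negative outside (minus the distance to the nearest foreground
#' voxel centre), computed with an exact anisotropic Euclidean distance
#' transform in mm. The zero level lies between the foreground and
#' background voxel layers.
#'
#' @param mask a [volume_mask()]
#' @return a numeric 3D array of distances (mm), same shape as the mask
#' @export
signed_distance_field <- function(mask) {
  signed_distance_core(mask$voxels, mask$grid$spacing)
}

# workhorse: signed EDT of a logical array
signed_distance_core <- function(voxels, spacing) {
  d <- dim(voxels)
  if (!any(voxels)) {
    ext <- sqrt(sum((d * spacing)^2))
    return(array(-2 * ext, d))
  }
  if (all(voxels)) {
    d_in <- sqrt(cpp_edt_sq(!voxels, d, spacing)) # sentinel: all large
    return(array(d_in, d))
  }
  d_out <- sqrt(cpp_edt_sq(as.vector(voxels), d, spacing))
  d_in <- sqrt(cpp_edt_sq(as.vector(!voxels), d, spacing))
  array(ifelse(as.vector(voxels), d_in, -d_out), d)
}

#' Minimum ablative margin between a tumor and an ablation mask
#'
#' The minimum ablative margin (MAM) is the minimum, over tumor surface
#' voxels (foreground voxels with a 6-connected background neighbour), of
#' the signed Euclidean distance to the ablation boundary: when the tumor
#' is fully covered, the smallest distance from a tumor surface voxel to
#' non-ablated tissue (positive); otherwise minus the largest distance
#' from uncovered tumor tissue to the ablation zone (negative).
#' `covered` reports exact set containment
#' (tumor subset of ablation). An empty ablation mask yields
#' `covered = FALSE` with `mam` set to minus the tumor's maximal surface
#' distance from its centroid (a radius proxy).
#'
#' @param tumor a non-empty [volume_mask()]
#' @param ablation a [volume_mask()] on the same grid
#' @return an object of class `margin_result`: fields `mam` (mm),
#'   `covered` (logical), `n_uncovered_voxels` (integer)
#' @examples
#' g <- grid_spec(c(40, 40, 40), 1)
#' tum <- volume_mask(rasterize_solids(g, c(0, 0, 0), rep(5, 3)), g, "tumor_true")
#' abl <- volume_mask(rasterize_solids(g, c(0, 0, 0), rep(10, 3)), g, "ablation_true")
#' compute_mam(tum, abl)$mam # close to 5
#' @export
compute_mam <- function(tumor, ablation) {
  if (!identical(tumor$grid$shape, ablation$grid$shape) ||
      !isTRUE(all.equal(tumor$grid$spacing, ablation$grid$spacing)))
    stop("tumor and ablation masks must share one grid", call. = FALSE)
  tv <- tumor$voxels
  av <- ablation$voxels
  if (!any(tv)) stop("tumor mask is empty", call. = FALSE)
  grid <- tumor$grid
  if (!any(av)) {
    n_unc <- sum(tv)
    ctr <- mask_centroid(tumor)
    ax <- grid_axes(grid)
    surf <- which(array(cpp_surface(as.vector(tv), grid$shape), dim(tv)),
                  arr.ind = TRUE)
    r <- sqrt((ax[[1]][surf[, 1]] - ctr[1])^2 +
              (ax[[2]][surf[, 2]] - ctr[2])^2 +
              (ax[[3]][surf[, 3]] - ctr[3])^2)
    return(margin_result(-max(r), FALSE, n_unc))
  }
  # crop to the union bounding box (padded); distances at tumor surface
  # voxels are unaffected because both masks lie inside the crop
  bb <- mask_bbox(tv | av, pad = 1L)
  ts <- tv[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
           drop = FALSE]
  as <- av[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
           drop = FALSE]
  res <- cpp_mam(as.vector(ts), as.vector(as), dim(ts), grid$spacing)
  margin_result(res[1], res[2] == 0, res[2])
}

margin_result <- function(mam, covered, n_uncovered) {
  structure(list(mam = mam, covered = covered,
                 n_uncovered_voxels = as.integer(n_uncovered)),
            class = "margin_result")
}

#' @export
print.margin_result <- function(x, ...) {
  cat(sprintf("<margin_result> mam = %.2f mm, covered = %s (%d uncovered voxels)\n",
              x$mam, x$covered, x$n_uncovered_voxels))
  invisible(x)
}
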