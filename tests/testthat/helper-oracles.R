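# Independent oracles used across the suite. These deliberately avoid the
# package's EDT machinery: distances are computed by exhaustive search over
# voxel pairs so they can certify compute_mam on small grids.

# all-pairs brute-force minimum ablative margin, same convention as
# compute_mam: covered -> min over tumor surface voxels of the distance to
# the nearest non-ablation voxel; uncovered -> minus the largest distance
# from an uncovered tumor voxel to the nearest ablation voxel
brute_force_mam <- function(tumor, ablation) {
  g <- tumor$grid
  ax <- lapply(1:3, function(a) {
    n <- g$shape[a]
    (seq_len(n) - 1 - (n - 1) / 2) * g$spacing[a]
  })
  coords <- function(idx) cbind(ax[[1]][idx[, 1]], ax[[2]][idx[, 2]],
                                ax[[3]][idx[, 3]])
  tv <- tumor$voxels
  av <- ablation$voxels
  # 6-connected surface, grid border counts as background
  is_surface <- function(v, i, j, k) {
    d <- dim(v)
    if (i == 1 || i == d[1] || j == 1 || j == d[2] || k == 1 || k == d[3])
      return(TRUE)
    !(v[i - 1, j, k] && v[i + 1, j, k] && v[i, j - 1, k] && v[i, j + 1, k] &&
        v[i, j, k - 1] && v[i, j, k + 1])
  }
  tum_idx <- which(tv, arr.ind = TRUE)
  unc <- !av[tv]
  min_cross <- function(from, to) { # min distance from each row of `from`
    vapply(seq_len(nrow(from)), function(r) {
      sqrt(min((to[, 1] - from[r, 1])^2 + (to[, 2] - from[r, 2])^2 +
                 (to[, 3] - from[r, 3])^2))
    }, numeric(1))
  }
  if (!any(unc)) {
    surf <- tum_idx[apply(tum_idx, 1, function(p)
      is_surface(tv, p[1], p[2], p[3])), , drop = FALSE]
    bg <- which(!av, arr.ind = TRUE)
    min(min_cross(coords(surf), coords(bg)))
  } else {
    uncovered <- tum_idx[unc, , drop = FALSE]
    fg <- which(av, arr.ind = TRUE)
    -max(min_cross(coords(uncovered), coords(fg)))
  }
}

# small random blob mask for property tests: union of a few random solids
random_blob <- function(grid, n_solids = 2, r_range = c(2, 5)) {
  half <- (grid$shape - 1) / 2 * grid$spacing
  centers <- t(replicate(n_solids, runif(3, -half / 3, half / 3)))
  semi <- matrix(runif(3 * n_solids, r_range[1], r_range[2]), ncol = 3)
  volume_mask(rasterize_solids(grid, centers, semi), grid, "tumor_true")
}

# records drawn from a known logistic law, for parameter recovery
logistic_records <- function(n, beta0, beta1) {
  x <- runif(n, -5, 10)
  y <- rbinom(n, 1, plogis(beta0 + beta1 * x)) == 1
  data.frame(mam_observed_mm = x,
             mam_true_mm = ifelse(y, 1, -1),
             e_mag_mm = 0)
}
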