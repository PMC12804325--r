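test_that("draw_errors follows the stated distributions", {
  set.seed(21)
  p <- sim_params(registration_sd_mm = 3, segmentation_sd_mm = 3,
                  satellite_prob = 0.5,
                  shrinkage_mean = 0.2, seg_noise_model = "gaussian")
  d <- replicate(8000, {
    e <- draw_errors(p)
    c(e$e_mag, match(e$e_dir, c("x", "y", "z")), e$p_satellite_draw,
      e$d_satellite, e$e_shrinkage)
  })
  expect_lt(abs(sd(d[1, ]) - 3), 0.1)        # registration sd
  expect_lt(abs(mean(d[1, ])), 0.1)          # centred
  freq <- tabulate(d[2, ], 3) / ncol(d)      # axis frequencies
  expect_true(all(abs(freq - 1 / 3) < 0.02))
  expect_lt(abs(mean(d[3, ]) - 0.5), 0.02)   # satellite presence rate
  sat_sizes <- d[4, d[3, ] == 1]
  expect_gte(min(sat_sizes), 0.5)
  expect_lte(max(sat_sizes), 2.5)
  expect_true(all(d[4, d[3, ] == 0] == 0))
  expect_true(all(d[5, ] >= 0))              # shrinkage clamped at 0
  expect_lt(abs(mean(d[5, ]) - 0.2), 0.01)
  # gaussian segmentation reading: offsets ~ Normal(0, 3)
  offs <- replicate(4000, draw_errors(p)$e_tumor_offset)
  expect_lt(abs(sd(offs) - 3), 0.15)
  # composite default: fixed N(0,1) plus bounded U(+-seg_error_scale * 3)
  pc <- sim_params(segmentation_sd_mm = 3)
  offc <- replicate(6000, draw_errors(pc)$e_ablation_offset)
  want_sd <- sqrt(pc$seg_fixed_sd_mm^2 +
                    (pc$seg_error_scale * 3)^2 / 3)
  expect_lt(abs(sd(offc) - want_sd), 0.1)
  expect_lt(abs(mean(offc)), 0.06)
})

test_that("degenerate error parameters give degenerate draws", {
  set.seed(2)
  p0 <- sim_params(registration_sd_mm = 0, segmentation_sd_mm = 0,
                   seg_fixed_sd_mm = 0)
  for (i in 1:20) {
    e <- draw_errors(p0)
    expect_identical(e$e_mag, 0)
    expect_identical(e$e_tumor_offset, 0)
    expect_false(e$p_satellite_draw)
    expect_identical(e$e_shrinkage, 0)
  }
  p1 <- sim_params(satellite_prob = 1)
  expect_true(all(replicate(20, draw_errors(p1)$p_satellite_draw)))
})

test_that("registration shift moves the centroid by the requested amount", {
  g <- grid_spec(c(61, 61, 61), 1)
  abl <- volume_mask(rasterize_solids(g, c(0, 0, 0), rep(10, 3)), g,
                     "ablation_imaged",
                     geom = solid_geom(c(0, 0, 0), rep(10, 3)))
  expect_identical(apply_registration_shift(abl, 0, "x")$voxels, abl$voxels)
  sh <- apply_registration_shift(abl, 3, "x")
  ctr <- mamsim:::mask_centroid(sh)
  expect_lt(abs(ctr[1] - 3), 0.2)
  expect_lt(abs(ctr[2]), 0.1)
  expect_lt(abs(ctr[3]), 0.1)
  # voxel count preserved within 2% under re-rasterization
  expect_lt(abs(sum(sh$voxels) - sum(abl$voxels)) / sum(abl$voxels), 0.02)
  # exactly one voxel along an axis equals the integer roll
  sh1 <- apply_registration_shift(abl, 1, "y")
  rolled <- array(FALSE, dim(abl$voxels))
  rolled[, 2:61, ] <- abl$voxels[, 1:60, ]
  expect_identical(sh1$voxels, rolled)
  # shifts beyond the boundary clip at the field of view; a solid pushed
  # entirely off the grid is a geometry error
  clipped <- apply_registration_shift(abl, 25, "z")
  expect_lt(sum(clipped$voxels), sum(abl$voxels))
  expect_gt(sum(clipped$voxels), 0)
  expect_error(apply_registration_shift(abl, 45, "z"),
               class = "mamsim_geometry_error")
})

test_that("segmentation noise dilates/erodes by the analytic amount and is monotone", {
  g <- grid_spec(c(61, 61, 61), 1)
  sph <- volume_mask(rasterize_solids(g, c(0, 0, 0), rep(10, 3)), g,
                     "tumor_imaged")
  expect_identical(apply_segmentation_noise(sph, 0)$voxels, sph$voxels)
  big <- apply_segmentation_noise(sph, 2)
  v12 <- 4 / 3 * pi * 12^3
  expect_lt(abs(sum(big$voxels) - v12) / v12, 0.05)
  small <- apply_segmentation_noise(sph, -2)
  v8 <- 4 / 3 * pi * 8^3
  # erosion carries a slightly larger quantization residual than dilation
  expect_lt(abs(sum(small$voxels) - v8) / v8, 0.08)
  # monotone in offset
  offs <- c(-3, -1, 0, 1, 3)
  masks <- lapply(offs, function(o) apply_segmentation_noise(sph, o)$voxels)
  for (i in seq_len(length(offs) - 1))
    expect_true(all(masks[[i + 1]][masks[[i]]]))
  # erosion below the radius empties the mask without error
  gone <- apply_segmentation_noise(sph, -11)
  expect_identical(sum(gone$voxels), 0L)
})

test_that("erode-then-dilate is contained in dilate-then-erode", {
  set.seed(4)
  g <- grid_spec(c(31, 31, 31), 1)
  blob <- random_blob(g, 2, c(3, 6))
  a <- apply_segmentation_noise(apply_segmentation_noise(blob, -2), 2)
  b <- apply_segmentation_noise(apply_segmentation_noise(blob, 2), -2)
  expect_true(all(b$voxels[a$voxels])) # opening subset of closing
})

test_that("offsets on concentric masks move the margin by their difference", {
  g <- grid_spec(c(61, 61, 61), 1)
  tum <- volume_mask(rasterize_solids(g, c(0, 0, 0), rep(8, 3)), g, "tumor_true")
  abl <- volume_mask(rasterize_solids(g, c(0, 0, 0), rep(13, 3)), g, "ablation_true")
  m0 <- compute_mam(tum, abl)$mam
  for (ta in list(c(1, 2), c(-1, 1), c(2, -1))) {
    t2 <- apply_segmentation_noise(tum, ta[1])
    a2 <- apply_segmentation_noise(abl, ta[2])
    m2 <- compute_mam(t2, a2)$mam
    expect_lt(abs((m2 - m0) - (ta[2] - ta[1])), 1 + 1e-9)
  }
})

test_that("slice resampling keeps in-plane structure and spans the solid", {
  g <- grid_spec(c(41, 41, 41), 1)
  sph <- volume_mask(rasterize_solids(g, c(0, 0, 0), rep(10, 3)), g,
                     "tumor_imaged")
  expect_identical(resample_slice_thickness(sph, 1), sph)
  rn <- resample_slice_thickness(sph, 5, method = "nearest")
  expect_identical(rn$grid$spacing, c(1, 1, 5))
  expect_identical(rn$grid$shape[1:2], c(41L, 41L))
  nz_fg <- sum(apply(rn$voxels, 3, any))
  expect_gte(nz_fg, 3) # 20 mm sphere at 5 mm slab centres
  expect_lte(nz_fg, 5)
  # nearest mode: every output slice is a verbatim copy of an input slice
  for (k in seq_len(dim(rn$voxels)[3])) {
    hits <- vapply(seq_len(41), function(j)
      identical(rn$voxels[, , k], sph$voxels[, , j]), logical(1))
    expect_true(any(hits))
  }
  # union mode contains the nearest-sample reconstruction and never
  # un-covers structure present in the thin slices
  ru <- resample_slice_thickness(sph, 5)
  expect_true(all(ru$voxels[rn$voxels]))
  z_in <- apply(sph$voxels, 3, any)
  expect_identical(sum(apply(ru$voxels, 3, any) ) >= sum(z_in) / 5, TRUE)
  expect_error(resample_slice_thickness(sph, 0.5), "thickness")
  emp <- volume_mask(array(FALSE, c(41, 41, 41)), g, "tumor_imaged")
  expect_identical(sum(resample_slice_thickness(emp, 3)$voxels), 0L)
})
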