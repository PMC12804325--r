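test_that("sample_case respects ranges and degenerates to point masses", {
  set.seed(42)
  p <- sim_params()
  for (i in 1:200) {
    cg <- sample_case(p)
    expect_gte(cg$d_tumor, 10); expect_lte(cg$d_tumor, 30)
    expect_gte(cg$margin_target, -5); expect_lte(cg$margin_target, 10)
  }
  pd <- sim_params(tumor_range_mm = c(20, 20), margin_range_mm = c(5, 5))
  cg <- sample_case(pd)
  expect_identical(cg$d_tumor, 20)
  expect_identical(cg$margin_target, 5)
})

test_that("sampled tumor size and margin have the uniform-law moments", {
  set.seed(7)
  p <- sim_params()
  draws <- replicate(10000, {
    cg <- sample_case(p); c(cg$d_tumor, cg$margin_target)
  })
  # Uniform(10,30): mean 20, se ~ 0.058; Uniform(-5,10): mean 2.5, se ~ 0.043
  expect_lt(abs(mean(draws[1, ]) - 20), 0.3)
  expect_lt(abs(mean(draws[2, ]) - 2.5), 0.2)
})

test_that("rasterized solids track analytic sphere volumes and shrink with spacing", {
  g1 <- grid_spec(c(41, 41, 41), 1)
  cg <- structure(list(d_tumor = 10, margin_target = 5,
                       shape_kind = "sphere",
                       ellipsoid_axis_ratio = c(1, 1, 1)),
                  class = "case_geometry")
  m <- rasterize_case(cg, g1)
  vol_t <- sum(m$tumor$voxels)
  vol_a <- sum(m$ablation$voxels)
  expect_lt(abs(vol_t - 4 / 3 * pi * 5^3) / (4 / 3 * pi * 5^3), 0.05)
  expect_lt(abs(vol_a - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3), 0.05)
  # refinement: relative volume error at 0.5 mm should at least halve
  g2 <- grid_spec(c(81, 81, 81), 0.5)
  m2 <- rasterize_case(cg, g2)
  err1 <- abs(vol_t - 4 / 3 * pi * 125) / (4 / 3 * pi * 125)
  err2 <- abs(sum(m2$tumor$voxels) * 0.5^3 - 4 / 3 * pi * 125) /
    (4 / 3 * pi * 125)
  expect_lt(err2, err1 / 2 + 1e-12)
})

test_that("zero margin gives identical masks and full negative clamp empties the ablation", {
  g <- grid_spec(c(41, 41, 41), 1)
  cg0 <- structure(list(d_tumor = 12, margin_target = 0,
                        shape_kind = "sphere",
                        ellipsoid_axis_ratio = c(1, 1, 1)),
                   class = "case_geometry")
  m0 <- rasterize_case(cg0, g)
  expect_identical(m0$tumor$voxels, m0$ablation$voxels)
  cgneg <- structure(list(d_tumor = 10, margin_target = -5,
                          shape_kind = "sphere",
                          ellipsoid_axis_ratio = c(1, 1, 1)),
                     class = "case_geometry")
  mneg <- rasterize_case(cgneg, g)
  expect_identical(sum(mneg$ablation$voxels), 0L)
})

test_that("apply_shrinkage scales linear dimensions and is monotone", {
  g <- grid_spec(c(41, 41, 41), 1)
  tum <- volume_mask(rasterize_solids(g, c(0, 0, 0), rep(10, 3)), g,
                     "tumor_imaged", geom = solid_geom(c(0, 0, 0), rep(10, 3)))
  expect_identical(apply_shrinkage(tum, 0)$voxels, tum$voxels)
  shr <- apply_shrinkage(tum, 0.3)
  expect_lt(abs(sum(shr$voxels) - 4 / 3 * pi * 7^3) / (4 / 3 * pi * 7^3),
            0.05)
  vols <- vapply(c(0, .1, .2, .3, .5, .9),
                 function(s) sum(apply_shrinkage(tum, s)$voxels), numeric(1))
  expect_true(all(diff(vols) <= 0))
  expect_error(apply_shrinkage(tum, 1), "shrink_fraction")
  # mask-only path agrees with the analytic path to a few percent
  tum_plain <- volume_mask(tum$voxels, g, "tumor_imaged")
  shr_plain <- apply_shrinkage(tum_plain, 0.3)
  expect_lt(abs(sum(shr_plain$voxels) - sum(shr$voxels)) / sum(shr$voxels),
            0.05)
})

test_that("add_satellite is tangent, protrudes two radii, and never removes voxels", {
  g <- grid_spec(c(61, 61, 61), 1)
  tum <- volume_mask(rasterize_solids(g, c(0, 0, 0), rep(10, 3)), g,
                     "tumor_imaged", geom = solid_geom(c(0, 0, 0), rep(10, 3)))
  expect_identical(add_satellite(tum, FALSE, 0)$voxels, tum$voxels)
  set.seed(11)
  for (i in 1:10) {
    d <- runif(1, 0.5, 2.5)
    out <- add_satellite(tum, TRUE, d)
    expect_true(all(out$voxels[tum$voxels])) # input is a subset
    # farthest foreground voxel from centre reaches r + 2 d (+- 1 voxel)
    ax <- seq_len(61) - 31
    w <- which(out$voxels, arr.ind = TRUE)
    rmax <- sqrt(max((ax[w[, 1]])^2 + (ax[w[, 2]])^2 + (ax[w[, 3]])^2))
    expect_lt(abs(rmax - (10 + 2 * d)), 1.0)
  }
})

test_that("satellite directions are uniform over the sphere", {
  g <- grid_spec(c(61, 61, 61), 1)
  tum <- volume_mask(rasterize_solids(g, c(0, 0, 0), rep(10, 3)), g,
                     "tumor_imaged", geom = solid_geom(c(0, 0, 0), rep(10, 3)))
  set.seed(5)
  dirs <- t(replicate(2000, {
    out <- add_satellite(tum, TRUE, 1.5)
    ctr <- out$geom[2, 1:3]
    ctr / sqrt(sum(ctr^2))
  }))
  # Rayleigh test of uniformity on the sphere: under H0 the resultant
  # length R satisfies 3 * n * |mean|^2 ~ chisq(3)
  stat <- 3 * nrow(dirs) * sum(colMeans(dirs)^2)
  expect_lt(stat, qchisq(0.99, df = 3))
  # each axis mean near zero
  expect_true(all(abs(colMeans(dirs)) < 0.05))
})

test_that("concentric construction reproduces the target margin within a voxel diagonal", {
  g <- grid_spec(c(80, 80, 80), 1)
  set.seed(3)
  for (i in 1:8) {
    cg <- sample_case(sim_params())
    m <- rasterize_case(cg, g)
    if (sum(m$ablation$voxels) == 0) next
    mm <- compute_mam(m$tumor, m$ablation)
    expect_lt(abs(mm$mam - cg$margin_target), sqrt(3) + 1e-9)
  }
})
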