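#' Simulation parameter set
#'
#' One permutation of the error/biology parameters plus the sampling
#' ranges, grid geometry and run size. Defaults are the all-minimal
#' baseline used by the one-factor sweeps: no biological effects and all
#' technical errors at their smallest studied value (1 mm).
#'
#' @param shrinkage_mean mean radial tissue shrinkage fraction (study
#'   values 0, 0.1, 0.2, 0.3); per-case draws are `Normal(mean, 0.05)`
#'   clamped below at 0
#' @param satellite_prob probability that a case carries one microscopic
#'   satellite lesion (study values 0, 0.25, 0.5, 0.75, 1)
#' @param registration_sd_mm registration error standard deviation in mm
#'   (study values 1-5)
#' @param segmentation_sd_mm segmentation error standard deviation in mm
#'   (study values 1-5)
#' @param slice_thickness_mm reconstructed slice thickness in mm (study
#'   values 1-5)
#' @param tumor_range_mm tumor diameter sampling range in mm
#' @param margin_range_mm target margin sampling range in mm
#' @param n_sims number of simulated cases per run
#' @param seed master seed; per-case streams are derived from it
#' @param grid a [grid_spec()]
#' @param shape_kind `"sphere"` (default) or `"ellipsoid"` (axis ratios
#'   Uniform(0.8, 1.2))
#' @param registration_model `"single"` (default: the post-ablation image
#'   carries the axis-aligned registration displacement, the tumor stays
#'   put) or `"paired"` (both images carry independent displacements whose
#'   net relative shift lands on the ablation mask)
#' @param seg_noise_model `"composite"` (default; fixed Gaussian
#'   inter-observer offset plus a bounded uniform component scaling with
#'   the nominal error) or `"gaussian"` (offsets
#'   `Normal(0, segmentation_sd_mm)`)
#' @param seg_fixed_sd_mm standard deviation (mm) of the fixed Gaussian
#'   segmentation offset component of the composite model
#' @param seg_error_scale half-width of the bounded uniform segmentation
#'   offset component, per mm of `segmentation_sd_mm`
#' @return an object of class `sim_params`
#' @export
sim_params <- function(shrinkage_mean = 0,
                       satellite_prob = 0,
                       registration_sd_mm = 1,
                       segmentation_sd_mm = 1,
                       slice_thickness_mm = 1,
                       tumor_range_mm = c(10, 30),
                       margin_range_mm = c(-5, 10),
                       n_sims = 1000L,
                       seed = 1L,
                       grid = default_grid(),
                       shape_kind = c("sphere", "ellipsoid"),
                       registration_model = c("single", "paired"),
                       seg_noise_model = c("composite", "gaussian"),
                       seg_fixed_sd_mm = 0.9,
                       seg_error_scale = 0.66) {
  shape_kind <- match.arg(shape_kind)
  registration_model <- match.arg(registration_model)
  seg_noise_model <- match.arg(seg_noise_model)
  stopifnot(
    seg_fixed_sd_mm >= 0, seg_error_scale >= 0,
    shrinkage_mean >= 0, shrinkage_mean < 1,
    satellite_prob >= 0, satellite_prob <= 1,
    registration_sd_mm >= 0, segmentation_sd_mm >= 0,
    slice_thickness_mm >= grid$spacing[3],
    length(tumor_range_mm) == 2, tumor_range_mm[1] <= tumor_range_mm[2],
    tumor_range_mm[1] > 0,
    length(margin_range_mm) == 2, margin_range_mm[1] <= margin_range_mm[2],
    n_sims >= 0
  )
  p <- structure(list(
    shrinkage_mean = shrinkage_mean,
    satellite_prob = satellite_prob,
    registration_sd_mm = registration_sd_mm,
    segmentation_sd_mm = segmentation_sd_mm,
    slice_thickness_mm = slice_thickness_mm,
    tumor_range_mm = as.numeric(tumor_range_mm),
    margin_range_mm = as.numeric(margin_range_mm),
    n_sims = as.integer(n_sims),
    seed = as.integer(seed),
    grid = grid,
    shape_kind = shape_kind,
    registration_model = registration_model,
    seg_noise_model = seg_noise_model,
    seg_fixed_sd_mm = seg_fixed_sd_mm,
    seg_error_scale = seg_error_scale
  ), class = "sim_params")
  assert_grid_fits(grid, p)
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_params> shrink %.2f | satellite %.2f | reg %.1f mm | ",
           "seg %.1f mm | slice %.1f mm | n = %d | seed = %d\n"),
    x$shrinkage_mean, x$satellite_prob, x$registration_sd_mm,
    x$segmentation_sd_mm, x$slice_thickness_mm, x$n_sims, x$seed))
  invisible(x)
}

#' Simulate a single case through the full measurement pipeline
#'
#' Executes, in order: sample the case geometry; rasterize the concentric
#' tumor/ablation pair; apply tissue shrinkage and a possible satellite
#' lesion to obtain the biologically true tumor; measure the true MAM
#' against the ablation zone; then apply registration shift (ablation),
#' segmentation boundary noise (both masks) and slice-thickness
#' resampling (both masks) to the imaged pair and measure the observed
#' MAM. Biological effects touch only the true tumor; technical errors
#' touch only the imaged masks. Uses R's global random number generator.
#'
#' @param params a [sim_params()] object
#' @return a one-row data frame (one `SimulationRecord`)
#' @export
run_simulation <- function(params) {
  rec <- run_case(params)
  as.data.frame(rec[record_fields()], stringsAsFactors = FALSE)
}

# one case as a plain list (cheap); redraws on geometry failure
run_case <- function(params) {
  for (attempt in 1:20) {
    rec <- tryCatch(run_simulation_once(params),
                    mamsim_geometry_error = function(e) NULL)
    if (!is.null(rec)) {
      rec$redraws <- attempt - 1L
      return(rec)
    }
  }
  stop("case redraw limit reached; grid too small for these parameters",
       call. = FALSE)
}

record_fields <- function() {
  c("d_tumor_mm", "margin_target_mm", "mam_true_mm", "mam_observed_mm",
    "covered_true", "e_mag_mm", "e_dir", "e_tumor_mm", "e_ablation_mm",
    "shrink_frac", "satellite", "d_satellite_mm")
}

run_simulation_once <- function(params) {
  geom <- sample_case(params)
  draws <- draw_errors(params)

  # feasibility on the configured grid, then a trimmed per-case grid on
  # the same voxel lattice (even voxel count keeps the centre phase), so
  # distance transforms and rasterizations touch fewer voxels
  v <- registration_vector(draws)
  r_t <- geom$d_tumor / 2 * max(geom$ellipsoid_axis_ratio)
  r_a <- max(r_t + geom$margin_target, 0)
  need <- max(r_t + 2 * draws$d_satellite,
              r_a + sqrt(sum(v^2)) + max(draws$e_ablation_offset, 0),
              r_t + max(draws$e_tumor_offset, 0)) + 2
  shape <- 2L * as.integer(ceiling(need / params$grid$spacing + 1))
  shape <- shape + (shape - params$grid$shape) %% 2L # match lattice phase
  shape <- pmin(shape, params$grid$shape)
  case_grid <- grid_spec(shape, params$grid$spacing)

  masks <- rasterize_case(geom, case_grid)

  # biologically true tumor: shrinkage then satellite
  tumor_true <- apply_shrinkage(masks$tumor, draws$e_shrinkage)
  tumor_true <- add_satellite(tumor_true, draws$p_satellite_draw,
                              draws$d_satellite)
  mam_true <- compute_mam(tumor_true, masks$ablation)

  # technical errors on the imaged pair; the net relative registration
  # displacement of the two image spaces lands on the ablation mask
  abl_obs <- apply_registration_shift(masks$ablation, draws$e_mag,
                                      draws$e_dir)
  if (draws$e_mag_pre != 0)
    abl_obs <- apply_registration_shift(abl_obs, -draws$e_mag_pre,
                                        draws$e_dir_pre)
  tum_obs <- apply_segmentation_noise(masks$tumor, draws$e_tumor_offset)
  abl_obs <- apply_segmentation_noise(abl_obs, draws$e_ablation_offset)
  if (params$slice_thickness_mm > params$grid$spacing[3]) {
    tum_obs <- resample_slice_thickness(tum_obs, params$slice_thickness_mm)
    abl_obs <- resample_slice_thickness(abl_obs, params$slice_thickness_mm)
  }
  mam_obs <- if (mask_volume(tum_obs) == 0L) {
    # segmentation erosion removed the tumor entirely: no measurable
    # margin; record a deeply negative observation
    margin_result(-max(params$tumor_range_mm), FALSE, 0L)
  } else {
    compute_mam(tum_obs, abl_obs)
  }

  list(
    d_tumor_mm = geom$d_tumor,
    margin_target_mm = geom$margin_target,
    mam_true_mm = mam_true$mam,
    mam_observed_mm = mam_obs$mam,
    covered_true = mam_true$mam > 0,
    e_mag_mm = sqrt(sum(registration_vector(draws)^2)),
    e_dir = draws$e_dir,
    e_tumor_mm = draws$e_tumor_offset,
    e_ablation_mm = draws$e_ablation_offset,
    shrink_frac = draws$e_shrinkage,
    satellite = draws$p_satellite_draw,
    d_satellite_mm = draws$d_satellite
  )
}

#' Run a batch of simulations with reproducible per-case seeding
#'
#' Each case re-seeds R's generator from a stream derived from
#' `(params$seed, case index)`, so results are bit-reproducible and
#' independent of execution order.
#'
#' @param params a [sim_params()] object
#' @param progress print a dot every 500 cases
#' @return data frame of `n_sims` records; total redraw count in
#'   `attr(, "n_redraws")`
#' @export
run_simulations <- function(params, progress = FALSE) {
  n <- params$n_sims
  if (n == 0L) return(empty_records())
  seeds <- case_seeds(params$seed, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    out[[i]] <- run_case(params)
    if (progress && i %% 500 == 0) cat(".")
  }
  if (progress) cat("\n")
  fields <- record_fields()
  recs <- as.data.frame(
    lapply(stats::setNames(fields, fields), function(f)
      unlist(lapply(out, `[[`, f), use.names = FALSE)),
    stringsAsFactors = FALSE)
  attr(recs, "n_redraws") <- sum(vapply(out, `[[`, 0L, "redraws"))
  recs
}

# per-case seed streams: deterministic function of (master seed, index),
# kept inside the 32-bit integer range
case_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

empty_records <- function() {
  data.frame(d_tumor_mm = numeric(0), margin_target_mm = numeric(0),
             mam_true_mm = numeric(0), mam_observed_mm = numeric(0),
             covered_true = logical(0), e_mag_mm = numeric(0),
             e_dir = character(0), e_tumor_mm = numeric(0),
             e_ablation_mm = numeric(0), shrink_frac = numeric(0),
             satellite = logical(0), d_satellite_mm = numeric(0),
             stringsAsFactors = FALSE)
}

#' One-factor parameter sweep
#'
#' Runs `params$n_sims` simulations at each value of one parameter, all
#' other parameters held at `base`, and fits the A0 estimate per value.
#' Each sweep point gets its own deterministic seed derived from the
#' master seed and the point index.
#'
#' @param base a [sim_params()] object (the baseline)
#' @param vary one of `"shrinkage_mean"`, `"satellite_prob"`,
#'   `"registration_sd_mm"`, `"segmentation_sd_mm"`, `"slice_thickness_mm"`
#' @param values numeric vector of parameter values
#' @param filter_reg_mm optional registration cutoff passed to
#'   [estimate_a0()]
#' @return list of class `sweep_result_list`; each element has `params`,
#'   `estimate`, `records`
#' @export
run_sweep <- function(base, vary, values, filter_reg_mm = NULL) {
  vary <- match.arg(vary, c("shrinkage_mean", "satellite_prob",
                            "registration_sd_mm", "segmentation_sd_mm",
                            "slice_thickness_mm"))
  out <- vector("list", length(values))
  for (i in seq_along(values)) {
    p <- base
    p[[vary]] <- values[i]
    p$seed <- derive_seed(base$seed, i)
    p <- do.call(sim_params, unclass(p))
    recs <- run_simulations(p)
    est <- if (nrow(recs) > 0)
      estimate_a0(recs, filter_reg_mm = filter_reg_mm)
    out[[i]] <- list(params = p, vary = vary, value = values[i],
                     estimate = est, records = recs)
  }
  structure(out, class = "sweep_result_list", vary = vary, values = values)
}

# deterministic sub-seed below 2^31
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 69069 + index * 10007) %% 2147483647)
}

#' Two-way A0 grid over segmentation and registration error
#'
#' Full Cartesian product of the given segmentation and registration
#' error values; per cell, `base$n_sims` simulations and an A0 fit.
#'
#' @param base baseline [sim_params()]
#' @param seg_values segmentation error values (mm)
#' @param reg_values registration error values (mm)
#' @return object of class `a0_grid`: matrix `x_a0` (rows = segmentation,
#'   columns = registration), list `estimates`, data frame `table`
#' @export
run_grid <- function(base, seg_values, reg_values) {
  m <- matrix(NA_real_, length(seg_values), length(reg_values),
              dimnames = list(paste0("seg", seg_values),
                              paste0("reg", reg_values)))
  ests <- list()
  rows <- list()
  k <- 0L
  for (i in seq_along(seg_values)) {
    for (j in seq_along(reg_values)) {
      k <- k + 1L
      p <- base
      p$segmentation_sd_mm <- seg_values[i]
      p$registration_sd_mm <- reg_values[j]
      p$seed <- derive_seed(base$seed, 1000L + k)
      p <- do.call(sim_params, unclass(p))
      recs <- run_simulations(p)
      est <- estimate_a0(recs)
      m[i, j] <- est$x_a0
      ests[[k]] <- est
      rows[[k]] <- data.frame(segmentation_sd_mm = seg_values[i],
                              registration_sd_mm = reg_values[j],
                              x_a0 = est$x_a0,
                              p_coverage_at_5mm = est$p_coverage_at_5mm,
                              n_used = est$n_used)
    }
  }
  structure(list(x_a0 = m, estimates = ests,
                 table = do.call(rbind, rows)),
            class = "a0_grid")
}

#' Enumerate study parameter permutations in chunks
#'
#' Builds the Cartesian product of the study parameter sets and assigns
#' chunk identifiers, so a large campaign can be split across processes.
#'
#' @param shrinkage,satellite,registration,segmentation,slice value sets
#' @param chunk_size permutations per chunk
#' @return data frame with one row per permutation and a `chunk` column
#' @export
enumerate_permutations <- function(shrinkage = c(0, .1, .2, .3),
                                   satellite = c(0, .25, .5, .75, 1),
                                   registration = 1:5,
                                   segmentation = 1:5,
                                   slice = 1:5,
                                   chunk_size = 100L) {
  g <- expand.grid(shrinkage_mean = shrinkage, satellite_prob = satellite,
                   registration_sd_mm = registration,
                   segmentation_sd_mm = segmentation,
                   slice_thickness_mm = slice,
                   KEEP.OUT.ATTRS = FALSE)
  g$chunk <- (seq_len(nrow(g)) - 1L) %/% chunk_size + 1L
  g
}
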