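# synthetic cohort generator: sampling, voxelization, strength model

test_that("cohort sampling honors counts, determinism, and calibration targets", {
  spec <- default_cohort_spec(0, 0)
  expect_equal(nrow(sample_cohort(spec, 1)), 0)

  spec2 <- default_cohort_spec(5, 3)
  d1 <- sample_cohort(spec2, 11)
  d2 <- sample_cohort(spec2, 11)
  expect_identical(d1, d2)
  expect_equal(sum(d1$sex == 0), 5)
  expect_equal(sum(d1$sex == 1), 3)
  expect_true(all(d1$age >= 18))
  # geometry invariants hold for every sampled donor
  for (i in seq_len(nrow(d1)))
    expect_lt(d1$cortical_thickness_mm[i],
              min(1, d1$ap_si_ratio[i]) * d1$fnw_mm[i] / 2)

  # mean-calibrated truncated normal: female mean age ~ 67.8 despite the
  # asymmetric 24-97 bounds
  big <- sample_cohort(default_cohort_spec(1000, 0), 7)
  se <- sd(big$age) / sqrt(1000)
  expect_lt(abs(mean(big$age) - 67.8), 2 * se)
})

test_that("cohort specs round-trip through YAML", {
  spec <- default_cohort_spec(10, 12)
  path <- tempfile(fileext = ".yaml")
  write_cohort_spec(spec, path)
  spec2 <- read_cohort_spec(path)
  expect_equal(unclass(spec2), unclass(spec), tolerance = 1e-12)
  expect_identical(sample_cohort(spec2, 5), sample_cohort(spec, 5))
  unlink(path)
})

test_that("invalid cohort specs fail with the offending field named", {
  spec <- default_cohort_spec()
  spec$age$female$sd <- -1
  expect_error(sample_cohort(spec, 1), "age\\$female")
  spec <- default_cohort_spec()
  spec$bvtv$male$lower <- 0.9
  expect_error(sample_cohort(spec, 1), "bvtv\\$male")
})

test_that("voxelized annulus matches the closed-form shell volume", {
  # circular tube D = 20 mm, t = 2 mm at 50 um voxels
  v <- annulus_phantom(d_mm = 20, t_mm = 2, L_mm = 2, h = 0.05)
  truth <- pi * 2 * (20 - 2) * 2 / 0.05^3
  expect_rel_error(sum(v$data == 1L), truth, 0.02)
  expect_equal(sum(v$data == 2L), 0)  # bvtv 0 -> empty interior
})

test_that("ap_si_ratio = 1 reproduces the circular geometry voxel-for-voxel", {
  a <- annulus_phantom(ratio = 1, bvtv = 0.2, seed = 5)
  b <- build_fn_volume(
    fn_geometry(neck_length = 2, si_outer_diameter = 20, ap_si_ratio = 1,
                cortical_thickness = 2, trabecular_bvtv = 0.2),
    voxel_size = 0.25, seed = 5)
  expect_identical(a$data, b$data)
})

test_that("trabecular fill hits the BV/TV target and resolution is enforced", {
  v <- annulus_phantom(bvtv = 0.3, seed = 9)
  interior <- sum(v$data == 2L) /
    (sum(v$data == 2L) + sum(v$data == 0L & (EBImage::fillHull(
      array((v$data > 0) * 1, dim(v$data))) > 0.5)))
  expect_lt(abs(interior - 0.3), 0.01)
  # rods pattern also hits the target
  vr <- annulus_phantom(bvtv = 0.3, seed = 9, pattern = "rods")
  expect_lt(abs(volume_properties(vr)$bvtv - 0.3), 0.01)
  expect_error(
    build_fn_volume(fn_geometry(cortical_thickness = 1), voxel_size = 0.6),
    "too coarse")
})

test_that("cortical voxel count converges to the annulus volume as voxels shrink", {
  truth <- pi * 2 * (20 - 2) * 1 # per mm of length
  err <- vapply(c(0.2, 0.1), function(h) {
    v <- annulus_phantom(d_mm = 20, t_mm = 2, L_mm = 1, h = h)
    abs(sum(v$data == 1L) * h^3 - truth) / truth
  }, numeric(1))
  expect_lt(err[2], 0.75 * err[1])
})

test_that("strength model: exact intercept, named-trait errors, offset recovery", {
  co <- list(intercept = 1234, cortical = 21.8, trabecular = 29.3,
             area = -281, age = -6, sex_offset = 0, pyd = 0, noise_sd = 0)
  tr <- data.frame(bmc_cortical = 0, bmc_trabecular = 0, area_cm2 = 0)
  cv <- data.frame(sex = 0, age = 0, pyd = 0)
  expect_equal(synthesize_strength(tr, cv, co), 1234)
  expect_error(synthesize_strength(tr[, -1, drop = FALSE], cv, co),
               "bmc_cortical")
  # defaults carry the published multivariable slopes
  def <- default_cohort_spec()$strength
  expect_equal(def$cortical, 21.8)
  expect_equal(def$trabecular, 29.3)

  # Monte-Carlo recovery of an injected sex offset with matched covariates
  n <- 2000
  withr::with_seed(3, {
    tr <- data.frame(bmc_cortical = rnorm(n, 90, 20),
                     bmc_trabecular = rnorm(n, 70, 20),
                     area_cm2 = rnorm(n, 5, 0.3))
    cv <- data.frame(sex = rep(0:1, each = n / 2), age = rnorm(n, 65, 10),
                     pyd = rnorm(n, 2, 0.5))
  })
  co$sex_offset <- 600
  co$noise_sd <- 800
  s <- synthesize_strength(tr, cv, co, seed = 4)
  fit <- lm(s ~ sex + bmc_cortical + bmc_trabecular + area_cm2 + age + pyd,
            data = cbind(tr, cv))
  est <- coef(summary(fit))["sex", ]
  expect_lt(abs(est["Estimate"] - 600), 2 * est["Std. Error"])
})

test_that("generated cohorts are deterministic and regenerable from donor seeds", {
  spec <- default_cohort_spec(4, 3)
  c1 <- generate_cohort(spec, seed = 21, mode = "voxel", voxel_size_mm = 0.3)
  c2 <- generate_cohort(spec, seed = 21, mode = "voxel", voxel_size_mm = 0.3)
  expect_equal(c1, c2, ignore_attr = TRUE)

  # volume regeneration from the stored per-donor seed is exact
  row <- c1[2, ]
  g <- fn_geometry(neck_length = row$neck_length_mm,
                   si_outer_diameter = row$fnw_mm,
                   ap_si_ratio = row$ap_si_ratio,
                   cortical_thickness = row$cortical_thickness_mm,
                   trabecular_bvtv = row$bvtv_target)
  v1 <- build_fn_volume(g, 0.3, seed = row$donor_seed)
  v2 <- build_fn_volume(g, 0.3, seed = row$donor_seed)
  expect_identical(v1$data, v2$data)

  # missing-strength flagging off -> no flagged donors
  spec$missing_strength_frac[] <- 0
  c3 <- generate_cohort(spec, seed = 21, mode = "analytic")
  expect_equal(sum(c3$strength_missing), 0)
})

test_that("analytic and voxel parameter paths agree within voxelization error", {
  spec <- default_cohort_spec(6, 6)
  spec$missing_strength_frac[] <- 0
  dv <- generate_cohort(spec, seed = 31, mode = "voxel", voxel_size_mm = 0.25)
  da <- generate_cohort(spec, seed = 31, mode = "analytic")
  for (v in c("area_cm2", "bmc", "abmd", "bmc_cortical", "bmc_trabecular",
              "ttar_cm2", "ttvol_cm3", "i_si_cm4", "i_ap_cm4", "bmc_ttar"))
    expect_lt(max(abs(dv[[v]] - da[[v]]) / abs(da[[v]])), 0.05)
})

test_that("calibrated cohorts reproduce the direction of every sex difference", {
  d <- generate_cohort(default_cohort_spec(200, 200), seed = 12,
                       mode = "analytic")
  f <- d$sex == 0
  expect_gt(mean(d$strength[!f], na.rm = TRUE), mean(d$strength[f], na.rm = TRUE))
  for (v in c("area_cm2", "bmc", "abmd"))
    expect_gt(mean(d[[v]][!f]), mean(d[[v]][f]))
  expect_gt(mean(d$pct_cortical[f]), mean(d$pct_cortical[!f]))
  # female mean area within 2 SE of the 4.70 cm2 calibration target
  se <- sd(d$area_cm2[f]) / sqrt(sum(f))
  expect_lt(abs(mean(d$area_cm2[f]) - 4.70), 2 * se)
})
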