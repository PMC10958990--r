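# section/volume properties, closed forms, idealized-geometry analysis

test_that("closed-form annulus properties match textbook values and a grid oracle", {
  # solid circle R = 1 cm
  s <- annulus_section_props(1, 1, 1)
  expect_equal(s$ct_ar_cm2, pi)
  expect_equal(s$i_ap_cm4, pi / 4)
  expect_equal(s$i_si_cm4, pi / 4)

  # circular annulus R = 1, t = 0.5: verify against 2D numerical integration
  a <- annulus_section_props(1, 1, 0.5)
  expect_equal(a$ct_ar_cm2, pi * 0.75)
  expect_equal(a$i_ap_cm4, pi / 4 * (1 - 0.5^4))
  hh <- 1 / 400
  gx <- seq(-1 + hh / 2, 1 - hh / 2, by = hh)
  gr2 <- outer(gx^2, gx^2, "+")
  ring <- gr2 <= 1 & gr2 > 0.25
  expect_rel_error(sum(ring) * hh^2, a$ct_ar_cm2, 1e-3)
  ii <- sum(outer(gx^2, rep(1, length(gx)))[ring]) * hh^2
  expect_rel_error(ii, a$i_ap_cm4, 1e-3)

  # b_ap = a_si reduces exactly to circular formulas; ordering for ellipses
  e <- annulus_section_props(1.2, 0.9, 0.3)
  expect_gt(e$i_ap_cm4, e$i_si_cm4)   # AP < SI -> I_SI < I_AP
  expect_error(annulus_section_props(1, 0.5, 0.8), "thickness")
})

test_that("voxel section properties converge to the closed forms", {
  truth <- annulus_section_props(1, 1, 0.2)   # R = 10 mm, t = 2 mm in cm
  err <- sapply(c(0.1, 0.05), function(h) {
    v <- annulus_phantom(d_mm = 20, t_mm = 2, L_mm = 3 * h, h = h)
    s <- section_properties(v)$summary
    c(ct = abs(s$ctar_cm2 - truth$ct_ar_cm2) / truth$ct_ar_cm2,
      isi = abs(s$i_si_cm4 - truth$i_si_cm4) / truth$i_si_cm4,
      iap = abs(s$i_ap_cm4 - truth$i_ap_cm4) / truth$i_ap_cm4,
      sym = abs(s$i_si_cm4 - s$i_ap_cm4) / truth$i_si_cm4)
  })
  expect_lt(max(err["ct", 2], err["isi", 2], err["iap", 2]), 0.01)
  expect_lt(err["sym", 2], 0.005)     # circular symmetry
  # circularity = 1 up to one-voxel quantization
  v <- annulus_phantom(d_mm = 20, t_mm = 2, L_mm = 0.3, h = 0.1)
  expect_lt(abs(section_properties(v)$summary$circularity - 1), 0.1 / 10)

  # ellipse with AP < SI: circularity < 1 and I_SI < I_AP
  ve <- annulus_phantom(d_mm = 20, t_mm = 2, L_mm = 1, h = 0.25, ratio = 0.8)
  se <- section_properties(ve)$summary
  expect_lt(se$circularity, 1)
  expect_lt(se$i_si_cm4, se$i_ap_cm4)
})

test_that("volume properties: shell-only, BV/TV round-trip, prism identity", {
  shell <- annulus_phantom(d_mm = 14, t_mm = 2, L_mm = 2, h = 0.25, bvtv = 0)
  vp <- volume_properties(shell)
  expect_equal(vp$pct_cortical, 100)

  filled <- annulus_phantom(d_mm = 14, t_mm = 2, L_mm = 3, h = 0.25, bvtv = 0.30,
                            seed = 12)
  expect_lt(abs(volume_properties(filled)$bvtv - 0.30), 0.01)

  # prismatic tube: Tt.Vol = slice-average Tt.Ar x length exactly
  sp <- section_properties(filled)$summary
  L_cm <- dim(filled$data)[3] * filled$spacing / 10
  expect_equal(volume_properties(filled)$ttvol_cm3, sp$ttar_cm2 * L_cm)
})

test_that("idealized-geometry fit predicts each gain from the other two", {
  fit1 <- shape_gain_predict(c(bmc = 12, ixx = 18), predict = "iyy")
  expect_lt(abs(fit1$predicted - 54), 1)
  fit2 <- shape_gain_predict(c(bmc = 12, iyy = 54), predict = "ixx")
  expect_lt(abs(fit2$predicted - 18), 1)
  fit3 <- shape_gain_predict(c(ixx = 18, iyy = 54), predict = "bmc")
  expect_lt(abs(fit3$predicted - 12), 1)
  # fitted geometry is a valid elliptical annulus
  expect_true(fit1$ap_si_ratio > 0 && fit1$ap_si_ratio < 1)
  expect_true(fit1$thickness_ratio > 0 &&
              fit1$thickness_ratio < fit1$ap_si_ratio)
  # degenerate: identical shapes
  expect_equal(shape_gain_predict(c(bmc = 0, ixx = 0), predict = "iyy")$predicted, 0)
  expect_error(shape_gain_predict(c(bmc = 90, ixx = 2), predict = "iyy"),
               "infeasibility")
})

test_that("size-adjusted BMC modes and units", {
  p <- data.frame(bmc = 100, area_cm2 = 4, fnw_avg_cm = 2, ttar_cm2 = 5)
  expect_equal(size_adjusted_bmc(p, "area"), 100 / 8)      # area^1.5
  expect_equal(size_adjusted_bmc(p, "area", exponent = 1), 100 / 4)  # = aBMD
  expect_equal(size_adjusted_bmc(p, "fnw"), 50)
  expect_equal(size_adjusted_bmc(p, "ttar"), 20)
  expect_error(size_adjusted_bmc(data.frame(bmc = 1, ttar_cm2 = 0), "ttar"),
               "non-positive")
})

test_that("Tt.Ar- and Tt.Vol-adjusted BMC are interchangeable on prisms", {
  d <- generate_cohort(default_cohort_spec(100, 100), seed = 17,
                       mode = "analytic")
  bmc_ttvol <- d$bmc / d$ttvol_cm3
  expect_gt(cor(d$bmc_ttar, bmc_ttvol), 0.99)
})
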