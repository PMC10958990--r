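#' Run the full simulated study
#'
#' Executes the study pipeline end to end: generate a calibrated cohort,
#' exclude strength-missing donors from strength analyses, age-adjust all
#' analysis variables to 65 years within sex, and produce
#' (1) a descriptive table (per-sex mean, SD, range, pooled t-test p),
#' (2) an elevation table comparing the strength regressions on BMC and on
#' every size-adjusted BMC measure (per-sex midpoint elevations with 95
#' percent CIs, difference, percent-of-mean difference, ANCOVA slope and
#' elevation p-values),
#' (3) the menu of structure regressions (per-sex slope, R2, p plus ANCOVA
#' tests) relating mass, volume, shape and compartment measures, and
#' (4) four nested multivariable strength models with VIF screening.
#' Everything is deterministic given the master seed.
#'
#' @param spec a `cohort_spec` (default [default_cohort_spec()]).
#' @param seed master seed.
#' @param mode cohort realization mode, `"analytic"` or `"voxel"`.
#' @param voxel_size_mm working voxel size for `mode = "voxel"`.
#' @param age_adjusted apply the age adjustment before the regressions
#'   (the primary analysis); set `FALSE` for an unadjusted sensitivity pass.
#' @return an object of class `study_report`: list with `table1`, `table2`,
#'   `regressions`, `table3`, `donors`, `manifest`.
#' @export
run_study <- function(spec = default_cohort_spec(), seed = 1L,
                      mode = c("analytic", "voxel"), voxel_size_mm = 0.25,
                      age_adjusted = TRUE) {
  mode <- match.arg(mode)
  donors <- generate_cohort(spec, seed = seed, mode = mode,
                            voxel_size_mm = voxel_size_mm)
  if (nrow(donors) == 0L) stop("empty cohort: config requested zero donors")
  sexf <- factor(ifelse(donors$sex == 0L, "female", "male"),
                 levels = c("female", "male"))

  # ---- per-sex descriptive table ---------------------------------------
  t1_vars <- c(age = "Age (years)", strength = "Strength (N)",
               area_cm2 = "pseudoDXA area (cm2)",
               bmc = "pseudoDXA BMC (1e6 voxels)",
               abmd = "pseudoDXA aBMD (1e6 voxels/cm2)",
               bmc_cortical = "pseudoDXA BMC-cortical (1e6 voxels)",
               bmc_trabecular = "pseudoDXA BMC-trabecular (1e6 voxels)",
               pct_cortical = "% bone voxels cortical")
  table1 <- do.call(rbind, lapply(names(t1_vars), function(v) {
    x <- donors[[v]]
    fx <- x[sexf == "female" & is.finite(x)]
    mx <- x[sexf == "male" & is.finite(x)]
    tt <- group_t_test(fx, mx)
    data.frame(measure = t1_vars[[v]], variable = v,
               female_mean = mean(fx), female_sd = sd(fx),
               female_min = min(fx), female_max = max(fx),
               male_mean = mean(mx), male_sd = sd(mx),
               male_min = min(mx), male_max = max(mx),
               p = tt$p, row.names = NULL)
  }))

  # ---- age adjustment ---------------------------------------------------
  adj_vars <- c("strength", "area_cm2", "bmc", "abmd", "bmc_cortical",
                "bmc_trabecular", "pct_cortical", "ttar_cm2", "ttvol_cm3",
                "i_si_cm4", "i_ap_cm4", "circularity", "bmc_fnw",
                "bmc_area15", "bmc_ttar")
  adj <- if (age_adjusted)
    age_adjust(donors, adj_vars, target_age = 65, by_group = "sex")
  else donors

  with_strength <- !adj$strength_missing

  # ---- strength-regression elevation table -----------------------------
  t2_defs <- list(
    c("Strength vs BMC", "bmc"),
    c("Strength vs BMC/FNW", "bmc_fnw"),
    c("Strength vs BMC/Area (aBMD)", "abmd"),
    c("Strength vs BMC/Area^1.5", "bmc_area15"),
    c("Strength vs BMC/TtAr", "bmc_ttar"))
  table2_fits <- lapply(t2_defs, function(d) {
    ancova_compare(adj[[d[2]]][with_strength],
                   adj$strength[with_strength], sexf[with_strength])
  })
  names(table2_fits) <- vapply(t2_defs, `[`, character(1), 1)
  table2 <- do.call(rbind, lapply(seq_along(t2_defs), function(i) {
    an <- table2_fits[[i]]
    e <- an$elevations
    data.frame(regression = t2_defs[[i]][1], x_variable = t2_defs[[i]][2],
               female = e$elevation[1], female_lo = e$lo[1], female_hi = e$hi[1],
               male = e$elevation[2], male_lo = e$lo[2], male_hi = e$hi[2],
               difference = an$elevation_diff, pct_difference = an$pct_diff,
               slope_p = an$slope_p, elevation_p = an$elevation_p,
               row.names = NULL)
  }))

  # ---- structure regression menu ---------------------------------------
  reg_defs <- list(
    c("Strength vs aBMD", "abmd", "strength"),
    c("Strength vs BMC", "bmc", "strength"),
    c("BMC vs TtVol", "ttvol_cm3", "bmc"),
    c("BMC-cortical vs TtVol", "ttvol_cm3", "bmc_cortical"),
    c("BMC-trabecular vs TtVol", "ttvol_cm3", "bmc_trabecular"),
    c("TtVol vs area", "area_cm2", "ttvol_cm3"),
    c("I_AP vs area", "area_cm2", "i_ap_cm4"),
    c("I_SI vs area", "area_cm2", "i_si_cm4"),
    c("Circularity vs area", "area_cm2", "circularity"),
    c("BMC-cortical vs BMC", "bmc", "bmc_cortical"),
    c("BMC-trabecular vs BMC", "bmc", "bmc_trabecular"),
    c("PctCortical vs BMC", "bmc", "pct_cortical"))
  regressions <- do.call(rbind, lapply(reg_defs, function(d) {
    keep <- if (d[3] == "strength") with_strength else rep(TRUE, nrow(adj))
    x <- adj[[d[2]]][keep]; yv <- adj[[d[3]]][keep]; g <- sexf[keep]
    ff <- linear_fit(x[g == "female"], yv[g == "female"])
    fm <- linear_fit(x[g == "male"], yv[g == "male"])
    an <- ancova_compare(x, yv, g)
    data.frame(regression = d[1], x_variable = d[2], y_variable = d[3],
               female_slope = ff$slope, female_r2 = ff$r2, female_p = ff$p,
               male_slope = fm$slope, male_r2 = fm$r2, male_p = fm$p,
               ancova_slope_p = an$slope_p, ancova_elevation_p = an$elevation_p,
               row.names = NULL)
  }))

  # ---- nested multivariable models, raw (not age-adjusted) -------------
  ds <- donors[with_strength, ]
  model_defs <- list(
    `Model 1` = c("sex", "age", "abmd"),
    `Model 2` = c("sex", "age", "bmc", "area_cm2"),
    `Model 3` = c("sex", "age", "bmc_cortical", "bmc_trabecular", "area_cm2"),
    `Model 4` = c("sex", "age", "bmc_cortical", "bmc_trabecular", "area_cm2",
                  "pyd"))
  table3_fits <- lapply(model_defs, function(v)
    multivariable_fit(ds$strength, ds[v]))
  table3 <- do.call(rbind, lapply(names(model_defs), function(mn) {
    mm <- table3_fits[[mn]]
    cbind(model = mn, adj_r2 = mm$adj_r2, mm$terms)
  }))

  manifest <- c(attr(donors, "manifest"),
                list(age_adjusted = age_adjusted,
                     target_age = 65,
                     n_excluded_strength = sum(!with_strength),
                     package_version = as.character(
                       utils::packageVersion("pseudoDXA"))))

  structure(list(table1 = table1, table2 = table2, regressions = regressions,
                 table3 = table3, table2_fits = table2_fits,
                 table3_fits = table3_fits, donors = donors,
                 manifest = manifest),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  cohort: %d female, %d male (%d strength-missing), mode = %s, seed = %d\n",
              x$manifest$n[["female"]], x$manifest$n[["male"]],
              x$manifest$n_strength_missing, x$manifest$mode, x$manifest$seed))
  cat("  elevation table:\n")
  t2 <- x$table2
  for (i in seq_len(nrow(t2)))
    cat(sprintf("    %-28s diff = %6.0f N (%5.1f%%), slope p = %.3f, elevation p = %.2g\n",
                t2$regression[i], t2$difference[i], t2$pct_difference[i],
                t2$slope_p[i], t2$elevation_p[i]))
  invisible(x)
}

#' Export a study report to disk
#'
#' Writes `donors.csv`, `table1.csv`, `table2.csv`, `table3.csv`,
#' `regressions.csv`, and `manifest.json` (configuration, seeds, exclusion
#' counts, package version) into a directory.
#'
#' @param report a `study_report`.
#' @param directory output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
export_report <- function(report, directory) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) stop("cannot create directory: ", directory)
  }
  paths <- c(donors = "donors.csv", table1 = "table1.csv",
             table2 = "table2.csv", table3 = "table3.csv",
             regressions = "regressions.csv")
  written <- character()
  for (nm in names(paths)) {
    p <- file.path(directory, paths[[nm]])
    write.csv(report[[nm]], p, row.names = FALSE)
    written <- c(written, p)
  }
  mp <- file.path(directory, "manifest.json")
  jsonlite::write_json(report$manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(written, mp))
}

#' VOI-extraction reliability experiment
#'
#' Mirrors the repeated region-of-interest extraction reliability check:
#' a set of phantoms is built, the femoral-neck VOI of each is extracted
#' `k` times with sub-voxel jitter of the slab center, pseudoDXA area and
#' BMC are measured at each repeat, and the test-retest ICC(2,1) is
#' computed per measure.
#'
#' @param n_phantoms number of phantoms (subjects), >= 5.
#' @param k repeats per phantom.
#' @param jitter_mm SD of the Gaussian center jitter, mm (sub-voxel).
#' @param voxel_size_mm working voxel size.
#' @param seed integer seed.
#' @return list with `icc_area` and `icc_bmc`, each an [icc21()] result.
#' @export
voi_reliability_icc <- function(n_phantoms = 8, k = 3, jitter_mm = 0.1,
                                voxel_size_mm = 0.25, seed = 1L) {
  spec <- default_cohort_spec(n_female = n_phantoms, n_male = 0)
  donors <- sample_cohort(spec, seed = seed)
  area <- matrix(NA_real_, n_phantoms, k)
  bmc <- matrix(NA_real_, n_phantoms, k)
  jit <- withr::with_seed(derive_seed(seed, 7001L),
                          matrix(rnorm(n_phantoms * k, 0, jitter_mm),
                                 n_phantoms, k))
  for (i in seq_len(n_phantoms)) {
    geom <- donor_geometry(donors[i, ])
    geom$neck_length <- geom$neck_length + 4   # margin so the slab can shift
    vol <- build_fn_volume(geom, voxel_size = voxel_size_mm,
                           seed = donors$donor_seed[i])
    for (j in seq_len(k)) {
      voi <- extract_fn_voi(vol, width_mm = spec$neck_length_mm,
                            center_mm = dim(vol$data)[3] * voxel_size_mm / 2 +
                              jit[i, j])
      roi <- roi_params(project_pseudodxa(voi, "total"))
      area[i, j] <- roi$area_cm2
      bmc[i, j] <- roi$bmc
    }
  }
  list(icc_area = icc21(area), icc_bmc = icc21(bmc))
}
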