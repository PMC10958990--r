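#' Cross-sectional properties of a femoral-neck VOI
#'
#' For each slice perpendicular to the neck axis: total (periosteal) area
#' Tt.Ar from the hole-filled bone silhouette, cortical area Ct.Ar, the
#' centroid of the filled silhouette, rectangular second moments of area
#' about the centroidal axes (I_AP with distances measured
#' superior-inferior, I_SI with distances measured anterior-posterior,
#' summed over bone voxels), the AP and SI silhouette widths, and the
#' circularity AP width / SI width. Slices without bone are excluded with a
#' warning; slice averages are reported alongside the per-slice table.
#'
#' @param voi a label [fn_volume] with at least one bone voxel.
#' @return an object of class `section_props`: list with `per_slice`
#'   (data.frame) and `summary` (named list of slice-averaged `ttar_cm2`,
#'   `ctar_cm2`, `i_si_cm4`, `i_ap_cm4`, `ap_width_cm`, `si_width_cm`,
#'   `circularity`).
#' @export
section_properties <- function(voi) {
  stopifnot(inherits(voi, "fn_volume"))
  d <- dim(voi$data)
  hcm <- voi$spacing / 10                       # cm per voxel
  bone <- bone_mask(voi)
  if (!any(bone)) stop("no bone voxels in VOI")
  filled <- EBImage::fillHull(array(bone * 1, d)) > 0.5

  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  per <- lapply(seq_len(d[3]), function(k) {
    b <- bone[, , k]
    if (!any(b)) return(NULL)
    f <- filled[, , k]
    px <- rowSums(f) > 0                        # AP columns of silhouette
    py <- colSums(f) > 0                        # SI rows
    # centroid of the filled silhouette
    cx <- sum(xs * rowSums(f)) / sum(f)
    cy <- sum(ys * colSums(f)) / sum(f)
    idx <- which(b, arr.ind = TRUE)
    i_ap <- sum(((idx[, 2] - cy) * hcm)^2) * hcm^2   # distances SI
    i_si <- sum(((idx[, 1] - cx) * hcm)^2) * hcm^2   # distances AP
    data.frame(slice = k,
               ttar_cm2 = sum(f) * hcm^2,
               ctar_cm2 = sum(voi$data[, , k] == 1L) * hcm^2,
               i_ap_cm4 = i_ap, i_si_cm4 = i_si,
               ap_width_cm = (max(xs[px]) - min(xs[px]) + 1L) * hcm,
               si_width_cm = (max(ys[py]) - min(ys[py]) + 1L) * hcm)
  })
  dropped <- sum(vapply(per, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " slice(s) without bone excluded from section properties")
  per <- do.call(rbind, per)
  per$circularity <- per$ap_width_cm / per$si_width_cm
  summ <- as.list(colMeans(per[, c("ttar_cm2", "ctar_cm2", "i_si_cm4",
                                   "i_ap_cm4", "ap_width_cm", "si_width_cm",
                                   "circularity")]))
  structure(list(per_slice = per, summary = summ), class = "section_props")
}

#' Volumetric properties of a femoral-neck VOI
#'
#' Tt.Vol is the sum of per-slice Tt.Ar times the slice thickness; BV/TV is
#' the trabecular voxel count divided by the interior (endosteal) volume,
#' where the interior is the filled periosteal silhouette minus the cortical
#' compartment; the cortical percentage is 100 x cortical / (cortical +
#' trabecular) voxels.
#'
#' @param voi a label [fn_volume].
#' @return list with `ttvol_cm3`, `bvtv`, `n_cortical`, `n_trabecular`,
#'   `n_interior`, `pct_cortical`.
#' @export
volume_properties <- function(voi) {
  stopifnot(inherits(voi, "fn_volume"))
  d <- dim(voi$data)
  hcm <- voi$spacing / 10
  bone <- bone_mask(voi)
  if (!any(bone)) stop("no bone voxels in VOI")
  filled <- EBImage::fillHull(array(bone * 1, d)) > 0.5
  n_c <- sum(voi$data == 1L)
  n_t <- sum(voi$data == 2L)
  n_interior <- sum(filled & voi$data != 1L)
  list(ttvol_cm3 = sum(filled) * hcm^3,
       bvtv = if (n_interior > 0) n_t / n_interior else NA_real_,
       n_cortical = n_c, n_trabecular = n_t, n_interior = n_interior,
       pct_cortical = 100 * n_c / (n_c + n_t))
}

#' Closed-form section properties of an elliptical annulus
#'
#' Outer ellipse with SI semi-axis `a_si` and AP semi-axis `b_ap`; inner
#' ellipse with both semi-axes reduced by the uniform thickness `t` (the
#' standard idealization of a uniform-thickness shell; true offset curves of
#' an ellipse are not ellipses). `t = min(a_si, b_ap)` gives a solid
#' section. Moments are about centroidal axes: `i_ap` integrates squared SI
#' distances, `i_si` squared AP distances.
#'
#' @param a_si,b_ap outer semi-axes, cm.
#' @param t shell thickness, cm, `0 < t <= min(a_si, b_ap)`.
#' @return list with `ct_ar_cm2`, `i_ap_cm4`, `i_si_cm4`.
#' @export
annulus_section_props <- function(a_si, b_ap, t) {
  if (t <= 0 || t > min(a_si, b_ap) + 1e-12)
    stop("thickness t must satisfy 0 < t <= min(a_si, b_ap)")
  ai <- max(a_si - t, 0); bi <- max(b_ap - t, 0)
  list(ct_ar_cm2 = pi * (a_si * b_ap - ai * bi),
       i_ap_cm4 = pi / 4 * (b_ap * a_si^3 - bi * ai^3),
       i_si_cm4 = pi / 4 * (a_si * b_ap^3 - ai * bi^3))
}

# percent-of-mean gains of a circular over an elliptical annulus with the
# same SI semi-axis (= 1) and same shell thickness
shape_gains <- function(q, tau) {
  ell <- annulus_section_props(1, q, tau)
  cir <- annulus_section_props(1, 1, tau)
  g <- function(c_, e_) 100 * (c_ - e_) / ((c_ + e_) / 2)
  c(bmc = g(cir$ct_ar_cm2, ell$ct_ar_cm2),
    ixx = g(cir$i_ap_cm4, ell$i_ap_cm4),
    iyy = g(cir$i_si_cm4, ell$i_si_cm4))
}

#' Idealized-geometry fit-and-predict analysis
#'
#' Compares two idealized cylindrical femoral necks with the same FN width
#' (SI outer diameter) and the same uniform cortical thickness: one circular,
#' one elliptical (narrower AP). Their percent-of-mean differences in BMC
#' (proportional to Ct.Ar), bending resistance about the horizontal axis
#' (Ixx, i.e. I_AP) and about the vertical axis (Iyy, i.e. I_SI) are all
#' determined by two dimensionless shape parameters: the AP/SI axis ratio of
#' the elliptical section and the thickness relative to the SI semi-axis.
#' Given any two of the percent gains, this function solves for the shape
#' parameters (root-finding tolerance 1e-6) and predicts the third.
#'
#' @param known named numeric vector with exactly two of `bmc`, `ixx`,
#'   `iyy`: the known percent gains of the circular over the elliptical
#'   section (percent-of-mean convention).
#' @param predict name of the remaining quantity to predict.
#' @return list with `predicted` (percent gain), `ap_si_ratio`, and
#'   `thickness_ratio` (thickness / SI semi-axis) of the fitted geometry.
#' @export
shape_gain_predict <- function(known, predict = c("iyy", "ixx", "bmc")) {
  predict <- match.arg(predict)
  if (length(known) != 2L || !all(names(known) %in% c("bmc", "ixx", "iyy")) ||
      predict %in% names(known))
    stop("`known` must name exactly two of bmc/ixx/iyy, excluding `predict`")
  if (all(known == 0))
    return(list(predicted = 0, ap_si_ratio = 1, thickness_ratio = NA_real_))
  kn <- names(known)
  objective <- function(th) {
    q <- th[1]; tau <- th[2]
    if (q <= 0 || q > 1 || tau <= 0 || tau >= q) return(c(1e6, 1e6))
    shape_gains(q, tau)[kn] - unname(known)
  }
  starts <- expand.grid(q = c(0.6, 0.75, 0.85, 0.95),
                        tau = c(0.1, 0.2, 0.35, 0.5))
  sol <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      pracma::fsolve(objective, as.numeric(starts[i, ]), tol = 1e-6),
      error = function(e) NULL)
    if (!is.null(fit) && max(abs(objective(fit$x))) < 1e-4) { sol <- fit$x; break }
  }
  if (is.null(sol) || sol[1] <= 0 || sol[1] > 1 || sol[2] <= 0 || sol[2] >= sol[1])
    stop("infeasibility error: no elliptical-annulus geometry matches the ",
         "stated percent gains")
  list(predicted = unname(shape_gains(sol[1], sol[2])[predict]),
       ap_si_ratio = sol[1], thickness_ratio = sol[2])
}

#' Size-adjusted BMC
#'
#' Divides BMC by one of the bone-size measures considered in the study:
#' the average FN width (units voxels/cm), the projected area raised to a
#' power (default 1.5, the stature-correction proposal; exponent 1 recovers
#' aBMD exactly; units voxels/cm^(2*exponent)), or the average total
#' cross-sectional area (voxels/cm2).
#'
#' @param params a list or one-row data.frame carrying `bmc` and the
#'   denominator fields `fnw_avg_cm`, `area_cm2`, `ttar_cm2` as needed.
#' @param mode `"fnw"`, `"area"`, or `"ttar"`.
#' @param exponent exponent applied to the area in `mode = "area"`.
#' @return the size-adjusted BMC value.
#' @export
size_adjusted_bmc <- function(params, mode = c("fnw", "area", "ttar"),
                              exponent = 1.5) {
  mode <- match.arg(mode)
  den <- switch(mode,
                fnw = params$fnw_avg_cm,
                area = params$area_cm2^exponent,
                ttar = params$ttar_cm2)
  if (is.null(den) || any(!is.finite(den)) || any(den <= 0))
    stop("size_adjusted_bmc: denominator for mode '", mode,
         "' missing or non-positive")
  params$bmc / den
}

#' Measure all femoral-neck parameters of a label VOI
#'
#' Runs the full measurement stage on one labelled VOI: pseudoDXA
#' projections per compartment, ROI parameters, FN widths, cross-sectional
#' and volumetric properties, and the size-adjusted BMC variants. BMC-type
#' outputs are expressed in units of 1e6 reference voxels so cohorts
#' simulated at different working voxel sizes are directly comparable
#' (default reference 27 um, the acquisition scale the calibration tables
#' are printed in): counts are scaled by `(spacing / reference_voxel_mm)^3`.
#'
#' @param voi a label [fn_volume].
#' @param reference_voxel_mm reference voxel edge length, mm.
#' @return one-row data.frame of FN parameters (see vignette for the column
#'   dictionary).
#' @export
measure_fn_volume <- function(voi, reference_voxel_mm = 0.027) {
  stopifnot(inherits(voi, "fn_volume"))
  vox_scale <- (voi$spacing / reference_voxel_mm)^3 / 1e6   # -> 1e6 ref voxels
  img_tot <- project_pseudodxa(voi, "total")
  img_cor <- project_pseudodxa(voi, "cortical")
  img_tra <- project_pseudodxa(voi, "trabecular")
  roi <- roi_params(img_tot)
  w <- fn_widths(img_tot)
  sp <- section_properties(voi)$summary
  vp <- volume_properties(voi)

  out <- data.frame(
    area_cm2 = roi$area_cm2,
    bmc = roi$bmc * vox_scale,
    abmd = roi$bmc * vox_scale / roi$area_cm2,
    bmc_cortical = sum(img_cor$counts) * vox_scale,
    bmc_trabecular = sum(img_tra$counts) * vox_scale,
    pct_cortical = vp$pct_cortical,
    fnw_avg_cm = w$fnw_avg_cm,
    fnw_min_cm = w$fnw_min_cm,
    ttar_cm2 = sp$ttar_cm2,
    ctar_cm2 = sp$ctar_cm2,
    ttvol_cm3 = vp$ttvol_cm3,
    bvtv = vp$bvtv,
    i_si_cm4 = sp$i_si_cm4,
    i_ap_cm4 = sp$i_ap_cm4,
    circularity = sp$circularity
  )
  out$bmc_fnw <- size_adjusted_bmc(out, "fnw")
  out$bmc_area15 <- size_adjusted_bmc(out, "area")
  out$bmc_ttar <- size_adjusted_bmc(out, "ttar")
  out
}
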