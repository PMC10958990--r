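#' Femoral-neck geometry specification
#'
#' Describes an idealized femoral neck as a straight elliptical-annulus tube:
#' an elliptical cortical shell of uniform thickness around a stochastic
#' trabecular interior. The superior-inferior (SI) outer diameter is the
#' ground-truth femoral-neck width (FNW); the anterior-posterior (AP) outer
#' width is `ap_si_ratio` times the SI width (the cross-sectional
#' circularity, 1 = circular, < 1 = elliptical with less out-of-plane bone).
#'
#' @param neck_length length of the tube along the neck axis, mm.
#' @param si_outer_diameter SI outer diameter (FNW ground truth), mm.
#' @param ap_si_ratio AP outer width / SI outer width (dimensionless,
#'   typically 0.7-1.2).
#' @param cortical_thickness uniform cortical shell thickness, mm; must be
#'   smaller than both outer semi-axes.
#' @param trabecular_bvtv target trabecular bone volume fraction (BV/TV) of
#'   the interior, in `[0, 1]`.
#' @param taper optional linear width variation along the neck axis,
#'   fraction per mm (0 = prismatic tube).
#' @return an object of class `fn_geometry`.
#' @export
fn_geometry <- function(neck_length = 15, si_outer_diameter = 31.3,
                        ap_si_ratio = 0.9, cortical_thickness = 1.2,
                        trabecular_bvtv = 0.13, taper = 0) {
  g <- list(neck_length = neck_length, si_outer_diameter = si_outer_diameter,
            ap_si_ratio = ap_si_ratio, cortical_thickness = cortical_thickness,
            trabecular_bvtv = trabecular_bvtv, taper = taper)
  if (any(!vapply(g, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1))))
    stop("all fn_geometry fields must be single finite numbers")
  if (neck_length <= 0 || si_outer_diameter <= 0 || cortical_thickness <= 0)
    stop("all lengths must be > 0")
  if (ap_si_ratio <= 0) stop("ap_si_ratio must be > 0")
  if (trabecular_bvtv < 0 || trabecular_bvtv > 1)
    stop("trabecular_bvtv must be in [0, 1]")
  semi_min <- min(1, ap_si_ratio) * si_outer_diameter / 2
  if (cortical_thickness >= semi_min)
    stop("cortical_thickness (", cortical_thickness,
         " mm) must be smaller than the smallest outer semi-axis (",
         round(semi_min, 3), " mm)")
  structure(g, class = "fn_geometry")
}

#' Build a voxelized femoral-neck label volume
#'
#' Voxelizes an [fn_geometry] on an isotropic grid. The cortical label forms
#' an elliptical-annulus tube (outer semi-axes from the SI/AP widths, inner
#' semi-axes reduced by the cortical thickness); the trabecular label fills
#' the interior either as a Bernoulli random field smoothed by one
#' morphological closing (`pattern = "stochastic"`) or as a regular lattice
#' of axis-aligned rods (`pattern = "rods"`). In both cases the realized
#' interior fill fraction is adjusted by random voxel flips to match
#' `trabecular_bvtv` exactly (well within the 1-percentage-point contract).
#'
#' @param geom an [fn_geometry].
#' @param voxel_size isotropic voxel size, mm; must not exceed half the
#'   cortical thickness so the shell is resolved.
#' @param seed integer seed; identical `(geom, voxel_size, seed)` give
#'   voxel-identical output.
#' @param pattern trabecular interior pattern, see above.
#' @param rod_spacing center-to-center rod spacing (mm) for `pattern="rods"`.
#' @return an [fn_volume] of kind `"label"` with labels {0,1,2}.
#' @export
build_fn_volume <- function(geom, voxel_size = 0.25, seed = 1L,
                            pattern = c("stochastic", "rods"),
                            rod_spacing = 2) {
  stopifnot(inherits(geom, "fn_geometry"))
  pattern <- match.arg(pattern)
  h <- voxel_size
  if (h <= 0) stop("voxel_size must be > 0")
  if (h > geom$cortical_thickness / 2)
    stop("voxel_size (", h, " mm) too coarse to resolve the cortical shell; ",
         "need voxel_size <= cortical_thickness/2 = ",
         geom$cortical_thickness / 2, " mm")

  L <- geom$neck_length
  a0 <- geom$si_outer_diameter / 2                  # SI outer semi-axis
  b0 <- geom$ap_si_ratio * geom$si_outer_diameter / 2  # AP outer semi-axis
  t <- geom$cortical_thickness
  smax <- 1 + abs(geom$taper) * L / 2

  nx <- ceiling(2 * b0 * smax / h) + 4L             # AP
  ny <- ceiling(2 * a0 * smax / h) + 4L             # SI
  nz <- max(1L, round_half_up(L / h))               # neck axis
  x <- (seq_len(nx) - (nx + 1) / 2) * h
  y <- (seq_len(ny) - (ny + 1) / 2) * h
  zc <- (seq_len(nz) - 0.5) * h                     # slice centers in [0, L]

  lab <- array(0L, dim = c(nx, ny, nz))
  x2 <- matrix(x, nx, ny)                            # AP coordinate per (x,y)
  y2 <- matrix(y, nx, ny, byrow = TRUE)

  sfac <- 1 + geom$taper * (zc - L / 2)
  if (any(sfac <= 0)) stop("taper makes the tube collapse within the neck length")
  prismatic <- geom$taper == 0

  slice_masks <- function(s) {
    a <- s * a0; b <- s * b0
    outer_m <- (x2 / b)^2 + (y2 / a)^2 <= 1
    ai <- a - t; bi <- b - t
    inner_m <- if (ai <= 0 || bi <= 0) matrix(FALSE, nx, ny)
               else (x2 / bi)^2 + (y2 / ai)^2 <= 1
    list(cort = outer_m & !inner_m, inner = inner_m)
  }

  withr::with_seed(as.integer(seed), {
    if (prismatic) {
      m <- slice_masks(1)
      cort3 <- array(m$cort, dim = c(nx, ny, nz))
      inner3 <- array(m$inner, dim = c(nx, ny, nz))
    } else {
      cort3 <- array(FALSE, dim = c(nx, ny, nz))
      inner3 <- array(FALSE, dim = c(nx, ny, nz))
      for (k in seq_len(nz)) {
        m <- slice_masks(sfac[k])
        cort3[, , k] <- m$cort
        inner3[, , k] <- m$inner
      }
    }
    lab[cort3] <- 1L

    n_int <- sum(inner3)
    bv <- geom$trabecular_bvtv
    if (n_int > 0L && bv > 0) {
      n_target <- round(bv * n_int)
      trab3 <- array(FALSE, dim = dim(lab))
      if (bv >= 1) {
        trab3 <- inner3
      } else if (pattern == "stochastic") {
        trab3[inner3] <- runif(n_int) < bv
        kern <- EBImage::makeBrush(3, shape = "box")
        trab3 <- EBImage::closing(trab3 * 1, kern) > 0.5
        trab3 <- trab3 & inner3
      } else {
        # regular rod lattice along the neck axis
        rr <- rod_spacing * sqrt(bv / pi)            # rod radius hitting BV/TV
        xm <- ((x2 + rod_spacing / 2) %% rod_spacing) - rod_spacing / 2
        ym <- ((y2 + rod_spacing / 2) %% rod_spacing) - rod_spacing / 2
        rods2 <- xm^2 + ym^2 <= rr^2
        trab3 <- array(rods2, dim = dim(lab)) & inner3
      }
      # exact-count adjustment to the BV/TV target
      n_have <- sum(trab3)
      if (n_have > n_target) {
        idx <- which(trab3)
        trab3[sample(idx, n_have - n_target)] <- FALSE
      } else if (n_have < n_target) {
        idx <- which(inner3 & !trab3)
        trab3[sample(idx, n_target - n_have)] <- TRUE
      }
      lab[trab3] <- 2L
    }
  })

  out <- fn_volume(lab, spacing = h, kind = "label")
  attr(out, "geometry") <- geom
  out
}

#' Simulate a calibrated-intensity (HU) volume from a label volume
#'
#' Assigns nominal Hounsfield-unit values to bone and background voxels and
#' adds Gaussian noise, producing the kind of input the segmentation stage
#' consumes. Used for segmentation validation and reliability experiments.
#'
#' @param vol a label [fn_volume].
#' @param hu_bone,hu_background mean HU of bone / background voxels.
#' @param noise_sd Gaussian noise SD in HU.
#' @param seed integer seed.
#' @return an [fn_volume] of kind `"hu"`.
#' @export
simulate_hu_volume <- function(vol, hu_bone = 1500, hu_background = -200,
                               noise_sd = 0, seed = 1L) {
  stopifnot(inherits(vol, "fn_volume"), vol$kind %in% c("label", "mask"))
  base <- ifelse(bone_mask(vol), hu_bone, hu_background)
  if (noise_sd > 0)
    base <- base + withr::with_seed(as.integer(seed),
                                    rnorm(length(base), 0, noise_sd))
  fn_volume(array(base, dim = dim(vol$data)), spacing = vol$spacing, kind = "hu")
}
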