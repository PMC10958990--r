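#' Calibrate raw attenuation intensities to Hounsfield units
#'
#' Two-point linear (affine) calibration using the air and water regions of
#' a scan phantom: air maps to -1000 HU and water to 0 HU. The
#' hydroxyapatite reading is not used in the map; it is converted and
#' attached as a quality-control readout for drift monitoring.
#'
#' @param vol an intensity [fn_volume].
#' @param phantom list/vector with named elements `air`, `water`, and
#'   optionally `hydroxyapatite` (mean raw intensities); must satisfy
#'   `air < water < hydroxyapatite`.
#' @return an [fn_volume] of kind `"hu"`; attribute `"phantom_hu"` carries
#'   the QC readings in HU.
#' @export
calibrate_to_hu <- function(vol, phantom) {
  stopifnot(inherits(vol, "fn_volume"))
  air <- phantom[["air"]]; water <- phantom[["water"]]
  ha <- phantom[["hydroxyapatite"]] %||% NA_real_
  if (is.null(air) || is.null(water)) stop("phantom must name `air` and `water`")
  if (!(air < water)) stop("calibration error: air intensity must be below water")
  if (is.finite(ha) && !(water < ha))
    stop("calibration error: hydroxyapatite intensity must exceed water")
  to_hu <- function(i) 1000 * (i - water) / (water - air)
  out <- fn_volume(array(to_hu(vol$data), dim = dim(vol$data)),
                   spacing = vol$spacing, kind = "hu")
  attr(out, "phantom_hu") <- c(air = -1000, water = 0, hydroxyapatite = to_hu(ha))
  out
}

#' Rigid rotation of a volume about a grid axis
#'
#' Rotates the volume about the stated axis through the geometric center of
#' the grid. The output grid is enlarged to contain the rotated bounding box
#' and padded with background (0). Label/mask volumes use nearest-neighbor
#' resampling, intensity volumes bilinear resampling in the rotation plane.
#' Multiples of 90 degrees are lattice-exact.
#'
#' @param vol an [fn_volume].
#' @param angle rotation angle in degrees (right-handed about the axis).
#' @param axis `"x"` (AP), `"y"` (SI), or `"z"` (neck axis).
#' @param interpolation `"nearest"`, `"trilinear"`, or `"auto"` (default:
#'   nearest for label/mask, trilinear for intensity/HU).
#' @return a rotated [fn_volume] of the same kind and spacing.
#' @export
rotate_volume <- function(vol, angle, axis = c("x", "y", "z"),
                          interpolation = c("auto", "nearest", "trilinear")) {
  stopifnot(inherits(vol, "fn_volume"))
  axis <- match.arg(axis)
  interpolation <- match.arg(interpolation)
  if (interpolation == "auto")
    interpolation <- if (vol$kind %in% c("label", "mask")) "nearest" else "trilinear"
  if (angle %% 360 == 0) return(vol)

  # rotation acts in the plane of the two axes other than `axis`
  plane <- switch(axis, x = c(2L, 3L), y = c(1L, 3L), z = c(1L, 2L))
  keep <- setdiff(1:3, plane)
  d <- dim(vol$data)
  th <- angle * pi / 180
  cs <- cos(th); sn <- sin(th)

  n1 <- d[plane[1]]; n2 <- d[plane[2]]
  m1 <- ceiling(abs(n1 * cs) + abs(n2 * sn) - 1e-9)
  m2 <- ceiling(abs(n1 * sn) + abs(n2 * cs) - 1e-9)
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
  o1 <- (m1 + 1) / 2; o2 <- (m2 + 1) / 2

  u <- matrix(seq_len(m1) - o1, m1, m2)
  v <- matrix(seq_len(m2) - o2, m1, m2, byrow = TRUE)
  # inverse map: source coords in the original plane
  s1 <- cs * u + sn * v + c1
  s2 <- -sn * u + cs * v + c2

  # permute so the rotation plane is dims 1-2, vectorized gather per plane
  perm <- c(plane, keep)
  src <- aperm(vol$data, perm)
  nk <- d[keep]
  outp <- array(0, dim = c(m1, m2, nk))

  if (interpolation == "nearest") {
    i1 <- round_half_up(s1); i2 <- round_half_up(s2)
    ok <- i1 >= 1 & i1 <= n1 & i2 >= 1 & i2 <= n2
    flat <- (as.vector(i2[ok]) - 1L) * n1 + as.vector(i1[ok])
    okv <- as.vector(ok)
    for (k in seq_len(nk)) {
      pl <- matrix(0, m1, m2)
      slab <- src[, , k]
      pl[okv] <- slab[flat]
      outp[, , k] <- pl
    }
  } else {
    f1 <- floor(s1); f2 <- floor(s2)
    w1 <- s1 - f1; w2 <- s2 - f2
    ok <- f1 >= 1 & f1 + 1 <= n1 & f2 >= 1 & f2 + 1 <= n2
    okv <- as.vector(ok)
    a1 <- as.vector(f1[ok]); a2 <- as.vector(f2[ok])
    ww1 <- as.vector(w1[ok]); ww2 <- as.vector(w2[ok])
    id00 <- (a2 - 1L) * n1 + a1
    id10 <- id00 + 1L
    id01 <- id00 + n1
    id11 <- id01 + 1L
    for (k in seq_len(nk)) {
      slab <- src[, , k]
      val <- slab[id00] * (1 - ww1) * (1 - ww2) + slab[id10] * ww1 * (1 - ww2) +
             slab[id01] * (1 - ww1) * ww2 + slab[id11] * ww1 * ww2
      pl <- matrix(0, m1, m2)
      pl[okv] <- val
      outp[, , k] <- pl
    }
  }

  out <- aperm(outp, order(perm))
  if (vol$kind %in% c("label", "mask")) out <- array(as.integer(out), dim = dim(out))
  fn_volume(out, spacing = vol$spacing, kind = vol$kind)
}

#' Extract a femoral-neck volume of interest
#'
#' Cuts a slab of consecutive slices perpendicular to the neck axis,
#' mimicking the standard 15-mm DXA-style FN region of interest. The number
#' of slices is `width / spacing` rounded half up (15 mm at 27 um spacing
#' gives 556 slices). For synthetic prismatic volumes the default placement
#' is the slab centered in the volume; real-data placement is given as an
#' explicit neck-axis coordinate.
#'
#' @param vol an [fn_volume].
#' @param width_mm slab width along the neck axis, mm (default 15).
#' @param center_mm slab center along the neck axis, in mm from the start of
#'   the volume; default is the volume center.
#' @return an [fn_volume] containing the slab.
#' @export
extract_fn_voi <- function(vol, width_mm = 15, center_mm = NULL) {
  stopifnot(inherits(vol, "fn_volume"))
  if (width_mm <= 0) stop("configuration error: VOI width must be > 0")
  h <- vol$spacing
  nz <- dim(vol$data)[3]
  n <- round_half_up(width_mm / h)
  if (n < 1) stop("configuration error: VOI narrower than one slice")
  center_mm <- center_mm %||% (nz * h / 2)
  if (center_mm < 0 || center_mm > nz * h)
    stop("bounds error: VOI center ", center_mm, " mm outside volume [0, ",
         nz * h, "] mm")
  c_idx <- center_mm / h + 0.5              # voxel-center index coordinate
  i1 <- round_half_up(c_idx - n / 2)
  if (i1 < 1 || i1 + n - 1 > nz)
    stop("bounds error: VOI [", i1, ", ", i1 + n - 1,
         "] exceeds volume extent (", nz, " slices)")
  fn_volume(vol$data[, , i1:(i1 + n - 1), drop = FALSE],
            spacing = h, kind = vol$kind)
}
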