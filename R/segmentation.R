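#' Segment bone from background
#'
#' Thresholds a calibrated (HU) volume into a binary bone mask. Voxels
#' strictly above the threshold become bone; a voxel exactly at the
#' threshold is background. `method = "otsu"` derives the threshold from
#' the intensity histogram; the threshold actually used is recorded in the
#' `"threshold_hu"` attribute for the run manifest.
#'
#' @param vol an [fn_volume] of kind `"hu"` (or `"intensity"`).
#' @param method `"fixed"` or `"otsu"`.
#' @param threshold fixed threshold in HU (used for `method = "fixed"`).
#' @return an [fn_volume] of kind `"mask"` (0/1).
#' @export
segment_bone <- function(vol, method = c("fixed", "otsu"), threshold = 300) {
  stopifnot(inherits(vol, "fn_volume"))
  method <- match.arg(method)
  if (length(vol$data) == 0L) stop("empty volume")
  if (method == "otsu") {
    rng <- range(vol$data)
    if (diff(rng) == 0) stop("constant volume: Otsu threshold undefined")
    norm <- (vol$data - rng[1]) / diff(rng)
    th01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    threshold <- rng[1] + th01 * diff(rng)
  }
  mask <- array(as.integer(vol$data > threshold), dim = dim(vol$data))
  out <- fn_volume(mask, spacing = vol$spacing, kind = "mask")
  attr(out, "threshold_hu") <- threshold
  out
}

#' Partition a bone mask into cortical and trabecular compartments
#'
#' A deterministic morphological definition of the cortical-trabecular
#' boundary, applied slice-by-slice perpendicular to the neck axis:
#' the mask is morphologically closed (sealing small pores in the cortical
#' shell) and hole-filled to give the periosteal region; the interior pore
#' space (periosteal region minus bone) is itself morphologically closed,
#' bridging across trabeculae, and the hole-filled largest connected
#' component of the closed pore space is the endosteal region (the solid
#' cortex contains no pores, so the closed pore space stops at the
#' endosteal surface). Bone voxels inside the endosteal region are labelled
#' trabecular and all remaining bone voxels cortical. The partition is
#' exhaustive and exclusive over the bone mask.
#'
#' @param mask an [fn_volume] of kind `"mask"` (or a label volume, whose
#'   bone voxels are used).
#' @param closing_radius_mm radius of the morphological closing, mm; must be
#'   at least one voxel.
#' @return an [fn_volume] of kind `"label"` with labels {0,1,2}.
#' @export
partition_cortical_trabecular <- function(mask, closing_radius_mm = 0.3) {
  stopifnot(inherits(mask, "fn_volume"))
  h <- mask$spacing
  if (closing_radius_mm < h)
    stop("configuration error: closing_radius_mm (", closing_radius_mm,
         ") must be at least one voxel (", h, " mm)")
  m <- bone_mask(mask)
  if (!any(m)) stop("empty bone mask")
  d <- dim(m)
  rad <- max(1L, round(closing_radius_mm / h))
  kern <- EBImage::makeBrush(2L * rad + 1L, shape = "disc")

  closed <- EBImage::closing(array(m * 1, d), kern) > 0.5
  filled <- EBImage::fillHull(array(closed * 1, d)) > 0.5
  pores <- filled & !m
  pores_closed <- EBImage::closing(array(pores * 1, d), kern) > 0.5

  lab <- array(0L, d)
  for (k in seq_len(d[3])) {
    msl <- m[, , k]
    if (!any(msl)) next
    cavity <- pores_closed[, , k] & filled[, , k]
    endo <- matrix(FALSE, d[1], d[2])
    if (any(cavity)) {
      comp <- EBImage::bwlabel(cavity * 1)
      sizes <- tabulate(comp[comp > 0])
      main <- which.max(sizes)
      endo <- EBImage::fillHull((comp == main) * 1) > 0.5
    }
    sl <- integer(length(msl))
    sl[msl & !endo] <- 1L
    sl[msl & endo] <- 2L
    lab[, , k] <- sl
  }
  fn_volume(lab, spacing = h, kind = "label")
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` for two binary masks on the same grid;
#' defined as 1 when both masks are empty.
#'
#' @param a,b binary arrays, logical arrays, or [fn_volume] masks of equal
#'   dimensions.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "fn_volume")) a <- a$data
  if (inherits(b, "fn_volume")) b <- b$data
  if (!identical(dim(a), dim(b))) stop("mask shape mismatch")
  a <- a > 0; b <- b > 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}
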