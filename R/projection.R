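#' Project a 3D VOI into a 2D pseudoDXA density map
#'
#' Counts bone voxels of the requested compartment along the
#' anterior-posterior (AP) ray for every (neck-axis, SI) pixel, mimicking
#' the projection geometry of a DXA scan without any X-ray physics. The sum
#' over the image equals the compartment voxel count exactly (projection
#' conservation).
#'
#' @param voi a label [fn_volume].
#' @param compartment `"total"` (cortical + trabecular), `"cortical"`, or
#'   `"trabecular"`.
#' @return an object of class `pseudodxa_image`: a neck-axis x SI matrix of
#'   non-negative integer counts with fields `spacing` (mm) and
#'   `compartment`.
#' @export
project_pseudodxa <- function(voi, compartment = c("total", "cortical", "trabecular")) {
  stopifnot(inherits(voi, "fn_volume"))
  compartment <- match.arg(compartment)
  labs <- switch(compartment, total = c(1L, 2L), cortical = 1L, trabecular = 2L)
  sel <- array(voi$data %in% labs, dim = dim(voi$data))
  counts <- t(colSums(sel))                     # [SI, neck] -> [neck, SI]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, spacing = voi$spacing,
                 compartment = compartment),
            class = "pseudodxa_image")
}

#' @export
print.pseudodxa_image <- function(x, ...) {
  cat(sprintf("<pseudodxa_image> %s, %d x %d pixels (neck x SI), %.4g mm, BMC = %d voxels\n",
              x$compartment, nrow(x$counts), ncol(x$counts), x$spacing,
              sum(x$counts)))
  invisible(x)
}

#' DXA-style region-of-interest parameters from a pseudoDXA image
#'
#' BMC is the total projected bone-voxel count; area is the bone silhouette
#' area (pixels with at least one bone voxel times the pixel area) in cm2;
#' aBMD is BMC / area in voxels per cm2. The silhouette definition makes
#' all three invariant to padding the image with empty border.
#'
#' @param image a `pseudodxa_image` from [project_pseudodxa()].
#' @return list with `bmc` (voxel count), `area_cm2`, `abmd` (voxels/cm2).
#' @export
roi_params <- function(image) {
  stopifnot(inherits(image, "pseudodxa_image"))
  bmc <- sum(image$counts)
  if (bmc == 0) stop("empty pseudoDXA image: aBMD undefined")
  area_cm2 <- sum(image$counts > 0) * (image$spacing / 10)^2
  list(bmc = bmc, area_cm2 = area_cm2, abmd = bmc / area_cm2)
}

#' Femoral-neck widths from a pseudoDXA image
#'
#' For every column along the neck axis, the width is the SI extent of the
#' nonzero pixels (max index - min index + 1, times the pixel spacing).
#' Returns the mean and minimum width over columns, in cm.
#'
#' @param image a `pseudodxa_image` (normally the `"total"` compartment).
#' @return list with `fnw_avg_cm` and `fnw_min_cm`.
#' @export
fn_widths <- function(image) {
  stopifnot(inherits(image, "pseudodxa_image"))
  widths <- apply(image$counts, 1, function(row) {
    nz <- which(row > 0)
    if (length(nz) == 0L)
      stop("empty neck-axis column: VOI misplaced (no bone in a slice)")
    (max(nz) - min(nz) + 1L)
  })
  list(fnw_avg_cm = mean(widths) * image$spacing / 10,
       fnw_min_cm = min(widths) * image$spacing / 10)
}
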