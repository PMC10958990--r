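#' Voxel volume container
#'
#' A light S3 wrapper around a 3D array with isotropic voxel spacing and a
#' fixed anatomical axis convention: dimension 1 = anterior-posterior (AP,
#' out of the DXA image plane), dimension 2 = superior-inferior (SI),
#' dimension 3 = neck axis. Label volumes use the coding
#' 0 = background, 1 = cortical bone, 2 = trabecular bone.
#'
#' @param data 3D numeric/integer/logical array.
#' @param spacing isotropic voxel spacing in mm (single positive number).
#' @param kind one of `"label"`, `"mask"`, `"intensity"`, `"hu"`.
#' @return an object of class `fn_volume`.
#' @export
fn_volume <- function(data, spacing, kind = c("label", "mask", "intensity", "hu")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive number (mm)")
  if (kind %in% c("label", "mask")) {
    u <- unique(as.vector(data))
    ok <- if (kind == "label") u %in% c(0, 1, 2) else u %in% c(0, 1, TRUE, FALSE)
    if (!all(ok)) stop("labels must be in {0,1,2} (0=background, 1=cortical, 2=trabecular)")
  }
  structure(list(data = data, spacing = spacing, kind = kind,
                 axes = c("AP", "SI", "neck")),
            class = "fn_volume")
}

#' @export
print.fn_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fn_volume> %s, %d x %d x %d voxels (AP x SI x neck), %.4g mm spacing\n",
              x$kind, d[1], d[2], d[3], x$spacing))
  if (x$kind %in% c("label", "mask")) {
    tab <- table(factor(as.vector(x$data), levels = 0:2))
    cat(sprintf("  background %d | cortical %d | trabecular %d\n",
                tab[[1]], tab[[2]], tab[[3]]))
  }
  invisible(x)
}

#' @export
dim.fn_volume <- function(x) dim(x$data)

#' Write / read a volume as NIfTI
#'
#' Volumes are stored as NIfTI-1 with the isotropic spacing recorded in the
#' header `pixdim`. Labels follow the `fn_volume` coding {0,1,2}.
#'
#' @param vol an [fn_volume].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param kind volume kind to assign on read.
#' @return `write_fn_volume` returns `path` invisibly; `read_fn_volume`
#'   returns an [fn_volume].
#' @export
write_fn_volume <- function(vol, path) {
  stopifnot(inherits(vol, "fn_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- rep(vol$spacing, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_fn_volume
#' @export
read_fn_volume <- function(path, kind = "label") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  if (length(unique(round(sp, 8))) != 1L)
    stop("anisotropic spacing in ", path, "; fn_volume requires isotropic voxels")
  dat <- array(as.vector(img), dim = dim(img))
  if (kind %in% c("label", "mask")) dat <- array(as.integer(round(dat)), dim = dim(dat))
  fn_volume(dat, spacing = sp[1], kind = kind)
}

# internal: pull a binary bone mask (any bone label) from a label volume
bone_mask <- function(vol) {
  stopifnot(inherits(vol, "fn_volume"))
  vol$data == 1L | vol$data == 2L
}
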