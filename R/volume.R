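#' Construct an image volume
#'
#' The canonical 3D image container used throughout the package. Voxels are
#' stored in a 3D array whose axes are, in order, x = left--right,
#' y = anterior--posterior and z = inferior--superior (an RAS-like layout:
#' increasing index moves right / anterior / superior). All downstream
#' operations -- projections, rotations, cropping -- assume this axis order.
#' The centre of voxel \code{(i, j, k)} (0-based) sits at physical position
#' \code{origin + c(i, j, k) * spacing} in millimetres.
#'
#' @param voxels 3D numeric array of voxel values; all values must be finite.
#' @param spacing numeric length-3 vector of voxel spacings in mm, all > 0.
#' @param origin numeric length-3 vector, physical position (mm) of the centre
#'   of voxel (0, 0, 0).
#' @param modality either \code{"PET"} or \code{"CT"}.
#' @return An object of class \code{image_volume}: a list with elements
#'   \code{voxels}, \code{spacing}, \code{origin}, \code{modality}.
#' @examples
#' vol <- image_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(vol$voxels)
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         modality = c("PET", "CT")) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels)))
    stop("all voxel values must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite numbers")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 modality = modality),
            class = "image_volume")
}

is_image_volume <- function(x) inherits(x, "image_volume")

assert_volume <- function(vol) {
  if (!is_image_volume(vol)) stop("expected an 'image_volume' object")
  invisible(vol)
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %s  %d x %d x %d voxels\n", x$modality,
              d[1], d[2], d[3]))
  cat(sprintf("  spacing (mm): %s\n", paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  origin  (mm): %s\n", paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  intensity range: [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Read a NIfTI volume into the canonical axis order
#'
#' Reads a \code{.nii}/\code{.nii.gz} file and reorients the data into the
#' package's canonical RAS-like axis order (x left--right, y
#' anterior--posterior, z inferior--superior) using the file's orientation
#' codes, so the on-disk storage order never leaks downstream. Spacing and
#' origin are taken from the (reoriented) header.
#'
#' @param path path to a readable NIfTI file.
#' @param modality \code{"PET"} or \code{"CT"}; stored on the returned volume.
#' @return An \code{\link{image_volume}}.
#' @seealso \code{\link{write_volume}}
#' @export
read_volume <- function(path, modality = c("PET", "CT")) {
  modality <- match.arg(modality)
  if (!file.exists(path))
    stop(sprintf("cannot read volume: file '%s' does not exist", path))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop(sprintf("cannot read '%s' as NIfTI: %s", path,
                                 conditionMessage(e)), call. = FALSE))
  if (length(dim(img)) != 3L)
    stop(sprintf("'%s' is not a 3D volume (found %d dims)", path,
                 length(dim(img))))
  ornt <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(ornt) && nzchar(ornt) && ornt != "RAS")
    RNifti::orientation(img) <- "RAS"
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop(sprintf("'%s' has missing or invalid voxel spacing", path))
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  org <- if (is.null(xf)) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  image_volume(array(as.numeric(img), dim = dim(img)), spacing = sp,
               origin = org, modality = modality)
}

#' Write a volume to a NIfTI file
#'
#' Writes voxels, spacing and origin with an RAS sform/qform so that
#' \code{\link{read_volume}} round-trips the volume exactly.
#'
#' @param vol an \code{\link{image_volume}}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  assert_volume(vol)
  img <- RNifti::asNifti(vol$voxels)
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing
  xf[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

## separable per-axis 1D interpolation with edge replication.
## arr: 3D array; axis: 1..3; x_in/x_out: physical coords along that axis.
resample_axis <- function(arr, axis, x_in, x_out, order) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  # edge replication: clamp the query points to the sampled extent
  xq <- pmin(pmax(x_out, min(x_in)), max(x_in))
  out <- matrix(0, nrow = length(x_out), ncol = ncol(m))
  if (order == 3 && length(x_in) >= 4) {
    for (j in seq_len(ncol(m)))
      out[, j] <- stats::spline(x_in, m[, j], xout = xq, method = "fmm")$y
  } else if (order == 0) {
    idx <- vapply(xq, function(q) which.min(abs(x_in - q)), integer(1))
    out <- m[idx, , drop = FALSE]
  } else {
    # linear; also the fallback when too few samples support a cubic fit
    for (j in seq_len(ncol(m)))
      out[, j] <- stats::approx(x_in, m[, j], xout = xq, rule = 2)$y
  }
  dim(out) <- c(length(x_out), d[-1])
  aperm(out, order(perm))
}

#' Resample a volume to isotropic spacing
#'
#' Separable per-axis interpolation onto an isotropic grid. The default cubic
#' (third-order) spline matches standard practice for PET/CT harmonisation;
#' order 1 gives linear interpolation (guaranteed never to overshoot the input
#' range) and order 0 nearest-neighbour. The output grid keeps the input
#' origin and covers the same physical extent: each axis gets
#' \code{floor(n * spacing / target_mm)} voxels. Query points beyond the
#' sampled voxel centres use edge replication.
#'
#' @param vol an \code{\link{image_volume}} with at least 2 voxels per axis.
#' @param target_mm target isotropic spacing in mm (> 0); default 1.0.
#' @param spline_order 0, 1 or 3.
#' @return A resampled \code{\link{image_volume}} with spacing
#'   \code{rep(target_mm, 3)}.
#' @export
resample_isotropic <- function(vol, target_mm = 1.0, spline_order = 3) {
  assert_volume(vol)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("'target_mm' must be a single positive number")
  if (!spline_order %in% c(0, 1, 3))
    stop("'spline_order' must be 0, 1 or 3")
  d <- dim(vol$voxels)
  if (any(d < 2L))
    stop("cannot resample a degenerate volume (every axis needs >= 2 voxels)")
  vox <- vol$voxels
  for (axis in 1:3) {
    n_in <- dim(vox)[axis]
    sp <- vol$spacing[axis]
    n_out <- max(1L, floor(n_in * sp / target_mm))
    x_in <- vol$origin[axis] + (seq_len(n_in) - 1) * sp
    x_out <- vol$origin[axis] + (seq_len(n_out) - 1) * target_mm
    vox <- resample_axis(vox, axis, x_in, x_out, spline_order)
  }
  image_volume(vox, spacing = rep(target_mm, 3), origin = vol$origin,
               modality = vol$modality)
}

#' Window a CT volume to the bone Hounsfield range
#'
#' Restricts CT intensities to the hard-tissue (bone) Hounsfield window,
#' 700--2000 HU by default, so that bone dominates subsequent maximum
#' intensity projections. The default semantics clamp (saturate) both tails,
#' which keeps the bone silhouette solid and bright; \code{mode = "floor"}
#' instead maps every out-of-window voxel to \code{lo}.
#'
#' @param vol a CT \code{\link{image_volume}}.
#' @param lo,hi window bounds in HU, \code{lo < hi}; defaults 700 and 2000.
#' @param mode \code{"clamp"} (default) or \code{"floor"}.
#' @return The windowed \code{\link{image_volume}}.
#' @export
clip_hu <- function(vol, lo = 700, hi = 2000, mode = c("clamp", "floor")) {
  assert_volume(vol)
  mode <- match.arg(mode)
  if (vol$modality != "CT")
    stop("clip_hu expects a CT volume")
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stop("'lo' must be smaller than 'hi'")
  v <- vol$voxels
  if (mode == "clamp") {
    v <- pmin(pmax(v, lo), hi)
  } else {
    v[v < lo | v > hi] <- lo
  }
  image_volume(v, spacing = vol$spacing, origin = vol$origin,
               modality = vol$modality)
}
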