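#' A single maximum intensity projection view
#'
#' @param pixels 2D numeric matrix indexed \code{[u, v]} (u horizontal, v the
#'   inferior--superior axis).
#' @param angle_deg axial rotation angle of the view, in \code{[0, 360)}.
#' @param pixel_spacing_mm positive length-2 pixel spacing.
#' @return An object of class \code{mip_image}.
#' @export
mip_image <- function(pixels, angle_deg, pixel_spacing_mm = c(1, 1)) {
  if (!is.matrix(pixels) || !all(is.finite(pixels)))
    stop("'pixels' must be a finite numeric matrix")
  if (!is.numeric(angle_deg) || length(angle_deg) != 1L ||
      angle_deg < 0 || angle_deg >= 360)
    stop("'angle_deg' must be a single number in [0, 360)")
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
    stop("'pixel_spacing_mm' must be two positive numbers")
  structure(list(pixels = pixels, angle_deg = angle_deg,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm)),
            class = "mip_image")
}

#' An ordered multi-angle MIP stack
#'
#' @param mips list of \code{\link{mip_image}} objects with strictly
#'   increasing angles \code{i * step_deg}.
#' @param step_deg the angular step in degrees.
#' @return An object of class \code{mip_stack}.
#' @export
mip_stack <- function(mips, step_deg) {
  n_expected <- round(360 / step_deg)
  if (length(mips) != n_expected)
    stop(sprintf("expected %d views for a %g-degree step, got %d",
                 n_expected, step_deg, length(mips)))
  angles <- vapply(mips, function(m) m$angle_deg, numeric(1))
  if (any(abs(angles - (seq_along(mips) - 1) * step_deg) > 1e-9))
    stop("view angles must be i * step_deg in order")
  structure(list(mips = mips, step_deg = step_deg), class = "mip_stack")
}

#' @export
print.mip_stack <- function(x, ...) {
  d <- dim(x$mips[[1]]$pixels)
  cat(sprintf("<mip_stack> %d views at %g-degree steps, %d x %d pixels\n",
              length(x$mips), x$step_deg, d[1], d[2]))
  invisible(x)
}

#' @export
length.mip_stack <- function(x) length(x$mips)

#' Rotate a volume about its superior--inferior axis
#'
#' In-plane (x, y) rotation about the geometric centre of the grid, applied
#' identically to every axial slice. Rotation is performed in physical
#' coordinates (so anisotropic in-plane spacing is handled correctly) with
#' bilinear interpolation; points sampled from outside the grid are filled
#' with 0, appropriate for cropped PET where the background is near zero.
#' The output grid equals the input grid. A positive angle rotates the
#' volume content counter-clockwise when viewed from the superior direction.
#'
#' @param vol an \code{\link{image_volume}}.
#' @param angle_deg rotation angle in degrees.
#' @return The rotated \code{\link{image_volume}}.
#' @export
rotate_axial <- function(vol, angle_deg) {
  assert_volume(vol)
  theta <- (angle_deg %% 360) * pi / 180
  if (abs(theta) < 1e-12) return(vol)
  d <- dim(vol$voxels)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  sx <- vol$spacing[1]; sy <- vol$spacing[2]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  ix <- rep(seq_len(nx) - 1, times = ny)
  iy <- rep(seq_len(ny) - 1, each = nx)
  # physical offsets from the rotation centre
  px <- (ix - cx) * sx
  py <- (iy - cy) * sy
  ct <- cos(theta); st <- sin(theta)
  # inverse map: where does each output voxel sample from
  qx <- ( px * ct + py * st) / sx + cx
  qy <- (-px * st + py * ct) / sy + cy
  x0 <- floor(qx); y0 <- floor(qy)
  fx <- qx - x0; fy <- qy - y0
  inside <- function(x, y) x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1
  v <- matrix(vol$voxels, nrow = nx * ny, ncol = nz)
  gather <- function(x, y, w) {
    ok <- inside(x, y) & w > 0
    out <- matrix(0, nrow = nx * ny, ncol = nz)
    if (any(ok)) {
      idx <- x[ok] + 1 + y[ok] * nx
      out[ok, ] <- v[idx, , drop = FALSE] * w[ok]
    }
    out
  }
  out <- gather(x0,     y0,     (1 - fx) * (1 - fy)) +
         gather(x0 + 1, y0,     fx       * (1 - fy)) +
         gather(x0,     y0 + 1, (1 - fx) * fy) +
         gather(x0 + 1, y0 + 1, fx       * fy)
  image_volume(array(out, dim = d), spacing = vol$spacing,
               origin = vol$origin, modality = vol$modality)
}

#' Generate multi-angle maximum intensity projections
#'
#' Rotates the (cropped PET) volume axially in steps of \code{step_deg}
#' degrees and captures a maximum intensity projection along the
#' anterior--posterior axis after each rotation, so the angle-0 view equals
#' the coronal MIP. With the default 5-degree step this yields 72 views
#' covering one full axial rotation. The module is deterministic: the same
#' volume always produces a bit-identical stack.
#'
#' @param vol an \code{\link{image_volume}} (typically the cropped PET).
#' @param step_deg angular step; \code{360 / step_deg} must be an integer.
#' @return A \code{\link{mip_stack}} of \code{360 / step_deg} views ordered
#'   by angle.
#' @export
generate_ma_mips <- function(vol, step_deg = 5) {
  assert_volume(vol)
  if (!is.numeric(step_deg) || length(step_deg) != 1L || step_deg <= 0)
    stop("'step_deg' must be a single positive number")
  n <- 360 / step_deg
  if (abs(n - round(n)) > 1e-9)
    stop(sprintf("'step_deg' must divide 360 (got %g)", step_deg))
  n <- as.integer(round(n))
  sp <- vol$spacing[c(1, 3)]
  mips <- vector("list", n)
  for (i in seq_len(n)) {
    ang <- (i - 1) * step_deg
    rv <- rotate_axial(vol, ang)
    mips[[i]] <- mip_image(plane_mip(rv, "coronal")[, , drop = FALSE],
                           angle_deg = ang, pixel_spacing_mm = sp)
  }
  mip_stack(mips, step_deg)
}

## bilinear resize of a matrix to out_h x out_w (pixel-centre alignment)
resize_bilinear <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  coord <- function(n_out, n_in) {
    q <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    pmin(pmax(q, 0), n_in - 1)
  }
  qi <- coord(out_h, in_h); qj <- coord(out_w, in_w)
  i0 <- pmin(floor(qi), in_h - 2); fi <- qi - i0
  j0 <- pmin(floor(qj), in_w - 2); fj <- qj - j0
  if (in_h == 1) { i0 <- rep(0, out_h); fi <- rep(0, out_h) }
  if (in_w == 1) { j0 <- rep(0, out_w); fj <- rep(0, out_w) }
  a <- m[i0 + 1, j0 + 1, drop = FALSE]
  b <- m[pmin(i0 + 2, in_h), j0 + 1, drop = FALSE]
  cc <- m[i0 + 1, pmin(j0 + 2, in_w), drop = FALSE]
  dd <- m[pmin(i0 + 2, in_h), pmin(j0 + 2, in_w), drop = FALSE]
  wi <- matrix(fi, out_h, out_w)
  wj <- matrix(fj, out_h, out_w, byrow = TRUE)
  a * (1 - wi) * (1 - wj) + b * wi * (1 - wj) +
    cc * (1 - wi) * wj + dd * wi * wj
}

#' Prepare a MIP view as CNN backbone input
#'
#' Maps the view to the 3-channel square tensor a 2D convolutional backbone
#' expects: intensity scaling to \code{[0, 1]}, centred zero-padding of the
#' short axis to a square, bilinear resize to \code{input_size}, replication
#' to three channels, and channel-wise standardisation with the backbone's
#' normalisation constants (defaults are the usual natural-image statistics).
#'
#' Intensity scaling is per-image min--max by default (a constant image maps
#' to all zeros). For cross-patient survival work a fixed
#' \code{intensity_window} (e.g. \code{c(0, SUVcap)}) is usually preferable:
#' it maps the window linearly to \code{[0, 1]} with clamping, so absolute
#' tracer-uptake level remains comparable between patients instead of being
#' normalised away per view.
#'
#' @param mip a \code{\link{mip_image}} or plain matrix.
#' @param input_size side length of the square network input.
#' @param normalization list with numeric length-3 \code{mean} and \code{sd}.
#' @param intensity_window optional length-2 numeric window mapped to
#'   \code{[0, 1]}; \code{NULL} (default) selects per-image min--max.
#' @return A numeric array of dim \code{c(input_size, input_size, 3)}.
#' @export
prep_for_backbone <- function(mip, input_size = 64,
                              normalization = list(
                                mean = c(0.485, 0.456, 0.406),
                                sd = c(0.229, 0.224, 0.225)),
                              intensity_window = NULL) {
  px <- if (inherits(mip, "mip_image")) mip$pixels else mip
  if (!is.matrix(px) || !all(is.finite(px)))
    stop("MIP pixels must be a finite numeric matrix")
  if (!is.null(intensity_window)) {
    if (length(intensity_window) != 2L ||
        intensity_window[1] >= intensity_window[2])
      stop("'intensity_window' must be c(lo, hi) with lo < hi")
    px <- pmin(pmax((px - intensity_window[1]) /
                      diff(intensity_window), 0), 1)
  } else {
    rng <- range(px)
    px <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1])
          else matrix(0, nrow(px), ncol(px))
  }
  side <- max(dim(px))
  sq <- matrix(0, side, side)
  off_r <- floor((side - nrow(px)) / 2)
  off_c <- floor((side - ncol(px)) / 2)
  sq[off_r + seq_len(nrow(px)), off_c + seq_len(ncol(px))] <- px
  rs <- resize_bilinear(sq, input_size, input_size)
  out <- array(0, c(input_size, input_size, 3))
  for (ch in 1:3)
    out[, , ch] <- (rs - normalization$mean[ch]) / normalization$sd[ch]
  out
}
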