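#' Axis-aligned 2D bounding box on a projection image
#'
#' Boxes are 0-based and half-open: a box \code{[u_min, u_max) x [v_min,
#' v_max)} on a projection image, where u is the horizontal image axis (x for
#' a coronal view, y for a sagittal view) and v the vertical
#' (inferior--superior) axis. \code{image_w}/\code{image_h} give the
#' projection size the box was defined on and are used for validation.
#'
#' @param plane \code{"coronal"} or \code{"sagittal"}.
#' @param u_min,u_max,v_min,v_max integer pixel bounds, 0-based half-open.
#' @param image_w,image_h projection image size in pixels.
#' @return An object of class \code{bbox_2d}.
#' @export
bbox_2d <- function(plane = c("coronal", "sagittal"), u_min, u_max,
                    v_min, v_max, image_w, image_h) {
  plane <- match.arg(plane)
  vals <- c(u_min, u_max, v_min, v_max, image_w, image_h)
  if (any(!is.finite(vals)) || any(vals != round(vals)))
    stop("box coordinates must be finite integers")
  if (u_min >= u_max || v_min >= v_max)
    stop("degenerate box: need u_min < u_max and v_min < v_max")
  if (u_min < 0 || v_min < 0 || u_max > image_w || v_max > image_h)
    stop(sprintf("box [%d,%d)x[%d,%d) lies outside the %dx%d image",
                 u_min, u_max, v_min, v_max, image_w, image_h))
  structure(list(plane = plane, u_min = as.integer(u_min),
                 u_max = as.integer(u_max), v_min = as.integer(v_min),
                 v_max = as.integer(v_max), image_w = as.integer(image_w),
                 image_h = as.integer(image_h)),
            class = "bbox_2d")
}

#' Axis-aligned 3D bounding box in voxel index space
#'
#' 0-based, half-open on every axis.
#'
#' @param x_min,x_max,y_min,y_max,z_min,z_max integer voxel bounds.
#' @return An object of class \code{bbox_3d}.
#' @export
bbox_3d <- function(x_min, x_max, y_min, y_max, z_min, z_max) {
  vals <- c(x_min, x_max, y_min, y_max, z_min, z_max)
  if (any(!is.finite(vals)) || any(vals != round(vals)))
    stop("box coordinates must be finite integers")
  if (x_min >= x_max || y_min >= y_max || z_min >= z_max)
    stop("degenerate 3D box: every axis needs min < max")
  if (any(c(x_min, y_min, z_min) < 0))
    stop("3D box coordinates must be non-negative")
  structure(list(x_min = as.integer(x_min), x_max = as.integer(x_max),
                 y_min = as.integer(y_min), y_max = as.integer(y_max),
                 z_min = as.integer(z_min), z_max = as.integer(z_max)),
            class = "bbox_3d")
}

#' @export
print.bbox_2d <- function(x, ...) {
  cat(sprintf("<bbox_2d %s> u [%d, %d)  v [%d, %d)  on %dx%d image\n",
              x$plane, x$u_min, x$u_max, x$v_min, x$v_max,
              x$image_w, x$image_h))
  invisible(x)
}

#' @export
print.bbox_3d <- function(x, ...) {
  cat(sprintf("<bbox_3d> x [%d, %d)  y [%d, %d)  z [%d, %d)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, x$z_min, x$z_max))
  invisible(x)
}

#' Coronal or sagittal maximum intensity projection
#'
#' Projects a volume along the anterior--posterior axis (coronal view) or the
#' left--right axis (sagittal view) by taking the per-ray voxel maximum. The
#' result is a matrix indexed \code{[u, v]}: u is x (coronal) or y
#' (sagittal), v is always the inferior--superior z axis, with \code{v = 1}
#' the most inferior row.
#'
#' @param vol an \code{\link{image_volume}}.
#' @param plane \code{"coronal"} or \code{"sagittal"}.
#' @return A numeric matrix with attributes \code{plane} and
#'   \code{pixel_spacing_mm}.
#' @export
plane_mip <- function(vol, plane = c("coronal", "sagittal")) {
  assert_volume(vol)
  plane <- match.arg(plane)
  v <- vol$voxels
  if (plane == "coronal") {
    out <- v[, 1, ]
    if (dim(v)[2] > 1)
      for (j in 2:dim(v)[2]) out <- pmax(out, v[, j, ])
    sp <- vol$spacing[c(1, 3)]
  } else {
    out <- v[1, , ]
    if (dim(v)[1] > 1)
      for (i in 2:dim(v)[1]) out <- pmax(out, v[i, , ])
    sp <- vol$spacing[c(2, 3)]
  }
  structure(out, plane = plane, pixel_spacing_mm = sp)
}

#' Read 2D head-and-neck boxes from an annotation file
#'
#' Accepts either the XML dialect written by common image-annotation tools
#' (an \code{<annotation>} element with \code{<size>} and one \code{<object>}
#' per box whose \code{<name>} is the plane and whose \code{<bndbox>} holds
#' \code{xmin/xmax/ymin/ymax}) or this package's JSON dialect: an array of
#' objects \code{\{plane, u_min, u_max, v_min, v_max, image_w, image_h\}}.
#' XML \code{x} maps to u and \code{y} to v, taken as 0-based half-open
#' bounds. Every box is validated against the stated image size.
#'
#' @param path path to an XML or JSON box file.
#' @return A list of \code{\link{bbox_2d}} objects.
#' @seealso \code{\link{write_boxes_2d}}
#' @export
load_boxes_2d <- function(path) {
  if (!file.exists(path))
    stop(sprintf("box file '%s' does not exist", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^\\s*[\\[{]", first)) {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    if (!length(recs)) stop(sprintf("no boxes found in '%s'", path))
    return(lapply(recs, function(r) {
      need <- c("plane", "u_min", "u_max", "v_min", "v_max",
                "image_w", "image_h")
      if (!all(need %in% names(r)))
        stop(sprintf("malformed JSON box in '%s': need fields %s", path,
                     paste(need, collapse = ", ")))
      bbox_2d(r$plane, r$u_min, r$u_max, r$v_min, r$v_max,
              r$image_w, r$image_h)
    }))
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("cannot parse '%s' as XML: %s", path,
                 conditionMessage(e)), call. = FALSE))
  w <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, ".//size/width")))
  h <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, ".//size/height")))
  if (is.na(w) || is.na(h))
    stop(sprintf("'%s' lacks a <size> element with width/height", path))
  objs <- xml2::xml_find_all(doc, ".//object")
  if (!length(objs)) stop(sprintf("no <object> boxes found in '%s'", path))
  lapply(objs, function(o) {
    plane <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    num <- function(tag) {
      val <- xml2::xml_text(xml2::xml_find_first(o, paste0("./bndbox/", tag)))
      out <- suppressWarnings(as.numeric(val))
      if (is.na(out)) stop(sprintf("malformed <bndbox> in '%s': bad <%s>",
                                   path, tag))
      out
    }
    bbox_2d(plane, num("xmin"), num("xmax"), num("ymin"), num("ymax"), w, h)
  })
}

#' Write 2D boxes to the package's JSON dialect
#'
#' @param boxes list of \code{\link{bbox_2d}} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_boxes_2d <- function(boxes, path) {
  if (inherits(boxes, "bbox_2d")) boxes <- list(boxes)
  recs <- lapply(boxes, function(b) unclass(b))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rule-based head-and-neck box proposal from bone-window CT projections
#'
#' A landmark heuristic that stands in for a trained detector on phantom-like
#' data. On each bone-window projection it finds the vertical extent running
#' from the shoulder girdle up to the top of the head, and the horizontal
#' extent of the bone column within the head region:
#' \itemize{
#'   \item v-extent: from the row of maximal above-threshold horizontal width
#'     (the shoulder row, a proxy for the sternoclavicular/acromioclavicular
#'     level; the most superior such row on ties) up to the topmost
#'     above-threshold row;
#'   \item u-extent: the above-threshold column span within the upper half of
#'     that v-extent, dilated by \code{margin} pixels.
#' }
#' Pixels count as bone when strictly above \code{threshold_hu}, so images
#' clamped to the bone window (where soft tissue saturates at the lower
#' bound) are handled correctly.
#'
#' @param bone_coronal,bone_sagittal bone-window MIP matrices as returned by
#'   \code{\link{plane_mip}} on a \code{\link{clip_hu}}-windowed CT.
#' @param threshold_hu bone threshold; defaults to the bone window's lower
#'   bound, 700 HU.
#' @param margin dilation of the horizontal extent, in pixels.
#' @return A list with elements \code{coronal} and \code{sagittal}, each a
#'   \code{\link{bbox_2d}}.
#' @export
propose_boxes_heuristic <- function(bone_coronal, bone_sagittal,
                                    threshold_hu = 700, margin = 8) {
  one_plane <- function(img, plane) {
    mask <- img > threshold_hu
    if (!any(mask))
      stop("no bone detected: no pixels above the threshold")
    nu <- nrow(mask); nv <- ncol(mask)
    width_by_row <- colSums(mask)
    v_top <- max(which(width_by_row > 0))           # topmost bone row
    shoulder <- max(which(width_by_row == max(width_by_row)))
    if (shoulder >= v_top) shoulder <- min(which(width_by_row > 0))
    v_lo <- min(shoulder, v_top)
    # head column: bone span in the upper half of the vertical extent
    upper <- mask[, ceiling((v_lo + v_top) / 2):v_top, drop = FALSE]
    cols <- which(rowSums(upper) > 0)
    u_lo <- max(1L, min(cols) - margin)
    u_hi <- min(nu, max(cols) + margin)
    bbox_2d(plane, u_lo - 1L, u_hi, v_lo - 1L, v_top, nu, nv)
  }
  list(coronal = one_plane(bone_coronal, "coronal"),
       sagittal = one_plane(bone_sagittal, "sagittal"))
}

#' Combine coronal and sagittal 2D boxes into a 3D crop box
#'
#' The x-extent comes from the coronal box's horizontal span, the y-extent
#' from the sagittal box's horizontal span, and the z-extent from the union
#' of the two vertical spans (over-inclusion keeps all primary tumours and
#' involved nodes inside the crop; use \code{z_rule = "intersection"} for the
#' tighter alternative). The result is clipped to the volume shape.
#'
#' @param coronal,sagittal \code{\link{bbox_2d}} objects tagged with the
#'   matching planes.
#' @param vol_shape integer length-3 volume shape (voxels).
#' @param z_rule \code{"union"} (default) or \code{"intersection"}.
#' @return A \code{\link{bbox_3d}}.
#' @export
combine_boxes_3d <- function(coronal, sagittal, vol_shape,
                             z_rule = c("union", "intersection")) {
  z_rule <- match.arg(z_rule)
  if (!inherits(coronal, "bbox_2d") || coronal$plane != "coronal")
    stop("'coronal' must be a bbox_2d tagged plane = 'coronal'")
  if (!inherits(sagittal, "bbox_2d") || sagittal$plane != "sagittal")
    stop("'sagittal' must be a bbox_2d tagged plane = 'sagittal'")
  vol_shape <- as.integer(vol_shape)
  if (length(vol_shape) != 3L || any(vol_shape < 1L))
    stop("'vol_shape' must be three positive integers")
  if (z_rule == "union") {
    z_min <- min(coronal$v_min, sagittal$v_min)
    z_max <- max(coronal$v_max, sagittal$v_max)
  } else {
    z_min <- max(coronal$v_min, sagittal$v_min)
    z_max <- min(coronal$v_max, sagittal$v_max)
  }
  x_min <- max(0L, coronal$u_min); x_max <- min(vol_shape[1], coronal$u_max)
  y_min <- max(0L, sagittal$u_min); y_max <- min(vol_shape[2], sagittal$u_max)
  z_min <- max(0L, z_min); z_max <- min(vol_shape[3], z_max)
  if (x_min >= x_max || y_min >= y_max || z_min >= z_max)
    stop("combined box has empty intersection with the volume")
  bbox_3d(x_min, x_max, y_min, y_max, z_min, z_max)
}

#' Map a 3D box between two registered volume grids
#'
#' Converts voxel indices defined on one volume's grid into indices on
#' another grid through physical (mm) coordinates, for co-registered volumes
#' that are not identically gridded (e.g. a box defined on the CT applied to
#' the PET). The physical extent is preserved; bounds are rounded outward
#' and clipped to the target volume.
#'
#' @param box a \code{\link{bbox_3d}} on \code{from}'s grid.
#' @param from,to \code{\link{image_volume}} objects sharing a world frame.
#' @return A \code{\link{bbox_3d}} on \code{to}'s grid.
#' @export
map_box_grid <- function(box, from, to) {
  if (!inherits(box, "bbox_3d")) stop("'box' must be a bbox_3d")
  assert_volume(from); assert_volume(to)
  lo_idx <- c(box$x_min, box$y_min, box$z_min)
  hi_idx <- c(box$x_max, box$y_max, box$z_max)
  # physical bounds of the covered region (voxel centres at origin + i*spacing)
  lo_mm <- from$origin + (lo_idx - 0.5) * from$spacing
  hi_mm <- from$origin + (hi_idx - 0.5) * from$spacing
  lo_to <- floor((lo_mm - to$origin) / to$spacing + 0.5)
  hi_to <- ceiling((hi_mm - to$origin) / to$spacing + 0.5)
  d <- dim(to$voxels)
  lo_to <- pmax(0L, pmin(as.integer(lo_to), d - 1L))
  hi_to <- pmax(1L, pmin(as.integer(hi_to), d))
  if (any(lo_to >= hi_to))
    stop("mapped box has empty intersection with the target volume")
  bbox_3d(lo_to[1], hi_to[1], lo_to[2], hi_to[2], lo_to[3], hi_to[3])
}

#' Crop a volume to a 3D box
#'
#' @param vol an \code{\link{image_volume}}.
#' @param box a \code{\link{bbox_3d}} in \code{vol}'s index space; it is
#'   clipped to the volume and must retain positive extent.
#' @return The cropped \code{\link{image_volume}}; the origin is shifted by
#'   the box minimum times the spacing.
#' @export
crop_volume <- function(vol, box) {
  assert_volume(vol)
  if (!inherits(box, "bbox_3d")) stop("'box' must be a bbox_3d")
  d <- dim(vol$voxels)
  lo <- pmax(c(box$x_min, box$y_min, box$z_min), 0L)
  hi <- pmin(c(box$x_max, box$y_max, box$z_max), d)
  if (any(lo >= hi))
    stop("crop box is empty after clipping to the volume")
  vox <- vol$voxels[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3],
                    drop = FALSE]
  image_volume(vox, spacing = vol$spacing,
               origin = vol$origin + lo * vol$spacing,
               modality = vol$modality)
}
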