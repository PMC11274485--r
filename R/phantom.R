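#' Specification of the synthetic PET/CT phantom family
#'
#' Defines the geometry, intensity and survival parameters of the paired
#' PET/CT phantoms used to exercise the pipeline end to end. The CT contains
#' a vertical head/spine bone column topped by a skull blob and a horizontal
#' shoulder bar, all at \code{bone_hu} within the 700--2000 HU bone window,
#' over soft tissue; the PET contains a small number of ellipsoidal hot
#' lesions inside the head-and-neck subregion over a low background with
#' additive Gaussian noise. Survival times follow a Cox model whose hazard
#' depends on a per-patient lesion burden summary through effect
#' \code{beta}, with an exponential baseline and uniform administrative
#' censoring.
#'
#' @param shape integer length-3 grid shape (voxels).
#' @param spacing voxel spacing in mm.
#' @param bone_hu bone intensity in HU (must lie in [700, 2000]).
#' @param soft_hu soft-tissue background in HU.
#' @param column_width_range min/max width (voxels) of the bone column.
#' @param shoulder_frac_range vertical position of the shoulder bar as a
#'   fraction of the grid height.
#' @param lesion_count_range min/max number of PET lesions.
#' @param lesion_radius_range_mm min/max ellipsoid semi-axis in mm.
#' @param lesion_peak_range min/max lesion peak intensity (SUV-like).
#' @param pet_background PET background level.
#' @param noise_sd standard deviation of additive PET noise.
#' @param beta log-hazard effect per standard deviation of the lesion
#'   burden summary.
#' @param baseline_hazard exponential baseline hazard rate (per time unit).
#' @param censor_horizon_frac administrative censoring horizon as a multiple
#'   of the baseline mean survival time \code{1 / baseline_hazard}; the
#'   default 9 yields roughly 20 percent censoring under the default effect
#'   size.
#' @param box_margin dilation (voxels) of the bone extent that defines the
#'   ground-truth head-and-neck box.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(48, 48, 64), spacing = c(1, 1, 1),
                         bone_hu = 1200, soft_hu = 40,
                         column_width_range = c(8, 12),
                         shoulder_frac_range = c(0.25, 0.35),
                         lesion_count_range = c(1, 3),
                         lesion_radius_range_mm = c(3, 8),
                         lesion_peak_range = c(2, 10),
                         pet_background = 0.2, noise_sd = 0.1,
                         beta = 1.5, baseline_hazard = 0.05,
                         censor_horizon_frac = 9, box_margin = 8) {
  if (bone_hu < 700 || bone_hu > 2000)
    stop("'bone_hu' must lie inside the bone window [700, 2000]")
  if (min(lesion_peak_range) <= pet_background)
    stop("lesion peaks must exceed the PET background")
  if (baseline_hazard <= 0 || censor_horizon_frac <= 0)
    stop("hazard and censoring parameters must be positive")
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("'shape' must be three integers >= 16")
  structure(as.list(environment()), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%dx%d voxels, bone %g HU, %d-%d lesions, beta=%g\n",
              x$shape[1], x$shape[2], x$shape[3], x$bone_hu,
              x$lesion_count_range[1], x$lesion_count_range[2], x$beta))
  invisible(x)
}

#' Generate one paired CT/PET phantom with ground truth
#'
#' Deterministic for a fixed seed. The CT holds the bone scaffold (head
#' column + skull + shoulder bar) the cropping heuristic keys on; the PET
#' holds the hot lesions the survival signal derives from. The ground truth
#' records lesion centres, semi-axes and peaks, the true head-and-neck box,
#' and the lesion burden summary \code{s = log(1 + sum(peak * volume))}
#' (volumes in cm^3, a total-lesion-glycolysis-like quantity).
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param seed integer seed.
#' @return A list with elements \code{ct} and \code{pet}
#'   (\code{\link{image_volume}}), and \code{truth} (list with
#'   \code{lesions} data.frame, \code{box} (\code{\link{bbox_3d}}),
#'   \code{shoulder_row}, \code{column_span_x}, \code{column_span_y},
#'   \code{s}).
#' @export
make_phantom_pair <- function(spec, seed = 1) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec")
  with_seed(seed, {
    nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
    ct <- array(spec$soft_hu, spec$shape)
    w <- round(stats::runif(1, spec$column_width_range[1],
                            spec$column_width_range[2]))
    shoulder <- round(nz * stats::runif(1, spec$shoulder_frac_range[1],
                                        spec$shoulder_frac_range[2]))
    cx <- round(nx / 2 + stats::runif(1, -2, 2))
    cy <- round(ny / 2 + stats::runif(1, -2, 2))
    hw <- max(1L, floor(w / 2))
    x_col <- max(1, cx - hw):min(nx, cx + hw)
    y_col <- max(1, cy - hw):min(ny, cy + hw)
    z_top <- nz - 2L
    # head/spine column
    ct[x_col, y_col, shoulder:z_top] <- spec$bone_hu
    # skull: wider blob at the top of the column
    sk <- max(1L, hw + 3L)
    z_skull <- max(shoulder, z_top - 6L):z_top
    ct[max(1, cx - sk):min(nx, cx + sk),
       max(1, cy - sk):min(ny, cy + sk), z_skull] <- spec$bone_hu
    # shoulder bar: wide in x, thin in y and z
    bar_halfwidth <- round(nx * 0.4)
    bar <- shoulder:min(nz, shoulder + 2L)
    ct[max(1, cx - bar_halfwidth):min(nx, cx + bar_halfwidth),
       max(1, cy - 2):min(ny, cy + 2), bar] <- spec$bone_hu
    # ground-truth head-and-neck box (0-based half-open), bone extent + margin
    m <- spec$box_margin
    x_lo <- max(0L, min(x_col) - 1L - m); x_hi <- min(nx, max(x_col) + m)
    y_lo <- max(0L, min(y_col) - 1L - m); y_hi <- min(ny, max(y_col) + m)
    box <- bbox_3d(x_lo, x_hi, y_lo, y_hi, shoulder - 1L, z_top)

    # PET: ellipsoidal lesions inside the head-and-neck region
    pet <- array(spec$pet_background, spec$shape)
    k <- sample(spec$lesion_count_range[1]:spec$lesion_count_range[2], 1)
    lesions <- data.frame(x = integer(k), y = integer(k), z = integer(k),
                          rx = numeric(k), ry = numeric(k), rz = numeric(k),
                          peak = numeric(k))
    r_max <- spec$lesion_radius_range_mm[2]
    for (li in seq_len(k)) {
      r3 <- stats::runif(3, spec$lesion_radius_range_mm[1],
                         spec$lesion_radius_range_mm[2])
      peak <- stats::runif(1, spec$lesion_peak_range[1],
                           spec$lesion_peak_range[2])
      pad <- ceiling(r_max / spec$spacing) + 1
      lim <- function(lo, hi, p, n) {
        a <- max(lo + 1 + p, 1); b <- min(hi - p, n)
        if (a > b) stop("lesions cannot fit inside the head-and-neck region")
        round(stats::runif(1, a, b))
      }
      czx <- lim(box$x_min, box$x_max, pad[1], nx)
      czy <- lim(box$y_min, box$y_max, pad[2], ny)
      czz <- lim(box$z_min + round((box$z_max - box$z_min) / 4),
                 box$z_max, pad[3], nz)
      lesions[li, ] <- list(czx, czy, czz, r3[1], r3[2], r3[3], peak)
      ix <- max(1, czx - pad[1]):min(nx, czx + pad[1])
      iy <- max(1, czy - pad[2]):min(ny, czy + pad[2])
      iz <- max(1, czz - pad[3]):min(nz, czz + pad[3])
      dx2 <- ((ix - czx) * spec$spacing[1] / r3[1])^2
      dy2 <- ((iy - czy) * spec$spacing[2] / r3[2])^2
      dz2 <- ((iz - czz) * spec$spacing[3] / r3[3])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      prof <- spec$pet_background + (peak - spec$pet_background) * pmax(1 - d2, 0)
      pet[ix, iy, iz] <- pmax(pet[ix, iy, iz], prof)
    }
    if (spec$noise_sd > 0)
      pet <- pmax(pet + array(stats::rnorm(length(pet), sd = spec$noise_sd),
                              spec$shape), 0)
    vol_cm3 <- (4 / 3) * pi * lesions$rx * lesions$ry * lesions$rz / 1000
    s <- log(1 + sum(lesions$peak * vol_cm3))
    list(ct = image_volume(ct, spacing = spec$spacing, modality = "CT"),
         pet = image_volume(pet, spacing = spec$spacing, modality = "PET"),
         truth = list(lesions = lesions, box = box,
                      shoulder_row = shoulder - 1L,
                      column_span_x = c(min(x_col) - 1L, max(x_col)),
                      column_span_y = c(min(y_col) - 1L, max(y_col)),
                      s = s))
  })
}

#' Generate a synthetic cohort with Cox-linked survival
#'
#' Draws \code{n} phantom pairs and right-censored survival records whose
#' hazard depends on the standardised lesion burden summary through
#' \code{exp(beta * s_std)}: event times are exponential with rate
#' \code{baseline_hazard * exp(beta * s_std)} and censoring is uniform
#' administrative on \code{[0, horizon]}. The truth table carries each
#' patient's burden summary, its standardised value and the true linear risk
#' so oracle concordance can be computed alongside pipeline results.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param n cohort size (>= 2).
#' @param seed integer seed; per-patient phantom seeds are derived from it.
#' @param keep_volumes keep the CT/PET volumes in the result (set to
#'   \code{FALSE} to retain only truth and survival for large cohorts).
#' @return A list with \code{pairs} (list of \code{\link{make_phantom_pair}}
#'   results, or truth-only entries), \code{records}
#'   (\code{\link{survival_records}} data.frame) and \code{truth}
#'   (data.frame with \code{s}, \code{s_std}, \code{risk},
#'   \code{time_uncensored}).
#' @export
make_cohort <- function(spec, n, seed = 1, keep_volumes = TRUE) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec")
  if (n < 2L) stop("cohort size must be at least 2")
  pair_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  pairs <- vector("list", n)
  s <- numeric(n)
  for (i in seq_len(n)) {
    p <- make_phantom_pair(spec, seed = pair_seeds[i])
    s[i] <- p$truth$s
    pairs[[i]] <- if (keep_volumes) p else list(truth = p$truth)
  }
  s_sd <- stats::sd(s)
  if (!is.finite(s_sd) || s_sd < 1e-12) {
    warning("lesion burden has (near) zero variance; risks are uninformative")
    s_std <- rep(0, n)
  } else {
    s_std <- (s - mean(s)) / s_sd
  }
  risk <- spec$beta * s_std
  horizon <- spec$censor_horizon_frac / spec$baseline_hazard
  surv <- with_seed(seed + 1L, {
    t_event <- stats::rexp(n, rate = spec$baseline_hazard * exp(risk))
    t_cens <- stats::runif(n, 0, horizon)
    list(time = pmax(pmin(t_event, t_cens), 1e-8),
         event = t_event <= t_cens, t_event = t_event)
  })
  records <- survival_records(sprintf("P%04d", seq_len(n)), surv$time,
                              surv$event)
  truth <- data.frame(patient_id = records$patient_id, s = s,
                      s_std = s_std, risk = risk,
                      time_uncensored = surv$t_event)
  list(pairs = pairs, records = records, truth = truth, spec = spec,
       seed = seed)
}

#' Run the imaging half of the pipeline over a cohort
#'
#' For each patient: bone-window the CT, take coronal and sagittal
#' projections, propose the head-and-neck box with the landmark heuristic,
#' crop the registered PET, generate the MA-MIP stack and extract pooled
#' deep features. Returns the per-patient view matrices (and, optionally,
#' statistically fused feature rows).
#'
#' @param cohort result of \code{\link{make_cohort}} (with volumes), or any
#'   list of \code{list(ct = , pet = )} pairs.
#' @param step_deg MA-MIP angular step.
#' @param backbone_id frozen backbone id.
#' @param pooling global pooling method.
#' @param fusion optional statistical fusion; \code{"none"} returns view
#'   matrices only.
#' @param boxes optional list of pre-computed \code{\link{bbox_3d}} crop
#'   boxes (one per patient) bypassing the heuristic.
#' @param intensity_window fixed intensity window for
#'   \code{\link{prep_for_backbone}}; the default \code{c(0, 12)} keeps
#'   absolute uptake comparable across patients (the phantom lesion peaks
#'   stay below 12). Use \code{NULL} for per-image min--max.
#' @return A list with \code{view_matrices} (list of V x C matrices),
#'   \code{features} (N x C matrix or NULL), \code{crop_boxes}.
#' @export
extract_cohort_features <- function(cohort, step_deg = 5,
                                    backbone_id = "small", pooling = "avg",
                                    fusion = c("none", "cw_mean", "cw_median",
                                               "cw_max", "cw_std"),
                                    boxes = NULL,
                                    intensity_window = c(0, 12)) {
  fusion <- match.arg(fusion)
  pairs <- if (!is.null(cohort$pairs)) cohort$pairs else cohort
  bb <- load_backbone(backbone_id)
  vms <- vector("list", length(pairs))
  crop_boxes <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (is.null(p$ct) || is.null(p$pet))
      stop("cohort entries must carry 'ct' and 'pet' volumes")
    box <- if (!is.null(boxes)) boxes[[i]] else {
      bone <- clip_hu(p$ct)
      prop <- propose_boxes_heuristic(plane_mip(bone, "coronal"),
                                      plane_mip(bone, "sagittal"))
      box_ct <- combine_boxes_3d(prop$coronal, prop$sagittal,
                                 dim(p$ct$voxels))
      if (identical(dim(p$ct$voxels), dim(p$pet$voxels)) &&
          all(abs(p$ct$spacing - p$pet$spacing) < 1e-9) &&
          all(abs(p$ct$origin - p$pet$origin) < 1e-9)) box_ct
      else map_box_grid(box_ct, p$ct, p$pet)
    }
    crop_boxes[[i]] <- box
    stack <- generate_ma_mips(crop_volume(p$pet, box), step_deg = step_deg)
    vms[[i]] <- extract_mamip_features(stack, bb, pooling,
                                       intensity_window = intensity_window)
  }
  feats <- if (fusion == "none") NULL else
    t(vapply(vms, function(m) as.numeric(fuse_statistical(m, fusion)),
             numeric(ncol(vms[[1]]))))
  list(view_matrices = vms, features = feats, crop_boxes = crop_boxes,
       backbone_id = bb$id, pooling = pooling, step_deg = step_deg,
       fusion = fusion)
}
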