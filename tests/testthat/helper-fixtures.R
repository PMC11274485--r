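# Small in-code fixtures shared across test files.

# volume with a reproducible random pattern
random_volume <- function(dims, seed = 1, spacing = c(1, 1, 1),
                          modality = "PET") {
  set.seed(seed)
  image_volume(array(stats::runif(prod(dims)), dims), spacing = spacing,
               modality = modality)
}

# axially symmetric volume: value depends only on in-plane radius and z.
# quadratic radial profile keeps curvature small so bilinear resampling of
# rotated grids stays well inside the comparison tolerance
radial_volume <- function(n = 24, nz = 16, R2 = 900) {
  cx <- (n - 1) / 2
  r2 <- outer((seq_len(n) - 1 - cx)^2, (seq_len(n) - 1 - cx)^2, "+")
  slice <- 1 - r2 / R2
  vox <- array(0, c(n, n, nz))
  for (k in seq_len(nz)) vox[, , k] <- slice * (1 + k / nz)
  image_volume(vox, modality = "PET")
}

# a bone-window style projection with a head column and a shoulder bar
synthetic_bone_mip <- function(nu = 128, nv = 128, col_span = c(51, 70),
                               shoulder_row = 80, bone = 1500, bg = 700) {
  img <- matrix(bg, nu, nv)
  img[col_span[1]:col_span[2], shoulder_row:(nv - 8)] <- bone
  img[10:(nu - 10), shoulder_row:(shoulder_row + 2)] <- bone
  img
}

# brute-force Harrell c-index by explicit pair enumeration
cindex_bruteforce <- function(time, event, risk) {
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ti <- time[i]; tj <- time[j]; ei <- event[i]; ej <- event[j]
      if (ti == tj) {
        if (ei + ej != 1) next
        short <- if (ei) i else j
        long <- if (ei) j else i
      } else {
        short <- if (ti < tj) i else j
        long <- if (ti < tj) j else i
        if (!event[short]) next
      }
      den <- den + 1
      if (risk[short] > risk[long]) num <- num + 1
      else if (risk[short] == risk[long]) num <- num + 0.5
    }
  }
  if (den == 0) return(NaN)
  num / den
}

# small cohort of view matrices with a planted per-patient signal
planted_view_cohort <- function(n = 40, V = 8, C = 5, noise_sd = 0.1,
                                seed = 1) {
  set.seed(seed)
  signal <- stats::rnorm(n)
  mats <- lapply(seq_len(n), function(i)
    matrix(signal[i], V, C) + matrix(stats::rnorm(V * C, sd = noise_sd), V, C))
  list(mats = mats, signal = signal)
}
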