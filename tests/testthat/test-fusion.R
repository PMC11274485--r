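test_that("channel-wise statistical fusion matches per-column brute force", {
  m <- matrix(c(1, 2, 6, 10, 20, 30), nrow = 3)
  expect_equal(as.numeric(fuse_statistical(m, "cw_max")), c(6, 30))
  expect_equal(as.numeric(fuse_statistical(m, "cw_mean")), c(3, 20))
  expect_equal(as.numeric(fuse_statistical(m, "cw_median")), c(2, 20))
  expect_equal(as.numeric(fuse_statistical(m, "cw_std")),
               c(sqrt(14 / 3), sqrt(200 / 3)))

  set.seed(14)
  for (rep in 1:5) {
    m <- matrix(stats::rnorm(7 * 4), 7, 4)
    for (stat in c("cw_mean", "cw_median", "cw_max", "cw_std")) {
      oracle <- numeric(4)
      for (j in 1:4) {
        col <- m[, j]
        oracle[j] <- switch(stat, cw_mean = mean(col),
                            cw_median = stats::median(col),
                            cw_max = max(col),
                            cw_std = sqrt(mean((col - mean(col))^2)))
      }
      expect_equal(as.numeric(fuse_statistical(m, stat)), oracle,
                   tolerance = 1e-6)
      # permutation invariance over views
      perm <- m[sample(7), ]
      expect_equal(as.numeric(fuse_statistical(perm, stat)),
                   as.numeric(fuse_statistical(m, stat)), tolerance = 1e-12)
    }
  }

  # V identical rows; single-view edge case
  r <- c(2, -1, 5)
  mm <- matrix(r, 4, 3, byrow = TRUE)
  for (stat in c("cw_mean", "cw_median", "cw_max"))
    expect_equal(as.numeric(fuse_statistical(mm, stat)), r)
  expect_equal(as.numeric(fuse_statistical(mm, "cw_std")), c(0, 0, 0))
  single <- matrix(r, 1, 3)
  expect_equal(as.numeric(fuse_statistical(single, "cw_median")), r)
  expect_equal(as.numeric(fuse_statistical(single, "cw_std")), c(0, 0, 0))
})

test_that("ICA fusion application is the stated linear map", {
  model <- structure(list(fusion_id = "ica", V = 3, C = 2,
                          unmixing = cbind(c(1, 0, 0), c(1, 1, 1) / 3),
                          fallback = c(FALSE, FALSE), seed = 1),
                     class = "fusion_model")
  m <- matrix(c(1, 2, 6, 10, 20, 30), nrow = 3)
  out <- apply_ica_fusion(model, m)
  expect_equal(as.numeric(out)[1], m[1, 1])            # unit unmixing e1
  expect_equal(as.numeric(out)[2], mean(m[, 2]))       # uniform = cw_mean
  # random model + matrix vs explicit dot-product loop
  set.seed(15)
  W <- matrix(stats::rnorm(3 * 2), 3, 2)
  model$unmixing <- W
  got <- as.numeric(apply_ica_fusion(model, m))
  for (ch in 1:2) expect_equal(got[ch], sum(W[, ch] * m[, ch]))
  expect_error(apply_ica_fusion(model, matrix(0, 4, 2)), "fitted")
})

test_that("ICA fusion recovers a planted per-patient source", {
  ph <- planted_view_cohort(n = 100, V = 8, C = 3, noise_sd = 0.1, seed = 2)
  model <- fit_ica_fusion(ph$mats, seed = 5)
  model2 <- fit_ica_fusion(ph$mats, seed = 5)
  expect_identical(model$unmixing, model2$unmixing)    # determinism

  fused <- t(vapply(ph$mats, function(m) as.numeric(apply_ica_fusion(model, m)),
                    numeric(3)))
  for (ch in 1:3) {
    expect_gte(abs(stats::cor(fused[, ch], ph$signal)), 0.9)
  }
})

test_that("patient-constant views reproduce the patient ordering", {
  set.seed(16)
  vals <- stats::rnorm(30)
  mats <- lapply(vals, function(v) matrix(v, 6, 2))
  model <- fit_ica_fusion(mats, seed = 3)
  fused <- vapply(mats, function(m) as.numeric(apply_ica_fusion(model, m))[1],
                  numeric(1))
  expect_equal(abs(stats::cor(fused, vals, method = "spearman")), 1)
})

test_that("autoencoder fusion trains deterministically and compresses", {
  # identical inputs reconstruct (near) exactly and fuse identically
  m0 <- matrix(stats::rnorm(6 * 4), 6, 4)
  same <- lapply(1:8, function(i) m0)
  ae <- fit_autoencoder_fusion(same, latent_dim = 2, seed = 4, epochs = 300)
  rec <- reconstruct_autoencoder(ae, m0)
  expect_lt(sqrt(mean((rec - as.vector(m0))^2)) /
              (stats::sd(as.vector(m0)) + 1e-12), 0.05)
  f1 <- apply_autoencoder_fusion(ae, same[[1]])
  f2 <- apply_autoencoder_fusion(ae, same[[5]])
  expect_identical(f1, f2)
  expect_length(as.numeric(f1), 2L)

  # determinism under a fixed seed
  ae2 <- fit_autoencoder_fusion(same, latent_dim = 2, seed = 4, epochs = 300)
  expect_identical(ae$W1, ae2$W1)
  expect_identical(apply_autoencoder_fusion(ae2, m0), f1)

  # cohort on a planted 2D linear manifold compresses to latent 2
  set.seed(17)
  basis <- matrix(stats::rnorm(2 * 24), 2, 24)
  coords <- matrix(stats::rnorm(2 * 40), 40, 2)
  mats <- lapply(1:40, function(i)
    matrix(as.vector(coords[i, ] %*% basis), 6, 4))
  ae3 <- fit_autoencoder_fusion(mats, latent_dim = 2, seed = 6, epochs = 400)
  rel <- vapply(mats, function(m) {
    r <- reconstruct_autoencoder(ae3, m)
    sqrt(sum((r - as.vector(m))^2)) / sqrt(sum(as.vector(m)^2))
  }, numeric(1))
  expect_lte(mean(rel), 0.05)

  expect_error(fit_autoencoder_fusion(same, latent_dim = 24), "smaller")
  expect_error(apply_autoencoder_fusion(ae, matrix(0, 3, 3)), "fitted")
})

test_that("fitted fusions never mutate on application", {
  ph <- planted_view_cohort(n = 20, V = 5, C = 3, seed = 7)
  model <- fit_ica_fusion(ph$mats[1:12], seed = 2)
  before <- unserialize(serialize(model, NULL))
  for (m in ph$mats[13:20]) apply_ica_fusion(model, m)
  expect_identical(model, before)
  ae <- fit_autoencoder_fusion(ph$mats[1:12], latent_dim = 3, seed = 2,
                               epochs = 50)
  before_ae <- unserialize(serialize(ae, NULL))
  for (m in ph$mats[13:20]) apply_autoencoder_fusion(ae, m)
  expect_identical(ae, before_ae)
})
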