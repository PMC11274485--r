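test_that("standard scaling learns on train and transfers to test", {
  set.seed(20)
  X <- cbind(stats::rnorm(50, 5, 2), stats::rnorm(50, -1, 0.5), rep(3, 50))
  S <- scale_standard(X)
  expect_equal(unname(colMeans(S)), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(S[, 1:2], 2, function(x) sqrt(mean((x - mean(x))^2)))),
               c(1, 1), tolerance = 1e-6)
  expect_true(all(S[, 3] == 0))                    # constant feature -> zeros
  expect_equal(as.vector(scale_standard(matrix(c(0, 2), 2, 1))), c(-1, 1))
  # test rows use the training statistics, not their own
  Xte <- matrix(c(100, -100), 1, 2)
  St <- scale_standard(X[, 1:2], Xte)
  expect_equal(as.vector(St),
               (c(100, -100) - colMeans(X[, 1:2])) /
                 apply(X[, 1:2], 2, function(x) sqrt(mean((x - mean(x))^2))))
})

test_that("correlated-feature elimination is greedy and absolute", {
  set.seed(21)
  a <- stats::rnorm(60)
  X <- cbind(a, stats::rnorm(60), a + 1e-9 * stats::rnorm(60), -a,
             stats::rnorm(60))
  kept <- drop_correlated(X, threshold = 0.95)
  expect_equal(kept, c(1L, 2L, 5L))               # duplicate and negation dropped

  # independent features at n = 200: nothing dropped (across several seeds)
  for (seed in 1:5) {
    set.seed(seed)
    Z <- matrix(stats::rnorm(200 * 8), 200, 8)
    expect_equal(drop_correlated(Z, 0.95), 1:8)
  }
})

test_that("ICA reduction is invertible at full rank and finds planted sources", {
  set.seed(22)
  X <- matrix(stats::runif(80 * 5)^2, 80, 5) %*% matrix(stats::rnorm(25), 5)
  X <- X + stats::rnorm(400, sd = 0.01)
  red <- reduce_ica(X, 5, seed = 2)
  Z <- apply_reduction(red, X)
  back <- Z %*% red$mixing
  recon <- sweep(back, 2, -red$center)
  expect_lt(max(abs(recon - X)), 1e-6)

  red2 <- reduce_ica(X, 5, seed = 2)
  expect_identical(red$unmix, red2$unmix)         # determinism

  # three planted independent non-Gaussian sources under a random mixing
  set.seed(23)
  S <- cbind(stats::runif(400, -1, 1)^3, sign(stats::rnorm(400)),
             stats::rexp(400) - 1)
  A <- matrix(stats::rnorm(3 * 6), 3, 6)
  Xm <- S %*% A
  red3 <- reduce_ica(Xm, 3, seed = 3)
  Z3 <- apply_reduction(red3, Xm)
  cors <- abs(stats::cor(Z3, S))
  # each source matched by some component up to permutation/sign
  expect_true(all(apply(cors, 2, max) >= 0.9))
})

test_that("Cox fitting orders risk as the planted effect dictates", {
  set.seed(24)
  n <- 50
  x <- stats::rnorm(n)
  # times (almost) deterministically decrease in x: near-perfect ordering
  tm <- exp(-3 * x + stats::rnorm(n, sd = 0.3))
  rec <- survival_records(paste0("p", 1:n), tm, rep(TRUE, n))
  fit <- fit_cox(matrix(x), rec)
  expect_gte(concordance_index(rec, predict(fit, matrix(x))), 0.95)
  fit2 <- fit_cox(matrix(x), rec)
  expect_identical(fit$coef, fit2$coef)

  # a feature unrelated to outcome: small coefficient, test c-index near 1/2
  set.seed(25)
  n2 <- 200
  x2 <- stats::rnorm(n2)
  tm2 <- stats::rexp(n2, rate = 0.1)
  rec2 <- survival_records(paste0("q", 1:n2), tm2, stats::runif(n2) < 0.8)
  half <- 1:100
  fit_null <- fit_cox(matrix(x2[half]), rec2[half, ])
  expect_lt(abs(fit_null$coef), 0.5)
  ci_test <- concordance_index(rec2[-half, ], x2[-half] * fit_null$coef)
  expect_gt(ci_test, 0.4); expect_lt(ci_test, 0.6)

  expect_error(fit_cox(matrix(x), survival_records(paste0("p", 1:n), tm,
                                                   rep(FALSE, n))),
               "event")
})

test_that("concordance index equals exhaustive pair enumeration", {
  # perfect ordering, all events
  tm <- c(5, 4, 3, 2, 1); rk <- 1:5
  rec <- survival_records(letters[1:5], tm, rep(TRUE, 5))
  expect_equal(concordance_index(rec, rk), 1.0)
  expect_equal(concordance_index(rec, rep(0, 5)), 0.5)   # all risks tied

  # hand-checkable mixed-censoring cohort
  rec5 <- survival_records(LETTERS[1:5], c(2, 3, 3, 7, 8),
                           c(TRUE, TRUE, FALSE, FALSE, TRUE))
  rk5 <- c(3, 1, 2, 2, 0)
  expect_equal(concordance_index(rec5, rk5),
               cindex_bruteforce(rec5$time, rec5$event, rk5))

  set.seed(26)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    tm <- sample(1:15, n, replace = TRUE)      # force time ties
    ev <- stats::runif(n) < 0.6
    rk <- sample(1:6, n, replace = TRUE)       # force risk ties
    rec <- survival_records(paste0("p", 1:n), tm, ev)
    expect_identical(concordance_index(rec, rk),
                     cindex_bruteforce(tm, ev, rk))
  }
})

test_that("sign-flipped risks mirror the c-index around one half", {
  set.seed(27)
  n <- 60
  tm <- stats::rexp(n); ev <- stats::runif(n) < 0.7
  rk <- stats::rnorm(n)                         # continuous: no risk ties
  rec <- survival_records(paste0("p", 1:n), tm, ev)
  expect_equal(concordance_index(rec, -rk), 1 - concordance_index(rec, rk),
               tolerance = 1e-12)
})

test_that("nested CV is deterministic, leakage-free and sane on synthetic data", {
  set.seed(28)
  N <- 80
  s <- stats::rnorm(N)
  X <- cbind(vapply(1:5, function(i) s + stats::rnorm(N, sd = 0.4),
                    numeric(N)),
             matrix(stats::rnorm(N * 5), N))
  te <- stats::rexp(N, rate = 0.05 * exp(1.5 * s))
  tc <- stats::runif(N, 0, 180)
  rec <- survival_records(paste0("p", 1:N), pmin(te, tc), te <= tc)
  grid <- list(n_components = c(3, 6), penalty = c(0, 0.1),
               cor_threshold = 0.95)
  res <- nested_cv(X, rec, n_repeats = 2, n_outer = 5, n_inner = 3,
                   grid = grid, seed = 11)
  expect_s3_class(res, "mamip_cv")
  expect_equal(nrow(res$per_split), 10L)
  expect_equal(res$mean, mean(res$per_split$cindex), tolerance = 1e-12)
  expect_gt(res$mean, 0.65)                     # informative features help
  expect_equal(res$n_failed, 0L)

  res2 <- nested_cv(X, rec, n_repeats = 2, n_outer = 5, n_inner = 3,
                    grid = grid, seed = 11)
  expect_identical(cv_result_json(res), cv_result_json(res2))
  expect_true(isTRUE(audit_leakage(res, X, rec)))

  # summary and plot accessors work
  sm <- summary(res)
  expect_s3_class(sm, "summary.mamip_cv")
  expect_equal(sm$n_splits, 10L)
  pdf(NULL); on.exit(dev.off(), add = TRUE)
  expect_invisible(plot(res))
})

test_that("nested CV supports fold-safe fitted fusion over view matrices", {
  ph <- planted_view_cohort(n = 40, V = 6, C = 4, noise_sd = 0.2, seed = 9)
  te <- stats::rexp(40, rate = 0.05 * exp(1.5 * scale(ph$signal)[, 1]))
  tc <- stats::runif(40, 0, 180)
  rec <- survival_records(paste0("p", 1:40), pmin(te, tc), te <= tc)
  res <- nested_cv(NULL, rec, n_repeats = 1, n_outer = 5, n_inner = 2,
                   grid = list(n_components = 2, penalty = 0.1,
                               cor_threshold = 0.99),
                   seed = 13, view_matrices = ph$mats, fusion = "ica")
  expect_equal(nrow(res$per_split), 5L)
  expect_true(all(is.finite(res$per_split$cindex)))
  expect_true(isTRUE(audit_leakage(res, NULL, rec,
                                   view_matrices = ph$mats)))
})
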