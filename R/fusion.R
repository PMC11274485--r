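## ---- multi-view feature fusion ----------------------------------------

as_view_matrix <- function(m) {
  if (inherits(m, "feature_matrix") || is.matrix(m)) {
    out <- unclass(m)
    attributes(out) <- list(dim = dim(out))
    return(out)
  }
  stop("expected a V x C feature matrix")
}

#' Channel-wise statistical fusion of multi-view features
#'
#' Collapses the V x C views-by-channels feature matrix of one patient into a
#' single length-C vector by taking, per channel (column), the maximum, mean,
#' median, or population standard deviation across views. These fusions are
#' permutation-invariant over views and require no fitting.
#'
#' @param m a V x C \code{feature_matrix} (or plain matrix).
#' @param stat one of \code{"cw_mean"}, \code{"cw_median"}, \code{"cw_max"},
#'   \code{"cw_std"}.
#' @return Numeric vector of length C with attribute \code{fusion_id}.
#' @export
fuse_statistical <- function(m, stat = c("cw_mean", "cw_median", "cw_max",
                                         "cw_std")) {
  stat <- match.arg(stat)
  x <- as_view_matrix(m)
  if (nrow(x) < 1L) stop("need at least one view")
  out <- switch(stat,
                cw_mean = colMeans(x),
                cw_median = apply(x, 2, stats::median),
                cw_max = apply(x, 2, max),
                cw_std = {
                  mu <- colMeans(x)
                  sqrt(pmax(colMeans(x^2) - mu^2, 0))
                })
  structure(out, fusion_id = stat)
}

## ---- FastICA (logcosh nonlinearity, deflation) ------------------------
##
## X: n x d data matrix (rows = observations). Returns unmixing directions in
## the original (centred) variable space: s = Xc %*% unmix gives the
## n x n_comp source estimates. No dedicated ICA package ships with the
## supported toolchain, so the fixed-point iteration is implemented here.
fastica_fit <- function(X, n_comp, seed, maxit = 200, tol = 1e-4) {
  n <- nrow(X); d <- ncol(X)
  if (n_comp > min(n - 1, d))
    stop("n_comp exceeds what the data can support")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  cv <- crossprod(Xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-10)
  if (length(keep) < n_comp)
    stop("data rank is below the requested number of components")
  keep <- keep[seq_len(max(n_comp, min(length(keep), n_comp)))]
  K <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[keep]), length(keep))   # d x k whitening
  Z <- Xc %*% K                                     # n x k, identity cov
  W <- matrix(0, ncol(K), n_comp)
  converged <- logical(n_comp)
  ws <- with_seed(seed, matrix(stats::rnorm(ncol(K) * n_comp), ncol(K)))
  for (p in seq_len(n_comp)) {
    w <- ws[, p]
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(maxit)) {
      wx <- Z %*% w
      g <- tanh(wx)
      gp <- 1 - g^2
      w_new <- colMeans(Z * as.vector(g)) - mean(gp) * w
      if (p > 1) {
        proj <- W[, seq_len(p - 1), drop = FALSE]
        w_new <- w_new - proj %*% crossprod(proj, w_new)
      }
      nrm <- sqrt(sum(w_new^2))
      if (nrm < 1e-12) break
      w_new <- w_new / nrm
      delta <- abs(abs(sum(w_new * w)) - 1)
      w <- as.vector(w_new)
      if (delta < tol) { converged[p] <- TRUE; break }
    }
    W[, p] <- w
  }
  unmix <- K %*% W                                  # d x n_comp
  list(center = center, unmix = unmix, whitening = K, rotation = W,
       converged = converged)
}

#' Fit per-channel ICA fusion on a training cohort
#'
#' For each feature channel c, the cohort's N x V matrix of that channel's
#' view values (patients as observations, views as mixed signals) is reduced
#' to a single independent component. The fitted unmixing vector (length V,
#' unit norm) summarises the V view values of any patient into one number per
#' channel. Sign indeterminacy is resolved so that the component correlates
#' non-negatively with the channel's cross-view mean; channels with (near-)
#' constant values across the cohort bypass ICA and use uniform weights
#' \code{1/V}, reproducing the constant. Channels whose fixed-point iteration
#' does not converge fall back to the first principal direction (recorded in
#' the model's \code{fallback} field).
#'
#' @param cohort list of V x C \code{feature_matrix} objects, one per
#'   training patient; at least 2, all sharing V and C.
#' @param seed integer seed; fitting is deterministic given the seed.
#' @return A \code{fusion_model} with \code{fusion_id = "ica"} holding the
#'   V x C unmixing matrix.
#' @export
fit_ica_fusion <- function(cohort, seed = 1) {
  mats <- lapply(cohort, as_view_matrix)
  n <- length(mats)
  if (n < 2L) stop("ICA fusion needs at least 2 training patients")
  V <- nrow(mats[[1]]); C <- ncol(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == c(V, C)), logical(1))))
    stop("all feature matrices must share the same V x C shape")
  unmix <- matrix(0, V, C)
  fallback <- logical(C)
  for (ch in seq_len(C)) {
    X <- t(vapply(mats, function(m) m[, ch], numeric(V)))  # N x V
    if (stats::sd(as.vector(X)) < 1e-12 ||
        all(apply(X, 2, stats::sd) < 1e-12)) {
      unmix[, ch] <- rep(1 / V, V)                         # constant channel
      next
    }
    fit <- tryCatch(fastica_fit(X, 1L, seed = seed + ch), error = function(e) NULL)
    w <- if (!is.null(fit) && fit$converged[1]) as.vector(fit$unmix)
         else {
           fallback[ch] <- TRUE
           pc <- eigen(stats::cov(X), symmetric = TRUE)$vectors[, 1]
           as.vector(pc)
         }
    w <- w / sqrt(sum(w^2))
    fused <- X %*% w
    r <- suppressWarnings(stats::cor(fused, rowMeans(X)))
    if (is.finite(r) && r < 0) w <- -w
    unmix[, ch] <- w
  }
  structure(list(fusion_id = "ica", V = V, C = C, unmixing = unmix,
                 fallback = fallback, seed = seed),
            class = "fusion_model")
}

#' Apply a fitted ICA fusion model
#'
#' \code{output[c]} is the dot product of the fitted unmixing vector for
#' channel c with the patient's column c of view values. Applying never
#' updates the model.
#'
#' @param model a \code{fusion_model} from \code{\link{fit_ica_fusion}}.
#' @param m a V x C \code{feature_matrix}.
#' @return Numeric vector of length C with attribute \code{fusion_id}.
#' @export
apply_ica_fusion <- function(model, m) {
  if (!inherits(model, "fusion_model") || model$fusion_id != "ica")
    stop("'model' must be a fitted ICA fusion_model")
  x <- as_view_matrix(m)
  if (nrow(x) != model$V || ncol(x) != model$C)
    stop(sprintf("feature matrix is %dx%d but model was fitted on %dx%d",
                 nrow(x), ncol(x), model$V, model$C))
  structure(colSums(x * model$unmixing), fusion_id = "ica")
}

#' Fit autoencoder fusion on a training cohort
#'
#' Trains a single-hidden-layer autoencoder (affine encoder and decoder) on
#' the patients' flattened V*C view-feature vectors with mean-squared
#' reconstruction loss, full-batch Adam, and a fixed seed for deterministic
#' initialisation. Inputs are standardised internally (the scaling is stored
#' with the model). The encoder output is the fused representation.
#'
#' @param cohort list of V x C \code{feature_matrix} objects (>= 2 patients).
#' @param latent_dim latent width; must be < V*C. Default 32.
#' @param seed integer seed.
#' @param epochs full-batch training epochs.
#' @param lr Adam learning rate.
#' @return A \code{fusion_model} with \code{fusion_id = "autoencoder"}.
#' @export
fit_autoencoder_fusion <- function(cohort, latent_dim = 32, seed = 1,
                                   epochs = 200, lr = 0.01) {
  mats <- lapply(cohort, as_view_matrix)
  n <- length(mats)
  if (n < 2L) stop("autoencoder fusion needs at least 2 training patients")
  V <- nrow(mats[[1]]); C <- ncol(mats[[1]])
  d <- V * C
  if (latent_dim >= d)
    stop(sprintf("latent_dim (%d) must be smaller than V*C (%d)",
                 latent_dim, d))
  X <- t(vapply(mats, as.vector, numeric(d)))        # n x d
  center <- colMeans(X)
  scale <- pop_sd(as.vector(sweep(X, 2, center)))
  if (scale < 1e-12) scale <- 1
  Xs <- sweep(X, 2, center) / scale
  params <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(d * latent_dim, sd = 1 / sqrt(d)), d, latent_dim),
    b1 = rep(0, latent_dim),
    W2 = matrix(stats::rnorm(latent_dim * d, sd = 1 / sqrt(latent_dim)),
                latent_dim, d),
    b2 = rep(0, d)))
  adam <- lapply(params, function(p) list(m = p * 0, v = p * 0))
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  loss <- NA_real_
  for (ep in seq_len(epochs)) {
    H <- sweep(Xs %*% params$W1, 2, params$b1, "+")   # n x L
    R <- sweep(H %*% params$W2, 2, params$b2, "+")    # n x d
    E <- R - Xs
    loss <- mean(E^2)
    gR <- 2 * E / (n * d)
    grads <- list(
      W1 = crossprod(Xs, gR %*% t(params$W2)),
      b1 = colSums(gR %*% t(params$W2)),
      W2 = crossprod(H, gR),
      b2 = colSums(gR))
    for (nm in names(params)) {
      adam[[nm]]$m <- b1m * adam[[nm]]$m + (1 - b1m) * grads[[nm]]
      adam[[nm]]$v <- b2m * adam[[nm]]$v + (1 - b2m) * grads[[nm]]^2
      mhat <- adam[[nm]]$m / (1 - b1m^ep)
      vhat <- adam[[nm]]$v / (1 - b2m^ep)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(list(fusion_id = "autoencoder", V = V, C = C,
                 latent_dim = latent_dim, center = center, scale = scale,
                 W1 = params$W1, b1 = params$b1, W2 = params$W2,
                 b2 = params$b2, final_loss = loss, epochs = epochs,
                 seed = seed),
            class = "fusion_model")
}

#' Apply a fitted autoencoder fusion model
#'
#' Encodes the patient's flattened and standardised V*C vector with the
#' trained encoder; the fused vector has length \code{latent_dim}.
#'
#' @param model a \code{fusion_model} from
#'   \code{\link{fit_autoencoder_fusion}}.
#' @param m a V x C \code{feature_matrix}.
#' @return Numeric vector of length \code{latent_dim}.
#' @export
apply_autoencoder_fusion <- function(model, m) {
  if (!inherits(model, "fusion_model") || model$fusion_id != "autoencoder")
    stop("'model' must be a fitted autoencoder fusion_model")
  x <- as_view_matrix(m)
  if (nrow(x) != model$V || ncol(x) != model$C)
    stop(sprintf("feature matrix is %dx%d but model was fitted on %dx%d",
                 nrow(x), ncol(x), model$V, model$C))
  xs <- (as.vector(x) - model$center) / model$scale
  structure(as.vector(xs %*% model$W1 + model$b1), fusion_id = "autoencoder")
}

#' Reconstruct inputs with a fitted autoencoder (for diagnostics)
#'
#' @param model an autoencoder \code{fusion_model}.
#' @param m a V x C \code{feature_matrix}.
#' @return Numeric vector of length V*C on the original input scale.
#' @export
reconstruct_autoencoder <- function(model, m) {
  if (!inherits(model, "fusion_model") || model$fusion_id != "autoencoder")
    stop("'model' must be a fitted autoencoder fusion_model")
  h <- apply_autoencoder_fusion(model, m)
  as.vector(h %*% model$W2 + model$b2) * model$scale + model$center
}

#' @export
print.fusion_model <- function(x, ...) {
  if (x$fusion_id == "ica") {
    cat(sprintf("<fusion_model ica> V=%d views, C=%d channels (%d PCA fallbacks)\n",
                x$V, x$C, sum(x$fallback)))
  } else {
    cat(sprintf("<fusion_model autoencoder> %d -> %d latent, final MSE %.3g\n",
                x$V * x$C, x$latent_dim, x$final_loss))
  }
  invisible(x)
}

#' Fuse a patient's feature matrix with any supported scheme
#'
#' Convenience dispatcher over the six fusion schemes: the four channel-wise
#' statistics need no model; \code{"ica"} and \code{"autoencoder"} require a
#' fitted \code{fusion_model}.
#'
#' @param m a V x C \code{feature_matrix}.
#' @param method fusion id.
#' @param model fitted \code{fusion_model} for the learned schemes.
#' @return Fused numeric vector.
#' @export
fuse_views <- function(m, method = c("cw_mean", "cw_median", "cw_max",
                                     "cw_std", "ica", "autoencoder"),
                       model = NULL) {
  method <- match.arg(method)
  if (method %in% c("ica", "autoencoder")) {
    if (is.null(model))
      stop(sprintf("fusion '%s' requires a fitted model", method))
    if (method == "ica") return(apply_ica_fusion(model, m))
    return(apply_autoencoder_fusion(model, m))
  }
  fuse_statistical(m, method)
}
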