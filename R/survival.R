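#' Validate a table of right-censored survival records
#'
#' @param patient_id character vector of unique ids.
#' @param time positive event/censoring times (one consistent unit).
#' @param event logical (or 0/1): \code{TRUE} if the event (recurrence) was
#'   observed, \code{FALSE} if censored.
#' @return A validated data.frame with columns \code{patient_id},
#'   \code{time}, \code{event}.
#' @export
survival_records <- function(patient_id, time, event) {
  patient_id <- as.character(patient_id)
  time <- as.numeric(time)
  event <- as.logical(event)
  if (anyDuplicated(patient_id)) stop("patient ids must be unique")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("all survival times must be positive and finite")
  if (any(is.na(event))) stop("event flags must be TRUE/FALSE")
  if (length(time) != length(patient_id) || length(event) != length(time))
    stop("patient_id, time and event must have equal length")
  data.frame(patient_id = patient_id, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Standard scaling fitted on a training cohort
#'
#' Per-feature centring and scaling to unit variance, with the mean and
#' (population) standard deviation estimated on the training rows only and
#' applied unchanged elsewhere. Zero-variance features map to 0.
#'
#' @param train numeric training matrix (rows = patients).
#' @param apply_to matrix to transform with the training statistics;
#'   defaults to \code{train}.
#' @return The scaled \code{apply_to} matrix, with the fitted \code{center}
#'   and \code{scale} vectors as attributes.
#' @export
scale_standard <- function(train, apply_to = train) {
  train <- as.matrix(train)
  apply_to <- as.matrix(apply_to)
  if (nrow(train) < 1L) stop("'train' must be non-empty")
  if (ncol(apply_to) != ncol(train))
    stop("'apply_to' must have the same features as 'train'")
  center <- colMeans(train)
  scale <- apply(train, 2, pop_sd)
  out <- sweep(apply_to, 2, center)
  nz <- scale > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, scale[nz], "/")
  out[, !nz] <- 0
  structure(out, center = center, scale = scale)
}

#' Greedy elimination of highly correlated features
#'
#' Scans features in order; feature j is dropped when its absolute Pearson
#' correlation with any earlier kept feature reaches \code{threshold}. The
#' returned index set is computed on the training rows only and must be
#' applied identically to held-out rows.
#'
#' @param train numeric matrix with at least 3 rows.
#' @param threshold drop threshold on |r|; default 0.95.
#' @return Integer vector of kept (1-based) column indices.
#' @export
drop_correlated <- function(train, threshold = 0.95) {
  train <- as.matrix(train)
  if (nrow(train) < 3L) stop("need at least 3 rows to estimate correlations")
  d <- ncol(train)
  if (d == 0L) return(integer(0))
  cm <- suppressWarnings(abs(stats::cor(train)))
  cm[is.na(cm)] <- 0                     # constant features correlate with nothing
  kept <- integer(0)
  for (j in seq_len(d)) {
    if (!length(kept) || all(cm[j, kept] < threshold)) kept <- c(kept, j)
  }
  kept
}

#' ICA dimensionality reduction fitted on a training fold
#'
#' Fits FastICA (logcosh, deflation) on the training matrix and returns a
#' transform that maps any matrix with the same columns into the
#' \code{n_components}-dimensional source space. Deterministic for a fixed
#' seed; if the fixed-point iteration fails to converge the fit is retried
#' with perturbed seeds, then handled per \code{on_fail}.
#'
#' @param train numeric training matrix.
#' @param n_components number of components,
#'   \code{<= min(nrow(train) - 1, ncol(train))}.
#' @param seed integer seed.
#' @param max_retries how many perturbed seeds to try after a
#'   non-convergent fit.
#' @param on_fail after all retries, either \code{"warn"} (default: keep the
#'   last orthonormal iterate, which still spans the whitened subspace --
#'   near-Gaussian features admit no unique independent directions, so this
#'   is the expected regime for weakly structured data) or \code{"error"}.
#' @return An object of class \code{ica_reduction} with fields
#'   \code{center}, \code{unmix} (D x K) and \code{mixing} (K x D, the
#'   pseudo-inverse, for reconstruction).
#' @export
reduce_ica <- function(train, n_components, seed = 1, max_retries = 3,
                       on_fail = c("warn", "error")) {
  on_fail <- match.arg(on_fail)
  train <- as.matrix(train)
  if (n_components > min(nrow(train) - 1, ncol(train)))
    stop("n_components must be <= min(N - 1, D)")
  fit <- NULL
  for (k in 0:max_retries) {
    fit <- fastica_fit(train, n_components, seed = seed + 1000L * k)
    if (all(fit$converged)) break
  }
  if (!all(fit$converged)) {
    msg <- sprintf("ICA did not converge for %d of %d components after %d retries",
                   sum(!fit$converged), n_components, max_retries)
    if (on_fail == "error") stop(msg)
    warning(msg)
  }
  structure(list(center = fit$center, unmix = fit$unmix,
                 mixing = pinv(fit$unmix), n_components = n_components,
                 seed = seed),
            class = "ica_reduction")
}

#' Apply a fitted ICA reduction
#'
#' @param reduction an \code{ica_reduction}.
#' @param x matrix (or vector) with the training feature columns.
#' @return Matrix of source estimates, \code{nrow(x)} x K.
#' @export
apply_reduction <- function(reduction, x) {
  if (!inherits(reduction, "ica_reduction"))
    stop("'reduction' must come from reduce_ica()")
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != length(reduction$center))
    stop("feature count mismatch with the fitted reduction")
  sweep(x, 2, reduction$center) %*% reduction$unmix
}

#' Fit a Cox proportional-hazards risk model
#'
#' Partial-likelihood fit of a linear Cox model on the given features, with
#' an optional ridge penalty on the coefficients. Returns linear risk scores
#' (higher = higher hazard). If the unpenalised fit fails (separation or
#' non-convergence), the fit is retried with a small ridge penalty before
#' erroring.
#'
#' @param train_features numeric matrix of predictors (rows = patients).
#' @param train_records survival records aligned with the rows (see
#'   \code{\link{survival_records}}); at least one event required.
#' @param penalty ridge penalty (0 = plain partial likelihood).
#' @return An object of class \code{mamip_cox} with the coefficient vector.
#' @export
fit_cox <- function(train_features, train_records, penalty = 0) {
  X <- as.matrix(train_features)
  if (nrow(X) != nrow(train_records))
    stop("features and records must align")
  if (!any(train_records$event))
    stop("cannot fit a Cox model without any observed events")
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$.time <- train_records$time
  df$.event <- as.integer(train_records$event)
  fit_once <- function(theta) {
    rhs <- if (theta > 0)
      sprintf("survival::ridge(%s, theta = %g, scale = FALSE)",
              paste(names(df)[seq_len(ncol(X))], collapse = ", "), theta)
    else paste(names(df)[seq_len(ncol(X))], collapse = " + ")
    fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
    suppressWarnings(survival::coxph(fml, data = df, ties = "breslow"))
  }
  fit <- tryCatch(fit_once(penalty), error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(stats::coef(fit))))
    fit <- tryCatch(fit_once(max(penalty, 0) + 1), error = function(e)
      stop("Cox fit failed even with an increased ridge penalty",
           call. = FALSE))
  beta <- as.vector(stats::coef(fit))
  if (any(!is.finite(beta)))
    stop("Cox fit produced non-finite coefficients")
  structure(list(coef = beta, penalty = penalty, n_features = ncol(X),
                 n_events = sum(train_records$event)),
            class = "mamip_cox")
}

#' @export
print.mamip_cox <- function(x, ...) {
  cat(sprintf("<mamip_cox> %d features, %d events, ridge penalty %g\n",
              x$n_features, x$n_events, x$penalty))
  cat("  coefficients:", format(x$coef, digits = 3), "\n")
  invisible(x)
}

#' Linear risk scores from a fitted Cox model
#'
#' @param object a \code{mamip_cox} model.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return Numeric vector of linear predictors (higher = higher hazard).
#' @export
predict.mamip_cox <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features)
    stop("feature count mismatch with the fitted Cox model")
  as.vector(X %*% object$coef)
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose predicted risk ordering agrees
#' with the observed event-time ordering. A pair is comparable when the
#' patient with the shorter time had the event, or when times are tied and
#' exactly one patient had the event; pairs with tied times and two events
#' are not comparable. A risk tie contributes 0.5.
#'
#' @param records survival records (see \code{\link{survival_records}}).
#' @param risks numeric risk scores aligned with the records (higher =
#'   higher predicted hazard).
#' @return The c-index in \code{[0, 1]}; \code{NaN} with a warning when no
#'   pair is comparable.
#' @export
concordance_index <- function(records, risks) {
  t <- records$time; e <- as.logical(records$event); r <- as.numeric(risks)
  n <- length(t)
  if (length(r) != n) stop("records and risks must have equal length")
  lt <- outer(t, t, "<")
  eq <- outer(t, t, "==")
  # [i, j] marks the comparable pair with i the shorter-time event patient,
  # or the event patient of a (event, censored) time tie
  comp <- (lt & e) | (eq & outer(e, !e, "&"))
  if (!any(comp)) {
    warning("no comparable pairs; c-index undefined")
    return(NaN)
  }
  conc <- outer(r, r, ">") + 0.5 * outer(r, r, "==")
  sum(conc[comp]) / sum(comp)
}

## ---- nested cross-validation ------------------------------------------

## stratified-by-event fold assignment (keeps events spread over folds)
make_folds <- function(event, k, seed) {
  fold <- integer(length(event))
  with_seed(seed, {
    for (grp in unique(event)) {
      idx <- which(event == grp)
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  fold
}

## Fit the full preprocessing + Cox pipeline on one training set.
fit_pipeline <- function(X, records, n_components, penalty, cor_threshold,
                         seed) {
  Xs <- scale_standard(X)
  center <- attr(Xs, "center"); scl <- attr(Xs, "scale")
  kept <- drop_correlated(Xs, threshold = cor_threshold)
  if (!length(kept)) stop("correlation filter removed every feature")
  rank <- qr(Xs[, kept, drop = FALSE])$rank
  k <- min(n_components, length(kept), nrow(X) - 1, rank)
  red <- reduce_ica(Xs[, kept, drop = FALSE], k, seed = seed)
  Z <- apply_reduction(red, Xs[, kept, drop = FALSE])
  cox <- fit_cox(Z, records, penalty = penalty)
  list(center = center, scale = scl, kept = kept, reduction = red,
       cox = cox, n_components = k, penalty = penalty,
       cor_threshold = cor_threshold, seed = seed)
}

apply_pipeline <- function(fit, X) {
  X <- as.matrix(X)
  out <- sweep(X, 2, fit$center)
  nz <- fit$scale > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, fit$scale[nz], "/")
  out[, !nz] <- 0
  Z <- apply_reduction(fit$reduction, out[, fit$kept, drop = FALSE])
  predict(fit$cox, Z)
}

pipeline_hash <- function(fit) {
  content_hash(list(fit$center, fit$scale, fit$kept, fit$reduction$center,
                    fit$reduction$unmix, fit$cox$coef))
}

#' Repeated nested cross-validated Cox survival analysis
#'
#' The outcome-prediction pipeline: outer 5-fold cross-validation (80/20)
#' repeated with reshuffled folds, an inner 5-fold grid search over the ICA
#' component count, ridge penalty and correlation threshold on the
#' outer-training data only, and Harrell's c-index on each untouched outer
#' test fold. Every fitted object -- scaler, kept-feature set, ICA
#' reduction, fitted fusion model where applicable, and the Cox model -- is
#' learned on outer-training data and applied exactly once to the outer test
#' fold. Fold assignment is stratified by event status so every training
#' fold contains events.
#'
#' Instead of a pre-fused feature matrix, per-patient V x C view matrices
#' can be supplied with a fusion scheme: statistical fusions are applied up
#' front (they need no fitting), while ICA and autoencoder fusion are fitted
#' per outer-training fold to keep the evaluation leakage-free.
#'
#' @param features N x D numeric matrix of per-patient features, or
#'   \code{NULL} when \code{view_matrices} is given.
#' @param records survival records aligned with the rows.
#' @param n_repeats repetitions of the outer 5-fold split (20 in the full
#'   protocol).
#' @param n_outer,n_inner outer and inner fold counts.
#' @param grid named list of hyperparameter candidates:
#'   \code{n_components}, \code{penalty}, \code{cor_threshold}.
#' @param seed master seed; the full procedure is deterministic given it.
#' @param view_matrices optional list of V x C \code{feature_matrix}
#'   objects, one per patient.
#' @param fusion fusion scheme used with \code{view_matrices}.
#' @param fusion_args extra arguments for the fitted fusion schemes
#'   (e.g. \code{latent_dim}, \code{epochs}).
#' @param keep_fits keep the numeric content of every outer-fold fit so the
#'   no-leakage audit can re-derive and compare it.
#' @return An object of class \code{mamip_cv}; see
#'   \code{\link{print.mamip_cv}}, \code{\link{summary.mamip_cv}},
#'   \code{\link{audit_leakage}}.
#' @export
nested_cv <- function(features, records, n_repeats = 20, n_outer = 5,
                      n_inner = 5,
                      grid = list(n_components = c(10, 20, 50),
                                  penalty = c(0, 0.1, 1),
                                  cor_threshold = 0.95),
                      seed = 1, view_matrices = NULL,
                      fusion = c("none", "cw_mean", "cw_median", "cw_max",
                                 "cw_std", "ica", "autoencoder"),
                      fusion_args = list(), keep_fits = TRUE) {
  fusion <- match.arg(fusion)
  fitted_fusion <- fusion %in% c("ica", "autoencoder")
  if (!is.null(view_matrices)) {
    if (fusion == "none")
      stop("supply a fusion scheme when passing view matrices")
    if (!fitted_fusion) {
      features <- t(vapply(view_matrices, function(m)
        as.numeric(fuse_statistical(m, fusion)),
        numeric(ncol(as_view_matrix(view_matrices[[1]])))))
    }
  } else if (fitted_fusion) {
    stop("fitted fusion schemes need 'view_matrices'")
  }
  if (!fitted_fusion) {
    features <- as.matrix(features)
    if (nrow(features) != nrow(records))
      stop("features and records must align")
  }
  n <- nrow(records)
  if (n < 25L) stop("nested cross-validation needs at least 25 patients")
  combos <- expand.grid(n_components = grid$n_components,
                        penalty = grid$penalty,
                        cor_threshold = grid$cor_threshold,
                        KEEP.OUT.ATTRS = FALSE)
  per_split <- list()
  splits <- list()
  for (rep_i in seq_len(n_repeats)) {
    fold <- make_folds(records$event, n_outer, seed = seed + 7919L * rep_i)
    for (f in seq_len(n_outer)) {
      split_seed <- seed + 7919L * rep_i + 97L * f
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      rec_tr <- records[train_idx, , drop = FALSE]
      rec_te <- records[test_idx, , drop = FALSE]
      fusion_model <- NULL
      if (fitted_fusion) {
        fusion_model <- if (fusion == "ica")
          fit_ica_fusion(view_matrices[train_idx], seed = split_seed)
        else do.call(fit_autoencoder_fusion,
                     c(list(view_matrices[train_idx], seed = split_seed),
                       fusion_args))
        fused <- lapply(view_matrices, function(m)
          as.numeric(fuse_views(m, fusion, fusion_model)))
        features <- do.call(rbind, fused)
      }
      Xtr <- features[train_idx, , drop = FALSE]
      Xte <- features[test_idx, , drop = FALSE]
      # inner grid search on outer-training data only
      inner_fold <- make_folds(rec_tr$event, n_inner,
                               seed = split_seed + 13L)
      combo_scores <- vapply(seq_len(nrow(combos)), function(ci) {
        sc <- vapply(seq_len(n_inner), function(g) {
          it_idx <- which(inner_fold != g)
          iv_idx <- which(inner_fold == g)
          if (!any(rec_tr$event[it_idx]) || !length(iv_idx)) return(NA_real_)
          fitg <- tryCatch(suppressWarnings(
            fit_pipeline(Xtr[it_idx, , drop = FALSE],
                         rec_tr[it_idx, , drop = FALSE],
                         combos$n_components[ci], combos$penalty[ci],
                         combos$cor_threshold[ci], seed = split_seed)),
            error = function(e) NULL)
          if (is.null(fitg)) return(NA_real_)
          ci_val <- tryCatch(suppressWarnings(
            concordance_index(rec_tr[iv_idx, , drop = FALSE],
                              apply_pipeline(fitg, Xtr[iv_idx, , drop = FALSE]))),
            error = function(e) NA_real_)
          ci_val
        }, numeric(1))
        if (all(is.na(sc))) -Inf else mean(sc, na.rm = TRUE)
      }, numeric(1))
      best <- which.max(combo_scores)
      note <- NA_character_
      cidx <- NA_real_
      fit <- tryCatch(suppressWarnings(
        fit_pipeline(Xtr, rec_tr, combos$n_components[best],
                     combos$penalty[best], combos$cor_threshold[best],
                     seed = split_seed)),
        error = function(e) { note <<- conditionMessage(e); NULL })
      if (!is.null(fit)) {
        cidx <- tryCatch(suppressWarnings(
          concordance_index(rec_te, apply_pipeline(fit, Xte))),
          error = function(e) { note <<- conditionMessage(e); NA_real_ })
      }
      per_split[[length(per_split) + 1L]] <- data.frame(
        repetition = rep_i, fold = f, cindex = cidx,
        n_components = combos$n_components[best],
        penalty = combos$penalty[best],
        cor_threshold = combos$cor_threshold[best],
        n_train = length(train_idx), n_test = length(test_idx),
        note = note, stringsAsFactors = FALSE)
      splits[[length(splits) + 1L]] <- list(
        repetition = rep_i, fold = f, train_idx = train_idx,
        test_idx = test_idx, split_seed = split_seed,
        params = combos[best, , drop = FALSE],
        fit_hash = if (!is.null(fit)) pipeline_hash(fit) else NA_character_,
        fusion_hash = if (fitted_fusion && !is.null(fusion_model))
          content_hash(fusion_model[!vapply(fusion_model, is.character,
                                            logical(1))]) else NA_character_,
        fit = if (keep_fits) fit else NULL)
    }
  }
  per_split <- do.call(rbind, per_split)
  ok <- is.finite(per_split$cindex)
  per_rep <- do.call(rbind, lapply(split(per_split[ok, ], per_split$repetition[ok]),
    function(d) data.frame(repetition = d$repetition[1],
                           mean = mean(d$cindex), sd = stats::sd(d$cindex),
                           n_folds = nrow(d))))
  structure(list(per_split = per_split,
                 mean = mean(per_split$cindex[ok]),
                 sd = stats::sd(per_split$cindex[ok]),
                 per_repetition = per_rep,
                 n_failed = sum(!ok),
                 config = list(n_repeats = n_repeats, n_outer = n_outer,
                               n_inner = n_inner, grid = grid,
                               fusion = fusion, fusion_args = fusion_args),
                 seed = seed, splits = splits),
            class = "mamip_cv")
}

#' @export
print.mamip_cv <- function(x, ...) {
  cat(sprintf("<mamip_cv> mean c-index %.3f +/- %.3f over %d outer splits (%d reps x %d folds)\n",
              x$mean, x$sd, nrow(x$per_split), x$config$n_repeats,
              x$config$n_outer))
  if (x$n_failed > 0)
    cat(sprintf("  %d split(s) failed (see $per_split$note)\n", x$n_failed))
  invisible(x)
}

#' Summarise a nested cross-validation result
#'
#' Reports the overall mean and standard deviation over all outer splits as
#' well as the per-repetition 5-fold summaries, plus how often each
#' hyperparameter combination was selected by the inner grid search.
#'
#' @param object a \code{mamip_cv} result.
#' @param ... unused.
#' @return A list of class \code{summary.mamip_cv}.
#' @export
summary.mamip_cv <- function(object, ...) {
  sel <- stats::aggregate(cbind(times_selected = repetition) ~
                            n_components + penalty + cor_threshold,
                          data = object$per_split, FUN = length)
  out <- list(mean = object$mean, sd = object$sd,
              n_splits = nrow(object$per_split),
              n_failed = object$n_failed,
              per_repetition = object$per_repetition,
              selected = sel, fusion = object$config$fusion)
  class(out) <- "summary.mamip_cv"
  out
}

#' @export
print.summary.mamip_cv <- function(x, ...) {
  cat(sprintf("Nested CV c-index: %.3f +/- %.3f (%d splits, %d failed, fusion %s)\n",
              x$mean, x$sd, x$n_splits, x$n_failed, x$fusion))
  cat("\nPer repetition (mean +/- sd over outer folds):\n")
  print(x$per_repetition, row.names = FALSE)
  cat("\nHyperparameter selections:\n")
  print(x$selected, row.names = FALSE)
  invisible(x)
}

#' Box plot of outer-fold c-indices per repetition
#'
#' @param x a \code{mamip_cv} result.
#' @param ... passed to \code{\link[graphics]{boxplot}}.
#' @export
plot.mamip_cv <- function(x, ...) {
  d <- x$per_split[is.finite(x$per_split$cindex), ]
  graphics::boxplot(cindex ~ repetition, data = d,
                    xlab = "repetition", ylab = "c-index",
                    main = sprintf("Outer-fold c-index (mean %.3f)", x$mean),
                    ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  invisible(x)
}

#' Re-derive every outer-fold fit and verify it is leakage-free
#'
#' For each stored outer split, refits the preprocessing + Cox pipeline (and
#' the fitted fusion model, when one was used) from the outer-training rows
#' alone, using the stored hyperparameters and seeds, and compares the
#' result with the fit actually applied during cross-validation. A match on
#' every split proves the applied transforms were functions of outer-training
#' data only.
#'
#' @param result a \code{mamip_cv} from \code{\link{nested_cv}} run with
#'   \code{keep_fits = TRUE}.
#' @param features the feature matrix given to \code{\link{nested_cv}} (or
#'   \code{NULL} with \code{view_matrices}).
#' @param records the survival records.
#' @param view_matrices the view matrices, when a fitted fusion was used.
#' @return \code{TRUE} when every split reproduces bit-identically;
#'   otherwise a data.frame of mismatching splits.
#' @export
audit_leakage <- function(result, features, records, view_matrices = NULL) {
  if (!inherits(result, "mamip_cv")) stop("'result' must be a mamip_cv")
  fusion <- result$config$fusion
  fitted_fusion <- fusion %in% c("ica", "autoencoder")
  if (!fitted_fusion && !is.null(features)) features <- as.matrix(features)
  bad <- list()
  for (s in result$splits) {
    if (is.na(s$fit_hash)) next
    tr <- s$train_idx
    if (fitted_fusion) {
      fm <- if (fusion == "ica")
        fit_ica_fusion(view_matrices[tr], seed = s$split_seed)
      else do.call(fit_autoencoder_fusion,
                   c(list(view_matrices[tr], seed = s$split_seed),
                     result$config$fusion_args))
      fh <- content_hash(fm[!vapply(fm, is.character, logical(1))])
      if (!identical(fh, s$fusion_hash)) {
        bad[[length(bad) + 1L]] <- data.frame(repetition = s$repetition,
                                              fold = s$fold,
                                              stage = "fusion")
        next
      }
      X <- do.call(rbind, lapply(view_matrices, function(m)
        as.numeric(fuse_views(m, fusion, fm))))
    } else {
      X <- features
    }
    refit <- suppressWarnings(
      fit_pipeline(X[tr, , drop = FALSE], records[tr, , drop = FALSE],
                   s$params$n_components, s$params$penalty,
                   s$params$cor_threshold, seed = s$split_seed))
    if (!identical(pipeline_hash(refit), s$fit_hash))
      bad[[length(bad) + 1L]] <- data.frame(repetition = s$repetition,
                                            fold = s$fold,
                                            stage = "pipeline")
  }
  if (!length(bad)) TRUE else do.call(rbind, bad)
}

#' Serialise a cross-validation result to JSON
#'
#' Writes the per-split c-indices, summary statistics and configuration in a
#' stable key order, suitable for archiving and for byte-level comparison of
#' repeated runs under one seed.
#'
#' @param result a \code{mamip_cv}.
#' @param path optional output path; when \code{NULL} the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to \code{path}).
#' @export
cv_result_json <- function(result, path = NULL) {
  if (!inherits(result, "mamip_cv")) stop("'result' must be a mamip_cv")
  payload <- list(
    mean = result$mean, sd = result$sd, seed = result$seed,
    n_failed = result$n_failed,
    config = result$config,
    per_split = result$per_split[, c("repetition", "fold", "cindex",
                                     "n_components", "penalty",
                                     "cor_threshold")],
    per_repetition = result$per_repetition)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}
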