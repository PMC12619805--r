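#' Balanced train/test split stratified on the response
#'
#' Samples are stratified by log IC50 above/below the cohort mean; test
#' members are drawn uniformly at random (seeded) within each stratum so
#' both activity levels are represented in both sets. Per-stratum test
#' counts are the floor of `test_fraction x stratum size`, with the
#' remainder allocated to strata by largest fractional part, so each
#' stratum's realized test fraction is within one sample of the global one.
#'
#' @param bio data.frame with `sample_id` and finite `log_ic50`.
#' @param test_fraction fraction of samples held out (0 < f < 0.5).
#' @param seed integer seed; the same seed reproduces the plan exactly.
#' @return A `split_plan` list: `train_ids`, `test_ids`, `strata`
#'   (named "high"/"low" per sample), `seed`.
#' @export
balanced_split <- function(bio, test_fraction = 0.2, seed = 1) {
  bio <- bio[is.finite(bio$log_ic50), , drop = FALSE]
  n <- nrow(bio)
  if (n < 5) stop("need at least 5 samples to split", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 0.5)
    stop("test_fraction must be in (0, 0.5)", call. = FALSE)
  strata <- ifelse(bio$log_ic50 >= mean(bio$log_ic50), "high", "low")
  sizes <- table(strata)
  if (any(sizes < 2))
    stop("a response stratum has fewer than 2 samples; ",
         "use a pooled (unstratified) split", call. = FALSE)
  n_test <- round(test_fraction * n)
  raw <- test_fraction * as.numeric(sizes)
  base <- floor(raw)
  extra <- n_test - sum(base)
  ord <- order(-(raw - base), names(sizes))
  take <- base
  k <- 1
  while (extra > 0) {
    take[ord[k]] <- take[ord[k]] + 1
    extra <- extra - 1
    k <- if (k == length(take)) 1 else k + 1
  }
  test_ids <- character()
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (g in names(sizes)) {
    ids <- bio$sample_id[strata == g]
    test_ids <- c(test_ids,
                  sample(ids, take[match(g, names(sizes))]))
  }
  structure(list(train_ids = setdiff(bio$sample_id, test_ids),
                 test_ids = sort(test_ids),
                 strata = stats::setNames(strata, bio$sample_id),
                 seed = seed),
            class = "split_plan")
}

# Core NIPALS PLS1 with deflation. X and y are consumed as given.
nipals_pls1 <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1, p)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  Xd <- X; yd <- y
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning("response orthogonal to remaining X variation; stopped at ",
              a_used, " component(s)", call. = FALSE)
      break
    }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24) break
    pl <- drop(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pl)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qa
    a_used <- a
  }
  if (a_used == 0L)
    stop("PLS found no usable component (y orthogonal to X)",
         call. = FALSE)
  list(W = W[, seq_len(a_used), drop = FALSE],
       P = P[, seq_len(a_used), drop = FALSE],
       T = Tm[, seq_len(a_used), drop = FALSE],
       q = q[seq_len(a_used)], ncomp = a_used)
}

# Regression vector using the first `a` components of a NIPALS fit.
pls_coef <- function(core, a = core$ncomp) {
  W <- core$W[, seq_len(a), drop = FALSE]
  P <- core$P[, seq_len(a), drop = FALSE]
  q <- core$q[seq_len(a)]
  drop(W %*% solve(crossprod(P, W), q))
}

#' Fit a PLS1 regression model (NIPALS with deflation)
#'
#' Per component: `w = X'y / ||X'y||`, `t = X w`, `p = X't / t't`,
#' `q = y't / t't`, then X and y are deflated. The regression vector is
#' assembled as `b = W (P'W)^{-1} q`. By default the predictor matrix is
#' auto-scaled and the response centered inside the fit; the fitted scaler
#' and response center travel with the model so [pls_predict()] can map new
#' raw rows to response units.
#'
#' @param X samples x features matrix (training predictors).
#' @param y numeric response (training).
#' @param ncomp number of latent components to extract (capped at
#'   `min(n - 1, p)`).
#' @param scale_method predictor scaling fitted on `X`: `"auto"`,
#'   `"pareto"`, `"none"` (center only) or `"asis"` (consume `X` exactly as
#'   given).
#' @param center_y center the response before fitting (default TRUE).
#' @return A `pls_model` with elements `W`, `P`, `T`, `q`, `b`, `ncomp`,
#'   `scaler`, `y_center`, `X_scaled`, `fitted`.
#' @export
pls_fit <- function(X, y, ncomp, scale_method = "auto", center_y = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y))
    stop("X rows must match length of y", call. = FALSE)
  scaler <- if (scale_method == "asis") NULL
            else fit_scaler(X, scale_method)
  Xs <- if (is.null(scaler)) X else apply_scaler(X, scaler)
  y_center <- if (center_y) mean(y) else 0
  ys <- y - y_center
  core <- nipals_pls1(Xs, ys, ncomp)
  b <- pls_coef(core)
  structure(c(core,
              list(b = b, scaler = scaler, y_center = y_center,
                   scale_method = scale_method,
                   feature_ids = colnames(X),
                   X_scaled = Xs,
                   fitted = drop(Xs %*% b) + y_center)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS1 model: %d component(s), %d features, %d samples\n",
              x$ncomp, length(x$b), nrow(x$T)))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' Applies the scaler stored at training time to the new raw rows, forms
#' `X_scaled b`, and adds back the response center so predictions are in
#' response units (log IC50).
#'
#' @param model a [pls_fit()] model.
#' @param X_new samples x features matrix with the model's feature set in
#'   the model's order (checked by name when both are named).
#' @param ncomp number of components to use (default: all fitted).
#' @return Numeric vector of predictions.
#' @export
pls_predict <- function(model, X_new, ncomp = model$ncomp) {
  X_new <- as.matrix(X_new)
  if (!is.null(model$feature_ids) && !is.null(colnames(X_new))) {
    if (!identical(colnames(X_new), model$feature_ids)) {
      missing_ids <- setdiff(model$feature_ids, colnames(X_new))
      extra_ids <- setdiff(colnames(X_new), model$feature_ids)
      if (length(missing_ids) || length(extra_ids))
        stop("feature mismatch; missing: ",
             paste(missing_ids, collapse = ", "), "; extra: ",
             paste(extra_ids, collapse = ", "), call. = FALSE)
      X_new <- X_new[, model$feature_ids, drop = FALSE]
    }
  } else if (ncol(X_new) != length(model$b)) {
    stop("X_new has ", ncol(X_new), " features but model has ",
         length(model$b), call. = FALSE)
  }
  Xs <- if (is.null(model$scaler)) X_new
        else apply_scaler(X_new, model$scaler)
  b <- if (ncomp == model$ncomp) model$b else pls_coef(model, ncomp)
  drop(Xs %*% b) + model$y_center
}

#' Choose the PLS component count by leave-one-out cross-validation
#'
#' Each sample is held out in turn; the scaler and the PLS model are refit
#' from scratch on the remaining samples (no leakage) and the held-out
#' sample predicted at every candidate component count. Returns the count
#' minimizing LOO RMSE, with ties broken toward fewer components.
#'
#' @param X training predictors (unscaled; the scaler is refit per fold).
#' @param y training response.
#' @param max_components largest candidate count.
#' @param scale_method predictor scaling refit inside each fold.
#' @return A list with `ncomp` (the selected count), `cv_rmse` (per
#'   candidate count), `predictions` (n x A matrix of LOO predictions).
#' @export
select_components_loo <- function(X, y, max_components,
                                  scale_method = "auto") {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 training samples", call. = FALSE)
  A <- min(max_components, n - 2, ncol(X))
  preds <- matrix(NA_real_, n, A)
  for (i in seq_len(n)) {
    fit <- pls_fit(X[-i, , drop = FALSE], y[-i], A,
                   scale_method = scale_method)
    for (a in seq_len(min(A, fit$ncomp)))
      preds[i, a] <- pls_predict(fit, X[i, , drop = FALSE], ncomp = a)
    if (fit$ncomp < A)   # fold stopped early: reuse last usable component
      preds[i, seq(fit$ncomp + 1, A)] <- preds[i, fit$ncomp]
  }
  cv <- apply(preds, 2, function(p) rmse(y, p))
  list(ncomp = which.min(cv), cv_rmse = cv, predictions = preds)
}

#' Root mean square error
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1)
    stop("observed and predicted must have equal length >= 1",
         call. = FALSE)
  sqrt(mean((observed - predicted)^2))
}

#' RMSE as a percentage of the observed response range
#'
#' `100 * rmse / (max(observed) - min(observed))`, the coefficient of
#' variation used to judge whether a given RMSE is large relative to the
#' spread of the modeled cohort.
#'
#' @param rmse_value an RMSE (response units).
#' @param observed the observed responses of the full modeled cohort.
#' @return Percentage, or NA with a warning when the range is zero.
#' @export
cv_percent <- function(rmse_value, observed) {
  rng <- max(observed) - min(observed)
  if (rng == 0) {
    warning("observed range is zero; CV% undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * rmse_value / rng
}

#' Default descending lambda grid for the lasso
#'
#' Runs from `lambda_max = max_j |x_j'y| / n` (the smallest penalty that
#' zeroes every coefficient) down to `lambda_max * min_ratio`,
#' log-spaced.
#'
#' @param X predictor matrix; @param y centered response.
#' @param n_lambda grid size (default 100).
#' @param min_ratio ratio of smallest to largest lambda. The default is
#'   1e-4 for n > p and 0.01 for p >= n, where the unpenalized end of the
#'   path is an interpolating fit that no cross-validation selects.
#' @return Descending numeric vector of length `n_lambda`.
#' @export
lambda_grid <- function(X, y, n_lambda = 100, min_ratio = NULL) {
  if (is.null(min_ratio))
    min_ratio <- if (ncol(X) >= nrow(X)) 0.01 else 1e-4
  lmax <- max(abs(drop(crossprod(X, y)))) / nrow(X)
  if (lmax == 0) stop("y is orthogonal to every column of X", call. = FALSE)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Lasso regularization path by cyclic coordinate descent
#'
#' Minimizes `(1/(2n)) ||y - X b||^2 + lambda ||b||_1` by cyclic
#' coordinate descent with soft-thresholding, warm-starting each lambda
#' from the previous (larger) one. `X` is consumed as given (the pipeline
#' feeds the Hellinger-transformed, auto-scaled matrix) and `y` should be
#' centered.
#'
#' @param X predictors (n x p); @param y centered response.
#' @param lambdas descending penalty grid (default [lambda_grid()]).
#' @param tol convergence tolerance on the maximum coefficient change per
#'   sweep (default 1e-7).
#' @return A `lasso_fit` list: `lambdas`, `beta` (p x L path matrix),
#'   `feature_ids`.
#' @export
lasso_fit <- function(X, y, lambdas = NULL, tol = 1e-7) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in lasso input", call. = FALSE)
  if (is.null(lambdas)) lambdas <- lambda_grid(X, y)
  if (is.unsorted(rev(lambdas)))
    stop("lambdas must be descending", call. = FALSE)
  beta <- .cd_lasso_path(X, y, lambdas, tol)
  rownames(beta) <- colnames(X)
  structure(list(lambdas = lambdas, beta = beta,
                 feature_ids = colnames(X)),
            class = "lasso_fit")
}

#' Select the lasso penalty by leave-one-out cross-validation
#'
#' The lambda grid is fixed on the full training set; each sample is held
#' out in turn and the whole path refit on the rest. The selected lambda
#' minimizes the LOO mean squared error (ties broken toward the larger,
#' sparser lambda); the model is then refit on the full training set at
#' that lambda and the nonzero feature set returned. If the selected
#' lambda zeroes everything, the nearest lambda with at least one nonzero
#' coefficient is used instead, with a warning.
#'
#' @param X predictors; @param y centered response.
#' @param lambdas optional descending grid (default [lambda_grid()] on the
#'   full training set).
#' @param tol coordinate-descent tolerance.
#' @return A `lasso_cv` list: `lambda` (selected), `lambda_index`,
#'   `cv_mse` (per lambda), `beta` (coefficients at the selection),
#'   `selected_ids` (nonzero features), `fit` (the full-data `lasso_fit`).
#' @export
lasso_select_loo <- function(X, y, lambdas = NULL, tol = 1e-7) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 training samples", call. = FALSE)
  if (is.null(lambdas)) lambdas <- lambda_grid(X, y)
  sq_err <- matrix(NA_real_, n, length(lambdas))
  for (i in seq_len(n)) {
    path <- .cd_lasso_path(X[-i, , drop = FALSE], y[-i], lambdas, tol)
    pred <- drop(X[i, , drop = FALSE] %*% path)
    sq_err[i, ] <- (y[i] - pred)^2
  }
  cv_mse <- colMeans(sq_err)
  idx <- which(cv_mse <= min(cv_mse) + 1e-15)[1]  # grid descending: first
  fit <- lasso_fit(X, y, lambdas, tol)
  beta <- fit$beta[, idx]
  if (all(beta == 0)) {
    nz <- which(colSums(fit$beta != 0) > 0)
    if (length(nz)) {
      alt <- nz[which.min(abs(nz - idx))]
      warning(sprintf(
        "empty selection at lambda %.4g; falling back to lambda %.4g",
        lambdas[idx], lambdas[alt]), call. = FALSE)
      idx <- alt
      beta <- fit$beta[, idx]
    } else {
      warning("lasso selected no features at any lambda", call. = FALSE)
    }
  }
  ids <- fit$feature_ids
  if (is.null(ids)) ids <- as.character(seq_len(nrow(fit$beta)))
  structure(list(lambda = lambdas[idx], lambda_index = idx,
                 cv_mse = cv_mse, beta = beta,
                 selected_ids = ids[beta != 0], fit = fit),
            class = "lasso_cv")
}
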