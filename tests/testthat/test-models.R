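make_bio <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%02d", 1:n),
             log_ic50 = runif(n, 4, 4.8))
}

test_that("balanced split stratifies the response and is seed-stable", {
  bio <- make_bio(40)
  sp <- balanced_split(bio, 0.2, seed = 17)
  expect_length(sp$test_ids, 8)
  expect_length(sp$train_ids, 32)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), bio$sample_id)
  # per-stratum test fraction within one sample of the global fraction
  for (g in c("high", "low")) {
    ids <- names(sp$strata)[sp$strata == g]
    expect_lte(abs(sum(sp$test_ids %in% ids) - 0.2 * length(ids)), 1)
  }
  expect_identical(balanced_split(bio, 0.2, seed = 17), sp)
  expect_false(identical(balanced_split(bio, 0.2, seed = 18)$test_ids,
                         sp$test_ids))

  # symmetric 20/20 strata: exactly 4 test samples from each
  bio2 <- data.frame(sample_id = sprintf("s%02d", 1:40),
                     log_ic50 = rep(c(4, 5), each = 20))
  sp2 <- balanced_split(bio2, 0.2, seed = 1)
  expect_equal(sum(sp2$test_ids %in% bio2$sample_id[1:20]), 4)
  expect_equal(sum(sp2$test_ids %in% bio2$sample_id[21:40]), 4)

  expect_error(balanced_split(make_bio(4)), "at least 5")
  bio3 <- data.frame(sample_id = c("a", "b", "c", "d", "e", "f"),
                     log_ic50 = c(1, 1, 1, 1, 1, 10))
  expect_error(balanced_split(bio3, 0.2, 1), "stratum")
})

test_that("PLS1 with full rank reproduces least squares (oracle)", {
  set.seed(4)
  X <- matrix(rnorm(30), 10, 3)
  beta <- c(1.5, -2, 0.5)
  y <- drop(X %*% beta)
  fit <- pls_fit(X, y, ncomp = 3, scale_method = "asis",
                 center_y = FALSE)
  b_ols <- solve(crossprod(X), crossprod(X, y))  # normal equations
  expect_equal(fit$b, drop(b_ols), tolerance = 1e-6)
  expect_equal(fit$fitted, y, tolerance = 1e-8)

  # noisy y, default scaling: max components still equals OLS predictions
  y2 <- y + rnorm(10, 0, 0.3)
  fit2 <- pls_fit(X, y2, ncomp = 3)
  Xs <- apply_scaler(X, fit2$scaler)
  ols2 <- drop(Xs %*% solve(crossprod(Xs), crossprod(Xs, y2 - mean(y2)))) +
    mean(y2)
  expect_equal(unname(fit2$fitted), unname(ols2), tolerance = 1e-6)
})

test_that("PLS1 closed forms: single column and orthonormal designs", {
  set.seed(5)
  x <- rnorm(12); y <- 2 * x + rnorm(12, 0, 0.1)
  fit <- pls_fit(matrix(x), y, 1, scale_method = "asis",
                 center_y = FALSE)
  expect_equal(fit$b, sum(x * y) / sum(x^2), tolerance = 1e-10)

  # hand-checkable 4x2 orthonormal design: b_j = x_j'y
  Q <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
  y2 <- c(1, -1, 0.5, 2)
  # orthonormal designs collapse to a single PLS component (the deflated
  # response is exactly orthogonal to the deflated predictors)
  expect_warning(
    fit2 <- pls_fit(Q, y2, 2, scale_method = "asis", center_y = FALSE),
    "orthogonal")
  expect_equal(fit2$b, drop(crossprod(Q, y2)), tolerance = 1e-8)
})

test_that("PLS score vectors are mutually orthogonal", {
  set.seed(6)
  for (s in 1:5) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    y <- rnorm(20)
    fit <- pls_fit(X, y, 5)
    g <- crossprod(fit$T)
    expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
    # coefficient route equals deflation route for in-sample predictions
    expect_equal(unname(pls_predict(fit, X)), unname(fit$fitted),
                 tolerance = 1e-10)
  }
})

test_that("prediction contracts: identity, mean row, column permutation", {
  set.seed(7)
  X <- matrix(rnorm(15 * 4), 15, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rnorm(15)
  fit <- pls_fit(X, y, 2)
  expect_equal(unname(pls_predict(fit, X)), unname(fit$fitted),
               tolerance = 1e-10)
  expect_equal(unname(pls_predict(fit, rbind(colMeans(X)))), mean(y),
               tolerance = 1e-10)
  # permuting columns with names present: mismatch order gets realigned
  perm <- c(3, 1, 4, 2)
  expect_equal(pls_predict(fit, X[, perm]), pls_predict(fit, X),
               tolerance = 1e-12)
  expect_error(pls_predict(fit, X[, 1:3]), "feature mismatch")
})

test_that("LOO component selection matches a naive refit loop (oracle)", {
  set.seed(8)
  X <- matrix(rnorm(18), 6, 3)
  y <- rnorm(6)
  res <- select_components_loo(X, y, 3)
  naive <- sapply(1:3, function(a) {
    pr <- sapply(1:6, function(i) {
      f <- pls_fit(X[-i, ], y[-i], a)
      pls_predict(f, X[i, , drop = FALSE], ncomp = a)
    })
    sqrt(mean((y - pr)^2))
  })
  expect_equal(res$cv_rmse, naive, tolerance = 1e-12)
})

test_that("LOO picks few components for noise and the true latent rank", {
  a_star <- vapply(1:50, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 20), 40, 20)
    y <- rnorm(40)
    select_components_loo(X, y, 6)$ncomp
  }, numeric(1))
  expect_gte(mean(a_star == 1), 0.9)

  # two latent variables, both needed for y: LOO must not undershoot the
  # true rank, and its typical choice is the true rank
  a2 <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    t1 <- rnorm(40); t2 <- rnorm(40)
    p1 <- rnorm(20); p2 <- rnorm(20)
    X <- outer(t1, p1) + outer(t2, p2) +
      matrix(rnorm(40 * 20, 0, 0.05), 40, 20)
    y <- t1 - 2 * t2 + rnorm(40, 0, 0.5)
    select_components_loo(X, y, 6)$ncomp
  }, numeric(1))
  expect_equal(median(a2), 2)
  expect_gte(mean(a2 >= 2), 0.9)
})

test_that("rmse and cv_percent follow their definitions", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 1), c(1, 0)), 1.0)
  obs <- c(4.04, 4.75)
  expect_equal(cv_percent(0.160, obs), 100 * 0.160 / 0.71,
               tolerance = 1e-12)
  expect_equal(cv_percent(0.160, obs), 22.54, tolerance = 0.02)
  expect_warning(out <- cv_percent(0.1, c(2, 2)), "zero")
  expect_true(is.na(out))
})

test_that("lasso path: zero at lambda_max, soft-threshold closed form", {
  set.seed(9)
  X <- matrix(rnorm(24), 8, 3)
  y <- rnorm(8); y <- y - mean(y)
  lmax <- max(abs(crossprod(X, y))) / 8
  fit <- lasso_fit(X, y, lambdas = c(lmax * 1.5, lmax))
  expect_true(all(fit$beta[, 1] == 0))
  # at lambda_max itself the subgradient condition holds with equality;
  # allow floating-point dust
  expect_lt(max(abs(fit$beta[, 2])), 1e-12)

  # orthonormal columns: beta_j = S(x_j'y/n, lambda) / (x_j'x_j/n)
  Q <- qr.Q(qr(matrix(rnorm(24), 8, 3)))
  rho <- drop(crossprod(Q, y)) / 8
  xx <- colSums(Q^2) / 8
  for (lam in c(0.02, 0.05, 0.2)) {
    b <- lasso_fit(Q, y, lambdas = lam)$beta[, 1]
    closed <- sign(rho) * pmax(abs(rho) - lam, 0) / xx
    expect_equal(unname(b), closed, tolerance = 1e-8)
  }

  # lambda = 0 on a well-conditioned design recovers least squares
  X2 <- matrix(rnorm(30), 10, 3)
  y2 <- drop(X2 %*% c(1, -1, 2)) + rnorm(10, 0, 0.1)
  y2 <- y2 - mean(y2)
  grid <- c(lambda_grid(X2, y2, 20), 0)
  b0 <- lasso_fit(X2, y2, grid)$beta[, 21]
  expect_equal(unname(b0),
               drop(solve(crossprod(X2), crossprod(X2, y2))),
               tolerance = 1e-6)
})

test_that("lasso solutions satisfy the KKT conditions and path monotonicity", {
  set.seed(10)
  for (s in 1:5) {
    n <- 20; p <- 12
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X[, 1:3] %*% c(2, -1, 1)) + rnorm(n)
    y <- y - mean(y)
    lam <- lambda_grid(X, y, 30)
    fit <- lasso_fit(X, y, lam)
    # on orthonormal designs the active set grows monotonically as the
    # penalty shrinks (soft-threshold closed form); correlated designs
    # can genuinely drop and re-admit variables, so monotonicity is only
    # a theorem here
    Qo <- qr.Q(qr(matrix(rnorm(n * 8), n, 8)))
    lamo <- lambda_grid(Qo, y, 30)
    nzo <- colSums(abs(lasso_fit(Qo, y, lamo)$beta) > 1e-10)
    expect_true(all(diff(nzo[order(lamo)]) <= 0))
    for (k in c(5, 15, 30)) {
      b <- fit$beta[, k]
      g <- drop(crossprod(X, y - X %*% b)) / n
      expect_true(all(abs(g[b == 0]) <= lam[k] + 1e-5))
      if (any(b != 0))
        expect_equal(g[b != 0], lam[k] * sign(b[b != 0]),
                     tolerance = 1e-4)
    }
  }
})

test_that("lasso path agrees with glmnet at matched penalties", {
  skip_if_not_installed("glmnet")
  set.seed(11)
  X <- scale(matrix(rnorm(40 * 10), 40, 10))
  y <- drop(X[, 1:2] %*% c(1.5, -1)) + rnorm(40, 0, 0.5)
  y <- y - mean(y)
  lam <- lambda_grid(X, y, 25)
  ours <- lasso_fit(X, y, lam)$beta
  theirs <- as.matrix(glmnet::glmnet(X, y, lambda = lam,
                                     standardize = FALSE,
                                     intercept = FALSE,
                                     thresh = 1e-12)$beta)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-4)
})

test_that("lasso LOO-CV matches a naive refit loop and selects sanely", {
  set.seed(12)
  X <- matrix(rnorm(24), 6, 4)
  y <- rnorm(6); y <- y - mean(y)
  lam <- lambda_grid(X, y, 12)
  cv <- lasso_select_loo(X, y, lam)
  naive <- rowMeans(sapply(1:6, function(i) {
    path <- lasso_fit(X[-i, ], y[-i], lam)$beta
    drop((y[i] - X[i, , drop = FALSE] %*% path)^2)
  }))
  expect_equal(cv$cv_mse, unname(naive), tolerance = 1e-10)
  expect_equal(cv$lambda, lam[which.min(cv$cv_mse)])
  expect_setequal(cv$selected_ids,
                  as.character(which(cv$beta != 0)))
})

test_that("lasso LOO recovers informative features and stays sparse on noise", {
  recov <- vapply(1:25, function(s) {
    set.seed(s)
    n <- 40
    sig <- matrix(rnorm(n * 3), n, 3)
    X <- cbind(sig, matrix(rnorm(n * 50), n, 50))
    colnames(X) <- paste0("f", 1:53)
    y <- drop(sig %*% c(1, 1, 1)) + rnorm(n, 0, 0.35)
    Xs <- scale(X); yc <- y - mean(y)
    # shorter path: with p > n the far tail of the default grid sits in
    # the interpolation regime and adds nothing to selection
    sel <- lasso_select_loo(Xs, yc,
                            lambda_grid(Xs, yc, 100, 0.01))$selected_ids
    all(c("f1", "f2", "f3") %in% sel)
  }, logical(1))
  expect_gte(mean(recov), 0.9)

  sizes <- vapply(1:100, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(20 * 15), 20, 15)
    y <- rnorm(20); y <- y - mean(y)
    suppressWarnings(length(lasso_select_loo(X, y)$selected_ids))
  }, numeric(1))
  expect_gte(mean(sizes <= 3), 0.8)
})
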