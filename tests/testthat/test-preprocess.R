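test_that("zero replacement touches only exact zeros", {
  ft <- feature_table(matrix(c(0, 5), 1), c("a", "b"), c(1, 2), c(1, 2),
                      "s1")
  # epsilon is not small relative to nothing here? smallest nonzero is 5
  out <- replace_zeros(ft, 0.001)
  expect_equal(unname(out$areas[1, ]), c(0.001, 5))

  ft2 <- toy_feature_table()
  expect_equal(replace_zeros(ft2)$areas, ft2$areas)

  ft3 <- feature_table(matrix(c(0, 0, 1, 2), 2), c("a", "b"),
                       c(1, 2), c(1, 2), c("s1", "s2"))
  out3 <- replace_zeros(ft3)
  expect_equal(unname(out3$areas[, "a"]), c(0.001, 0.001))
  expect_warning(replace_zeros(ft3, epsilon = 10), "not small")
  expect_error(replace_zeros(ft3, epsilon = -1), "epsilon")
})

test_that("zero-variance features are dropped, order preserved", {
  a <- cbind(c(7, 7, 7), c(1, 2, 3), c(5, 5, 6), c(2, 2, 2))
  ft <- feature_table(a, c("const1", "vary", "onejump", "const2"),
                      1:4, 1:4, c("s1", "s2", "s3"))
  out <- drop_zero_variance(ft)
  expect_equal(out$removed_ids, c("const1", "const2"))
  expect_equal(out$table$feature_ids, c("vary", "onejump"))

  allconst <- feature_table(matrix(3, 2, 2), c("a", "b"), 1:2, 1:2,
                            c("s1", "s2"))
  out2 <- drop_zero_variance(allconst)
  expect_length(out2$table$feature_ids, 0)
  expect_equal(out2$removed_ids, c("a", "b"))
})

test_that("Hellinger rows are sqrt proportions on the unit sphere", {
  ft <- feature_table(matrix(c(1, 4, 4), 1), c("a", "b", "c"),
                      1:3, 1:3, "s1")
  expect_equal(unname(hellinger(ft)[1, ]), c(1 / 3, 2 / 3, 2 / 3))

  expect_equal(unname(hellinger(matrix(7.3, 1, 1))[1, 1]), 1)

  set.seed(1)
  m <- matrix(rexp(40), 5, 8)
  h <- hellinger(m)
  expect_equal(rowSums(h^2), rep(1, 5), tolerance = 1e-12)
  expect_equal(h, sqrt(m / rowSums(m)), tolerance = 1e-14)

  bad <- matrix(c(0, 0, 1, 2), 2, byrow = TRUE,
                dimnames = list(c("sampX", "sampY"), NULL))
  expect_error(hellinger(bad), "sampX")
})

test_that("scaler state is train-fitted, invertible, and method-aware", {
  expect_equal(apply_scaler(matrix(c(1, 3), 2), fit_scaler(matrix(c(1, 3), 2), "auto"))[, 1],
               c(-0.7071, 0.7071), tolerance = 1e-4)

  set.seed(2)
  X <- matrix(rnorm(60, 5, 3), 10, 6)
  st <- fit_scaler(X, "auto")
  Xs <- apply_scaler(X, st)
  expect_equal(colMeans(Xs), rep(0, 6), tolerance = 1e-12)
  expect_equal(apply(Xs, 2, sd), rep(1, 6), tolerance = 1e-12)
  expect_equal(apply_scaler(Xs, st, inverse = TRUE), X,
               tolerance = 1e-10)

  stp <- fit_scaler(X, "pareto")
  expect_equal(stp$divisor, sqrt(apply(X, 2, sd)))
  # a test row equal to the train means scales to 0 under any method
  for (m in c("auto", "pareto", "none"))
    expect_equal(unname(apply_scaler(rbind(colMeans(X)),
                                     fit_scaler(X, m))[1, ]),
                 rep(0, 6), tolerance = 1e-12)

  Xz <- cbind(X, 0)
  colnames(Xz) <- c(paste0("f", 1:6), "dead")
  expect_error(fit_scaler(Xz, "auto"), "dead")
})

test_that("normality screen ranks transforms by median Shapiro-Wilk W", {
  set.seed(11)
  n <- 40; p <- 12
  a <- matrix(rlnorm(n * p, 8, 1.5), n, p)   # heavy-tailed raw areas
  ft <- feature_table(a, sprintf("f%02d", 1:p), seq_len(p), seq_len(p),
                      sprintf("s%02d", 1:n))
  rep <- normality_screen(ft)
  expect_setequal(unique(rep$summary$candidate),
                  c("hellinger+auto", "log+auto", "hellinger+pareto",
                    "log+pareto"))
  expect_true(all(rep$per_feature$W > 0 & rep$per_feature$W <= 1))
  # W is affine invariant: auto vs Pareto variants tie per feature
  w <- rep$per_feature
  expect_equal(w$W[w$candidate == "log+auto"],
               w$W[w$candidate == "log+pareto"], tolerance = 1e-10)
  # log transform normalizes i.i.d. lognormal features better than
  # sqrt-proportions do for this single-feature-dominant design
  oracle_logW <- median(apply(log(a + 0.001), 2,
                              function(x) shapiro.test(scale(x))$statistic))
  expect_equal(rep$summary$median_W[rep$summary$candidate == "log+auto"],
               oracle_logW, tolerance = 1e-10)

  # a feature constant on the log scale is skipped there with a warning
  # (its sqrt-proportion can still vary through the row sums)
  ftc <- feature_table(cbind(a[, 1], 5), c("v", "const"), 1:2, 1:2,
                       sprintf("s%02d", 1:n))
  expect_warning(normality_screen(ftc, candidates = "log+auto"),
                 "skipped")
  rc <- suppressWarnings(normality_screen(ftc))
  logs <- rc$per_feature[grepl("^log", rc$per_feature$candidate), ]
  expect_false(any(logs$feature_id == "const"))
})

test_that("lognormal features look more normal after log over seeds", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    x <- rlnorm(40, 0, 1.5)
    shapiro.test(log(x))$statistic > shapiro.test(x)$statistic
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # and the null: i.i.d. normal gives high W nearly always
  w <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    unname(shapiro.test(rnorm(40))$statistic)
  }, numeric(1))
  expect_gte(mean(w > 0.9), 0.95)
})

test_that("PCA is SVD-exact: rank, rotation invariance, reconstruction", {
  t_line <- seq(0, 1, length.out = 8)
  X <- cbind(2 * t_line, -t_line, 0.5 * t_line)
  res <- pca(X)
  expect_equal(res$explained[1], 1.0, tolerance = 1e-10)

  set.seed(3)
  Y <- matrix(rnorm(24), 6, 4)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(pca(Y %*% Q)$explained, pca(Y)$explained,
               tolerance = 1e-10)

  res2 <- pca(Y)
  recon <- res2$scores %*% t(res2$loadings) +
    matrix(res2$center, 6, 4, byrow = TRUE)
  expect_equal(recon, Y, tolerance = 1e-10)
  cv <- crossprod(res2$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
  expect_error(pca(Y[1, , drop = FALSE]), "2 samples")
})

test_that("zero-variance removal commutes with zero replacement", {
  set.seed(9)
  for (s in 1:5) {
    ft <- random_feature_table(n = 8, p = 15, nb = 0, seed = s,
                               missing_rate = 0.3)
    # add an all-zero feature: constant before and after replacement
    ft$areas[, 3] <- 0
    before <- drop_zero_variance(ft)$removed_ids
    after <- drop_zero_variance(replace_zeros(ft))$removed_ids
    expect_equal(before, after)
  }
})
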