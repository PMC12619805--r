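#' Replace exact zeros with a small constant
#'
#' Missing measurements are encoded as 0 in aligned feature tables; before
#' transformation they are replaced by a small positive constant on the raw
#' area scale (default 0.001).
#'
#' @param ft a [feature_table()].
#' @param epsilon replacement value (> 0).
#' @return The table with all exact-zero areas set to `epsilon`.
#' @export
replace_zeros <- function(ft, epsilon = 0.001) {
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("epsilon must be > 0", call. = FALSE)
  nz <- ft$areas[ft$areas > 0]
  if (length(nz) && epsilon >= min(nz))
    warning(sprintf(
      "epsilon %g is not small relative to the smallest nonzero area %g",
      epsilon, min(nz)), call. = FALSE)
  ft$areas[ft$areas == 0] <- epsilon
  ft
}

#' Remove zero-variance features
#'
#' @param ft a [feature_table()] with at least 2 samples.
#' @return A list with `table` (survivors, original order) and
#'   `removed_ids` (ids of constant features).
#' @export
drop_zero_variance <- function(ft) {
  if (nrow(ft$areas) < 2) stop("need at least 2 samples", call. = FALSE)
  v <- apply(ft$areas, 2, function(x) max(x) - min(x))
  removed <- ft$feature_ids[v == 0]
  keep <- ft$feature_ids[v > 0]
  list(table = ft_subset(ft, features = keep), removed_ids = removed)
}

#' Hellinger transform
#'
#' Square root of the within-sample relative abundance: for sample i and
#' feature j, `h_ij = sqrt(area_ij / sum_j area_ij)`. Each transformed
#' sample row lies on the unit sphere (`sum h^2 = 1`), which damps the
#' dominance of large peaks and removes per-sample total-signal differences.
#'
#' @param x a [feature_table()] or a nonnegative samples x features matrix.
#' @return The transformed matrix (rownames = sample ids when available).
#' @export
hellinger <- function(x) {
  m <- if (inherits(x, "feature_table")) x$areas else as.matrix(x)
  if (any(m < 0)) stop("areas must be >= 0", call. = FALSE)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    bad <- rownames(m)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("zero row sum for sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sqrt(m / rs)
}

#' Fit a column scaler on training data
#'
#' Auto-scaling divides each centered feature by its standard deviation
#' (n - 1 denominator); Pareto scaling divides by the square root of the
#' standard deviation; `none` centers only. The fitted state is applied
#' unchanged to test data so no test-set information leaks into the scale.
#'
#' @param train samples x features numeric matrix (>= 2 rows).
#' @param method one of `"auto"`, `"pareto"`, `"none"`.
#' @return A `scaler_state` list: `mean`, `divisor`, `method`.
#' @export
fit_scaler <- function(train, method = c("auto", "pareto", "none")) {
  method <- match.arg(method)
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("need at least 2 training samples", call. = FALSE)
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  if (method != "none" && any(sdv == 0)) {
    bad <- colnames(train)[sdv == 0]
    if (is.null(bad)) bad <- which(sdv == 0)
    stop("zero training standard deviation for feature(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  divisor <- switch(method,
                    auto = sdv,
                    pareto = sqrt(sdv),
                    none = rep(1, length(mu)))
  structure(list(mean = mu, divisor = divisor, method = method),
            class = "scaler_state")
}

#' Apply (or invert) a fitted scaler
#'
#' @param x samples x features matrix with the same feature count/order the
#'   scaler was fitted on.
#' @param state a `scaler_state` from [fit_scaler()].
#' @param inverse logical; if TRUE, undo the scaling.
#' @return The scaled (or reconstructed) matrix.
#' @export
apply_scaler <- function(x, state, inverse = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != length(state$mean))
    stop("matrix has ", ncol(x), " features but scaler was fitted on ",
         length(state$mean), call. = FALSE)
  if (inverse)
    sweep(sweep(x, 2, state$divisor, "*"), 2, state$mean, "+")
  else
    sweep(sweep(x, 2, state$mean, "-"), 2, state$divisor, "/")
}

#' Rank transformation candidates by per-feature normality
#'
#' Applies each candidate transform + scaling combination to the raw area
#' matrix and computes the Shapiro-Wilk W statistic and p-value per feature;
#' candidates are ranked by median W (higher = more normal). Note that W is
#' location/scale invariant, so auto- and Pareto-scaled variants of the same
#' transform tie exactly; both are reported for completeness.
#'
#' @param ft a [feature_table()] (blanks should be dropped first).
#' @param epsilon offset used for the log candidate `ln(x + epsilon)` and
#'   zero replacement.
#' @param candidates character vector of candidates among
#'   `"hellinger+auto"`, `"log+auto"`, `"hellinger+pareto"`, `"log+pareto"`.
#' @return A `normality_report` list: `per_feature` (data.frame of
#'   candidate, feature_id, W, p), `summary` (data.frame of candidate and
#'   median_W, ranked descending), `best` (top-ranked candidate name).
#' @export
normality_screen <- function(ft, epsilon = 0.001,
                             candidates = c("hellinger+auto", "log+auto",
                                            "hellinger+pareto",
                                            "log+pareto")) {
  n <- nrow(ft$areas)
  if (n < 3) stop("Shapiro-Wilk needs at least 3 samples", call. = FALSE)
  base <- replace_zeros(ft, epsilon)
  mats <- list()
  for (cand in candidates) {
    parts <- strsplit(cand, "+", fixed = TRUE)[[1]]
    tm <- switch(parts[1],
                 hellinger = hellinger(base),
                 log = log(base$areas + epsilon),
                 stop("unknown transform: ", parts[1], call. = FALSE))
    keep <- apply(tm, 2, function(x) max(x) - min(x) > 0)
    if (any(!keep))
      warning("feature(s) skipped in normality screen (constant): ",
              paste(ft$feature_ids[!keep], collapse = ", "),
              call. = FALSE)
    st <- fit_scaler(tm[, keep, drop = FALSE], parts[2])
    m <- apply_scaler(tm[, keep, drop = FALSE], st)
    colnames(m) <- ft$feature_ids[keep]
    mats[[cand]] <- m
  }
  per <- do.call(rbind, lapply(names(mats), function(cand) {
    m <- mats[[cand]]
    res <- lapply(seq_len(ncol(m)), function(j) {
      x <- m[, j]
      if (max(x) - min(x) == 0 || n > 5000) {
        warning(sprintf("feature '%s' skipped in normality screen",
                        colnames(m)[j]), call. = FALSE)
        return(NULL)
      }
      sw <- stats::shapiro.test(x)
      data.frame(candidate = cand, feature_id = colnames(m)[j],
                 W = unname(sw$statistic), p = sw$p.value,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }))
  summ <- do.call(rbind, lapply(split(per, per$candidate), function(d)
    data.frame(candidate = d$candidate[1], median_W = stats::median(d$W),
               stringsAsFactors = FALSE)))
  summ <- summ[order(-summ$median_W), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(per_feature = per, summary = summ,
                 best = summ$candidate[1]),
            class = "normality_report")
}

#' Principal component analysis (SVD-based)
#'
#' Thin wrapper around the singular value decomposition with internal
#' centering; explained-variance fractions sum to 1 over all retained
#' components and components are ordered by decreasing variance.
#'
#' @param x samples x features numeric matrix (>= 2 rows).
#' @param center logical; center columns before decomposition.
#' @return A list with `scores` (n x k), `loadings` (p x k),
#'   `explained` (length-k fractions), `center` (column means used).
#' @export
pca <- function(x, center = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples for PCA", call. = FALSE)
  pr <- stats::prcomp(x, center = center, scale. = FALSE)
  v <- pr$sdev^2
  keep <- v > max(v) * 1e-14
  list(scores = pr$x[, keep, drop = FALSE],
       loadings = pr$rotation[, keep, drop = FALSE],
       explained = v[keep] / sum(v[keep]),
       center = if (center) pr$center else rep(0, ncol(x)))
}
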