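#' Four-parameter logistic dose-response fit
#'
#' Fits `y = lower + (upper - lower) / (1 + (x / inflection)^slope)` to
#' percent-viability data by multi-start nonlinear least squares
#' (Levenberg-Marquardt, starts over slope {0.5, 1, 2, 4} with the
#' inflection initialized at the geometric mean of the positive doses and
#' the asymptotes at the observed viability extremes). Zero-dose wells
#' anchor the upper asymptote and are held out of the power term: the model
#' value at dose 0 is `upper`. The IC50 is the dose at which the fitted
#' curve crosses 50% viability,
#' `inflection * ((upper - 50) / (50 - lower))^(1/slope)`, reported only
#' when 50% lies strictly between the fitted asymptotes.
#'
#' @param doses dose vector (ug/ml, >= 0); at least 4 distinct levels.
#' @param viability percent viability, same length as `doses`.
#' @return A `dose_response_fit` list: `lower`, `upper`, `slope`,
#'   `inflection` (ug/ml), `ic50` (ug/ml or NA), `converged`,
#'   `residual_sse`.
#' @export
fit_4pl <- function(doses, viability) {
  doses <- as.numeric(doses); viability <- as.numeric(viability)
  if (length(doses) != length(viability))
    stop("doses and viability must have equal length", call. = FALSE)
  if (any(!is.finite(doses)) || any(!is.finite(viability)))
    stop("doses and viability must be finite", call. = FALSE)
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  if (length(unique(doses)) < 4)
    stop("need at least 4 distinct dose levels", call. = FALSE)

  f4pl <- function(x, lower, upper, slope, inflection) {
    y <- rep(upper, length(x))
    pos <- x > 0
    y[pos] <- lower + (upper - lower) / (1 + (x[pos] / inflection)^slope)
    y
  }
  lo0 <- min(viability); up0 <- max(viability)
  if (up0 - lo0 < 1e-8) { up0 <- lo0 + 1e-6 }
  c0 <- exp(mean(log(doses[doses > 0])))

  best <- NULL
  for (b0 in c(0.5, 1, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        viability ~ f4pl(doses, lower, upper, slope, inflection),
        start = list(lower = lo0, upper = up0, slope = b0,
                     inflection = c0),
        lower = c(-Inf, -Inf, 1e-3, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(coef = stats::coef(fit), sse = sse)
  }

  if (is.null(best)) {
    # Levenberg-Marquardt can fail on degenerate data (e.g. flat
    # viability); fall back to direct SSE minimization with a positivity
    # parameterization of slope and inflection.
    obj <- function(par)
      sum((viability - f4pl(doses, par[1], par[2], exp(par[3]),
                            exp(par[4])))^2)
    for (b0 in c(0.5, 1, 2, 4)) {
      op <- tryCatch(
        stats::optim(c(lo0, up0, log(b0), log(c0)), obj,
                     method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(op)) next
      cf <- c(lower = op$par[1], upper = op$par[2],
              slope = exp(op$par[3]), inflection = exp(op$par[4]))
      if (is.null(best) || op$value < best$sse)
        best <- list(coef = cf, sse = op$value)
    }
  }
  if (is.null(best)) {
    return(structure(list(lower = NA_real_, upper = NA_real_,
                          slope = NA_real_, inflection = NA_real_,
                          ic50 = NA_real_, converged = FALSE,
                          residual_sse = NA_real_),
                     class = "dose_response_fit"))
  }
  cf <- best$coef
  lower <- unname(cf["lower"]); upper <- unname(cf["upper"])
  slope <- unname(cf["slope"]); inflection <- unname(cf["inflection"])
  ic50 <- NA_real_
  if (min(lower, upper) < 50 && 50 < max(lower, upper)) {
    ic50 <- inflection * ((upper - 50) / (50 - lower))^(1 / slope)
    if (!is.finite(ic50) || ic50 <= 0) ic50 <- NA_real_
  }
  structure(list(lower = lower, upper = upper, slope = slope,
                 inflection = inflection, ic50 = ic50,
                 converged = TRUE, residual_sse = best$sse),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("4PL fit: lower %.2f, upper %.2f, slope %.3f, ",
                     "inflection %.3f, IC50 %s\n"),
              x$lower, x$upper, x$slope, x$inflection,
              if (is.na(x$ic50)) "undefined" else sprintf("%.3f", x$ic50)))
  invisible(x)
}

#' Summarize per-replicate IC50 values for one sample
#'
#' Computes the replicate mean and sample standard deviation (n - 1
#' denominator) and the natural log of the mean IC50, the response used in
#' downstream modeling.
#'
#' @param per_replicate_ic50 numeric vector of IC50 values (ug/ml);
#'   non-finite entries (failed fits) are dropped with a warning.
#' @param sample_id sample identifier.
#' @return A `bioactivity_summary` list: `sample_id`, `ic50_mean`,
#'   `ic50_sd`, `log_ic50`, `n_replicates`, `usable`.
#' @export
summarize_bioactivity <- function(per_replicate_ic50, sample_id) {
  x <- as.numeric(per_replicate_ic50)
  ok <- is.finite(x) & x > 0
  if (any(!ok))
    warning(sprintf("sample '%s': dropped %d unusable IC50 replicate(s)",
                    sample_id, sum(!ok)), call. = FALSE)
  x <- x[ok]
  if (length(x) == 0) {
    warning(sprintf("sample '%s': no usable IC50 replicates; excluded",
                    sample_id), call. = FALSE)
    return(structure(list(sample_id = sample_id, ic50_mean = NA_real_,
                          ic50_sd = NA_real_, log_ic50 = NA_real_,
                          n_replicates = 0L, usable = FALSE),
                     class = "bioactivity_summary"))
  }
  m <- mean(x)
  s <- if (length(x) > 1) stats::sd(x) else 0
  structure(list(sample_id = sample_id, ic50_mean = m, ic50_sd = s,
                 log_ic50 = log(m), n_replicates = length(x),
                 usable = TRUE),
            class = "bioactivity_summary")
}

#' Compute per-sample IC50 summaries from plate viability data
#'
#' For each sample, fits a 4PL curve either per plate replicate (default;
#' IC50 replicates then averaged) or on the pooled wells, and summarizes
#' with [summarize_bioactivity()].
#'
#' @param assay a data.frame with columns
#'   `sample_id,dose_ug_ml,viability_pct,plate_rep`
#'   (see [read_bioassay_csv()]).
#' @param per_plate logical; fit one curve per `plate_rep` (TRUE, default)
#'   or one curve on pooled wells (FALSE).
#' @return A data.frame with one row per sample: `sample_id`, `ic50`,
#'   `ic50_sd`, `log_ic50`, `n_replicates`, `usable`.
#' @export
ic50_from_assay <- function(assay, per_plate = TRUE) {
  out <- lapply(split(assay, assay$sample_id), function(d) {
    reps <- if (per_plate) split(d, d$plate_rep) else list(d)
    ic50s <- vapply(reps, function(r) {
      fit <- tryCatch(fit_4pl(r$dose_ug_ml, r$viability_pct),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) NA_real_ else fit$ic50
    }, numeric(1))
    s <- summarize_bioactivity(ic50s, d$sample_id[1])
    data.frame(sample_id = s$sample_id, ic50 = s$ic50_mean,
               ic50_sd = s$ic50_sd, log_ic50 = s$log_ic50,
               n_replicates = s$n_replicates, usable = s$usable,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
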