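#' Run the full biochemometric prioritization pipeline
#'
#' Chains the workflow end to end on an aligned feature table and
#' per-sample bioactivity summaries:
#' \enumerate{
#'   \item blank filter (fold-change vs. mean blank area) and source-group
#'     presence filter on raw areas, with a stepwise trace;
#'   \item Pearson audit of everything the filters removed;
#'   \item zero replacement, zero-variance removal, Hellinger transform;
#'   \item balanced 80:20 split stratified on log IC50; auto-scaling
#'     fitted on the training set only;
#'   \item LASSO preselection with LOO-CV penalty choice;
#'   \item PLS regression on the selected features with LOO-CV component
#'     choice; train (LOO) and test RMSE;
#'   \item VIP + Selectivity Ratio scoring, threshold union, and
#'     direction-of-activity assignment on raw areas.
#' }
#'
#' @param ft a [feature_table()] including blank injections.
#' @param metadata sample metadata for the non-blank samples.
#' @param bio per-sample bioactivity data.frame with `sample_id`, `ic50`,
#'   `log_ic50` (e.g. from [ic50_from_assay()]).
#' @param blank_fold blank-filter fold threshold (default 5).
#' @param min_samples blank-filter sample count; `"auto"` = half the
#'   smaller source group.
#' @param presence_mode source filter clause combination
#'   (`"each-group"`/`"any-group"`).
#' @param epsilon zero-replacement constant (default 0.001).
#' @param test_fraction held-out fraction for the split (default 0.2).
#' @param max_components PLS component ceiling (default 10).
#' @param vip_threshold,sr_threshold,selection_mode candidate-selection
#'   settings (defaults 1.0, 0.5, `"union"`).
#' @param direction_k group size for the most/least-active comparison.
#' @param seed integer seed controlling the split.
#' @param audit run the Pearson audit of removed features (default TRUE;
#'   the scan is linear in removed features but can be switched off).
#' @return A `biochemom_result` list: `candidates` (report data.frame),
#'   `scores`, `validation` (rmse_train_cv, rmse_test, cv_percent_train,
#'   cv_percent_test, per-sample predictions), `traces` (filter ledger),
#'   `audit`, `split`, `lasso`, `model`, `n_features` (named stepwise
#'   counts).
#' @export
run_pipeline <- function(ft, metadata, bio,
                         blank_fold = 5, min_samples = "auto",
                         presence_mode = "each-group",
                         epsilon = 0.001, test_fraction = 0.2,
                         max_components = 10,
                         vip_threshold = 1.0, sr_threshold = 0.5,
                         selection_mode = "union", direction_k = 5,
                         seed = 1, audit = TRUE) {
  meta_nb <- metadata[!metadata$sample_id %in% ft$blank_ids, , drop = FALSE]
  counts <- c(aligned = length(ft$feature_ids))

  bf <- blank_filter(ft, fold = blank_fold, min_samples = min_samples,
                     metadata = meta_nb)
  counts["blank_filter"] <- length(bf$table$feature_ids)
  sf <- source_presence_filter(bf$table, meta_nb,
                               presence_threshold = epsilon,
                               mode = presence_mode)
  counts["source_filter"] <- length(sf$table$feature_ids)

  removed <- c(bf$trace$removed$feature_id, sf$trace$removed$feature_id)
  audit_rep <- if (audit && length(removed))
    audit_removed(removed, ft, bio) else NULL

  tab <- ft_drop_blanks(sf$table)
  tab <- ft_subset(tab, samples = intersect(tab$sample_ids,
                                            bio$sample_id))
  tab <- replace_zeros(tab, epsilon)
  zv <- drop_zero_variance(tab)
  tab <- zv$table
  counts["zero_variance"] <- length(tab$feature_ids)
  if (length(tab$feature_ids) == 0)
    stop("no features left after filtering; cannot model", call. = FALSE)

  H <- hellinger(tab)
  bio_m <- bio[match(tab$sample_ids, bio$sample_id), , drop = FALSE]

  split <- balanced_split(bio_m, test_fraction = test_fraction,
                          seed = seed)
  tr <- match(split$train_ids, tab$sample_ids)
  te <- match(split$test_ids, tab$sample_ids)
  y_tr <- bio_m$log_ic50[tr]; y_te <- bio_m$log_ic50[te]

  scaler <- fit_scaler(H[tr, , drop = FALSE], "auto")
  Xs_tr <- apply_scaler(H[tr, , drop = FALSE], scaler)
  las <- lasso_select_loo(Xs_tr, y_tr - mean(y_tr))
  sel_ids <- las$selected_ids
  if (length(sel_ids) == 0) {
    warning("LASSO selected no features; modeling all filtered features",
            call. = FALSE)
    sel_ids <- tab$feature_ids
  }
  counts["lasso"] <- length(sel_ids)

  ji <- match(sel_ids, tab$feature_ids)
  X_tr <- H[tr, ji, drop = FALSE]; X_te <- H[te, ji, drop = FALSE]
  colnames(X_tr) <- sel_ids; colnames(X_te) <- sel_ids
  comp <- select_components_loo(X_tr, y_tr, max_components)
  model <- pls_fit(X_tr, y_tr, comp$ncomp)

  pred_te <- pls_predict(model, X_te)
  rmse_train_cv <- comp$cv_rmse[comp$ncomp]
  rmse_test <- rmse(y_te, pred_te)
  validation <- list(
    ncomp = comp$ncomp,
    cv_rmse_curve = comp$cv_rmse,
    rmse_train_cv = rmse_train_cv,
    rmse_test = rmse_test,
    cv_percent_train = cv_percent(rmse_train_cv, bio_m$log_ic50),
    cv_percent_test = cv_percent(rmse_test, bio_m$log_ic50),
    predictions = data.frame(sample_id = split$test_ids,
                             observed = y_te, predicted = pred_te,
                             stringsAsFactors = FALSE))

  sel <- select_candidates(model, vip_threshold = vip_threshold,
                           sr_threshold = sr_threshold,
                           mode = selection_mode)
  cand_ids <- sel$selected_ids
  direction <- if (length(cand_ids))
    assign_direction(cand_ids, tab, bio_m, k = direction_k)
    else stats::setNames(character(), character())
  ci <- match(cand_ids, tab$feature_ids)
  cand_scores <- sel$scores[match(cand_ids, sel$scores$feature_id), ,
                            drop = FALSE]
  candidates <- data.frame(
    feature_id = cand_ids,
    mz = tab$mz[ci], rt = tab$rt[ci],
    vip = cand_scores$vip, sr = cand_scores$sr,
    direction = unname(direction[cand_ids]),
    lasso_coef = unname(las$beta[match(cand_ids, names(las$beta))]),
    best_match_id = NA_character_, cosine = NA_real_,
    filters_passed = "blank_filter;source_filter;lasso;vip_sr",
    stringsAsFactors = FALSE)
  if (nrow(candidates))
    candidates <- candidates[order(-candidates$sr, -candidates$vip,
                                   candidates$feature_id), , drop = FALSE]
  rownames(candidates) <- NULL

  structure(list(candidates = candidates, scores = sel,
                 validation = validation,
                 traces = list(blank = bf$trace, source = sf$trace),
                 audit = audit_rep, split = split, lasso = las,
                 model = model, n_features = counts,
                 feature_table = tab),
            class = "biochemom_result")
}

#' @export
print.biochemom_result <- function(x, ...) {
  cat("biochemometric pipeline result\n")
  cat("  features: ",
      paste(sprintf("%s=%d", names(x$n_features), x$n_features),
            collapse = " -> "), "\n", sep = "")
  cat(sprintf("  PLS components: %d | LOO RMSE %.4f | test RMSE %.4f\n",
              x$validation$ncomp, x$validation$rmse_train_cv,
              x$validation$rmse_test))
  cat(sprintf("  candidates: %d (mode %s)\n", nrow(x$candidates),
              x$scores$mode))
  invisible(x)
}

#' Attach MS2 library annotations to a candidate report
#'
#' For each candidate with a spectrum whose identifier equals the feature
#' id, runs [cosine_match()] against the library and fills
#' `best_match_id`/`cosine` with the top hit.
#'
#' @param candidates candidate report data.frame (from [run_pipeline()]).
#' @param query_spectra list of [spectrum2()] with identifiers matching
#'   feature ids.
#' @param library list of library [spectrum2()] objects.
#' @param precursor_tol,fragment_tol match tolerances (Da).
#' @return The report with annotation columns filled where a match exists.
#' @export
annotate_candidates <- function(candidates, query_spectra, library,
                                precursor_tol = 0.01,
                                fragment_tol = 0.02) {
  qids <- vapply(query_spectra, function(s) s$identifier, character(1))
  for (i in seq_len(nrow(candidates))) {
    k <- match(candidates$feature_id[i], qids)
    if (is.na(k)) next
    hits <- cosine_match(query_spectra[[k]], library,
                         precursor_tol, fragment_tol)
    if (nrow(hits)) {
      candidates$best_match_id[i] <- hits$library_id[1]
      candidates$cosine[i] <- hits$cosine[1]
    }
  }
  candidates
}
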