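#' Blank-injection fold-change filter
#'
#' Retains a feature only if, in at least `min_samples` non-blank samples,
#' its raw peak area exceeds `fold` times the feature's mean area across
#' all blank injections (zeros included in the blank mean). A blank mean of
#' 0 means any positive area counts. Operates on raw areas, before any
#' transformation: fold-change thresholds are meaningless after row
#' normalization.
#'
#' @param ft a [feature_table()] with at least one blank sample.
#' @param fold fold-change threshold (> 0, default 5).
#' @param min_samples minimum number of qualifying non-blank samples;
#'   `"auto"` (default) uses `ceiling(smallest source group / 2)` and then
#'   requires `metadata`.
#' @param metadata sample metadata data.frame (needed for
#'   `min_samples = "auto"`).
#' @return A list with `table` (retained features, blanks dropped from the
#'   threshold count but kept in the table) and `trace` (a `filter_trace`).
#' @export
blank_filter <- function(ft, fold = 5, min_samples = "auto",
                         metadata = NULL) {
  if (length(ft$blank_ids) == 0)
    stop(paste("no blank samples present; skip the blank filter",
               "explicitly if none were acquired"), call. = FALSE)
  if (fold <= 0) stop("fold must be > 0", call. = FALSE)
  if (identical(min_samples, "auto")) {
    if (is.null(metadata))
      stop("min_samples = \"auto\" requires metadata", call. = FALSE)
    gsz <- table(metadata$source_group)
    min_samples <- ceiling(min(gsz) / 2)
  }
  min_samples <- as.integer(min_samples)
  if (min_samples < 1) stop("min_samples must be >= 1", call. = FALSE)

  bi <- match(ft$blank_ids, ft$sample_ids)
  si <- which(!(ft$sample_ids %in% ft$blank_ids))
  blank_mean <- colMeans(ft$areas[bi, , drop = FALSE])
  above <- colSums(ft$areas[si, , drop = FALSE] >
                     rep(fold * blank_mean, each = length(si)))
  keep <- above >= min_samples
  removed <- ft$feature_ids[!keep]
  trace <- filter_trace(
    "blank_filter", length(ft$feature_ids), sum(keep),
    removed_ids = removed,
    reasons = sprintf(
      "area > %g x blank mean (%.4g) in only %d of %d samples (< %d)",
      fold, blank_mean[!keep], above[!keep], length(si), min_samples),
    parameters = list(fold = fold, min_samples = min_samples))
  list(table = ft_subset(ft, features = ft$feature_ids[keep]),
       trace = trace)
}

#' Source-group presence filter
#'
#' Retains a feature if it is present (area strictly above
#' `presence_threshold`) in every non-blank sample, or present in at least
#' half of each source group (ceiling on odd group sizes). With
#' `mode = "any-group"` the second clause requires only one group to reach
#' half. Operates on raw areas.
#'
#' @param ft a [feature_table()].
#' @param metadata sample metadata with `sample_id` and `source_group`
#'   for every non-blank sample.
#' @param presence_threshold area above which a feature counts as present
#'   (default: the zero-replacement epsilon, 0.001).
#' @param mode `"each-group"` (default) or `"any-group"`.
#' @return A list with `table` and `trace` as in [blank_filter()].
#' @export
source_presence_filter <- function(ft, metadata,
                                   presence_threshold = 0.001,
                                   mode = c("each-group", "any-group")) {
  mode <- match.arg(mode)
  nb <- setdiff(ft$sample_ids, ft$blank_ids)
  grp <- metadata$source_group[match(nb, metadata$sample_id)]
  if (anyNA(grp))
    stop("metadata missing for sample(s): ",
         paste(nb[is.na(grp)], collapse = ", "), call. = FALSE)
  groups <- unique(grp)
  if (length(groups) < 2)
    stop("need at least 2 source groups", call. = FALSE)
  gsz <- table(grp)
  if (any(gsz == 0)) stop("empty source group", call. = FALSE)

  present <- ft$areas[match(nb, ft$sample_ids), , drop = FALSE] >
    presence_threshold
  in_all <- colSums(present) == length(nb)
  half_counts <- vapply(groups, function(g)
    as.integer(ceiling(sum(grp == g) / 2)), integer(1))
  per_group <- vapply(groups, function(g)
    colSums(present[grp == g, , drop = FALSE]), numeric(ncol(present)))
  per_group <- matrix(per_group, ncol = length(groups),
                      dimnames = list(NULL, groups))
  meets_half <- per_group >= rep(half_counts, each = ncol(present))
  half_clause <- if (mode == "each-group") apply(meets_half, 1, all)
                 else apply(meets_half, 1, any)
  keep <- in_all | half_clause
  removed <- ft$feature_ids[!keep]
  reasons <- apply(per_group[!keep, , drop = FALSE], 1, function(cnt)
    paste(sprintf("%s: %d/%d present", groups, cnt, as.integer(gsz[groups])),
          collapse = "; "))
  trace <- filter_trace(
    "source_presence_filter", length(ft$feature_ids), sum(keep),
    removed_ids = removed, reasons = reasons,
    parameters = list(presence_threshold = presence_threshold,
                      mode = mode,
                      half_counts = stats::setNames(half_counts, groups)))
  list(table = ft_subset(ft, features = ft$feature_ids[keep]),
       trace = trace)
}

filter_trace <- function(name, n_in, n_out, removed_ids, reasons,
                         parameters) {
  stopifnot(n_out == n_in - length(removed_ids))
  structure(list(filter = name, features_in = n_in, features_out = n_out,
                 removed = data.frame(feature_id = removed_ids,
                                      reason = if (length(removed_ids))
                                        reasons else character(),
                                      stringsAsFactors = FALSE),
                 parameters = parameters),
            class = "filter_trace")
}

#' @export
print.filter_trace <- function(x, ...) {
  cat(sprintf("%s: %d -> %d features (%d removed, %.1f%%)\n",
              x$filter, x$features_in, x$features_out,
              nrow(x$removed),
              100 * nrow(x$removed) / max(x$features_in, 1)))
  invisible(x)
}

#' Pearson audit of filtered-out features
#'
#' Before discarding features, checks that none of them track the
#' bioactivity response: computes the Pearson correlation between each
#' removed feature's raw area vector and per-sample log IC50, flagging any
#' with `|r| >= r_threshold` as a possibly discarded active.
#'
#' @param removed_ids feature ids that a filter removed.
#' @param ft the pre-filter [feature_table()] containing those features.
#' @param bio data.frame with `sample_id` and `log_ic50` (as produced by
#'   [ic50_from_assay()]).
#' @param r_threshold flag threshold on `|r|` (default 0.5).
#' @return An `audit_report` list: `per_feature` (feature_id, r, n,
#'   flagged), `max_abs_r`, `n_flagged`.
#' @export
audit_removed <- function(removed_ids, ft, bio, r_threshold = 0.5) {
  nb <- setdiff(ft$sample_ids, ft$blank_ids)
  common <- intersect(nb, bio$sample_id[is.finite(bio$log_ic50)])
  if (length(common) < 3)
    stop("need >= 3 samples with both areas and log IC50", call. = FALSE)
  y <- bio$log_ic50[match(common, bio$sample_id)]
  rows <- lapply(removed_ids, function(id) {
    x <- ft$areas[match(common, ft$sample_ids), match(id, ft$feature_ids)]
    r <- if (max(x) - min(x) == 0) NA_real_ else stats::cor(x, y)
    data.frame(feature_id = id, r = r, n = length(common),
               flagged = is.finite(r) && abs(r) >= r_threshold,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  if (is.null(per))
    per <- data.frame(feature_id = character(), r = numeric(),
                      n = integer(), flagged = logical())
  flagged <- per$feature_id[per$flagged]
  if (length(flagged))
    warning("possibly discarded active feature(s): ",
            paste(flagged, collapse = ", "), call. = FALSE)
  structure(list(per_feature = per,
                 max_abs_r = if (any(is.finite(per$r)))
                   max(abs(per$r), na.rm = TRUE) else NA_real_,
                 n_flagged = sum(per$flagged)),
            class = "audit_report")
}
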