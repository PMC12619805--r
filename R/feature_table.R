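#' Construct a feature table
#'
#' A `feature_table` holds an aligned untargeted-metabolomics dataset:
#' a nonnegative peak-area matrix (samples x features), the feature
#' annotations (m/z in Da, retention time in minutes), and the identity of
#' blank-injection samples. Missing measurements are encoded as 0.
#'
#' @param areas numeric matrix, `n_samples x n_features`, peak areas (>= 0).
#' @param feature_ids character vector of unique feature identifiers.
#' @param mz numeric vector of feature m/z values (Da).
#' @param rt numeric vector of feature retention times (minutes).
#' @param sample_ids character vector of unique sample identifiers.
#' @param blank_ids character vector, subset of `sample_ids`, flagging
#'   blank (solvent-only) injections.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(areas, feature_ids, mz, rt, sample_ids,
                          blank_ids = character()) {
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  ft <- structure(
    list(areas = areas,
         feature_ids = as.character(feature_ids),
         mz = as.numeric(mz),
         rt = as.numeric(rt),
         sample_ids = as.character(sample_ids),
         blank_ids = as.character(blank_ids)),
    class = "feature_table")
  validate_feature_table(ft)
  dimnames(ft$areas) <- list(ft$sample_ids, ft$feature_ids)
  ft
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples (%d blank) x %d features\n",
              length(x$sample_ids), length(x$blank_ids),
              length(x$feature_ids)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$areas)

validate_feature_table <- function(ft) {
  if (nrow(ft$areas) != length(ft$sample_ids))
    stop("areas has ", nrow(ft$areas), " rows but ",
         length(ft$sample_ids), " sample ids", call. = FALSE)
  if (ncol(ft$areas) != length(ft$feature_ids))
    stop("areas has ", ncol(ft$areas), " columns but ",
         length(ft$feature_ids), " feature ids", call. = FALSE)
  if (length(ft$mz) != length(ft$feature_ids) ||
      length(ft$rt) != length(ft$feature_ids))
    stop("mz/rt length must match number of features", call. = FALSE)
  dup <- unique(ft$feature_ids[duplicated(ft$feature_ids)])
  if (length(dup))
    stop("duplicate feature ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  dup <- unique(ft$sample_ids[duplicated(ft$sample_ids)])
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (anyNA(ft$areas) || any(!is.finite(ft$areas)))
    stop("areas must be finite and non-missing", call. = FALSE)
  if (any(ft$areas < 0)) {
    bad <- which(ft$areas < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative peak area at sample '%s', feature '%s'",
                 ft$sample_ids[bad[1]], ft$feature_ids[bad[2]]),
         call. = FALSE)
  }
  extra <- setdiff(ft$blank_ids, ft$sample_ids)
  if (length(extra))
    stop("blank ids not among sample ids: ",
         paste(extra, collapse = ", "), call. = FALSE)
  invisible(ft)
}

#' Subset a feature table by feature and/or sample ids
#'
#' @param ft a `feature_table`.
#' @param features character vector of feature ids to keep (default all).
#' @param samples character vector of sample ids to keep (default all).
#' @return A `feature_table` restricted to the requested ids, in the
#'   requested order.
#' @export
ft_subset <- function(ft, features = ft$feature_ids,
                      samples = ft$sample_ids) {
  fi <- match(features, ft$feature_ids)
  si <- match(samples, ft$sample_ids)
  if (anyNA(fi))
    stop("unknown feature ids: ",
         paste(features[is.na(fi)], collapse = ", "), call. = FALSE)
  if (anyNA(si))
    stop("unknown sample ids: ",
         paste(samples[is.na(si)], collapse = ", "), call. = FALSE)
  feature_table(ft$areas[si, fi, drop = FALSE],
                ft$feature_ids[fi], ft$mz[fi], ft$rt[fi],
                ft$sample_ids[si],
                intersect(ft$blank_ids, ft$sample_ids[si]))
}

#' Drop blank-injection samples from a feature table
#'
#' @param ft a `feature_table`.
#' @return The table restricted to non-blank samples.
#' @export
ft_drop_blanks <- function(ft) {
  ft_subset(ft, samples = setdiff(ft$sample_ids, ft$blank_ids))
}
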