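#' Load a feature table and sample metadata from CSV
#'
#' The on-disk feature table is MZmine-export-like: features as rows with a
#' `feature_id,mz,rt,<sample_id_1>,...` header; in memory the matrix is
#' transposed to samples x features. Metadata rows are matched to sample
#' columns by exact, case-sensitive id. Blank injections are identified by
#' the metadata `is_blank` column, or, when no metadata row exists for a
#' column, by `blank_pattern` matched against the sample id.
#'
#' @param feature_table_path path to the feature-table CSV.
#' @param metadata_path path to the metadata CSV with header
#'   `sample_id,source_group,species,replicate,is_blank`.
#' @param blank_pattern optional regular expression; sample columns with no
#'   metadata row whose id matches are treated as blanks.
#' @return A list with elements `table` (a [feature_table()]) and
#'   `metadata` (a data.frame of the non-blank sample metadata, ordered as
#'   the matrix rows).
#' @export
load_dataset <- function(feature_table_path, metadata_path,
                         blank_pattern = NULL) {
  tab <- read_feature_csv(feature_table_path)
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  req <- c("sample_id", "source_group", "species", "replicate", "is_blank")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta$is_blank <- as.logical(meta$is_blank)
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup))
    stop("duplicate metadata sample ids: ", paste(dup, collapse = ", "),
         call. = FALSE)

  blanks <- meta$sample_id[meta$is_blank]
  unknown <- setdiff(tab$sample_ids, meta$sample_id)
  if (!is.null(blank_pattern) && length(unknown)) {
    pat_blank <- unknown[grepl(blank_pattern, unknown)]
    blanks <- union(blanks, pat_blank)
    unknown <- setdiff(unknown, pat_blank)
  }
  if (length(unknown))
    stop("no metadata row for sample id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  extra <- setdiff(meta$sample_id, tab$sample_ids)
  if (length(extra))
    stop("metadata sample id(s) absent from feature table: ",
         paste(extra, collapse = ", "), call. = FALSE)

  ft <- feature_table(tab$areas, tab$feature_ids, tab$mz, tab$rt,
                      tab$sample_ids, intersect(blanks, tab$sample_ids))
  nb <- setdiff(ft$sample_ids, ft$blank_ids)
  meta <- meta[match(nb, meta$sample_id), , drop = FALSE]
  meta <- meta[!is.na(meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  grp <- table(meta$source_group)
  if (length(grp) >= 1 && any(grp < 1))
    stop("every declared source group needs at least one sample",
         call. = FALSE)
  list(table = ft, metadata = meta)
}

read_feature_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  req <- c("feature_id", "mz", "rt")
  if (!all(req %in% names(raw)[1:3]))
    stop("feature table header must start with feature_id,mz,rt",
         call. = FALSE)
  sample_ids <- setdiff(names(raw), req)
  num <- matrix(NA_real_, nrow(raw), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(raw[[sample_ids[j]]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf(
        "non-numeric peak area '%s' at feature row %d, sample column '%s'",
        raw[[sample_ids[j]]][i], i, sample_ids[j]), call. = FALSE)
    }
    num[, j] <- v
  }
  list(areas = t(num),                      # samples x features
       feature_ids = raw$feature_id,
       mz = as.numeric(raw$mz),
       rt = as.numeric(raw$rt),
       sample_ids = sample_ids)
}

#' Write a feature table to CSV
#'
#' Inverse of the reader used by [load_dataset()]: features as rows,
#' samples as columns, full numeric precision.
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(feature_id = ft$feature_ids,
                   mz = ft$mz, rt = ft$rt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  areas <- t(ft$areas)
  for (j in seq_along(ft$sample_ids)) df[[ft$sample_ids[j]]] <- areas[, j]
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a candidate report to TSV
#'
#' Rows are ordered deterministically: descending Selectivity Ratio,
#' ties broken by descending VIP, then lexicographic feature id.
#'
#' @param report a data.frame with columns `feature_id,mz,rt,vip,sr,
#'   direction,lasso_coef,best_match_id,cosine,filters_passed`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(report, path) {
  cols <- c("feature_id", "mz", "rt", "vip", "sr", "direction",
            "lasso_coef", "best_match_id", "cosine", "filters_passed")
  miss <- setdiff(cols, names(report))
  if (length(miss))
    stop("candidate report missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  report <- report[, cols, drop = FALSE]
  if (nrow(report)) {
    ord <- order(-report$sr, -report$vip, report$feature_id)
    report <- report[ord, , drop = FALSE]
  }
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read bioassay plate data from CSV
#'
#' @param path CSV with header `sample_id,dose_ug_ml,viability_pct,plate_rep`.
#' @return A data.frame with those columns, doses and viability numeric.
#' @export
read_bioassay_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "dose_ug_ml", "viability_pct", "plate_rep")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("bioassay CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$dose_ug_ml <- as.numeric(df$dose_ug_ml)
  df$viability_pct <- as.numeric(df$viability_pct)
  if (anyNA(df$dose_ug_ml) || anyNA(df$viability_pct))
    stop("non-numeric dose or viability value in ", path, call. = FALSE)
  df
}
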