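#' Cosine similarity search against a spectral library
#'
#' Library entries are first screened by precursor m/z
#' (`|delta| <= precursor_tol`). For each surviving entry, intensities are
#' square-root transformed and normalized to unit Euclidean norm per
#' spectrum; fragment peaks are then greedily paired within
#' `fragment_tol` (largest intensity product first, each peak used once)
#' and the cosine score is the sum of matched intensity products, so a
#' spectrum matched against itself scores exactly 1.
#'
#' @param query a [spectrum2()].
#' @param library a list of [spectrum2()] objects.
#' @param precursor_tol precursor m/z tolerance (Da, > 0).
#' @param fragment_tol fragment m/z tolerance (Da, > 0).
#' @return A data.frame of matches sorted by descending cosine:
#'   `query_id, library_id, cosine, n_matched, precursor_delta`. Empty
#'   when nothing passes the precursor screen.
#' @export
cosine_match <- function(query, library, precursor_tol = 0.01,
                         fragment_tol = 0.02) {
  if (precursor_tol <= 0 || fragment_tol <= 0)
    stop("tolerances must be > 0", call. = FALSE)
  rows <- lapply(library, function(lib) {
    delta <- lib$precursor_mz - query$precursor_mz
    if (abs(delta) > precursor_tol) return(NULL)
    cm <- spectral_cosine(query, lib, fragment_tol)
    data.frame(query_id = query$identifier, library_id = lib$identifier,
               cosine = cm$cosine, n_matched = cm$n_matched,
               precursor_delta = delta, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(query_id = character(), library_id = character(),
                      cosine = numeric(), n_matched = integer(),
                      precursor_delta = numeric()))
  out <- out[order(-out$cosine, out$library_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# sqrt-intensity cosine with greedy one-to-one peak pairing
spectral_cosine <- function(a, b, fragment_tol) {
  ia <- sqrt(a$intensity); ia <- ia / sqrt(sum(ia^2))
  ib <- sqrt(b$intensity); ib <- ib / sqrt(sum(ib^2))
  pairs <- list()
  for (i in seq_along(a$mz)) {
    js <- which(abs(b$mz - a$mz[i]) <= fragment_tol)
    for (j in js)
      pairs[[length(pairs) + 1L]] <- c(i, j, ia[i] * ib[j])
  }
  if (!length(pairs)) return(list(cosine = 0, n_matched = 0L))
  pm <- do.call(rbind, pairs)
  pm <- pm[order(-pm[, 3]), , drop = FALSE]
  used_a <- logical(length(a$mz)); used_b <- logical(length(b$mz))
  score <- 0; nmatch <- 0L
  for (r in seq_len(nrow(pm))) {
    i <- pm[r, 1]; j <- pm[r, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    score <- score + pm[r, 3]
    nmatch <- nmatch + 1L
  }
  list(cosine = min(score, 1), n_matched = nmatch)
}

#' Export mirror-plot data for a query/library spectrum pair
#'
#' Writes a two-block CSV (`block` = "query" or "library") with each
#' block's intensities normalized to base peak 100; library intensities
#' are negated so the file plots directly as a mirror plot.
#'
#' @param query,match [spectrum2()] objects (both nonempty).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_mirror <- function(query, match, path) {
  norm100 <- function(s) 100 * s$intensity / max(s$intensity)
  df <- rbind(
    data.frame(block = "query", mz = query$mz,
               intensity = norm100(query), stringsAsFactors = FALSE),
    data.frame(block = "library", mz = match$mz,
               intensity = -norm100(match), stringsAsFactors = FALSE))
  utils::write.csv(format(df, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
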