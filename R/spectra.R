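#' Construct an MS2 spectrum
#'
#' @param precursor_mz precursor m/z (Da).
#' @param mz fragment m/z values (Da).
#' @param intensity fragment intensities (>= 0), same length as `mz`.
#' @param identifier spectrum identifier string.
#' @return A `spectrum2` object; peaks are stored sorted ascending in m/z.
#' @export
spectrum2 <- function(precursor_mz, mz, intensity, identifier = "") {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length", call. = FALSE)
  if (length(mz) < 1) stop("a spectrum needs at least one peak", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  o <- order(mz)
  structure(list(precursor_mz = as.numeric(precursor_mz),
                 mz = as.numeric(mz[o]),
                 intensity = as.numeric(intensity[o]),
                 identifier = as.character(identifier)),
            class = "spectrum2")
}

#' @export
print.spectrum2 <- function(x, ...) {
  cat(sprintf("spectrum2 '%s': precursor m/z %.5f, %d peaks\n",
              x$identifier, x$precursor_mz, length(x$mz)))
  invisible(x)
}

#' Read spectra from a Mascot Generic Format (MGF) file
#'
#' One [spectrum2()] is returned per BEGIN IONS / END IONS block; each block
#' must carry a PEPMASS line. Blocks with no peaks are skipped with a
#' warning. Peak lines are `m/z intensity` (whitespace separated; a missing
#' intensity is read as 1).
#'
#' @param path path to the MGF file.
#' @return A list of `spectrum2` objects (possibly empty).
#' @export
load_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  spectra <- list()
  i <- 1L; block <- 0L
  while (i <= length(lines)) {
    if (lines[i] != "BEGIN IONS") { i <- i + 1L; next }
    block <- block + 1L
    i <- i + 1L
    pep <- NA_real_; title <- sprintf("scan_%d", block)
    mzv <- numeric(); intv <- numeric()
    closed <- FALSE
    while (i <= length(lines)) {
      ln <- lines[i]
      if (ln == "END IONS") { closed <- TRUE; i <- i + 1L; break }
      if (grepl("^PEPMASS=", ln)) {
        pep <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
      } else if (grepl("^TITLE=", ln)) {
        title <- sub("^TITLE=", "", ln)
      } else if (grepl("^[A-Za-z_]+=", ln) || ln == "") {
        # other key=value headers ignored
      } else {
        parts <- strsplit(ln, "[[:space:],]+")[[1]]
        m <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(m))
          stop(sprintf("malformed peak line in MGF block %d: '%s'",
                       block, ln), call. = FALSE)
        mzv <- c(mzv, m)
        iv <- if (length(parts) >= 2)
          suppressWarnings(as.numeric(parts[2])) else 1
        intv <- c(intv, if (is.na(iv)) 1 else iv)
      }
      i <- i + 1L
    }
    if (!closed)
      stop(sprintf("MGF block %d has no END IONS", block), call. = FALSE)
    if (is.na(pep))
      stop(sprintf("MGF block %d has no PEPMASS", block), call. = FALSE)
    if (length(mzv) == 0) {
      warning(sprintf("MGF block %d has no peaks; skipped", block),
              call. = FALSE)
      next
    }
    spectra[[length(spectra) + 1L]] <- spectrum2(pep, mzv, intv, title)
  }
  if (block == 0L && length(lines) &&
      any(nzchar(lines)))
    stop("no BEGIN IONS block found in ", path, call. = FALSE)
  if (block == 0L) warning("empty MGF file: ", path, call. = FALSE)
  spectra
}

#' Write spectra to a Mascot Generic Format (MGF) file
#'
#' @param spectra a list of [spectrum2()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$identifier),
                 sprintf("PEPMASS=%.*g", 17, s$precursor_mz),
                 sprintf("%.*g %.*g", 17, s$mz, 17, s$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}
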