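# Small in-code fixtures shared across test files.

toy_feature_table <- function() {
  feature_table(matrix(c(1, 2,
                         3, 4,
                         5, 6), nrow = 3, byrow = TRUE),
                feature_ids = c("fA", "fB"),
                mz = c(150.1, 300.2), rt = c(1.5, 6.2),
                sample_ids = c("s1", "s2", "s3"))
}

write_toy_csvs <- function(dir, drop_meta_for = NULL) {
  ftp <- file.path(dir, "features.csv")
  mdp <- file.path(dir, "metadata.csv")
  writeLines(c("feature_id,mz,rt,s1,s2,s3",
               "fA,150.1,1.5,1,3,5",
               "fB,300.2,6.2,2,4,6"), ftp)
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     source_group = c("greenhouse", "greenhouse",
                                      "consumer"),
                     species = "basil", replicate = 1,
                     is_blank = FALSE)
  if (!is.null(drop_meta_for))
    meta <- meta[meta$sample_id != drop_meta_for, ]
  write.csv(meta, mdp, row.names = FALSE, quote = FALSE)
  list(features = ftp, metadata = mdp)
}

# Random feature table with nb blanks appended; areas log-normal.
random_feature_table <- function(n = 10, p = 20, nb = 2, seed = 1,
                                 missing_rate = 0) {
  set.seed(seed)
  a <- matrix(rlnorm(n * p, 8, 1), n, p)
  if (missing_rate > 0) a[runif(n * p) < missing_rate] <- 0
  blanks <- matrix(0, nb, p)
  ids <- sprintf("f%03d", seq_len(p))
  feature_table(rbind(a, blanks), ids,
                mz = runif(p, 100, 900), rt = runif(p, 0.5, 12),
                sample_ids = c(sprintf("s%02d", seq_len(n)),
                               sprintf("bl%d", seq_len(nb))),
                blank_ids = sprintf("bl%d", seq_len(nb)))
}

viability_4pl <- function(dose, lower = 0, upper = 100, slope = 2,
                          inflection = 50) {
  ifelse(dose == 0, upper,
         lower + (upper - lower) / (1 + (dose / inflection)^slope))
}

# Tiny two-peak spectra for annotation tests.
spec_pair <- function() {
  list(query = spectrum2(200.05, c(100, 200), c(4, 1), "q1"),
       lib = spectrum2(200.05, c(100), c(1), "lib1"))
}
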