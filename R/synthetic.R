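#' Scenario specification for the synthetic extract-panel generator
#'
#' Defines the statistical structure of a simulated two-source extract
#' panel: log-normal background peak areas with per-feature-per-group
#' batch shifts and group-dependent missingness, blank injections, a small
#' set of "active" features whose raw area is calibrated to a target
#' Pearson correlation with per-sample log IC50, and "contaminant"
#' features as abundant in blanks as in samples (so the blank filter
#' should remove them).
#'
#' @param n_per_group named integer vector of non-blank samples per source
#'   group (default 24 greenhouse + 16 consumer).
#' @param n_features total features in the aligned table (default 1600).
#' @param n_blanks number of blank injections (default 3).
#' @param n_active_spikes number of bioactivity-linked features
#'   (default 4).
#' @param active_r target absolute Pearson correlation between each active
#'   feature's raw area and log IC50 (default 0.8; in-sample calibration
#'   is exact). Must be < 0.99.
#' @param active_sign correlation sign per active spike with log IC50;
#'   -1 = more area in more active (lower IC50) samples (default two of
#'   each sign).
#' @param n_contaminant_spikes blank-borne features (default 30).
#' @param p_core probability a background feature is a "core" metabolite
#'   present (rate `1 - core_missing`) in both groups; the rest are patchy,
#'   with presence probability below one half in a random group.
#' @param core_missing missingness rate of core features (default 0.05).
#' @param patchy_presence length-2 ranges for the patchy presence
#'   probabilities: `rare` in the sparse group, `other` elsewhere.
#' @param area_meanlog,area_sdlog log-normal peak-area parameters.
#' @param batch_sdlog sd of the per-feature-per-group multiplicative
#'   (log-scale) batch shift driving source-group separation.
#' @param ic50_range IC50 range in ug/ml; log IC50 is uniform over its log
#'   (default 57-117).
#' @param viability_noise_sd sd of plate viability noise in percentage
#'   points (default 2).
#' @param dose_grid assay dose grid in ug/ml.
#' @param plate_reps plates per sample (default 3).
#' @param seed integer RNG seed.
#' @return A `scenario_spec` list of the above.
#' @export
scenario_spec <- function(n_per_group = c(greenhouse = 24, consumer = 16),
                          n_features = 1600, n_blanks = 3,
                          n_active_spikes = 4, active_r = 0.8,
                          active_sign = NULL,
                          n_contaminant_spikes = 30,
                          p_core = 0.2, core_missing = 0.05,
                          patchy_presence = list(rare = c(0, 0.3),
                                                 other = c(0.2, 1)),
                          area_meanlog = 10, area_sdlog = 1.2,
                          batch_sdlog = 0.8,
                          ic50_range = c(57, 117),
                          viability_noise_sd = 2,
                          dose_grid = c(0, 25, 50, 100, 200),
                          plate_reps = 3, seed = 1) {
  if (is.null(active_sign))
    active_sign <- rep(c(-1, 1), length.out = n_active_spikes)
  if (abs(active_r) >= 0.99)
    stop("infeasible correlation target |r| >= 0.99", call. = FALSE)
  if (n_active_spikes + n_contaminant_spikes > n_features)
    stop("spike counts exceed n_features", call. = FALSE)
  if (core_missing < 0 || core_missing >= 1)
    stop("core_missing must be in [0, 1)", call. = FALSE)
  structure(list(n_per_group = n_per_group, n_features = n_features,
                 n_blanks = n_blanks, n_active_spikes = n_active_spikes,
                 active_r = active_r, active_sign = active_sign,
                 n_contaminant_spikes = n_contaminant_spikes,
                 p_core = p_core, core_missing = core_missing,
                 patchy_presence = patchy_presence,
                 area_meanlog = area_meanlog, area_sdlog = area_sdlog,
                 batch_sdlog = batch_sdlog, ic50_range = ic50_range,
                 viability_noise_sd = viability_noise_sd,
                 dose_grid = dose_grid, plate_reps = plate_reps,
                 seed = seed),
            class = "scenario_spec")
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

draw_ic50 <- function(spec) {
  with_seed(spec$seed, {
    groups <- rep(names(spec$n_per_group), spec$n_per_group)
    ids <- unlist(lapply(names(spec$n_per_group), function(g)
      sprintf("%s_%02d", substr(g, 1, 2), seq_len(spec$n_per_group[[g]]))))
    lic <- stats::runif(length(ids), log(spec$ic50_range[1]),
                        log(spec$ic50_range[2]))
    data.frame(sample_id = ids, source_group = groups,
               log_ic50 = lic, ic50 = exp(lic),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic extract-panel dataset
#'
#' @param spec a [scenario_spec()].
#' @return A list with `table` (a [feature_table()] including blanks),
#'   `metadata` (sample metadata data.frame), `bio` (per-sample IC50
#'   summary: sample_id, ic50, ic50_sd, log_ic50), and `truth`
#'   (`active_ids`, `active_sign`, `contaminant_ids`, `log_ic50`,
#'   `fourpl` parameters per sample).
#' @export
generate_dataset <- function(spec = scenario_spec()) {
  samp <- draw_ic50(spec)
  n <- nrow(samp)
  with_seed(spec$seed + 1L, {
    p <- spec$n_features
    blank_ids <- sprintf("blank_%d", seq_len(spec$n_blanks))
    feature_ids <- sprintf("F%04d", seq_len(p))
    mz <- stats::runif(p, 100, 1000)
    rt <- stats::runif(p, 0.5, 12)

    roles <- rep("background", p)
    special <- sample.int(p, spec$n_active_spikes +
                            spec$n_contaminant_spikes)
    active_idx <- special[seq_len(spec$n_active_spikes)]
    contam_idx <- setdiff(special, active_idx)
    roles[active_idx] <- "active"
    roles[contam_idx] <- "contaminant"

    areas <- matrix(0, n, p)
    blanks <- matrix(0, spec$n_blanks, p)
    grp <- samp$source_group
    group_names <- names(spec$n_per_group)

    bg <- which(roles == "background")
    mu_f <- stats::rnorm(p, spec$area_meanlog, 0.5)
    shift <- matrix(stats::rnorm(p * length(group_names), 0,
                                 spec$batch_sdlog),
                    p, length(group_names),
                    dimnames = list(NULL, group_names))
    is_core <- stats::runif(p) < spec$p_core
    rare_group <- sample(group_names, p, replace = TRUE)
    pres <- matrix(1 - spec$core_missing, p, length(group_names),
                   dimnames = list(NULL, group_names))
    for (g in group_names) {
      patchy <- !is_core
      rare <- patchy & rare_group == g
      oth <- patchy & rare_group != g
      pres[rare, g] <- stats::runif(sum(rare), spec$patchy_presence$rare[1],
                                    spec$patchy_presence$rare[2])
      pres[oth, g] <- stats::runif(sum(oth), spec$patchy_presence$other[1],
                                   spec$patchy_presence$other[2])
    }
    for (j in bg) {
      lo <- mu_f[j] + shift[j, grp] +
        stats::rnorm(n, 0, spec$area_sdlog)
      a <- exp(lo)
      a[stats::runif(n) >= pres[j, grp]] <- 0
      areas[, j] <- a
    }

    for (j in contam_idx) {
      lev <- mu_f[j]
      blanks[, j] <- exp(stats::rnorm(spec$n_blanks, lev, 0.3))
      areas[, j] <- exp(stats::rnorm(n, lev, 0.3))
    }

    for (k in seq_len(spec$n_active_spikes)) {
      j <- active_idx[k]
      sgn <- spec$active_sign[k]
      s <- drop(scale(sgn * samp$log_ic50))
      e <- stats::rnorm(n)
      e <- stats::residuals(stats::lm(e ~ s))
      e <- drop(scale(e))
      x <- spec$active_r * s + sqrt(1 - spec$active_r^2) * e
      base <- exp(mu_f[j])
      areas[, j] <- base * (x - min(x) + 0.5)
    }

    tab <- feature_table(rbind(areas, blanks), feature_ids, mz, rt,
                         c(samp$sample_id, blank_ids), blank_ids)
    species_pool <- c("O_basilicum", "O_tenuiflorum", "O_gratissimum")
    metadata <- data.frame(
      sample_id = c(samp$sample_id, blank_ids),
      source_group = c(grp, rep("blank", spec$n_blanks)),
      species = c(sample(species_pool, n, replace = TRUE),
                  rep("none", spec$n_blanks)),
      replicate = 1L,
      is_blank = c(rep(FALSE, n), rep(TRUE, spec$n_blanks)),
      stringsAsFactors = FALSE)
    bio <- data.frame(sample_id = samp$sample_id, ic50 = samp$ic50,
                      ic50_sd = 0, log_ic50 = samp$log_ic50,
                      stringsAsFactors = FALSE)
    truth <- list(active_ids = feature_ids[active_idx],
                  active_sign = stats::setNames(spec$active_sign,
                                                feature_ids[active_idx]),
                  contaminant_ids = feature_ids[contam_idx],
                  log_ic50 = stats::setNames(samp$log_ic50,
                                             samp$sample_id),
                  fourpl = data.frame(sample_id = samp$sample_id,
                                      lower = 0, upper = 100, slope = 2,
                                      inflection = samp$ic50,
                                      stringsAsFactors = FALSE))
    list(table = tab,
         metadata = metadata[!metadata$is_blank, , drop = FALSE],
         metadata_full = metadata, bio = bio, truth = truth)
  })
}

#' Generate synthetic viability plate data
#'
#' Per sample, evaluates a four-parameter logistic curve (lower 0, upper
#' 100, Hill slope 2, inflection = the sample's true IC50) on the assay
#' dose grid, replicated over plates, with Gaussian viability noise.
#' With the default `ic50 = NULL` the per-sample IC50s are the same ones
#' [generate_dataset()] draws for the same spec.
#'
#' @param spec a [scenario_spec()].
#' @param ic50 optional data.frame with `sample_id` and `ic50` overriding
#'   the scenario-derived values.
#' @return A data.frame of plate rows:
#'   `sample_id,dose_ug_ml,viability_pct,plate_rep`.
#' @export
generate_viability <- function(spec = scenario_spec(), ic50 = NULL) {
  if (is.null(ic50)) {
    samp <- draw_ic50(spec)
    ic50 <- data.frame(sample_id = samp$sample_id, ic50 = samp$ic50,
                       stringsAsFactors = FALSE)
  }
  with_seed(spec$seed + 2L, {
    rows <- expand.grid(plate_rep = seq_len(spec$plate_reps),
                        dose_ug_ml = spec$dose_grid,
                        sample_id = ic50$sample_id,
                        stringsAsFactors = FALSE)
    c50 <- ic50$ic50[match(rows$sample_id, ic50$sample_id)]
    v <- ifelse(rows$dose_ug_ml == 0, 100,
                100 / (1 + (rows$dose_ug_ml / c50)^2))
    rows$viability_pct <- v +
      stats::rnorm(nrow(rows), 0, spec$viability_noise_sd)
    rows[, c("sample_id", "dose_ug_ml", "viability_pct", "plate_rep")]
  })
}
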