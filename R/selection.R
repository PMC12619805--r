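#' Variable Importance in Projection (VIP) scores
#'
#' `VIP_j = sqrt( p * sum_a[ SSY_a * (w_ja / ||w_a||)^2 ] / sum_a SSY_a )`,
#' where `SSY_a = q_a^2 * t_a't_a` is the response variance explained by
#' component a. The scores are normalized so the mean squared VIP over
#' features equals 1; features above 1 contribute more than an average
#' feature to the explained response variance.
#'
#' @param model a fitted [pls_fit()] model.
#' @return Named numeric vector of per-feature VIP scores.
#' @export
vip_scores <- function(model) {
  W <- model$W; Tm <- model$T; q <- model$q
  p <- nrow(W)
  ssy <- q^2 * colSums(Tm^2)
  if (sum(ssy) == 0)
    stop("model explains no response variance; VIP undefined",
         call. = FALSE)
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  vip <- sqrt(p * drop(wn2 %*% ssy) / sum(ssy))
  names(vip) <- model$feature_ids
  vip
}

#' Selectivity Ratio (SR) via target projection
#'
#' Projects the training matrix onto the normalized PLS regression vector
#' (the target-projection component `t_TP = X b / ||b||`), computes
#' target-projection loadings `p_TP = X' t_TP / t_TP't_TP`, and for each
#' feature returns the ratio of variance explained by that rank-one
#' approximation to the residual variance:
#' `SR_j = ||t_TP p_TP_j||^2 / ||x_j - t_TP p_TP_j||^2`.
#'
#' @param model a fitted [pls_fit()] model.
#' @param X_scaled the matrix the model was fit on (default: the scaled
#'   training matrix stored in the model).
#' @param cap value reported for features with (numerically) zero residual
#'   variance, flagged as perfect fits (default 1e6).
#' @return A list with `sr` (named numeric vector) and `perfect` (logical
#'   vector marking capped features).
#' @export
selectivity_ratio <- function(model, X_scaled = model$X_scaled,
                              cap = 1e6) {
  b <- model$b
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("zero regression vector; SR undefined", call. = FALSE)
  X <- as.matrix(X_scaled)
  t_tp <- drop(X %*% b) / nb
  tt <- sum(t_tp^2)
  p_tp <- drop(crossprod(X, t_tp)) / tt
  v_exp <- tt * p_tp^2
  v_res <- colSums((X - tcrossprod(t_tp, p_tp))^2)
  total <- colSums(X^2)
  perfect <- v_res <= total * 1e-12
  sr <- ifelse(perfect, cap, v_exp / pmax(v_res, .Machine$double.xmin))
  names(sr) <- model$feature_ids
  list(sr = sr, perfect = perfect)
}

#' Direction of association with bioactivity
#'
#' Compares each candidate feature's raw peak area between the k most
#' active samples (lowest IC50) and the k least active (highest IC50).
#' A higher mean area in the most active samples reads as association with
#' increased activity (`positive_activity`); otherwise
#' `negative_activity`. Exact ties resolve to `negative_activity` with a
#' warning.
#'
#' @param candidate_ids feature ids to assign.
#' @param ft a [feature_table()] holding those features (raw areas).
#' @param bio data.frame with `sample_id` and `ic50` for the modeled
#'   samples.
#' @param k group size for the comparison (default 5); needs `2k` samples.
#' @return Named character vector of directions.
#' @export
assign_direction <- function(candidate_ids, ft, bio, k = 5) {
  bio <- bio[is.finite(bio$ic50), , drop = FALSE]
  n <- nrow(bio)
  if (k > n / 2)
    stop("k = ", k, " exceeds half of the ", n, " bioassayed samples",
         call. = FALSE)
  ord <- order(bio$ic50)
  most <- bio$sample_id[ord[seq_len(k)]]
  least <- bio$sample_id[ord[seq(n - k + 1, n)]]
  mi <- match(most, ft$sample_ids); li <- match(least, ft$sample_ids)
  if (anyNA(mi) || anyNA(li))
    stop("bioassay sample ids missing from feature table", call. = FALSE)
  out <- vapply(candidate_ids, function(id) {
    j <- match(id, ft$feature_ids)
    if (is.na(j)) stop("unknown feature id: ", id, call. = FALSE)
    d <- mean(ft$areas[mi, j]) - mean(ft$areas[li, j])
    if (d == 0) {
      warning("tied group means for feature '", id,
              "'; assigned negative_activity", call. = FALSE)
      "negative_activity"
    } else if (d > 0) "positive_activity" else "negative_activity"
  }, character(1))
  stats::setNames(out, candidate_ids)
}

#' Combine VIP and SR threshold passes into a candidate set
#'
#' @param vip named numeric vector of VIP scores.
#' @param sr named numeric vector of SR scores (same features).
#' @param vip_threshold,sr_threshold strict lower cuts.
#' @param mode `"union"` (either cut), `"intersection"` (both),
#'   `"sr_only"`, or `"vip_only"`.
#' @return A logical vector (named like `vip`) marking selected features.
#' @export
combine_selection <- function(vip, sr, vip_threshold = 1.0,
                              sr_threshold = 0.5,
                              mode = c("union", "intersection",
                                       "sr_only", "vip_only")) {
  mode <- match.arg(mode)
  if (length(vip) != length(sr))
    stop("vip and sr must score the same features", call. = FALSE)
  passes_vip <- vip > vip_threshold
  passes_sr <- sr > sr_threshold
  switch(mode,
         union = passes_vip | passes_sr,
         intersection = passes_vip & passes_sr,
         sr_only = passes_sr,
         vip_only = passes_vip)
}

#' Score features and select bioactivity candidates
#'
#' Computes VIP and SR on a fitted PLS model, applies the two thresholds,
#' and combines them: `union` (default, features passing either cut),
#' `intersection`, `sr_only`, or `vip_only`.
#'
#' @param model a fitted [pls_fit()] model.
#' @param vip_threshold VIP cut (default 1.0).
#' @param sr_threshold SR cut (default 0.5).
#' @param mode combination rule.
#' @return A `selection_scores` list: `scores` (data.frame with
#'   feature_id, vip, sr, passes_vip, passes_sr, selected),
#'   `selected_ids`, thresholds and mode.
#' @export
select_candidates <- function(model, vip_threshold = 1.0,
                              sr_threshold = 0.5,
                              mode = c("union", "intersection",
                                       "sr_only", "vip_only")) {
  mode <- match.arg(mode)
  vip <- vip_scores(model)
  srr <- selectivity_ratio(model)
  ids <- if (is.null(model$feature_ids))
    as.character(seq_along(vip)) else model$feature_ids
  passes_vip <- vip > vip_threshold
  passes_sr <- srr$sr > sr_threshold
  selected <- combine_selection(vip, srr$sr, vip_threshold,
                                sr_threshold, mode)
  scores <- data.frame(feature_id = ids, vip = unname(vip),
                       sr = unname(srr$sr),
                       sr_perfect = unname(srr$perfect),
                       passes_vip = unname(passes_vip),
                       passes_sr = unname(passes_sr),
                       selected = unname(selected),
                       stringsAsFactors = FALSE)
  structure(list(scores = scores, selected_ids = ids[selected],
                 vip_threshold = vip_threshold,
                 sr_threshold = sr_threshold, mode = mode),
            class = "selection_scores")
}
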