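#' Cohen's Kappa from confusion counts
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (TP + TN) / n` and expected agreement
#' `p_e = ((TP+FP)(TP+FN) + (FN+TN)(FP+TN)) / n^2`. When `p_e = 1` (all
#' calls and all labels in one class) Kappa is returned as 0 by convention.
#'
#' @param tp,fp,fn,tn Nonnegative confusion counts.
#' @return Kappa in \[-1, 1\].
#' @export
#' @examples
#' cohens_kappa(50, 0, 0, 50)   # perfect agreement: 1
#' cohens_kappa(25, 25, 25, 25) # chance agreement: 0
cohens_kappa <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || anyNA(counts)) {
    stopf("confusion counts must be nonnegative", class = "oefish_domain_error")
  }
  n <- sum(counts)
  if (n == 0) {
    stopf("total count must be positive", class = "oefish_domain_error")
  }
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (p_e >= 1) return(0)
  (p_o - p_e) / (1 - p_e)
}

#' Kappa-maximising presence threshold
#'
#' Evaluates Cohen's Kappa of presence calls (`call = prob >= t`, the
#' inclusive convention) against the observed labels at every threshold `t`
#' on the inclusive grid `{0, grid_step, ..., 1}` (201 values at the default
#' 0.005 step) and returns the threshold maximising Kappa. Ties are broken
#' toward the smallest threshold, which favours sensitivity and is
#' deterministic.
#'
#' @param labels 0/1 observed presence per site; both classes required.
#' @param probs Predicted capture probabilities in \[0, 1\].
#' @param grid_step Threshold grid step.
#' @return A tibble of class `oe_threshold` with one row: `threshold`,
#'   `kappa`, `grid_step`, `tp`, `fp`, `fn`, `tn`.
#' @export
select_threshold <- function(labels, probs, grid_step = 0.005) {
  if (length(labels) != length(probs)) {
    stopf("labels and probs must have equal length",
          class = "oefish_consistency_error")
  }
  if (length(unique(labels)) < 2) {
    stopf("threshold undefined: labels contain a single class",
          class = "oefish_data_error")
  }
  if (any(probs < 0 | probs > 1, na.rm = TRUE)) {
    stopf("probs must lie in [0, 1]", class = "oefish_domain_error")
  }
  grid <- seq(0, 1, by = grid_step)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  pos <- labels == 1
  best <- list(kappa = -Inf, t = NA_real_)
  stats <- vapply(grid, function(t) {
    call <- probs >= t
    tp <- sum(call & pos); fp <- sum(call & !pos)
    fn <- sum(!call & pos); tn <- sum(!call & !pos)
    c(tp, fp, fn, tn, cohens_kappa(tp, fp, fn, tn))
  }, numeric(5))
  i <- which.max(stats[5, ])   # first maximum = smallest threshold
  out <- tibble::tibble(
    threshold = grid[i], kappa = stats[5, i], grid_step = grid_step,
    tp = as.integer(stats[1, i]), fp = as.integer(stats[2, i]),
    fn = as.integer(stats[3, i]), tn = as.integer(stats[4, i])
  )
  class(out) <- c("oe_threshold", class(out))
  out
}

#' Fill a species model's threshold slot
#'
#' Runs the Kappa grid search on the model's training labels against its
#' fitted (in-sample) probabilities — the convention for O/E threshold
#' selection — or against out-of-fold probabilities when
#' `out_of_fold = TRUE`.
#'
#' @param bundle A fitted `oe_species_brt`.
#' @param data The training table used to fit the bundle.
#' @param grid_step Threshold grid step.
#' @param out_of_fold Use pooled out-of-fold predictions instead of
#'   in-sample predictions.
#' @return The bundle with `threshold` and `kappa_at_threshold` filled.
#' @export
select_threshold_for <- function(bundle, data, grid_step = 0.005,
                                 out_of_fold = FALSE) {
  probs <- if (out_of_fold) {
    bundle$oof_pred
  } else {
    x <- as.matrix(data[, bundle$feature_names, drop = FALSE])
    predict(bundle$booster, x)
  }
  res <- select_threshold(bundle$outcome, probs, grid_step)
  bundle$threshold <- res$threshold
  bundle$kappa_at_threshold <- res$kappa
  bundle$threshold_detail <- res
  bundle
}

#' Presence calls from probabilities
#'
#' A species is called present where its capture probability is greater
#' than or equal to the threshold (inclusive).
#'
#' @param probs Numeric probabilities.
#' @param threshold Threshold in \[0, 1\].
#' @return Integer 0/1 vector (NA where `probs` is NA).
#' @export
call_presence <- function(probs, threshold) {
  check_scalar_number(threshold, "threshold", 0, 1)
  as.integer(probs >= threshold)
}
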