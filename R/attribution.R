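#' Attribute O/E to anthropogenic pressures
#'
#' Models the per-reach O/E ratio as a function of pressure covariates
#' (downstream dams, nutrient concentrations, riparian/sediment condition,
#' predicted exotic presence, ...) with the same cross-validated boosted-tree
#' procedure as the occurrence models, but on squared-error loss since O/E
#' is continuous. Reaches with undefined O/E never enter the fit. The
#' cross-validated correlation is the Pearson r between pooled out-of-fold
#' predictions and the O/E values.
#'
#' @param oe An `oe_result` tibble from [compute_oe()].
#' @param pressures Reach table subset: `reach_id` plus numeric pressure
#'   columns.
#' @param config A [brt_config()].
#' @param min_reaches Minimum number of defined-O/E reaches required.
#' @return An object of class `oe_attribution`: `cv_correlation`,
#'   `relative_influence` (percent, sums to 100), `n_reaches_used`, the
#'   fitted booster and out-of-fold predictions.
#' @export
fit_attribution <- function(oe, pressures, config = brt_config(),
                            min_reaches = 50) {
  check_columns(oe, c("reach_id", "ratio"), "O/E table")
  check_columns(pressures, "reach_id", "pressure table")
  dat <- dplyr::inner_join(oe, pressures, by = "reach_id") |>
    dplyr::filter(!is.na(.data$ratio))
  if (nrow(dat) < min_reaches) {
    stopf("only %d reaches with defined O/E (need >= %d)", nrow(dat),
          min_reaches, class = "oefish_data_error")
  }
  if (sd(dat$ratio) == 0) {
    stopf("O/E is identical across reaches; attribution target is degenerate",
          class = "oefish_degenerate_error")
  }
  covs <- setdiff(names(pressures), "reach_id")
  covs <- covs[vapply(pressures[covs], is.numeric, TRUE)]
  if (!length(covs)) {
    stopf("pressure table has no numeric covariates",
          class = "oefish_schema_error")
  }
  x <- as.matrix(dat[, covs, drop = FALSE])
  y <- dat$ratio
  # a noise-dominated O/E target may never support min_trees boosting
  # rounds; the attribution model accepts the CV-optimal ensemble with a
  # warning rather than failing the whole pipeline
  fit <- brt_cv_engine(x, y, config, "regression", label = "attribution",
                       enforce_min_trees = FALSE)
  structure(
    list(cv_correlation = cor(fit$oof, y),
         relative_influence = relative_influence(fit$booster, covs),
         n_reaches_used = nrow(dat), booster = fit$booster,
         n_trees = fit$n_trees, learning_rate = fit$learning_rate,
         oof_pred = fit$oof, ratio = y, reach_id = dat$reach_id,
         config = config),
    class = "oe_attribution"
  )
}

#' Percent agreement between two prediction sets
#'
#' For each species, the percentage of reaches at which two presence/absence
#' prediction tables agree, plus the across-species mean (attached as the
#' `mean_agreement` attribute). Used to compare the pipeline's predicted
#' current distributions against an external model's predictions.
#'
#' @param set_a,set_b Wide 0/1 tibbles (`reach_id` + one column per
#'   species) over the same reaches and species.
#' @return A tibble `species`, `agreement_pct` with attribute
#'   `mean_agreement`.
#' @export
percent_agreement <- function(set_a, set_b) {
  check_columns(set_a, "reach_id", "set_a")
  check_columns(set_b, "reach_id", "set_b")
  sp <- setdiff(names(set_a), "reach_id")
  if (!setequal(sp, setdiff(names(set_b), "reach_id")) ||
      !identical(set_a$reach_id, set_b$reach_id)) {
    stopf("prediction sets must share reach index and species universe",
          class = "oefish_consistency_error")
  }
  out <- tibble::tibble(
    species = sp,
    agreement_pct = vapply(sp, function(s) {
      100 * mean(set_a[[s]] == set_b[[s]])
    }, numeric(1), USE.NAMES = FALSE)
  )
  attr(out, "mean_agreement") <- mean(out$agreement_pct)
  out
}

#' Ordinate species by their influential environmental variables
#'
#' Builds a species-by-covariate matrix keeping each species' `k_top`
#' largest relative influences (all others set to 0), computes Euclidean
#' distances between species, and embeds them in `dims` dimensions by
#' non-metric multidimensional scaling minimising Kruskal stress-1. The
#' best of `n_starts` seeded random starts is returned; coordinates are
#' identifiable only up to rotation/reflection/translation, so downstream
#' comparisons should be at the stress or distance level.
#'
#' @param bundles List of fitted `oe_species_brt` models (>= 3).
#' @param k_top Number of top influences kept per species.
#' @param dims Embedding dimension.
#' @param seed Integer seed.
#' @param n_starts Number of random starts.
#' @return An object of class `oe_ordination`: `coordinates` tibble
#'   (`species`, `NMDS1`, ...), `stress` (Kruskal stress-1, in \[0, 1\]),
#'   and the input influence matrix.
#' @export
nmds_influences <- function(bundles, k_top = 5, dims = 2, seed = 1,
                            n_starts = 20) {
  if (length(bundles) < 3) {
    stopf("need at least 3 species to ordinate", class = "oefish_data_error")
  }
  if (length(bundles) < dims + 1) {
    stopf("need more species than embedding dimensions",
          class = "oefish_dimension_error")
  }
  infl <- do.call(rbind, lapply(bundles, function(b) b$relative_influence))
  rownames(infl) <- vapply(bundles, function(b) b$species, character(1))
  top <- t(apply(infl, 1, function(v) {
    keep <- rank(-v, ties.method = "first") <= k_top
    ifelse(keep, v, 0)
  }))
  d <- stats::dist(top, method = "euclidean")
  best <- NULL
  with_seed(derive_seed(seed, "nmds"), {
    for (s in seq_len(n_starts)) {
      init <- matrix(rnorm(nrow(top) * dims), ncol = dims)
      fit <- vegan::monoMDS(d, y = init, k = dims, model = "global")
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
  })
  coords <- tibble::as_tibble(best$points, .name_repair = "minimal")
  names(coords) <- paste0("NMDS", seq_len(dims))
  coords <- dplyr::bind_cols(tibble::tibble(species = rownames(top)), coords)
  structure(list(coordinates = coords, stress = best$stress,
                 input_matrix = top, distances = d),
            class = "oe_ordination")
}
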