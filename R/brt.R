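#' Boosted regression tree configuration
#'
#' Hyperparameters of the per-species boosted-tree occurrence models. The
#' defaults are the standard regime for presence/absence distribution
#' modelling at national survey scale: tree complexity (interaction depth)
#' 5, a learning rate chosen so that at least 1,000 trees are assembled, a
#' bag fraction of 0.15 and 10-fold cross-validation. The learning rate
#' starts at `initial_learning_rate` and is halved (at most `max_halvings`
#' times) until the cross-validation-optimal tree count reaches `min_trees`.
#'
#' @param tree_complexity Per-tree interaction depth.
#' @param min_trees Minimum acceptable CV-optimal ensemble size.
#' @param initial_learning_rate Starting shrinkage, in (0, 1].
#' @param bag_fraction Per-tree row subsampling rate, in (0, 1].
#' @param n_folds Number of cross-validation folds.
#' @param max_halvings Bound on learning-rate halvings.
#' @param seed Integer seed controlling fold assignment and tree bagging.
#' @return A list of class `oe_brt_config`.
#' @export
brt_config <- function(tree_complexity = 5, min_trees = 1000,
                       initial_learning_rate = 0.01, bag_fraction = 0.15,
                       n_folds = 10, max_halvings = 6, seed = 1) {
  check_count(tree_complexity, "tree_complexity")
  check_count(min_trees, "min_trees")
  check_scalar_number(initial_learning_rate, "initial_learning_rate",
                      lower = 1e-8, upper = 1)
  check_scalar_number(bag_fraction, "bag_fraction", lower = 1e-8, upper = 1)
  check_count(n_folds, "n_folds")
  check_count(max_halvings, "max_halvings", positive = FALSE)
  structure(list(tree_complexity = as.integer(tree_complexity),
                 min_trees = as.integer(min_trees),
                 initial_learning_rate = initial_learning_rate,
                 bag_fraction = bag_fraction, n_folds = as.integer(n_folds),
                 max_halvings = as.integer(max_halvings),
                 seed = as.integer(seed)),
            class = "oe_brt_config")
}

# Stratified (binary) or plain random fold assignment.
assign_folds <- function(y, n_folds, seed, stratify) {
  n <- length(y)
  with_seed(seed, {
    fold <- integer(n)
    if (stratify) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
    } else {
      fold <- sample(rep_len(seq_len(n_folds), n))
    }
    fold
  })
}

# Core cross-validated stagewise boosting engine shared by the occurrence
# models (Bernoulli deviance) and the attribution model (squared error).
# Selects the ensemble size by n-fold cross-validated loss, halving the
# learning rate until the optimum is at least min_trees; returns the final
# full-data booster plus pooled out-of-fold predictions at the optimum.
brt_cv_engine <- function(x, y, config, objective = c("binary", "regression"),
                          label = "model", enforce_min_trees = TRUE) {
  objective <- match.arg(objective)
  obj <- if (objective == "binary") "binary:logistic" else "reg:squarederror"
  metric <- if (objective == "binary") "logloss" else "rmse"
  n <- nrow(x)
  seed0 <- derive_seed(config$seed, paste0("brt:", label))
  folds <- assign_folds(y, config$n_folds, seed0, objective == "binary")
  nr_max <- max(2L * config$min_trees, 200L)

  lr <- config$initial_learning_rate
  lr_path <- numeric(0)
  for (attempt in seq_len(config$max_halvings + 1L)) {
    lr_path <- c(lr_path, lr)
    loss <- matrix(NA_real_, nr_max, config$n_folds)
    wt <- numeric(config$n_folds)
    models <- vector("list", config$n_folds)
    for (k in seq_len(config$n_folds)) {
      tr <- folds != k
      dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr])
      dva <- xgboost::xgb.DMatrix(x[!tr, , drop = FALSE], label = y[!tr])
      params <- list(objective = obj, eta = lr,
                     max_depth = config$tree_complexity,
                     subsample = config$bag_fraction,
                     base_score = mean(y[tr]), nthread = 1,
                     eval_metric = metric,
                     seed = derive_seed(seed0, paste0("fold", k)))
      m <- xgboost::xgb.train(params = params, data = dtr, nrounds = nr_max,
                              evals = list(va = dva), verbose = 0)
      loss[, k] <- attributes(m)$evaluation_log[[paste0("va_", metric)]]
      wt[k] <- sum(!tr)
      models[[k]] <- m
    }
    cv_curve <- as.vector(loss %*% wt) / sum(wt)
    best <- which.min(cv_curve)
    if (best >= config$min_trees || attempt == config$max_halvings + 1L) {
      break
    }
    lr <- lr / 2
  }
  if (best < config$min_trees) {
    if (enforce_min_trees) {
      stopf("CV-optimal tree count %d < %d after %d learning-rate halvings (final rate %g)",
            best, config$min_trees, config$max_halvings, lr,
            class = "oefish_convergence_error")
    }
    warn(sprintf(
      "CV-optimal tree count %d < %d at learning rate %g; accepting the smaller ensemble (weak or noise-dominated signal)",
      best, config$min_trees, lr))
  }
  oof <- numeric(n)
  for (k in seq_len(config$n_folds)) {
    idx <- folds == k
    oof[idx] <- predict(models[[k]], x[idx, , drop = FALSE],
                        iterationrange = c(1L, best))
  }
  final <- xgboost::xgb.train(
    params = list(objective = obj, eta = lr,
                  max_depth = config$tree_complexity,
                  subsample = config$bag_fraction, base_score = mean(y),
                  nthread = 1, seed = derive_seed(seed0, "final")),
    data = xgboost::xgb.DMatrix(x, label = y), nrounds = best, verbose = 0
  )
  list(booster = final, n_trees = best, learning_rate = lr,
       lr_path = lr_path, folds = folds, oof = oof, cv_curve = cv_curve)
}

# Relative influence: each covariate's share of total loss reduction (gain)
# across all splits of the ensemble, normalised to 100. Computed from the
# tree dump directly. Unused covariates get 0.
relative_influence <- function(booster, feature_names) {
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  splits <- dump[dump$Feature != "Leaf", , drop = FALSE]
  out <- setNames(rep(0, length(feature_names)), feature_names)
  if (nrow(splits) == 0L) {
    warn("ensemble contains no splits; influence undefined, returning uniform")
    return(out + 100 / length(out))
  }
  gain <- tapply(splits$Gain, splits$Feature, sum)
  out[names(gain)] <- gain
  100 * out / sum(out)
}

#' Fit a boosted-tree occurrence model for one species
#'
#' Stagewise gradient boosting on Bernoulli deviance with interaction depth
#' `tree_complexity` and per-tree row subsampling `bag_fraction`. The
#' ensemble size is chosen by `n_folds`-fold cross-validated deviance; if the
#' optimum falls below `min_trees` the learning rate is halved and fitting
#' restarts. The reported AUC is computed from pooled out-of-fold
#' predictions (fold-averaged AUC is reported alongside).
#'
#' @param data One row per survey site: a 0/1 outcome column named by
#'   `species`, the covariate columns, and optionally `river_class` (used to
#'   record the classes the model may predict into).
#' @param species Name of the outcome column.
#' @param covariates Character vector of covariate column names; default all
#'   numeric columns except the outcome.
#' @param config A [brt_config()].
#' @param native Logical: is this a native species (member of the O/E set)?
#' @param retained_classes Optional character vector of river classes the
#'   model is allowed to predict into; defaults to the classes present in
#'   `data`, or no restriction if `data` has no `river_class` column.
#' @return An object of class `oe_species_brt`: the fitted ensemble, tree
#'   count, final learning rate, pooled and fold-averaged cross-validated
#'   AUC, relative influences (percent, summing to 100), out-of-fold
#'   predictions, and an empty threshold slot filled by
#'   [select_threshold_for()].
#' @export
fit_species_model <- function(data, species, covariates = NULL,
                              config = brt_config(), native = TRUE,
                              retained_classes = NULL) {
  check_columns(data, species, "training table")
  y <- data[[species]]
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stopf("outcome `%s` must be 0/1 with no missing values", species,
          class = "oefish_data_error")
  }
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stopf("species `%s` has fewer than 2 presences or 2 absences; unfittable",
          species, class = "oefish_unfittable_error")
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], species)
  }
  check_columns(data, covariates, "training table")
  x <- as.matrix(data[, covariates, drop = FALSE])
  if (is.null(retained_classes) && "river_class" %in% names(data)) {
    retained_classes <- sort(unique(data$river_class))
  }
  fit <- brt_cv_engine(x, y, config, "binary", label = species)
  fold_auc <- vapply(seq_len(config$n_folds), function(k) {
    idx <- fit$folds == k
    if (length(unique(y[idx])) < 2) NA_real_ else roc_auc(y[idx], fit$oof[idx])
  }, numeric(1))
  structure(
    list(species = species, booster = fit$booster,
         feature_names = covariates, n_trees = fit$n_trees,
         learning_rate = fit$learning_rate, lr_path = fit$lr_path,
         cv_auc = roc_auc(y, fit$oof),
         cv_auc_fold_mean = mean(fold_auc, na.rm = TRUE),
         relative_influence = relative_influence(fit$booster, covariates),
         oof_pred = fit$oof, outcome = y,
         prevalence = mean(y), native = native,
         retained_classes = retained_classes,
         threshold = NA_real_, kappa_at_threshold = NA_real_,
         config = config),
    class = "oe_species_brt"
  )
}

#' Predict capture probability over a reach table
#'
#' Deterministic inverse-logit ensemble prediction. Reaches outside the
#' model's retained river classes are not predicted: their probability is
#' `NA` with a reason code, to limit extrapolation beyond the environments
#' the model was trained in.
#'
#' @param bundle A fitted `oe_species_brt`.
#' @param reaches Reach table supplying every training covariate (and
#'   `river_class` if the model is class-restricted).
#' @return A tibble: `reach_id` (if present in `reaches`), `prob`,
#'   `masked_reason` (`NA` or `"out_of_class"`).
#' @export
predict_probability <- function(bundle, reaches) {
  if (!inherits(bundle, "oe_species_brt")) {
    stopf("`bundle` must be a fitted oe_species_brt",
          class = "oefish_config_error")
  }
  check_columns(reaches, bundle$feature_names, "reach table")
  x <- as.matrix(reaches[, bundle$feature_names, drop = FALSE])
  prob <- predict(bundle$booster, x)
  masked <- rep(NA_character_, nrow(reaches))
  if (!is.null(bundle$retained_classes) && "river_class" %in% names(reaches)) {
    out <- !reaches$river_class %in% bundle$retained_classes
    prob[out] <- NA_real_
    masked[out] <- "out_of_class"
  }
  tibble::tibble(
    reach_id = reaches$reach_id %||% seq_len(nrow(reaches)),
    prob = prob, masked_reason = masked
  )
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counted half.
#'
#' @param labels 0/1 outcome vector.
#' @param scores Numeric scores.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stopf("labels and scores must have equal length",
          class = "oefish_consistency_error")
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stopf("AUC undefined: both classes must be present",
          class = "oefish_data_error")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
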