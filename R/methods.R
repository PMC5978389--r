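#' @export
print.oe_species_brt <- function(x, ...) {
  cat(sprintf("<oe_species_brt> %s (%s)\n", x$species,
              if (isTRUE(x$native)) "native" else "exotic"))
  cat(sprintf("  trees: %d  learning rate: %g  CV AUC: %.3f\n",
              x$n_trees, x$learning_rate, x$cv_auc))
  if (!is.na(x$threshold)) {
    cat(sprintf("  threshold: %.3f  kappa: %.3f\n", x$threshold,
                x$kappa_at_threshold))
  }
  invisible(x)
}

#' Tidy a fitted species model: one row per covariate influence
#'
#' @param x A fitted `oe_species_brt`.
#' @param ... Unused.
#' @return A tibble `species`, `covariate`, `influence_pct`, sorted by
#'   decreasing influence.
#' @method tidy oe_species_brt
#' @export
tidy.oe_species_brt <- function(x, ...) {
  tibble::tibble(species = x$species,
                 covariate = names(x$relative_influence),
                 influence_pct = unname(x$relative_influence)) |>
    dplyr::arrange(dplyr::desc(.data$influence_pct))
}

#' One-row summary of a fitted species model
#'
#' @param x A fitted `oe_species_brt`.
#' @param ... Unused.
#' @method glance oe_species_brt
#' @export
glance.oe_species_brt <- function(x, ...) {
  tibble::tibble(species = x$species, native = isTRUE(x$native),
                 n_trees = x$n_trees, learning_rate = x$learning_rate,
                 cv_auc = x$cv_auc, cv_auc_fold_mean = x$cv_auc_fold_mean,
                 prevalence = x$prevalence, threshold = x$threshold,
                 kappa = x$kappa_at_threshold)
}

#' @export
print.oe_attribution <- function(x, ...) {
  cat(sprintf("<oe_attribution> %d reaches, CV correlation %.3f\n",
              x$n_reaches_used, x$cv_correlation))
  top <- sort(x$relative_influence, decreasing = TRUE)
  for (nm in names(head(top, 5))) {
    cat(sprintf("  %-18s %5.1f%%\n", nm, top[[nm]]))
  }
  invisible(x)
}

#' Tidy an attribution fit: one row per pressure influence
#' @param x An `oe_attribution`.
#' @param ... Unused.
#' @method tidy oe_attribution
#' @export
tidy.oe_attribution <- function(x, ...) {
  tibble::tibble(pressure = names(x$relative_influence),
                 influence_pct = unname(x$relative_influence)) |>
    dplyr::arrange(dplyr::desc(.data$influence_pct))
}

#' One-row summary of an attribution fit
#' @param x An `oe_attribution`.
#' @param ... Unused.
#' @method glance oe_attribution
#' @export
glance.oe_attribution <- function(x, ...) {
  tibble::tibble(cv_correlation = x$cv_correlation,
                 n_reaches_used = x$n_reaches_used, n_trees = x$n_trees,
                 learning_rate = x$learning_rate)
}

#' Tidy an ordination: species coordinates
#' @param x An `oe_ordination`.
#' @param ... Unused.
#' @method tidy oe_ordination
#' @export
tidy.oe_ordination <- function(x, ...) x$coordinates

#' One-row summary of an ordination
#' @param x An `oe_ordination`.
#' @param ... Unused.
#' @method glance oe_ordination
#' @export
glance.oe_ordination <- function(x, ...) {
  tibble::tibble(stress = x$stress, n_species = nrow(x$coordinates))
}

#' Histogram of per-reach O/E ratios
#'
#' @param object An `oe_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oe_result
#' @export
autoplot.oe_result <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$ratio))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "steelblue", colour = "grey30") +
    ggplot2::labs(x = "O/E ratio", y = "Reaches",
                  title = "Observed/expected fish assemblage ratio") +
    ggplot2::theme_minimal()
}

#' Bar chart of attribution influences
#'
#' @param object An `oe_attribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oe_attribution
#' @export
autoplot.oe_attribution <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$pressure, .data$influence_pct),
    y = .data$influence_pct)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Relative influence (%)",
                  title = sprintf("Pressures on O/E (CV r = %.2f)",
                                  object$cv_correlation)) +
    ggplot2::theme_minimal()
}

#' Scatter of the species ordination
#'
#' @param object An `oe_ordination`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oe_ordination
#' @export
autoplot.oe_ordination <- function(object, ...) {
  ggplot2::ggplot(object$coordinates,
                  ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2,
                               label = .data$species)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_text(vjust = -0.7, size = 3) +
    ggplot2::labs(title = sprintf("Species by influential variables (stress %.3f)",
                                  object$stress)) +
    ggplot2::theme_minimal()
}
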