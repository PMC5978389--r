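#' Declare a covariate scenario
#'
#' A scenario is a declarative set of covariate edits defining a
#' counterfactual state of the river network, typically the reference
#' condition against which O/E is computed. Three kinds of edit are
#' supported, applied column-wise:
#'
#' * `set_to` — overwrite a covariate with a constant (e.g. upstream native
#'   cover to 1, pasture to 0, riparian native percent to 100);
#' * `cap_at` — reduce a covariate to a ceiling *only where it exceeds it*
#'   (e.g. nutrient concentrations capped at the upper bound of high
#'   ecological health);
#' * `substitute_from` — replace a covariate with a companion column carrying
#'   its counterfactual value (e.g. riparian shade replaced by the estimated
#'   pre-human shade).
#'
#' @param set_to Named list/vector: covariate -> constant.
#' @param cap_at Named list/vector: covariate -> ceiling.
#' @param substitute_from Named character: covariate -> companion column name.
#' @return An object of class `oe_scenario`.
#' @seealso [default_reference_scenario()], [apply_reference_transform()]
#' @export
scenario_spec <- function(set_to = list(), cap_at = list(),
                          substitute_from = character()) {
  set_to <- as.list(set_to); cap_at <- as.list(cap_at)
  substitute_from <- unlist(substitute_from) %||% character()
  keys <- c(names(set_to), names(cap_at), names(substitute_from))
  if (anyDuplicated(keys)) {
    stopf("scenario keys must be disjoint across set_to / cap_at / substitute_from (duplicated: %s)",
          paste(unique(keys[duplicated(keys)]), collapse = ", "),
          class = "oefish_config_error")
  }
  bad <- c(names(which(!vapply(set_to, is.numeric, TRUE))),
           names(which(!vapply(cap_at, is.numeric, TRUE))))
  if (length(bad)) {
    stopf("scenario values must be numeric (offending: %s)",
          paste(bad, collapse = ", "), class = "oefish_config_error")
  }
  structure(list(set_to = set_to, cap_at = cap_at,
                 substitute_from = substitute_from),
            class = "oe_scenario")
}

#' The default reference-condition scenario
#'
#' Full native upstream and riparian cover, no pasture, pre-human riparian
#' shade, and nutrient concentrations capped (where exceeded) at 0.11 mg/L
#' nitrate-nitrogen and 0.006 mg/L dissolved reactive phosphorus — the upper
#' range of nutrient enrichment consistent with high ecological health.
#' All values are configuration, overridable via [scenario_spec()].
#'
#' @return An `oe_scenario` object.
#' @export
#' @examples
#' reach <- tibble::tibble(reach_id = "R1", us_native = 0.4, us_pasture = 0.5,
#'                         rip_native_pct = 30, rip_shade = 0.2,
#'                         rip_shade_ref = 0.7, no3n = 0.25, drp = 0.01)
#' apply_reference_transform(reach, default_reference_scenario())
default_reference_scenario <- function() {
  scenario_spec(
    set_to = list(us_native = 1, us_pasture = 0, rip_native_pct = 100),
    cap_at = list(no3n = 0.11, drp = 0.006),
    substitute_from = c(rip_shade = "rip_shade_ref")
  )
}

#' Read a scenario from a YAML file
#'
#' Expects top-level keys `set_to`, `cap_at`, `substitute_from`, each a
#' mapping of covariate name to value/column.
#'
#' @param path Path to a YAML scenario file.
#' @return An `oe_scenario` object.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  scenario_spec(set_to = y$set_to %||% list(),
                cap_at = y$cap_at %||% list(),
                substitute_from = unlist(y$substitute_from) %||% character())
}

#' Apply a reference-condition scenario to a reach table
#'
#' Returns a new reach table in which `set_to` columns are overwritten with
#' their constants, `cap_at` columns are replaced by `min(current, ceiling)`
#' (values at or below the ceiling untouched), and `substitute_from` columns
#' are replaced by their companion columns. All other columns are returned
#' unchanged; the input is never mutated. The transform is idempotent.
#'
#' @param reaches A reach table (data frame, one row per reach).
#' @param spec An [scenario_spec()]; defaults to the reference condition.
#' @return A tibble of the same shape as `reaches`.
#' @export
apply_reference_transform <- function(reaches,
                                      spec = default_reference_scenario()) {
  if (!inherits(spec, "oe_scenario")) {
    stopf("`spec` must be created by scenario_spec()",
          class = "oefish_config_error")
  }
  targets <- c(names(spec$set_to), names(spec$cap_at),
               names(spec$substitute_from))
  check_columns(reaches, targets, "reach table")
  check_columns(reaches, unname(spec$substitute_from), "reach table")
  out <- tibble::as_tibble(reaches)
  for (nm in targets) {
    if (!is.numeric(out[[nm]])) {
      bad <- which(!is.na(out[[nm]]))[1] %||% 1L
      stopf("column `%s` must be numeric to be transformed (see row %d)",
            nm, bad, class = "oefish_data_error")
    }
  }
  for (nm in names(spec$set_to)) out[[nm]] <- spec$set_to[[nm]] + 0 * out[[nm]]
  for (nm in names(spec$cap_at)) out[[nm]] <- pmin(out[[nm]], spec$cap_at[[nm]])
  for (nm in names(spec$substitute_from)) {
    out[[nm]] <- reaches[[spec$substitute_from[[nm]]]]
  }
  out
}

#' Predict per-reach species assemblages
#'
#' Converts each fitted species model's capture probabilities into presence
#' calls at that species' threshold (call = probability >= threshold) and
#' assembles them into wide 0/1 tables, native and exotic species separately.
#' Reaches outside the model's retained river classes get `NA` calls.
#'
#' @param bundles A list of fitted `oe_species_brt` models (see
#'   [fit_species_model()]); every bundle must carry a threshold.
#' @param reaches A reach table supplying every covariate the models use.
#' @return A list with tibbles `native` and `exotic` (columns: `reach_id`
#'   then one 0/1 column per species) and `masked`, a logical vector marking
#'   out-of-class reaches.
#' @export
predict_assemblage <- function(bundles, reaches) {
  if (!length(bundles)) {
    stopf("`bundles` is empty", class = "oefish_config_error")
  }
  calls <- list()
  masked <- rep(FALSE, nrow(reaches))
  for (b in bundles) {
    if (!inherits(b, "oe_species_brt")) {
      stopf("all bundles must be oe_species_brt objects",
            class = "oefish_config_error")
    }
    if (is.null(b$threshold) || is.na(b$threshold)) {
      stopf("bundle for species `%s` has no threshold; run select_threshold() first",
            b$species, class = "oefish_config_error")
    }
    pr <- predict_probability(b, reaches)
    masked <- masked | !is.na(pr$masked_reason)
    calls[[b$species]] <- call_presence(pr$prob, b$threshold)
  }
  natives <- vapply(bundles, function(b) isTRUE(b$native), TRUE)
  wide <- tibble::as_tibble(calls)
  wide$reach_id <- reaches$reach_id
  nat_cols <- names(calls)[natives]
  exo_cols <- names(calls)[!natives]
  list(
    native = wide[, c("reach_id", nat_cols), drop = FALSE],
    exotic = wide[, c("reach_id", exo_cols), drop = FALSE],
    masked = masked
  )
}

#' Per-reach observed/expected ratio
#'
#' Implements the three O/E counting steps: E is the set of native species
#' predicted to occur under reference conditions; O is the set predicted
#' present under current conditions *and* expected under reference
#' (current-only species never count toward O, which guarantees O is a
#' subset of E and the ratio lies in \[0, 1\]); the ratio is |O|/|E|, and is
#' flagged undefined where E is empty. High ratios mean the present-day
#' assemblage resembles the reference assemblage.
#'
#' @param current_sets Wide 0/1 tibble of native species calls under current
#'   conditions (`reach_id` + one column per species).
#' @param reference_sets Same shape, under the reference scenario.
#' @param exotic Character vector of exotic species ids; their presence in
#'   either table is a contract violation.
#' @return A tibble of class `oe_result`: `reach_id`, `e_count`, `o_count`,
#'   `ratio` (NA where undefined) and `flag` (`"ok"` or `"E0"`). Reaches with
#'   `NA` calls (masked out-of-class) get flag `"masked"`.
#' @export
compute_oe <- function(current_sets, reference_sets, exotic = character()) {
  check_columns(current_sets, "reach_id", "current_sets")
  check_columns(reference_sets, "reach_id", "reference_sets")
  sp_cur <- setdiff(names(current_sets), "reach_id")
  sp_ref <- setdiff(names(reference_sets), "reach_id")
  if (!setequal(sp_cur, sp_ref)) {
    stopf("current and reference tables must cover the same species",
          class = "oefish_consistency_error")
  }
  if (!identical(current_sets$reach_id, reference_sets$reach_id)) {
    stopf("current and reference tables must share the same reach index",
          class = "oefish_consistency_error")
  }
  bad <- intersect(sp_cur, exotic)
  if (length(bad)) {
    stopf("exotic species must not enter the O/E computation: %s",
          paste(bad, collapse = ", "), class = "oefish_contract_error")
  }
  cur <- as.matrix(current_sets[, sp_ref, drop = FALSE])
  ref <- as.matrix(reference_sets[, sp_ref, drop = FALSE])
  e <- rowSums(ref)
  o <- rowSums(ref * cur)
  masked <- is.na(e) | is.na(o)
  ratio <- ifelse(!masked & e > 0, o / e, NA_real_)
  out <- tibble::tibble(
    reach_id = current_sets$reach_id,
    e_count = ifelse(masked, NA_integer_, as.integer(e)),
    o_count = ifelse(masked, NA_integer_, as.integer(o)),
    ratio = ratio,
    flag = dplyr::case_when(masked ~ "masked", e == 0 ~ "E0", TRUE ~ "ok")
  )
  class(out) <- c("oe_result", class(out))
  out
}
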