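#' Pipeline run configuration
#'
#' Aggregates every stage's parameters with defaults matching the standard
#' regime: survey filters (year >= 2000, December-March, electric fishing,
#' >= 150 m reach, one record per site), prevalence rule (species at >= 150
#' sites), river-class rule (classes with >= 1,000 survey sites), the BRT
#' hyperparameters, the Kappa grid step (0.005) and the reference scenario.
#'
#' @param brt A [brt_config()].
#' @param scenario An [scenario_spec()]; defaults to the reference condition.
#' @param min_year,months,min_length_m Survey record filters.
#' @param min_species_sites Prevalence rule threshold.
#' @param min_class_sites River-class rule threshold.
#' @param kappa_step Threshold grid step.
#' @param seed Global seed, fanned out to per-stage seeds by stable hashing.
#' @param out_dir Optional output directory for CSV/JSON artefacts.
#' @return A list of class `oe_run_config`.
#' @export
run_config <- function(brt = brt_config(), scenario = default_reference_scenario(),
                       min_year = 2000, months = c(12L, 1L, 2L, 3L),
                       min_length_m = 150, min_species_sites = 150,
                       min_class_sites = 1000, kappa_step = 0.005,
                       seed = 42, out_dir = NULL) {
  structure(list(brt = brt, scenario = scenario, min_year = min_year,
                 months = months, min_length_m = min_length_m,
                 min_species_sites = min_species_sites,
                 min_class_sites = min_class_sites, kappa_step = kappa_step,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "oe_run_config")
}

#' Run the full O/E pipeline
#'
#' Executes ingest -> class restriction -> prevalence -> per-species BRT
#' fits -> Kappa thresholds -> current and reference assemblage prediction
#' -> per-reach O/E -> pressure attribution -> influence ordination, and
#' returns every intermediate product plus a provenance manifest. The whole
#' run is deterministic given the configuration.
#'
#' @param reaches Reach table (tibble or CSV/TSV path).
#' @param surveys Survey table (tibble or CSV/TSV path).
#' @param config An [run_config()].
#' @param covariates Covariate columns used by the occurrence models;
#'   default: all numeric reach columns except `reach_id` and the
#'   reference-companion columns named by the scenario's `substitute_from`.
#' @param native_species Optional character vector naming which species
#'   columns are native (members of the O/E set); by default, species ids
#'   starting with `"exo"` are treated as exotic, all others as native.
#' @return A list of class `oe_run`: filtered surveys, reports, fitted
#'   `bundles`, assemblage tables, `oe` results, `attribution`, `ordination`
#'   and `manifest`.
#' @export
run_pipeline <- function(reaches, surveys, config = run_config(),
                         covariates = NULL, native_species = NULL) {
  if (is.character(reaches)) reaches <- read_table_auto(reaches)
  if (is.character(surveys)) surveys <- read_table_auto(surveys)
  check_columns(reaches, c("reach_id", "river_class"), "reach table")

  # stage 1: record filters + site dedup
  flt <- filter_surveys(surveys, seed = derive_seed(config$seed, "dedup"),
                        min_year = config$min_year, months = config$months,
                        min_length_m = config$min_length_m)
  analysis <- flt$surveys

  # stage 2: river-class rule; restrict records and prediction domain
  cls <- class_filter(analysis, reaches, min_sites = config$min_class_sites)
  reach_class <- reaches$river_class[match(analysis$reach_id, reaches$reach_id)]
  analysis <- analysis[reach_class %in% cls$classes, , drop = FALSE]
  predict_reaches <- reaches[reaches$river_class %in% cls$classes, ,
                             drop = FALSE]

  # stage 3: prevalence rule on the analysis set
  prev <- prevalence_filter(analysis, min_sites = config$min_species_sites)
  species <- prev$species
  if (!length(species)) {
    stopf("no species pass the prevalence rule", class = "oefish_data_error")
  }
  if (is.null(native_species)) {
    native_species <- species[!startsWith(species, "exo")]
  }

  if (is.null(covariates)) {
    companions <- unname(config$scenario$substitute_from)
    covariates <- setdiff(
      names(reaches)[vapply(reaches, is.numeric, TRUE)],
      c("reach_id", companions)
    )
  }

  # stage 4: per-species BRT fits + thresholds
  train <- dplyr::inner_join(analysis[, c("site_id", "reach_id", species)],
                             reaches, by = "reach_id")
  bundles <- list()
  unfittable <- character(0)
  for (sp in species) {
    b <- tryCatch(
      fit_species_model(train, sp, covariates = covariates,
                        config = config$brt,
                        native = sp %in% native_species,
                        retained_classes = cls$classes),
      oefish_unfittable_error = function(e) NULL
    )
    if (is.null(b)) {
      unfittable <- c(unfittable, sp)
    } else {
      bundles[[sp]] <- select_threshold_for(b, train,
                                            grid_step = config$kappa_step)
    }
  }
  if (!length(bundles)) {
    stopf("no species could be fitted", class = "oefish_data_error")
  }

  # stage 5: scenario predictions and O/E
  ref_reaches <- apply_reference_transform(predict_reaches, config$scenario)
  current <- predict_assemblage(bundles, predict_reaches)
  reference <- predict_assemblage(bundles, ref_reaches)
  exotics <- names(bundles)[!vapply(bundles, function(b) b$native, TRUE)]
  oe <- compute_oe(current$native, reference$native, exotic = exotics)

  # stage 6: attribution to pressures (dams, nutrients, exotic presence)
  pressure_cols <- intersect(c("ds_dam", "no3n", "drp"),
                             names(predict_reaches))
  pressures <- predict_reaches[, c("reach_id", pressure_cols), drop = FALSE]
  if (ncol(current$exotic) > 1) {
    pressures <- dplyr::left_join(pressures, current$exotic, by = "reach_id")
  }
  attribution <- tryCatch(
    fit_attribution(oe, pressures, config = config$brt),
    oefish_data_error = function(e) NULL,
    oefish_degenerate_error = function(e) NULL
  )

  # stage 7: ordination of species by influential variables
  native_bundles <- bundles[vapply(bundles, function(b) b$native, TRUE)]
  ordination <- if (length(native_bundles) >= 3) {
    nmds_influences(native_bundles, seed = derive_seed(config$seed, "nmds"))
  }

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  manifest <- list(
    seed = config$seed,
    config_hash = str_hash32(paste(deparse(unclass(cfg_for_hash)),
                                   collapse = "")),
    stage_counts = list(
      input_records = nrow(surveys),
      retained_sites = nrow(flt$surveys),
      sites_in_retained_classes = nrow(analysis),
      retained_classes = cls$classes,
      retained_species = names(bundles),
      unfittable_species = unfittable,
      predicted_reaches = nrow(predict_reaches),
      oe_defined = sum(!is.na(oe$ratio))
    ),
    models = lapply(bundles, function(b) {
      list(species = b$species, n_trees = b$n_trees,
           learning_rate = b$learning_rate, cv_auc = b$cv_auc,
           threshold = b$threshold, kappa = b$kappa_at_threshold)
    }),
    attribution = if (!is.null(attribution)) {
      list(cv_correlation = attribution$cv_correlation,
           n_reaches_used = attribution$n_reaches_used)
    }
  )

  out <- structure(
    list(surveys = analysis, filter_report = flt$report,
         class_report = cls$report, prevalence_report = prev$report,
         bundles = bundles, current = current, reference = reference,
         oe = oe, attribution = attribution, ordination = ordination,
         reaches = predict_reaches, config = config, manifest = manifest),
    class = "oe_run"
  )
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

#' Write pipeline outputs to disk
#'
#' Emits the O/E table, per-species thresholds and influences as CSV, and
#' the manifest plus attribution summary as JSON, under `dir`.
#'
#' @param run An `oe_run` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$oe, file.path(dir, "oe.csv"), row.names = FALSE)
  thr <- purrr::map_dfr(run$bundles, function(b) {
    tibble::tibble(species = b$species, native = b$native,
                   cv_auc = b$cv_auc, n_trees = b$n_trees,
                   learning_rate = b$learning_rate,
                   threshold = b$threshold, kappa = b$kappa_at_threshold)
  })
  utils::write.csv(thr, file.path(dir, "models.csv"), row.names = FALSE)
  infl <- purrr::map_dfr(run$bundles, function(b) {
    tibble::tibble(species = b$species,
                   covariate = names(b$relative_influence),
                   influence_pct = unname(b$relative_influence))
  })
  utils::write.csv(infl, file.path(dir, "influences.csv"), row.names = FALSE)
  sp <- setdiff(names(run$reference$native), "reach_id")
  long <- run$reference$native |>
    tidyr::pivot_longer(dplyr::all_of(sp), names_to = "species",
                        values_to = "expected") |>
    dplyr::left_join(
      tidyr::pivot_longer(run$current$native, dplyr::all_of(sp),
                          names_to = "species", values_to = "current"),
      by = c("reach_id", "species")) |>
    dplyr::mutate(observed = as.integer(.data$expected == 1 &
                                          .data$current == 1))
  utils::write.csv(long, file.path(dir, "oe_species.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list.files(dir, full.names = TRUE))
}

#' Demo run on a synthetic river network
#'
#' Generates the fixed desk-scale demonstration world (2,000 reaches, 1,500
#' survey sites, 8 native and 2 exotic species, two river classes) and runs
#' the full pipeline on it. The river-class rule is desk-scaled to 300
#' sites per class (the package default of 1,000 matches national survey
#' volumes, not a 1,500-site simulation). Returns the run plus the
#' generating truth so recovery can be assessed.
#'
#' @param seed Global seed (default 42).
#' @param n_reaches,n_sites,n_species Generator dimensions.
#' @param impact_strength Anthropogenic suppression multiplier.
#' @param brt Optional [brt_config()] override (seeded from `seed` by
#'   default).
#' @param min_species_sites,min_class_sites Filter thresholds; the defaults
#'   are the demonstration-scale values (smaller worlds need smaller
#'   thresholds).
#' @param out_dir Optional output directory.
#' @return A list: `run` (`oe_run`), `truth` (`oe_truth`), `cfg`
#'   (the generator configuration), `reaches`, `surveys`.
#' @export
oe_demo <- function(seed = 42, n_reaches = 2000, n_sites = 1500,
                    n_species = 8, impact_strength = 1, brt = NULL,
                    min_species_sites = 150, min_class_sites = 300,
                    out_dir = NULL) {
  cfg <- synthetic_config(n_reaches = n_reaches, n_sites = n_sites,
                          n_species = n_species,
                          impact_strength = impact_strength, seed = seed)
  reaches <- generate_reaches(cfg)
  truth <- generate_truth(reaches, cfg)
  surveys <- generate_surveys(reaches, truth, cfg)
  rc <- run_config(
    brt = brt %||% brt_config(seed = derive_seed(seed, "brt")),
    min_species_sites = min_species_sites,
    min_class_sites = min_class_sites, seed = seed, out_dir = out_dir
  )
  run <- run_pipeline(reaches, surveys, config = rc)
  list(run = run, truth = truth, cfg = cfg, reaches = reaches,
       surveys = surveys)
}
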