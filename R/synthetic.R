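#' Configuration for the synthetic river-network generator
#'
#' Bundles the knobs of the synthetic data generator: how many reaches and
#' survey sites to simulate, how many native and exotic species, how strongly
#' anthropogenic pressure suppresses native occurrence, and the detection
#' probability of a single electric-fishing pass.
#'
#' The generator emulates the statistical structure of a national river
#' survey compilation: correlated geographic/climatic covariates along a
#' lowland-upland gradient, an anthropogenic gradient (pasture cover,
#' nutrients, riparian loss, downstream dams) riding on it, and species whose
#' occurrence probabilities are smooth nonlinear functions of a handful of
#' covariates. Reaches are exchangeable rows; no network topology is
#' simulated.
#'
#' @param n_reaches Number of river reaches to generate.
#' @param n_sites Number of distinct survey sites (must be <= `n_reaches`;
#'   each site sits on its own reach).
#' @param n_species Number of native species with ground-truth response
#'   functions. Native responses are monotonically non-increasing in every
#'   anthropogenic covariate and non-decreasing in native-cover covariates.
#' @param n_exotic Number of exotic species (disturbance-favouring responses;
#'   excluded from the O/E index, used only as attribution pressures).
#' @param n_covariates Number of inert nuisance covariates appended to the
#'   core environmental suite (standard normal, independent of everything).
#' @param impact_strength Nonnegative multiplier on all anthropogenic
#'   coefficients in the species truth. `0` yields a world in which reference
#'   and current occurrence probabilities coincide, so true O/E = 1 wherever
#'   E > 0 (calibration preset).
#' @param detection_prob Probability, in (0, 1], that a truly present species
#'   is detected by one survey record.
#' @param violation_rate Fraction of survey records, per filter rule, that
#'   deliberately violate it (pre-2000 year, off-season month, non-electric
#'   method, short reach) so the filtering stage has work to do.
#' @param duplicate_rate Fraction of sites receiving a second survey record.
#' @param class_labels Named numeric vector of river-class mixing
#'   proportions; must sum to 1.
#' @param seed Integer RNG seed; all outputs are deterministic given the
#'   full configuration.
#'
#' @return A list of class `oe_synth_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_reaches = 200, n_sites = 150, n_species = 4,
#'                         seed = 1)
#' reaches <- generate_reaches(cfg)
synthetic_config <- function(n_reaches = 2000,
                             n_sites = 1500,
                             n_species = 8,
                             n_exotic = 2,
                             n_covariates = 3,
                             impact_strength = 1,
                             detection_prob = 1,
                             violation_rate = 0.05,
                             duplicate_rate = 0.1,
                             class_labels = c(A = 0.7, C = 0.3),
                             seed = 1) {
  check_count(n_reaches, "n_reaches")
  check_count(n_sites, "n_sites")
  check_count(n_species, "n_species")
  check_count(n_exotic, "n_exotic", positive = FALSE)
  check_count(n_covariates, "n_covariates", positive = FALSE)
  check_scalar_number(impact_strength, "impact_strength", lower = 0)
  check_scalar_number(detection_prob, "detection_prob", upper = 1)
  if (detection_prob <= 0) {
    stopf("`detection_prob` must be in (0, 1]", class = "oefish_config_error")
  }
  check_scalar_number(violation_rate, "violation_rate", 0, 0.5)
  check_scalar_number(duplicate_rate, "duplicate_rate", 0, 1)
  if (n_sites > n_reaches) {
    stopf("`n_sites` (%d) must not exceed `n_reaches` (%d)",
          n_sites, n_reaches, class = "oefish_config_error")
  }
  if (is.null(names(class_labels)) || any(!nzchar(names(class_labels)))) {
    stopf("`class_labels` must be a named vector of proportions",
          class = "oefish_config_error")
  }
  if (any(class_labels < 0) || abs(sum(class_labels) - 1) > 1e-9) {
    stopf("`class_labels` proportions must be nonnegative and sum to 1",
          class = "oefish_config_error")
  }
  structure(
    list(n_reaches = as.integer(n_reaches), n_sites = as.integer(n_sites),
         n_species = as.integer(n_species), n_exotic = as.integer(n_exotic),
         n_covariates = as.integer(n_covariates),
         impact_strength = impact_strength, detection_prob = detection_prob,
         violation_rate = violation_rate, duplicate_rate = duplicate_rate,
         class_labels = class_labels, seed = as.integer(seed)),
    class = "oe_synth_config"
  )
}

#' Generate a synthetic reach table
#'
#' One row per river reach, with the core environmental covariate suite used
#' by the distribution models: upstream native and pasture proportions
#' (negatively correlated), riparian native cover and shade with a pre-human
#' shade companion column, nitrate-nitrogen and dissolved reactive phosphorus
#' (both positively correlated with pasture), a downstream-dam indicator,
#' segment slope, summer air temperature, flood frequency and distance to
#' coast, plus a river-class label and any nuisance covariates.
#'
#' @param cfg An [synthetic_config()] object.
#' @return A tibble with one row per reach.
#' @export
generate_reaches <- function(cfg) {
  if (!inherits(cfg, "oe_synth_config")) {
    stopf("`cfg` must be created by synthetic_config()",
          class = "oefish_config_error")
  }
  n <- cfg$n_reaches
  with_seed(derive_seed(cfg$seed, "reaches"), {
    # lowland-ness gradient g: high = warm, flat, coastal, developable
    g <- rnorm(n)
    dev_noise <- rnorm(n)
    dev <- plogis(0.8 * g + 0.9 * dev_noise)   # development pressure in (0,1)

    us_pasture <- pmin(1, pmax(0, dev + rnorm(n, 0, 0.08)))
    us_native <- pmax(0, pmin(1, 1 - us_pasture - runif(n, 0, 0.15)))
    rip_native_pct <- 100 * pmin(1, pmax(0, us_native + rnorm(n, 0, 0.1)))
    rip_shade_ref <- runif(n, 0.35, 0.8)       # shade under complete vegetation
    rip_shade <- rip_shade_ref * (0.2 + 0.8 * rip_native_pct / 100)

    no3n <- (0.05 + 0.55 * us_pasture) * exp(rnorm(n, 0, 0.35))
    drp <- (0.003 + 0.02 * us_pasture) * exp(rnorm(n, 0, 0.35))
    ds_dam <- rbinom(n, 1, 0.08 + 0.25 * dev)

    jan_air_temp <- pmin(19.8, pmax(5, 15.5 + 2 * g + rnorm(n, 0, 1)))
    seg_slope <- pmin(30, exp(0.5 - 1.0 * g + rnorm(n, 0, 0.7)))
    flood_freq <- exp(rnorm(n, 2.6, 0.4))
    dist_coast_km <- exp(4.0 - 0.6 * g + rnorm(n, 0, 0.7))

    river_class <- sample(names(cfg$class_labels), n, replace = TRUE,
                          prob = cfg$class_labels)

    out <- tibble::tibble(
      reach_id = sprintf("R%05d", seq_len(n)),
      river_class = river_class,
      us_native = us_native, us_pasture = us_pasture,
      rip_native_pct = rip_native_pct,
      rip_shade = rip_shade, rip_shade_ref = rip_shade_ref,
      no3n = no3n, drp = drp, ds_dam = as.numeric(ds_dam),
      seg_slope = seg_slope, jan_air_temp = jan_air_temp,
      flood_freq = flood_freq, dist_coast_km = dist_coast_km
    )
    if (cfg$n_covariates > 0) {
      for (j in seq_len(cfg$n_covariates)) {
        out[[sprintf("nuis%02d", j)]] <- rnorm(n)
      }
    }
    out
  })
}

# Fixed feature standardisations used by the ground-truth response functions.
# Defined in code (not data-dependent) so the same function can be evaluated
# on current and reference-transformed covariates.
truth_features <- function(reaches) {
  tibble::tibble(
    z_temp = (reaches$jan_air_temp - 16) / 2,
    z_slope = log1p(reaches$seg_slope) - 1,
    z_flood = (log(reaches$flood_freq) - 2.6) / 0.4,
    z_coast = (log(reaches$dist_coast_km) - 4) / 0.9,
    pasture = reaches$us_pasture,
    native = reaches$us_native,
    shade = reaches$rip_shade,
    dam = reaches$ds_dam,
    z_no3n = log1p(reaches$no3n / 0.11),
    z_drp = log1p(reaches$drp / 0.006)
  )
}

# Evaluate one species' occurrence probability over a reach table.
eval_truth_prob <- function(par, reaches, impact_strength) {
  f <- truth_features(reaches)
  lp <- par$b0 - par$t_coef * ((reaches$jan_air_temp - par$t_opt) / 2)^2
  for (nm in names(par$nat_coefs)) lp <- lp + par$nat_coefs[[nm]] * f[[nm]]
  lp <- lp + par$int_coef * f[[par$int_pair[1]]] * f[[par$int_pair[2]]]
  # every covariate the reference transform can touch is scaled by
  # impact_strength, so impact_strength = 0 makes reference and current
  # probabilities identical (calibration preset)
  for (nm in names(par$anth_coefs)) {
    lp <- lp + impact_strength * par$anth_coefs[[nm]] * f[[nm]]
  }
  for (nm in names(par$cover_coefs)) {
    lp <- lp + impact_strength * par$cover_coefs[[nm]] * f[[nm]]
  }
  plogis(lp)
}

draw_species_params <- function(native) {
  # coefficient scales give steep responses: the strongest species reach a
  # generating (Bayes) AUC above 0.95 at national-survey sample sizes
  natural <- c("z_slope", "z_flood", "z_coast")
  k_nat <- sample(1:2, 1)
  nat_terms <- sample(natural, k_nat)
  nat_coefs <- setNames(sample(c(-1, 1), k_nat, TRUE) * runif(k_nat, 1.4, 2.6),
                        nat_terms)
  int_pair <- sample(natural, 2)
  int_coef <- sample(c(-1, 1), 1) * runif(1, 0.5, 1.0)

  anth_pool <- c(pasture = -runif(1, 2.0, 3.5),
                 z_no3n = -runif(1, 1.0, 2.0),
                 dam = -runif(1, 1.2, 2.8),
                 z_drp = -runif(1, 0.6, 1.6))
  anth_coefs <- as.list(anth_pool[sample(names(anth_pool), sample(2:3, 1))])
  cover_nm <- sample(c("native", "shade"), 1)
  cover_coefs <- setNames(list(runif(1, 0.5, 1.5) * c(native = 1, shade = 2)[[cover_nm]]),
                          cover_nm)
  if (!native) {
    # exotics favour disturbance: flip anthropogenic terms up, cover terms down
    anth_coefs <- lapply(anth_coefs, function(x) -x)
    cover_coefs <- lapply(cover_coefs, function(x) -x)
  }
  list(b0 = 0, t_opt = runif(1, 13.5, 18.5), t_coef = runif(1, 1.0, 2.0),
       nat_coefs = as.list(nat_coefs), int_pair = int_pair,
       int_coef = int_coef, anth_coefs = anth_coefs,
       cover_coefs = cover_coefs, prevalence_target = runif(1, 0.25, 0.55))
}

#' Generate the ground-truth table for a synthetic community
#'
#' Draws one smooth nonlinear response function per species (logistic link
#' over a linear predictor with a quadratic temperature optimum, one pairwise
#' interaction between natural covariates, and signed anthropogenic /
#' native-cover terms), evaluates it on the current reach table and on the
#' reference-transformed reach table, and draws presence under both states.
#' Native responses are non-increasing in every anthropogenic covariate and
#' non-decreasing in native cover, so the true reference probability is
#' always >= the true current probability. Intercepts are calibrated so each
#' species has a realistic prevalence on the generated reach set.
#'
#' @param reaches Reach table from [generate_reaches()].
#' @param cfg The same [synthetic_config()] used to generate `reaches`.
#' @return An object of class `oe_truth`: species parameter table, native /
#'   exotic species ids, and `n_reaches x n_species` matrices of current and
#'   reference occurrence probabilities plus presence draws.
#' @export
generate_truth <- function(reaches, cfg) {
  if (!inherits(cfg, "oe_synth_config")) {
    stopf("`cfg` must be created by synthetic_config()",
          class = "oefish_config_error")
  }
  check_columns(reaches, c("reach_id", "jan_air_temp"), "reach table")
  species <- c(sprintf("nat%02d", seq_len(cfg$n_species)),
               if (cfg$n_exotic > 0) sprintf("exo%02d", seq_len(cfg$n_exotic)))
  is_native <- startsWith(species, "nat")
  ref_reaches <- apply_reference_transform(reaches, default_reference_scenario())

  with_seed(derive_seed(cfg$seed, "truth"), {
    params <- list()
    p_cur <- p_ref <- matrix(NA_real_, nrow(reaches), length(species),
                             dimnames = list(reaches$reach_id, species))
    for (j in seq_along(species)) {
      par <- draw_species_params(is_native[j])
      # calibrate intercept to the target prevalence under current conditions
      lp0 <- qlogis(eval_truth_prob(par, reaches, cfg$impact_strength))
      par$b0 <- qlogis(par$prevalence_target) - mean(lp0)
      params[[species[j]]] <- par
      p_cur[, j] <- eval_truth_prob(par, reaches, cfg$impact_strength)
      p_ref[, j] <- eval_truth_prob(par, ref_reaches, cfg$impact_strength)
    }
    y_cur <- matrix(rbinom(length(p_cur), 1, p_cur), nrow(p_cur),
                    dimnames = dimnames(p_cur))
    y_ref <- matrix(rbinom(length(p_ref), 1, p_ref), nrow(p_ref),
                    dimnames = dimnames(p_ref))
    structure(
      list(species = species, native = species[is_native],
           exotic = species[!is_native], params = params,
           reach_id = reaches$reach_id,
           p_current = p_cur, p_reference = p_ref,
           y_current = y_cur, y_reference = y_ref,
           impact_strength = cfg$impact_strength),
      class = "oe_truth"
    )
  })
}

#' Generate a synthetic survey table
#'
#' One row per sampling event. Each of `n_sites` reaches receives one record;
#' a `duplicate_rate` fraction receive a second. Species presence is drawn as
#' Bernoulli(true current probability x `detection_prob`). A `violation_rate`
#' fraction of records independently violate each ingest filter (pre-2000
#' year, off-season month, non-electric method, reach shorter than 150 m) so
#' the filter stage is exercised.
#'
#' @param reaches Reach table from [generate_reaches()].
#' @param truth Truth object from [generate_truth()].
#' @param cfg The matching [synthetic_config()].
#' @return A tibble with columns `site_id`, `reach_id`, `date`, `method`,
#'   `reach_length_m` and one 0/1 presence column per species.
#' @export
generate_surveys <- function(reaches, truth, cfg) {
  if (!inherits(truth, "oe_truth")) {
    stopf("`truth` must be created by generate_truth()",
          class = "oefish_consistency_error")
  }
  if (!identical(truth$reach_id, reaches$reach_id)) {
    stopf("truth and reach table disagree on reach ids",
          class = "oefish_consistency_error")
  }
  with_seed(derive_seed(cfg$seed, "surveys"), {
    site_reach <- sort(sample(nrow(reaches), cfg$n_sites))
    n_dup <- round(cfg$duplicate_rate * cfg$n_sites)
    rec_reach <- c(site_reach,
                   if (n_dup > 0) sample(site_reach, n_dup))
    m <- length(rec_reach)

    year <- sample(2001:2015, m, replace = TRUE)
    month <- sample(c(12L, 1L, 2L, 3L), m, replace = TRUE)
    method <- rep("electric", m)
    reach_length_m <- runif(m, 150, 400)

    bad <- function() runif(m) < cfg$violation_rate
    i <- bad(); year[i] <- sample(1995:1999, sum(i), replace = TRUE)
    i <- bad(); month[i] <- sample(5:10, sum(i), replace = TRUE)
    i <- bad(); method[i] <- "net"
    i <- bad(); reach_length_m[i] <- runif(sum(i), 40, 149)

    day <- sample(1:28, m, replace = TRUE)
    out <- tibble::tibble(
      site_id = sprintf("S%05d", rec_reach),
      reach_id = reaches$reach_id[rec_reach],
      date = as.Date(sprintf("%04d-%02d-%02d", year, month, day)),
      method = method,
      reach_length_m = reach_length_m
    )
    for (sp in truth$species) {
      p <- truth$p_current[rec_reach, sp] * cfg$detection_prob
      out[[sp]] <- rbinom(m, 1, p)
    }
    out
  })
}

#' True O/E from the ground truth
#'
#' Oracle twin of the pipeline's O/E: applies the same counting rules to the
#' TRUE occurrence probabilities. A native species is expected at a reach
#' when its true reference probability meets its threshold, and observed when
#' additionally its true current probability meets the threshold. Used in
#' recovery tests only.
#'
#' @param truth Truth object from [generate_truth()].
#' @param thresholds Named vector of per-species presence thresholds in
#'   \[0, 1\] (names must cover the native species).
#' @return A tibble: `reach_id`, `e_count`, `o_count`, `ratio` (NA where
#'   `e_count` is 0).
#' @export
true_oe <- function(truth, thresholds) {
  if (!inherits(truth, "oe_truth")) {
    stopf("`truth` must be created by generate_truth()",
          class = "oefish_consistency_error")
  }
  missing <- setdiff(truth$native, names(thresholds))
  if (length(missing)) {
    stopf("thresholds missing for species: %s", paste(missing, collapse = ", "),
          class = "oefish_consistency_error")
  }
  if (any(thresholds < 0 | thresholds > 1)) {
    stopf("thresholds must lie in [0, 1]", class = "oefish_config_error")
  }
  th <- thresholds[truth$native]
  exp_mat <- sweep(truth$p_reference[, truth$native, drop = FALSE], 2, th, `>=`)
  cur_mat <- sweep(truth$p_current[, truth$native, drop = FALSE], 2, th, `>=`)
  e <- rowSums(exp_mat)
  o <- rowSums(exp_mat & cur_mat)
  tibble::tibble(reach_id = truth$reach_id,
                 e_count = as.integer(e), o_count = as.integer(o),
                 ratio = ifelse(e > 0, o / e, NA_real_))
}

#' Write a synthetic scenario to delimited text
#'
#' Writes the reach table, survey table and truth probabilities as CSV and
#' the configuration as YAML, so a generated world can be inspected or
#' re-used outside R.
#'
#' @param dir Output directory (created if absent).
#' @param reaches,surveys,truth,cfg The generated objects.
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic <- function(dir, reaches, surveys, truth, cfg) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("reaches.csv", "surveys.csv",
                            "truth_current.csv", "truth_reference.csv",
                            "config.yaml"))
  utils::write.csv(reaches, paths[1], row.names = FALSE)
  utils::write.csv(surveys, paths[2], row.names = FALSE)
  utils::write.csv(cbind(reach_id = truth$reach_id,
                         as.data.frame(truth$p_current)),
                   paths[3], row.names = FALSE)
  utils::write.csv(cbind(reach_id = truth$reach_id,
                         as.data.frame(truth$p_reference)),
                   paths[4], row.names = FALSE)
  yaml::write_yaml(unclass(cfg), paths[5])
  invisible(paths)
}
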