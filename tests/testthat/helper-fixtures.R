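# Shared fixtures, built lazily and cached for the session.

`%||%` <- function(x, y) if (is.null(x)) y else x

.fixture_cache <- new.env(parent = emptyenv())

# A small synthetic world: 400 reaches, 300 sites, 3 natives + 1 exotic.
tiny_world <- function() {
  if (is.null(.fixture_cache$tiny)) {
    cfg <- synthetic_config(n_reaches = 400, n_sites = 300, n_species = 3,
                            n_exotic = 1, seed = 7)
    reaches <- generate_reaches(cfg)
    truth <- generate_truth(reaches, cfg)
    surveys <- generate_surveys(reaches, truth, cfg)
    .fixture_cache$tiny <- list(cfg = cfg, reaches = reaches, truth = truth,
                                surveys = surveys)
  }
  .fixture_cache$tiny
}

# Cheap BRT regime for unit tests (the default 1,000-tree regime is used in
# the acceptance suite).
cheap_brt <- function(seed = 3) {
  brt_config(min_trees = 30, initial_learning_rate = 0.1, n_folds = 4,
             max_halvings = 3, seed = seed)
}

# A fitted bundle on the tiny world, with threshold, cached.
tiny_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    w <- tiny_world()
    flt <- filter_surveys(w$surveys, seed = 1)
    train <- dplyr::inner_join(
      flt$surveys[, c("site_id", "reach_id", w$truth$species)],
      w$reaches, by = "reach_id")
    covs <- setdiff(names(w$reaches)[vapply(w$reaches, is.numeric, TRUE)],
                    "rip_shade_ref")
    b <- fit_species_model(train, "nat01", covariates = covs,
                           config = cheap_brt())
    .fixture_cache$bundle <- list(bundle = select_threshold_for(b, train),
                                  train = train)
  }
  .fixture_cache$bundle
}

# True covariate importance of a generated species: the standard deviation,
# over reaches, of each term's contribution to the linear predictor
# (interaction terms split evenly between their two covariates). Returns the
# two most important covariates, named by their reach-table columns.
truth_top2 <- function(par, reaches) {
  f <- oefish:::truth_features(reaches)
  colmap <- c(z_slope = "seg_slope", z_flood = "flood_freq",
              z_coast = "dist_coast_km", pasture = "us_pasture",
              z_no3n = "no3n", dam = "ds_dam", z_drp = "drp",
              native = "us_native", shade = "rip_shade")
  add <- function(imp, col, v) {
    imp[col] <- sum(c(imp[col], v), na.rm = TRUE)
    imp
  }
  imp <- c(jan_air_temp =
             sd(-par$t_coef * ((reaches$jan_air_temp - par$t_opt) / 2)^2))
  for (nm in names(par$nat_coefs)) {
    imp <- add(imp, colmap[[nm]], sd(par$nat_coefs[[nm]] * f[[nm]]))
  }
  int_sd <- sd(par$int_coef * f[[par$int_pair[1]]] * f[[par$int_pair[2]]])
  for (nm in par$int_pair) imp <- add(imp, colmap[[nm]], int_sd / 2)
  for (nm in names(par$anth_coefs)) {
    imp <- add(imp, colmap[[nm]], sd(par$anth_coefs[[nm]] * f[[nm]]))
  }
  for (nm in names(par$cover_coefs)) {
    imp <- add(imp, colmap[[nm]], sd(par$cover_coefs[[nm]] * f[[nm]]))
  }
  names(sort(imp, decreasing = TRUE))[1:2]
}

# Independent Cohen's Kappa oracle: reconstructs the two 0/1 vectors from
# confusion counts and computes agreement via marginal cross-products.
kappa_oracle <- function(tp, fp, fn, tn) {
  pred <- c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn))
  obs <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
  n <- length(pred)
  po <- mean(pred == obs)
  pe <- sum(vapply(c(0, 1), function(v) mean(pred == v) * mean(obs == v),
                   numeric(1)))
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

# Brute-force AUC oracle: enumerate positive-negative pairs.
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# Brute-force threshold-search oracle over the same grid.
threshold_oracle <- function(labels, probs, step = 0.005) {
  grid <- seq(0, 1, by = step)
  best_k <- -Inf
  best_t <- NA
  for (t in grid) {
    call <- as.integer(probs >= t)
    tp <- sum(call == 1 & labels == 1); fp <- sum(call == 1 & labels == 0)
    fn <- sum(call == 0 & labels == 1); tn <- sum(call == 0 & labels == 0)
    k <- kappa_oracle(tp, fp, fn, tn)
    if (k > best_k + 1e-12) {
      best_k <- k
      best_t <- t
    }
  }
  list(threshold = best_t, kappa = best_k)
}
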