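make_pressures <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    reach_id = sprintf("r%04d", seq_len(n)),
    ds_dam = rbinom(n, 1, 0.2),
    no3n = rlnorm(n, -1.5, 0.6),
    drp = rlnorm(n, -4.5, 0.6),
    exo01 = rbinom(n, 1, 0.3)
  )
}

test_that("a noiseless monotone pressure-response is recovered", {
  n <- 600
  pr <- make_pressures(n, seed = 2)
  oe <- tibble::tibble(reach_id = pr$reach_id,
                       ratio = plogis(2 - 3 * log(pr$no3n + 0.05)))
  oe$ratio <- oe$ratio / max(oe$ratio)
  fit <- fit_attribution(oe, pr, config = cheap_brt())
  expect_gt(fit$cv_correlation, 0.95)
  expect_equal(names(which.max(fit$relative_influence)), "no3n")
  expect_gt(fit$relative_influence[["no3n"]], 50)
  expect_equal(sum(fit$relative_influence), 100, tolerance = 1e-6)
})

test_that("O/E independent of all pressures yields near-zero CV correlation", {
  n <- 1000
  pr <- make_pressures(n, seed = 3)
  set.seed(33)
  oe <- tibble::tibble(reach_id = pr$reach_id, ratio = runif(n))
  # a pure-noise target cannot support the minimum-tree rule; the
  # attribution model accepts the CV-optimal ensemble with a warning
  fit <- suppressWarnings(fit_attribution(oe, pr, config = cheap_brt()))
  expect_lt(abs(fit$cv_correlation), 0.15)
})

test_that("constant pressure columns get zero influence", {
  n <- 300
  pr <- make_pressures(n, seed = 4)
  pr$flat <- 1
  oe <- tibble::tibble(reach_id = pr$reach_id,
                       ratio = plogis(-2 * log(pr$no3n + 0.05)))
  fit <- fit_attribution(oe, pr, config = cheap_brt())
  expect_equal(fit$relative_influence[["flat"]], 0)
})

test_that("undefined O/E reaches never enter the attribution fit", {
  n <- 300
  pr <- make_pressures(n, seed = 5)
  oe <- tibble::tibble(reach_id = pr$reach_id,
                       ratio = plogis(-log(pr$no3n + 0.05)))
  oe$ratio[1:40] <- NA
  fit <- fit_attribution(oe, pr, config = cheap_brt())
  expect_equal(fit$n_reaches_used, n - 40)
  expect_lte(fit$n_reaches_used, n)
})

test_that("degenerate targets and tiny inputs are rejected", {
  pr <- make_pressures(100, seed = 6)
  flat <- tibble::tibble(reach_id = pr$reach_id, ratio = 0.5)
  expect_error(fit_attribution(flat, pr, config = cheap_brt()),
               class = "oefish_degenerate_error")
  small <- tibble::tibble(reach_id = pr$reach_id[1:10],
                          ratio = runif(10))
  expect_error(fit_attribution(small, pr, config = cheap_brt()),
               class = "oefish_data_error")
})

test_that("percent agreement is symmetric and complements Hamming distance", {
  n <- 100
  set.seed(7)
  a <- tibble::tibble(reach_id = sprintf("r%03d", 1:n),
                      s1 = rbinom(n, 1, 0.5), s2 = rbinom(n, 1, 0.3))
  expect_equal(percent_agreement(a, a)$agreement_pct, c(100, 100))
  flipped <- a
  flipped$s1 <- 1L - a$s1
  flipped$s2 <- 1L - a$s2
  expect_equal(percent_agreement(a, flipped)$agreement_pct, c(0, 0))

  b <- a
  b$s1[1:7] <- 1L - b$s1[1:7]   # 93 matches of 100
  pa <- percent_agreement(a, b)
  expect_equal(pa$agreement_pct[pa$species == "s1"], 93)
  ab <- percent_agreement(a, b)
  ba <- percent_agreement(b, a)
  expect_equal(ab$agreement_pct, ba$agreement_pct)
  hamming_pct <- 100 * mean(a$s1 != b$s1)
  expect_equal(ab$agreement_pct[ab$species == "s1"], 100 - hamming_pct)
  expect_equal(attr(ab, "mean_agreement"), mean(ab$agreement_pct))
  expect_error(percent_agreement(a, b[1:50, ]),
               class = "oefish_consistency_error")
})

fake_bundle <- function(species, infl) {
  structure(list(species = species, native = TRUE,
                 relative_influence = 100 * infl / sum(infl)),
            class = "oe_species_brt")
}

test_that("identical influence vectors sit at zero distance in the ordination", {
  covs <- paste0("c", 1:6)
  v <- setNames(c(40, 30, 15, 10, 4, 1), covs)
  bundles <- list(fake_bundle("a", v), fake_bundle("b", v),
                  fake_bundle("c", setNames(rev(v), covs)))
  ord <- nmds_influences(bundles, seed = 1, n_starts = 5)
  d <- as.matrix(ord$distances)
  expect_equal(d["a", "b"], 0)
  expect_gt(d["a", "c"], 0)
})

test_that("three equidistant species embed with near-zero stress", {
  covs <- paste0("c", 1:3)
  bundles <- list(
    fake_bundle("a", setNames(c(1, 0, 0), covs)),
    fake_bundle("b", setNames(c(0, 1, 0), covs)),
    fake_bundle("c", setNames(c(0, 0, 1), covs))
  )
  ord <- nmds_influences(bundles, k_top = 3, seed = 2, n_starts = 10)
  # an exact 2-D representation exists, so the nonmetric fit reaches ~0 stress
  expect_lt(ord$stress, 0.01)
})

test_that("stress matches an independent NMDS implementation", {
  set.seed(9)
  covs <- paste0("c", 1:6)
  bundles <- lapply(1:10, function(i) {
    fake_bundle(paste0("sp", i), setNames(runif(6), covs))
  })
  ord <- nmds_influences(bundles, k_top = 5, seed = 3, n_starts = 20)
  best <- Inf
  for (s in 1:20) {
    set.seed(100 + s)
    init <- matrix(rnorm(10 * 2), ncol = 2)
    fit <- MASS::isoMDS(ord$distances, y = init, k = 2, trace = FALSE)
    best <- min(best, fit$stress / 100)
  }
  expect_lt(abs(ord$stress - best), 0.02)
})

test_that("ordination distances are invariant to isometries of the solution", {
  set.seed(10)
  covs <- paste0("c", 1:5)
  bundles <- lapply(1:8, function(i) {
    fake_bundle(paste0("sp", i), setNames(runif(5), covs))
  })
  ord <- nmds_influences(bundles, seed = 4, n_starts = 5)
  expect_gte(ord$stress, 0)
  xy <- as.matrix(ord$coordinates[, c("NMDS1", "NMDS2")])
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- sweep(xy %*% rot, 2, c(3, -1), `+`)
  moved[, 1] <- -moved[, 1]  # reflection
  expect_equal(as.numeric(dist(moved)), as.numeric(dist(xy)),
               tolerance = 1e-10)
  expect_error(nmds_influences(bundles[1:2], seed = 1),
               class = "oefish_data_error")
})
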