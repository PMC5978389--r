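test_that("degenerate configurations are rejected", {
  expect_error(synthetic_config(n_reaches = 0), class = "oefish_config_error")
  expect_error(synthetic_config(n_sites = 100, n_reaches = 50),
               class = "oefish_config_error")
  expect_error(synthetic_config(class_labels = c(A = 0.6, B = 0.5)),
               class = "oefish_config_error")
  expect_error(synthetic_config(detection_prob = 0),
               class = "oefish_config_error")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_reaches = 150, n_sites = 100, n_species = 2,
                          seed = 7)
  r1 <- generate_reaches(cfg)
  r2 <- generate_reaches(cfg)
  expect_identical(r1, r2)
  t1 <- generate_truth(r1, cfg)
  s1 <- generate_surveys(r1, t1, cfg)
  s2 <- generate_surveys(r2, generate_truth(r2, cfg), cfg)
  expect_identical(s1, s2)
})

test_that("generated covariates respect their declared ranges", {
  w <- tiny_world()
  r <- w$reaches
  expect_true(all(r$us_native >= 0 & r$us_native <= 1))
  expect_true(all(r$us_pasture >= 0 & r$us_pasture <= 1))
  expect_true(all(r$rip_native_pct >= 0 & r$rip_native_pct <= 100))
  expect_true(all(r$rip_shade >= 0 & r$rip_shade <= 1))
  expect_true(all(r$rip_shade <= r$rip_shade_ref))
  expect_true(all(r$no3n >= 0))
  expect_true(all(r$drp >= 0))
  expect_true(all(r$ds_dam %in% c(0, 1)))
  expect_true(all(r$seg_slope >= 0))
  expect_true(all(r$flood_freq >= 0))
  expect_true(all(r$dist_coast_km >= 0))
  expect_true(all(r$river_class %in% names(w$cfg$class_labels)))
})

test_that("the anthropogenic gradient induces the expected correlations", {
  cfg <- synthetic_config(n_reaches = 2000, n_sites = 1500,
                          impact_strength = 1, seed = 11)
  r <- generate_reaches(cfg)
  expect_gt(cor(r$us_pasture, r$no3n), 0.3)
  expect_gt(cor(r$us_pasture, r$drp), 0.3)
  expect_lt(cor(r$us_pasture, r$us_native), -0.5)
})

test_that("truth probabilities are valid and reference >= current for natives", {
  w <- tiny_world()
  tr <- w$truth
  expect_true(all(tr$p_current >= 0 & tr$p_current <= 1))
  expect_true(all(tr$p_reference >= 0 & tr$p_reference <= 1))
  nat <- tr$native
  expect_true(all(tr$p_reference[, nat] >= tr$p_current[, nat] - 1e-12))
})

test_that("reference probability is the response evaluated on transformed covariates", {
  w <- tiny_world()
  ref <- apply_reference_transform(w$reaches, default_reference_scenario())
  for (sp in w$truth$species) {
    recomputed <- oefish:::eval_truth_prob(w$truth$params[[sp]], ref,
                                           w$cfg$impact_strength)
    expect_equal(unname(w$truth$p_reference[, sp]), recomputed,
                 tolerance = 1e-12)
  }
})

test_that("zero impact strength is a calibrated world: true O/E = 1 where E > 0", {
  cfg <- synthetic_config(n_reaches = 300, n_sites = 200, n_species = 3,
                          impact_strength = 0, seed = 5)
  r <- generate_reaches(cfg)
  tr <- generate_truth(r, cfg)
  expect_equal(tr$p_current, tr$p_reference, tolerance = 1e-12)
  toe <- true_oe(tr, setNames(rep(0.4, length(tr$native)), tr$native))
  defined <- !is.na(toe$ratio)
  expect_true(all(toe$ratio[defined] == 1))
})

test_that("true O/E arithmetic follows the counting rules", {
  fake <- structure(list(
    native = c("a", "b", "c", "d", "e"),
    reach_id = c("r1", "r2", "r3"),
    p_current = matrix(c(0.9, 0.9, 0.9, 0.1, 0.1,   # r1: 3 of 5 present
                         0.9, 0.9, 0.9, 0.9, 0.9,   # r2: all present
                         0.1, 0.1, 0.1, 0.1, 0.1),  # r3: none expected
                       3, 5, byrow = TRUE,
                       dimnames = list(NULL, c("a", "b", "c", "d", "e"))),
    p_reference = matrix(c(rep(0.9, 5), rep(0.9, 5), rep(0.1, 5)),
                         3, 5, byrow = TRUE,
                         dimnames = list(NULL, c("a", "b", "c", "d", "e")))),
    class = "oe_truth")
  toe <- true_oe(fake, setNames(rep(0.5, 5), c("a", "b", "c", "d", "e")))
  expect_equal(toe$ratio, c(0.6, 1, NA))
  expect_equal(toe$e_count, c(5L, 5L, 0L))
  expect_error(true_oe(fake, setNames(rep(1.5, 5), fake$native)),
               class = "oefish_config_error")
})

test_that("survey generator injects the configured violation fractions", {
  cfg <- synthetic_config(n_reaches = 5000, n_sites = 4545, n_species = 2,
                          violation_rate = 0.1, duplicate_rate = 0.1,
                          seed = 13)
  r <- generate_reaches(cfg)
  tr <- generate_truth(r, cfg)
  s <- generate_surveys(r, tr, cfg)
  m <- nrow(s)
  year <- as.integer(format(s$date, "%Y"))
  # each violated fraction is binomial(m, 0.1): allow ~5 sd
  expect_equal(sum(year < 2000), 0.1 * m, tolerance = 0.25)
  expect_equal(sum(s$reach_length_m < 150), 0.1 * m, tolerance = 0.25)
  expect_equal(sum(s$method != "electric"), 0.1 * m, tolerance = 0.25)
})

test_that("forced detection extremes propagate to presence columns", {
  w <- tiny_world()
  cfg0 <- synthetic_config(n_reaches = 100, n_sites = 80, n_species = 1,
                           n_exotic = 0, detection_prob = 1, seed = 3)
  r <- generate_reaches(cfg0)
  tr <- generate_truth(r, cfg0)
  tr$p_current[, "nat01"] <- 1   # species truly everywhere
  s <- generate_surveys(r, tr, cfg0)
  expect_true(all(s$nat01 == 1))
  tr$p_current[, "nat01"] <- 0
  s0 <- generate_surveys(r, tr, cfg0)
  expect_true(all(s0$nat01 == 0))
  expect_length(prevalence_filter(s0, min_sites = 1)$species, 0)
})

test_that("synthetic outputs round-trip through delimited text", {
  w <- tiny_world()
  dir <- withr::local_tempdir()
  paths <- write_synthetic(dir, w$reaches, w$surveys, w$truth, w$cfg)
  expect_true(all(file.exists(paths)))
  back <- read_table_auto(file.path(dir, "reaches.csv"))
  expect_equal(nrow(back), nrow(w$reaches))
  expect_equal(back$no3n, w$reaches$no3n, tolerance = 1e-12)
})
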