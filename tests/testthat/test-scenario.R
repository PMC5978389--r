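ref_reach <- function(no3n = 0.25, drp = 0.01) {
  tibble::tibble(reach_id = "R1", us_native = 0.4, us_pasture = 0.5,
                 rip_native_pct = 30, rip_shade = 0.2, rip_shade_ref = 0.7,
                 no3n = no3n, drp = drp, other = 99)
}

test_that("scenario specs validate their key sets", {
  expect_error(scenario_spec(set_to = list(no3n = 0.11),
                             cap_at = list(no3n = 0.11)),
               class = "oefish_config_error")
  expect_error(scenario_spec(set_to = list(no3n = "high")),
               class = "oefish_config_error")
  expect_error(apply_reference_transform(ref_reach()[, -7],
                                         default_reference_scenario()),
               class = "oefish_schema_error")
})

test_that("the reference transform sets, caps and substitutes as declared", {
  out <- apply_reference_transform(ref_reach(), default_reference_scenario())
  expect_equal(out$us_native, 1)
  expect_equal(out$us_pasture, 0)
  expect_equal(out$rip_native_pct, 100)
  expect_equal(out$rip_shade, 0.7)        # pre-human companion substituted
  expect_equal(out$no3n, 0.11)            # 0.25 mg/L exceeds the ceiling
  expect_equal(out$drp, 0.006)            # 0.01 mg/L exceeds the ceiling
  expect_equal(out$other, 99)             # untouched column bit-identical

  below <- apply_reference_transform(ref_reach(no3n = 0.05, drp = 0.004),
                                     default_reference_scenario())
  expect_equal(below$no3n, 0.05)          # below ceiling: unchanged
  expect_equal(below$drp, 0.004)
})

test_that("the transform is idempotent and never mutates its input", {
  w <- tiny_world()
  r0 <- w$reaches
  snapshot <- r0
  once <- apply_reference_transform(r0, default_reference_scenario())
  twice <- apply_reference_transform(once, default_reference_scenario())
  expect_identical(once, twice)
  expect_identical(r0, snapshot)
  untouched <- setdiff(names(r0), c("us_native", "us_pasture",
                                    "rip_native_pct", "rip_shade",
                                    "no3n", "drp"))
  expect_identical(once[untouched], r0[untouched])
})

test_that("riparian values above the nominal bound are handled by set/cap semantics", {
  odd <- ref_reach()
  odd$rip_native_pct <- 100.10   # observed in real covariate layers
  out <- apply_reference_transform(odd, default_reference_scenario())
  expect_equal(out$rip_native_pct, 100)  # set_to overwrites regardless
  capped <- apply_reference_transform(
    odd, scenario_spec(cap_at = list(rip_native_pct = 100)))
  expect_equal(capped$rip_native_pct, 100)  # cap never raises values
})

test_that("scenarios round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(set_to = list(us_pasture = 0),
                        cap_at = list(no3n = 0.11),
                        substitute_from = list(rip_shade = "rip_shade_ref")),
                   path)
  sc <- read_scenario(path)
  expect_s3_class(sc, "oe_scenario")
  out <- apply_reference_transform(ref_reach(), sc)
  expect_equal(out$us_pasture, 0)
  expect_equal(out$no3n, 0.11)
  expect_equal(out$rip_shade, 0.7)
})

make_sets <- function(reach_id, ...) {
  tibble::tibble(reach_id = reach_id, ...)
}

test_that("O/E counting follows the expected-set restriction", {
  cur <- make_sets("r1", a = 1L, b = 1L, c = 0L, d = 0L)
  ref <- make_sets("r1", a = 1L, b = 1L, c = 1L, d = 1L)
  res <- compute_oe(cur, ref)
  expect_equal(res$e_count, 4L)
  expect_equal(res$o_count, 2L)
  expect_equal(res$ratio, 0.5)

  # species present now but not expected do not count toward O
  cur2 <- make_sets("r1", a = 1L, b = 0L, x = 1L)
  ref2 <- make_sets("r1", a = 1L, b = 1L, x = 0L)
  res2 <- compute_oe(cur2, ref2)
  expect_equal(res2$o_count, 1L)
  expect_equal(res2$e_count, 2L)
  expect_equal(res2$ratio, 0.5)

  # empty expected set: undefined, reason-coded
  res3 <- compute_oe(make_sets("r1", a = 1L), make_sets("r1", a = 0L))
  expect_true(is.na(res3$ratio))
  expect_equal(res3$flag, "E0")

  expect_error(compute_oe(cur, ref, exotic = "a"),
               class = "oefish_contract_error")
  expect_error(compute_oe(cur, make_sets("r2", a = 1L, b = 1L, c = 1L, d = 1L)),
               class = "oefish_consistency_error")
})

test_that("O/E ratios are structurally bounded to [0, 1]", {
  set.seed(14)
  for (i in 1:20) {
    n <- 50
    sp <- paste0("s", 1:6)
    cur <- tibble::as_tibble(setNames(
      as.data.frame(matrix(rbinom(n * 6, 1, runif(1)), n)), sp))
    ref <- tibble::as_tibble(setNames(
      as.data.frame(matrix(rbinom(n * 6, 1, runif(1)), n)), sp))
    cur$reach_id <- ref$reach_id <- sprintf("r%02d", 1:n)
    res <- compute_oe(cur, ref)
    ok <- !is.na(res$ratio)
    expect_true(all(res$ratio[ok] >= 0 & res$ratio[ok] <= 1))
    expect_true(all(res$o_count <= res$e_count))
    expect_true(all(res$e_count[!ok] == 0))
  }
})

test_that("assemblage prediction enforces thresholds and matches direct calling", {
  fx <- tiny_bundle()
  w <- tiny_world()
  b <- fx$bundle
  no_thr <- b
  no_thr$threshold <- NA_real_
  expect_error(predict_assemblage(list(no_thr), w$reaches),
               class = "oefish_config_error")

  sets <- predict_assemblage(list(b), w$reaches)
  direct <- call_presence(predict_probability(b, w$reaches)$prob, b$threshold)
  expect_equal(sets$native[[b$species]], direct)
  expect_identical(sets, predict_assemblage(list(b), w$reaches))

  high <- b
  high$threshold <- 1
  none <- predict_assemblage(list(high), w$reaches)
  if (all(predict_probability(b, w$reaches)$prob < 1)) {
    expect_true(all(none$native[[b$species]] == 0))
  }
})

test_that("an empty scenario is the identity: O/E = 1 wherever E > 0", {
  fx <- tiny_bundle()
  w <- tiny_world()
  b <- fx$bundle
  empty <- scenario_spec()
  same <- apply_reference_transform(w$reaches, empty)
  expect_identical(same, tibble::as_tibble(w$reaches))
  cur <- predict_assemblage(list(b), w$reaches)
  ref <- predict_assemblage(list(b), same)
  res <- compute_oe(cur$native, ref$native)
  defined <- !is.na(res$ratio)
  expect_true(all(res$ratio[defined] == 1))
})

test_that("reaches already at reference score O/E = 1 where E > 0", {
  fx <- tiny_bundle()
  w <- tiny_world()
  b <- fx$bundle
  at_ref <- apply_reference_transform(w$reaches, default_reference_scenario())
  cur <- predict_assemblage(list(b), at_ref)
  ref <- predict_assemblage(
    list(b), apply_reference_transform(at_ref, default_reference_scenario()))
  res <- compute_oe(cur$native, ref$native)
  defined <- !is.na(res$ratio)
  expect_true(all(res$ratio[defined] == 1))
})
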