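toy_pop <- function(spike = 1000, background = 100000) {
  clone_population(tibble::tibble(
    clone_id = c("spike", "bg"),
    class_id = c("target_binder", "nonbinder"),
    count = c(spike, background),
    spike = c(TRUE, FALSE)))
}

test_that("population and config validation catch malformed inputs", {
  expect_error(clone_population(tibble::tibble(clone_id = "a")), "columns")
  expect_error(clone_population(tibble::tibble(
    clone_id = "a", class_id = "alien", count = 1, spike = FALSE)), "class_id")
  expect_error(clone_population(tibble::tibble(
    clone_id = c("a", "b"), class_id = "nonbinder", count = 1,
    spike = TRUE)), "one spike")
  expect_error(panning_config(display_efficiency = 1.5), "probabilities")
  expect_error(panning_config(surface = "teflon"), "arg")
})

test_that("molecule counts are conserved exactly in every round", {
  cfgs <- list(
    panning_config(),
    panning_config(preincubation_depletion = 0.8, elution = "biotin_then_edta"),
    panning_config(surface = "ni_nta", washes = 5))
  pop <- clone_population(tibble::tibble(
    clone_id = c("t", "m", "s", "n"),
    class_id = c("target_binder", "streptavidin_motif_binder",
                 "surface_sticker", "nonbinder"),
    count = c(1e4, 1e4, 1e4, 1e6),
    spike = c(TRUE, FALSE, FALSE, FALSE)))
  for (cfg in cfgs) {
    for (mode in c("sample", "expectation")) {
      r <- simulate_round(pop, cfg, mode = mode, seed = 33)
      d <- r$data
      expect_equal(d$functional,
                   d$depleted + d$flow_through + d$washed + d$eluted + d$discarded,
                   tolerance = 1e-12)
      # wash breakdown sums to the washed total
      expect_equal(vapply(d$wash_counts, sum, numeric(1)), d$washed)
      # without depletion and with EDTA the extra buckets are empty
      if (cfg$preincubation_depletion == 0 && cfg$elution == "edta") {
        expect_true(all(d$depleted == 0) && all(d$discarded == 0))
      }
    }
  }
})

test_that("degenerate configs behave as their limits dictate", {
  pop <- toy_pop()
  zero <- simulate_round(pop, panning_config(display_efficiency = 0), seed = 1)
  expect_true(all(zero$data$eluted == 0))

  lossless <- panning_config(display_efficiency = 1, washes = 7)
  classes1 <- clone_classes(target_retention = 1, nonbinder_retention = 1,
                            motif_retention = 1, sticker_retention = 1,
                            target_capture = 1, baseline_capture = 1,
                            motif_capture_streptavidin = 1, sticker_capture = 1)
  r <- simulate_round(pop, lossless, classes = classes1, seed = 2)
  expect_equal(r$data$eluted, r$data$input)
})

test_that("functional complex counts match the binomial mean", {
  pop <- clone_population(tibble::tibble(
    clone_id = "c", class_id = "nonbinder", count = 1e5, spike = FALSE))
  r <- simulate_round(pop, panning_config(display_efficiency = 0.04), seed = 3)
  se <- sqrt(1e5 * 0.04 * 0.96)
  expect_lt(abs(r$data$functional - 4000), 4 * se)
})

test_that("biotin elution discards stickers; EDTA recovers a superset", {
  pop <- clone_population(tibble::tibble(
    clone_id = c("t", "m", "s", "n"),
    class_id = c("target_binder", "streptavidin_motif_binder",
                 "surface_sticker", "nonbinder"),
    count = rep(1e5, 4), spike = c(TRUE, FALSE, FALSE, FALSE)))
  cfg_b <- panning_config(elution = "biotin_then_edta")
  rb <- simulate_round(pop, cfg_b, seed = 4)
  expect_equal(rb$data$eluted[rb$data$class_id == "surface_sticker"], 0)
  expect_equal(rb$data$eluted[rb$data$class_id == "nonbinder"], 0)
  # EDTA recovers every class biotin does, and more
  re <- simulate_round(pop, panning_config(elution = "edta"), seed = 4)
  b_classes <- rb$data$class_id[rb$data$eluted > 0]
  e_classes <- re$data$class_id[re$data$eluted > 0]
  expect_true(all(b_classes %in% e_classes))
  expect_true("surface_sticker" %in% e_classes)
})

test_that("Ni-NTA surface drops streptavidin-motif capture to baseline", {
  pop <- clone_population(tibble::tibble(
    clone_id = "m", class_id = "streptavidin_motif_binder", count = 1e6,
    spike = FALSE))
  strep <- simulate_round(pop, panning_config(surface = "streptavidin_plate"),
                          mode = "expectation")
  ni <- simulate_round(pop, panning_config(surface = "ni_nta"),
                       mode = "expectation")
  classes <- clone_classes()
  expect_equal(ni$data$eluted / strep$data$eluted,
               classes$capture_ni_nta[2] / classes$capture_streptavidin_plate[2],
               tolerance = 1e-12)
})

test_that("expectation mode matches the two-type closed form exactly", {
  cfg <- panning_config(input_size = 101000)
  classes <- clone_classes()
  pop <- toy_pop(1000, 100000)
  camp <- run_campaign(pop, rep(list(cfg), 3), classes, mode = "expectation")
  s <- class_survival(cfg, classes, "target_binder")
  b <- class_survival(cfg, classes, "nonbinder")
  p0 <- 1000 / 101000
  for (r in 1:3) {
    expect_equal(camp$trajectory$spike_fraction_eluted[r],
                 two_type_fraction(p0, s, b, r), tolerance = 1e-12)
  }
})

test_that("sampled campaigns agree with expectation mode within Monte Carlo error", {
  cfg <- panning_config(input_size = NULL, amplification_factor = 1)
  classes <- clone_classes()
  pop <- clone_population(tibble::tibble(
    clone_id = c("a", "b", "c"),
    class_id = c("target_binder", "surface_sticker", "nonbinder"),
    count = c(500, 500, 5000), spike = c(TRUE, FALSE, FALSE)))
  exp_camp <- run_campaign(pop, list(cfg, cfg), classes, mode = "expectation")
  exp_final <- sum(exp_camp$rounds[[2]]$data$eluted)
  set.seed(88)
  finals <- replicate(300, {
    sum(run_campaign(pop, list(cfg, cfg), classes,
                     mode = "sample")$rounds[[2]]$data$eluted)
  })
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - exp_final), 3 * se)
})

test_that("spike fraction is monotone when the spike out-survives every background", {
  sc <- make_scenario("egfp_campaign", scaled = TRUE)
  camp <- run_scenario(sc, mode = "expectation")
  expect_true(all(diff(camp$trajectory$spike_fraction_eluted) > 0))
  # survival advantage holds by construction
  s <- class_survival(sc$rounds[[1]], sc$classes, "target_binder")
  b <- class_survival(sc$rounds[[1]], sc$classes, "nonbinder")
  expect_gt(s, b)
})

test_that("display efficiency is recovered unbiased from simulated elutions", {
  eff <- 0.04
  cfg <- panning_config(display_efficiency = eff)
  classes1 <- clone_classes(target_retention = 1, target_capture = 1)
  pop <- clone_population(tibble::tibble(
    clone_id = "t", class_id = "target_binder", count = 1e5, spike = TRUE))
  set.seed(55)
  ests <- replicate(150, {
    r <- simulate_round(pop, cfg, classes1)
    display_efficiency(sum(r$data$input), sum(r$data$eluted))
  })
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - eff), 3 * se)
})

test_that("campaigns terminate with explicit status on extinction", {
  pop <- toy_pop(0, 0)
  camp <- run_campaign(pop, list(panning_config()), mode = "sample", seed = 1)
  expect_equal(camp$status, "extinct")
  expect_equal(nrow(camp$trajectory), 0)
})

test_that("campaigns are reproducible under a seed and expose tidy output", {
  sc <- make_scenario("egfp_campaign", scaled = TRUE)
  a <- run_scenario(sc, mode = "sample", seed = 19)
  b <- run_scenario(sc, mode = "sample", seed = 19)
  expect_identical(a$trajectory, b$trajectory)
  td <- tidy(a$rounds[[1]])
  expect_true(all(c("fraction", "count") %in% names(td)))
  expect_s3_class(glance(a), "tbl_df")
})
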