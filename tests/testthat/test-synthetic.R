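test_that("generators are pure functions of (config, seed)", {
  cfg <- generator_config(species = "P_mirabilis", n_cells = 40, seed = 99)
  expect_identical(gen_event_table(cfg), gen_event_table(cfg))
  cfg3 <- generator_config(n_cells = 30, seed = 5)
  expect_identical(gen_size_table(cfg3), gen_size_table(cfg3))
  truth <- list(b = 2, c = 0.2, d = 1, e = 600)
  expect_identical(gen_killcurve(truth, noise_sd = 0.02, seed = 8),
                   gen_killcurve(truth, noise_sd = 0.02, seed = 8))
  # different seeds genuinely differ
  expect_false(identical(gen_event_table(cfg),
                         gen_event_table(generator_config(species = "P_mirabilis",
                                                          n_cells = 40, seed = 100))))
  # generators leave the caller's RNG stream untouched
  set.seed(123); before <- runif(5)
  set.seed(123); invisible(gen_event_table(cfg)); after <- runif(5)
  expect_identical(before, after)
})

test_that("generated event tables satisfy the table invariants by construction", {
  for (seed in c(2, 17, 301)) {
    cfg <- generator_config(n_cells = 50, seed = seed)
    tab <- gen_event_table(cfg)
    # re-validating from a plain data frame exercises every invariant check
    expect_silent(event_table(as.data.frame(tab)))
    expect_true(all(tab$progeny_count >= 2))
    for (col in c("t_dnaN1", "t_release", "d_ftsZ")) {
      v <- tab[[col]]
      expect_true(all(v[!is.na(v)] > 0))
    }
    # missing events stay missing: no FtsZ duration in S. flexneri
    expect_true(all(is.na(tab$d_ftsZ[tab$species == "S_flexneri"])))
    expect_true(all(is.na(tab$t_parB3[tab$species == "P_mirabilis"])))
  }
})

test_that("event-time means are recovered across all species at n = 2000", {
  cfg <- generator_config(n_cells = 2000, seed = 12)
  tab <- gen_event_table(cfg)
  out <- summarize_events(tab)
  # events whose neighbours in the ordering chain sit within one marginal SD:
  # strict temporal ordering displaces their means by a small irreducible
  # amount (see the methods vignette), allowed for as 3 extra minutes
  tight <- c("t_parB2", "t_dnaN2", "t_parB3", "t_dnaN3", "t_parB4",
             "t_ftsZ1", "t_ftsZ2", "t_ftsZ3")
  for (sp in species_three) {
    p <- load_prey_params(sp)
    for (ev in names(p$event_timings)) {
      target <- p$event_timings[[ev]]
      got <- out[out$species == sp & out$event == ev, ]
      slack <- 3 * target$sd / sqrt(2000) + if (ev %in% tight) 3 else 0
      expect_lt(abs(got$mean - target$mean), slack,
                label = sprintf("|mean(%s, %s) - %g|", sp, ev, target$mean))
    }
  }
})

test_that("marginal spreads track the back-derived per-cell SDs", {
  cfg <- generator_config(n_cells = 10000, seed = 4)
  out <- summarize_events(gen_event_table(cfg))
  for (sp in species_three) {
    p <- load_prey_params(sp)
    for (ev in names(p$event_timings)) {
      ratio <- out[out$species == sp & out$event == ev, "sd"] /
        p$event_timings[[ev]]$sd
      # ordering enforcement and positivity compress the realized spread
      # below the normal-theory target; the scale must still be preserved
      expect_gt(ratio, 0.75, label = sprintf("sd ratio %s %s", sp, ev))
      expect_lt(ratio, 1.10, label = sprintf("sd ratio %s %s", sp, ev))
    }
  }
})

test_that("a perfectly shared tempo with equal SDs gives rigid schedules", {
  ov <- list(event_timings = list(
    t_dnaN1 = list(mean = 46, ci95_half = 4, n = 100),
    t_parB2 = list(mean = 69, ci95_half = 4, n = 100),
    t_dnaN2 = list(mean = 119, ci95_half = 4, n = 100),
    t_ftsZ1 = list(mean = 165, ci95_half = 4, n = 100),
    t_release = list(mean = 252, ci95_half = 4, n = 100),
    d_oric_migration = NULL, d_ftsZ = NULL, d_replication = NULL
  ))
  p <- load_prey_params("P_mirabilis", overrides = ov)
  cfg <- generator_config(species = "P_mirabilis", n_cells = 60, seed = 6,
                          tempo_share = 1)
  tab <- gen_event_table(cfg, params = p)
  gaps <- tab$t_release - tab$t_dnaN1
  expect_equal(max(gaps) - min(gaps), 0, tolerance = 1e-9)
  gaps2 <- tab$t_parB2 - tab$t_dnaN1
  expect_equal(max(gaps2) - min(gaps2), 0, tolerance = 1e-9)
})

test_that("impossible timing configurations abort with a rejection diagnostic", {
  ov <- list(event_timings = list(
    t_dnaN1 = list(mean = 1, ci95_half = 20, n = 100),
    t_release = list(mean = 1, ci95_half = 20, n = 100)
  ))
  p <- load_prey_params("P_mirabilis", overrides = ov)
  cfg <- generator_config(species = "P_mirabilis", n_cells = 50, seed = 1)
  expect_error(gen_event_table(cfg, params = p), "50%")
})

test_that("calibrate_noise inverts the linear-model correlation", {
  expect_equal(calibrate_noise(0.5, 1, 0.87), 0.5 * sqrt(1 / 0.7569 - 1),
               tolerance = 1e-6)
  expect_equal(calibrate_noise(0.5, 1, 0.87), 0.28336, tolerance = 1e-4)
  # limit: a target correlation approaching 1 needs vanishing noise
  expect_lt(calibrate_noise(0.5, 1, 0.999999), 1e-3)
  # scale equivariance in slope and predictor spread
  expect_equal(calibrate_noise(1, 2, 0.6), 4 * calibrate_noise(0.5, 1, 0.6))
  expect_error(calibrate_noise(0, 1, 0.87), "non-zero")
  expect_error(calibrate_noise(0.5, 1, 1.2), "between 0 and 1")
  expect_error(calibrate_noise(0.5, -1, 0.87), "> 0")
})

test_that("size tables hit the pooled correlation target", {
  cfg <- generator_config(n_cells = 100, seed = 1)
  st <- gen_size_table(cfg)
  expect_s3_class(st, "size_table")
  expect_equal(nrow(st), 300)
  expect_true(all(st$prey_length > 0 & st$bdelloplast_diameter > 0))
  r <- pearson_r(st$prey_length, st$bdelloplast_diameter)
  expect_equal(r, 0.87, tolerance = 0.05 / 0.87)  # within +/- 0.05

  # closed-form noise calibration verified by Monte Carlo at n = 1e5 per species
  big <- gen_size_table(generator_config(n_cells = 100000, seed = 2))
  r_big <- pearson_r(big$prey_length, big$bdelloplast_diameter)
  expect_lt(abs(r_big - 0.87), 0.01)
})

test_that("zero residual noise gives a perfect pooled correlation", {
  cfg <- generator_config(n_cells = 200, seed = 9, target_pooled_r = 0.999999)
  st <- gen_size_table(cfg)
  expect_gt(pearson_r(st$prey_length, st$bdelloplast_diameter), 0.999)
  cfg$size_model$slope <- 0
  expect_error(gen_size_table(cfg), "non-zero")
})

test_that("synthetic kill curves sit on the Bioscreen grid and recover truth", {
  truth <- list(b = 2, c = 0.2, d = 1, e = 600)
  kc <- gen_killcurve(truth)
  expect_equal(nrow(kc), 127)
  expect_equal(range(kc$time_min), c(0, 2520))
  expect_equal(kc$od600, weibull4(kc$time_min, truth$b, truth$c, truth$d, truth$e))

  fit <- fit_weibull4(gen_killcurve(truth, noise_sd = 0.01, seed = 3))
  for (par in c("b", "c", "d", "e")) {
    expect_equal(fit[[par]], truth[[par]], tolerance = 0.05)
  }
})

test_that("sampled event means stay inside the printed confidence intervals", {
  # coverage over 200 seeds at the published n = 100; the printed half-width
  # is ~2 standard errors, so per-seed coverage should be ~95%; 0.9 is a
  # conservative binomial lower bound at 200 draws
  p <- load_prey_params("P_mirabilis")
  events <- c("t_dnaN1", "t_ftsZ1", "d_ftsZ", "d_replication", "t_release")
  hits <- matrix(FALSE, 200, length(events), dimnames = list(NULL, events))
  for (s in 1:200) {
    tab <- gen_event_table(generator_config(species = "P_mirabilis",
                                            n_cells = 100, seed = s))
    for (ev in events) {
      tt <- p$event_timings[[ev]]
      hits[s, ev] <- abs(mean(tab[[ev]]) - tt$mean) < tt$ci95_half
    }
  }
  for (ev in events) {
    expect_gte(mean(hits[, ev]), 0.90)
  }
})
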