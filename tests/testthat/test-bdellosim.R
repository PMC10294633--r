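pm <- load_prey_params("P_mirabilis")

test_that("one step attacks, converts and releases in the right order", {
  s0 <- population_state(0L, 250, 2.1e7, 0, 4.2e8)
  s1 <- sim_step(s0, pm)
  expect_equal(s1$free_predators, 0)
  expect_equal(s1$bdelloplasts, 2.1e7)
  expect_equal(s1$unattacked_prey, 3.99e8)
  expect_equal(s1$t_min, 250)

  # release with no prey left
  s <- sim_step(population_state(0L, 250, 0, 1e6, 0), pm)
  expect_equal(s$free_predators, 2e6)
  expect_equal(s$bdelloplasts, 0)
  expect_equal(s$unattacked_prey, 0)

  # attachment capped at available prey (progeny mean 4)
  p4 <- load_prey_params("P_mirabilis",
                         overrides = list(progeny_pmf = list(`4` = 1)))
  s <- sim_step(population_state(0L, 250, 5, 0, 3), p4)
  expect_equal(s$free_predators, 2)
  expect_equal(s$bdelloplasts, 3)
  expect_equal(s$unattacked_prey, 0)
})

test_that("default runs terminate with every printed lysis time and state count", {
  traj <- simulate_predation(pm)
  expect_s3_class(traj, "predation_trajectory")
  expect_true(attr(traj, "terminated"))
  expect_equal(nrow(traj), 11)   # initial state + 10 steps
  expect_equal(complete_lysis_time(traj), 2500)
  final <- traj[nrow(traj), ]
  expect_equal(final$free_predators, 4.41e8)
  expect_equal(final$bdelloplasts, 0)
  expect_equal(final$unattacked_prey, 0)

  expect_equal(complete_lysis_time(simulate_predation(load_prey_params("S_enterica"))), 1740)
  expect_equal(complete_lysis_time(simulate_predation(load_prey_params("S_flexneri"))), 1520)
})

test_that("predator excess collapses the prey in exactly two steps", {
  for (sp in species_three) {
    p <- load_prey_params(sp)
    traj <- simulate_predation(p, initial_predators = 1e9, initial_prey = 1e8)
    expect_equal(nrow(traj), 3)  # states 0, 1, 2
    expect_equal(complete_lysis_time(traj), 2 * p$cycle_step_min)
  }
  p100 <- load_prey_params("P_mirabilis",
                           overrides = list(lifecycle = list(mean = 100, ci95_half = 7, n = 100)))
  expect_equal(complete_lysis_time(simulate_predation(p100, 10, 5)), 200)
})

test_that("trajectory invariants hold: time grid, positivity, prey conservation", {
  set.seed(5)
  for (i in 1:25) {
    p <- load_prey_params("S_enterica")
    traj <- simulate_predation(p,
                               initial_predators = runif(1, 1, 1e8),
                               initial_prey = runif(1, 1, 1e9))
    expect_equal(traj$t_min, traj$step * p$cycle_step_min)
    expect_true(all(traj$free_predators >= 0))
    expect_true(all(traj$bdelloplasts >= 0))
    expect_true(all(diff(traj$unattacked_prey) <= 0))
    # prey leave the unattacked pool exactly through bdelloplast formation
    consumed <- traj$unattacked_prey[1] - traj$unattacked_prey
    expect_equal(consumed, cumsum(c(0, traj$bdelloplasts[-1])), tolerance = 1e-12)
  }
})

test_that("terminated runs conserve cells: F_final = F0 + (p - 1) P0", {
  for (sp in species_three) {
    p <- load_prey_params(sp)
    f0 <- p$predator_inoculum
    p0 <- p$culture_volume_ml * p$cells_per_ml_at_od1
    traj <- simulate_predation(p)
    expect_equal(traj$free_predators[nrow(traj)], f0 + (p$progeny_mean - 1) * p0,
                 tolerance = 1e-9)
  }
})

test_that("lysis time is monotone in progeny mean, inoculum and prey load", {
  lysis <- function(pmean, f0, p0) {
    ov <- list(progeny_pmf = stats::setNames(list(1), as.character(pmean)))
    complete_lysis_time(simulate_predation(
      load_prey_params("P_mirabilis", overrides = ov),
      initial_predators = f0, initial_prey = p0))
  }
  set.seed(21)
  for (i in 1:15) {
    f0 <- runif(1, 1, 100)
    p0 <- runif(1, 50, 5000)
    pmean <- sample(2:7, 1)
    expect_lte(lysis(pmean + 1, f0, p0), lysis(pmean, f0, p0))
    expect_lte(lysis(pmean, f0 * 2, p0), lysis(pmean, f0, p0))
    expect_gte(lysis(pmean, f0, p0 * 2), lysis(pmean, f0, p0))
  }
})

test_that("non-termination is flagged, not silently truncated", {
  traj <- simulate_predation(pm, max_steps = 3L)
  expect_false(attr(traj, "terminated"))
  expect_equal(nrow(traj), 4)
  expect_error(complete_lysis_time(traj), "did not reach complete lysis")
})

test_that("recursion matches the naive brute-force simulator state for state", {
  set.seed(87)
  p_of <- function(pmean) load_prey_params(
    "P_mirabilis",
    overrides = list(progeny_pmf = stats::setNames(list(1), as.character(pmean))))
  for (i in 1:60) {
    f0 <- sample(1:50, 1)
    p0 <- sample(1:50, 1)
    pmean <- sample(2:8, 1)
    pars <- p_of(pmean)
    traj <- simulate_predation(pars, initial_predators = f0, initial_prey = p0)
    oracle <- brute_force_sim(f0, p0, pmean, pars$cycle_step_min)
    expect_equal(nrow(traj), nrow(oracle))
    expect_equal(traj$t_min, unname(oracle[, "t"]))
    expect_equal(traj$free_predators, unname(oracle[, "Fr"]))
    expect_equal(traj$bdelloplasts, unname(oracle[, "B"]))
    expect_equal(traj$unattacked_prey, unname(oracle[, "P"]))
  }
})

test_that("OD projection spans [od_floor, od_top] and matches the direct formula", {
  traj <- simulate_predation(pm)
  kc <- od_projection(traj, od_top = 0.9, od_floor = 0.1)
  expect_s3_class(kc, "kill_curve")
  expect_equal(kc$od600[1], 0.9)
  expect_equal(kc$od600[nrow(kc)], 0.1)
  expect_true(all(diff(kc$od600) <= 0))
  i <- 5L
  frac <- (traj$unattacked_prey[i] + traj$bdelloplasts[i]) / traj$unattacked_prey[1]
  expect_equal(kc$od600[i], 0.1 + 0.8 * frac)

  # resampling onto a 20-min grid interpolates between states
  grid <- od_projection(traj, od_top = 0.9, od_floor = 0.1,
                        times = seq(0, 2520, 20))
  expect_equal(nrow(grid), 127)
  expect_equal(grid$od600[grid$time_min == 2500], 0.1)
  # hand interpolation at t = 260 min, between the states at 250 and 500
  frac <- (traj$unattacked_prey + traj$bdelloplasts) / traj$unattacked_prey[1]
  f260 <- frac[2] + (260 - 250) / 250 * (frac[3] - frac[2])
  expect_equal(grid$od600[grid$time_min == 260], 0.1 + 0.8 * f260)

  expect_error(od_projection(traj, od_top = 0.1, od_floor = 0.9), "exceed")
})
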