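zero_noise_profile <- function(mu = 8) {
  list(setpoint_mu = mu, ou_sigma = 0.5, ou_tau = 2, circadian_amp = 0,
       glycation_offset = 0, wear_prob = 1)
}

test_that("a noiseless profile yields a constant trace at the setpoint", {
  prof <- zero_noise_profile(8)
  prof$ou_sigma <- 0  # degenerate: no OU variation
  # ou_sigma = 0 would make the innovation SD zero; the AR recursion then
  # pins the process at the setpoint regardless of the initial draw
  set.seed(1)
  sim <- simulate_trace(prof, as.Date("2020-01-01"), days = 2, interval_min = 60)
  expect_true(all(abs(sim$trace$glucose - 8) < 1e-12))
  expect_equal(sim$true_ag, 8)
  expect_equal(length(sim$trace$glucose), 48L)
})

test_that("trace simulation is seed-deterministic", {
  prof <- list(setpoint_mu = 9, ou_sigma = 2, ou_tau = 2, circadian_amp = 0.5,
               glycation_offset = 0, wear_prob = 0.9)
  set.seed(99); a <- simulate_trace(prof, as.Date("2020-01-01"), 5, 15)
  set.seed(99); b <- simulate_trace(prof, as.Date("2020-01-01"), 5, 15)
  expect_identical(a, b)
})

test_that("the OU component reproduces its stationary mean", {
  # oracle: the exact discretization of an OU process has stationary
  # distribution N(setpoint, ou_sigma^2); window means over many seeds
  # must straddle the setpoint
  prof <- list(setpoint_mu = 10.3, ou_sigma = 1.7, ou_tau = 2,
               circadian_amp = 0, glycation_offset = 0, wear_prob = 1)
  set.seed(5)
  means <- replicate(20, simulate_trace(prof, as.Date("2020-01-01"),
                                        days = 90, interval_min = 30)$true_ag)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 10.3), 3 * se + 1e-9)
  # stationary SD shows up in the readings themselves
  set.seed(6)
  tr <- simulate_trace(prof, as.Date("2020-01-01"), 90, 30)$trace
  expect_equal(sd(tr$glucose), 1.7, tolerance = 0.15)
})

test_that("outcome assignment follows the logistic link in setpoint", {
  cfg <- simulation_config(outcome_beta0 = 0.2, outcome_beta1 = 0)
  set.seed(3)
  draws <- replicate(2000, assign_outcome(zero_noise_profile(9), cfg)$group)
  p <- plogis(0.2)
  ci <- qbinom(c(0.005, 0.995), 2000, p) / 2000
  expect_gte(mean(draws == "case"), ci[1])
  expect_lte(mean(draws == "case"), ci[2])
  # beta0 -> -inf: no cases
  cfg0 <- simulation_config(outcome_beta0 = -50, outcome_beta1 = 0)
  set.seed(4)
  expect_true(all(replicate(200, assign_outcome(zero_noise_profile(9), cfg0)$group)
                  == "control"))
  # steep link: cases carry higher setpoints in every replicate
  cfg1 <- simulation_config(outcome_beta0 = -48, outcome_beta1 = 5)
  for (s in 1:5) {
    set.seed(s)
    prof <- replicate(300, draw_profile(cfg1), simplify = FALSE)
    grp <- vapply(prof, function(p) assign_outcome(p, cfg1)$group, character(1))
    mu <- vapply(prof, `[[`, numeric(1), "setpoint_mu")
    expect_gt(mean(mu[grp == "case"]), mean(mu[grp == "control"]))
  }
  # diagnosis dates fall in the final simulated year
  cfg2 <- simulation_config(outcome_beta0 = 50)
  set.seed(8)
  dd <- replicate(50, assign_outcome(zero_noise_profile(9), cfg2)$diagnosis_date)
  dd <- as.Date(dd, origin = "1970-01-01")
  expect_true(all(dd > cfg2$start_date + cfg2$horizon_days - 366))
  expect_true(all(dd <= cfg2$start_date + cfg2$horizon_days))
})

test_that("with zero noise, visit HbA1c equals the uGMI of the window AG", {
  cfg <- tiny_config(sigma_glycation = 0, hba1c_assay_sd = 0)
  set.seed(10)
  sim <- simulate_participant(cfg, "Z1")
  expect_equal(sim$record$visits$hba1c, ugmi(sim$truth$true_ag),
               tolerance = 1e-12)
  # hidden truth is recorded alongside the record
  expect_named(sim$truth, c("id", "profile", "true_ag", "p_case"))
  expect_equal(length(sim$truth$true_ag), nrow(sim$record$visits))
})

test_that("the HbA1c link is mean-zero over many participants", {
  cfg <- simulation_config(interval_min = 240, visits_min = 1, visits_max = 1)
  set.seed(12)
  gaps <- replicate(400, {
    sim <- simulate_participant(cfg)
    mean(sim$record$visits$hba1c - ugmi(sim$truth$true_ag))
  })
  # gap = glycation offset + assay noise, sd ~ sqrt(6^2 + 1.5^2)
  se <- sqrt(cfg$sigma_glycation^2 + cfg$hba1c_assay_sd^2) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps)), 3.5 * se)
})

test_that("cohort simulation hits exact quotas and is seed-reproducible", {
  cfg <- tiny_config()
  coh1 <- simulate_cohort(cfg, seed = 21)
  coh2 <- simulate_cohort(cfg, seed = 21)
  expect_identical(coh1, coh2)
  groups <- vapply(coh1$records, `[[`, character(1), "group")
  expect_equal(sum(groups == "case"), 6L)
  expect_equal(sum(groups == "control"), 8L)
  # every case is analyzable: at least one pre-diagnosis visit
  for (r in coh1$records) {
    if (r$group == "case") expect_true(any(r$visits$date < r$diagnosis_date))
  }
  coh3 <- simulate_cohort(cfg, seed = 22)
  expect_false(identical(coh1$records, coh3$records))
})

test_that("degenerate outcome coefficients abort with a diagnostic", {
  cfg <- tiny_config(outcome_beta0 = -50, outcome_beta1 = 0, max_draws = 50)
  expect_error(simulate_cohort(cfg, seed = 1), "rejection sampling")
})

test_that("with zero noise the aggregated HbA1c matches uGMI of the pooled AG", {
  # at the nominal 5-minute sampling the wear-thinning noise on the pooled
  # AG is well inside the window-vs-pool discretization budget
  cfg <- tiny_config(sigma_glycation = 0, hba1c_assay_sd = 0,
                     interval_min = 5, n_cases = 4, n_controls = 5)
  coh <- simulate_cohort(cfg, seed = 31)
  ft <- build_feature_table(coh$records)
  expect_lt(max(abs(ft$hba1c - ft$ugmi)), 0.2)
})

test_that("steeper outcome coefficients widen the case-control AG gap", {
  gap <- function(beta1, seed) {
    # rescale beta0 to hold prevalence near the calibrated level
    cfg <- tiny_config(n_cases = 10, n_controls = 10, outcome_beta1 = beta1,
                       outcome_beta0 = -beta1 * 9.63 - 0.24)
    coh <- simulate_cohort(cfg, seed = seed)
    ft <- build_feature_table(coh$records)
    mean(ft$ag[ft$outcome == 1]) - mean(ft$ag[ft$outcome == 0])
  }
  gaps <- vapply(1:4, function(s) c(gap(0.474, s), gap(2.5, s)), numeric(2))
  expect_gt(mean(gaps[2, ]), mean(gaps[1, ]))
})
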