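#' Configuration for the synthetic case-control cohort generator
#'
#' Defaults describe the study conditions the generator emulates: 71 cases
#' and 90 analyzable controls followed over a 3-year horizon, 2-5 clinic
#' visits per participant each carrying a 90-day CGM window at 5-minute
#' sampling, chronic glucose setpoints drawn from N(9.63, 1.7) mmol/l, and
#' an incident-retinopathy outcome driven by the setpoint through a
#' logistic link.  The logistic coefficients were calibrated once (by
#' numerical integration against the setpoint prior) so that the expected
#' case/control mean glucose is 10.3 / 9.1 mmol/l at prevalence 71/161.
#' Laboratory HbA1c is linked to each window's true mean glucose through
#' the uGMI transform plus a per-participant glycation offset
#' (`sigma_glycation`, default 6 mmol/mol, a typical glycation-gap spread)
#' and assay noise (`hba1c_assay_sd`, default 1.5 mmol/mol).
#'
#' @param n_cases,n_controls Target group sizes.
#' @param visits_min,visits_max Range of visits per participant.
#' @param window_days CGM window per visit, days.
#' @param interval_min Sampling interval, minutes.
#' @param horizon_days Simulated follow-up horizon, days.
#' @param setpoint_mean,setpoint_sd Population distribution of the chronic
#'   glucose setpoint, mmol/l (truncated to `[4, 20]`).
#' @param ou_sigma_mean,ou_sigma_sd Population distribution of the
#'   stationary within-participant glucose SD, mmol/l (truncated at 0.5).
#' @param ou_tau_hours Mean-reversion time of the Ornstein-Uhlenbeck
#'   component, hours.
#' @param circadian_amp_mean,circadian_amp_sd Population distribution of
#'   the 24-h sinusoid amplitude, mmol/l (truncated at 0).
#' @param wear_prob_min,wear_prob_max Uniform range of the per-participant
#'   probability that a scheduled reading is captured.
#' @param sigma_glycation SD of the per-participant glycation offset,
#'   mmol/mol.
#' @param hba1c_assay_sd Per-visit HbA1c assay SD, mmol/mol.
#' @param outcome_beta0,outcome_beta1 Logistic coefficients of
#'   `P(case) = plogis(beta0 + beta1 * setpoint)`.
#' @param start_date Calendar start of the simulation.
#' @param max_draws Cap on rejection-sampling draws before aborting.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cases = 71, n_controls = 90,
                              visits_min = 2, visits_max = 5,
                              window_days = 90, interval_min = 5,
                              horizon_days = 1095,
                              setpoint_mean = 9.63, setpoint_sd = 1.7,
                              ou_sigma_mean = 3.2, ou_sigma_sd = 1.0,
                              ou_tau_hours = 2,
                              circadian_amp_mean = 0.5, circadian_amp_sd = 0.2,
                              wear_prob_min = 0.75, wear_prob_max = 0.98,
                              sigma_glycation = 6, hba1c_assay_sd = 1.5,
                              outcome_beta0 = -4.836, outcome_beta1 = 0.474,
                              start_date = "2015-01-01",
                              max_draws = 60 * (n_cases + n_controls)) {
  stopifnot(n_cases > 0, n_controls > 0, visits_min >= 1,
            visits_max >= visits_min, window_days > 0, interval_min > 0,
            sigma_glycation >= 0, hba1c_assay_sd >= 0,
            setpoint_sd > 0, ou_sigma_sd >= 0,
            horizon_days > window_days + 365)
  cfg <- mget(names(formals(simulation_config)), envir = environment())
  cfg$start_date <- as.Date(start_date)
  structure(cfg, class = "simulation_config")
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Draw a participant profile from the population distributions
#'
#' @param config A [simulation_config()].
#' @return A list with `setpoint_mu`, `ou_sigma`, `ou_tau`, `circadian_amp`,
#'   `glycation_offset`, `wear_prob`.
#' @export
draw_profile <- function(config) {
  list(setpoint_mu = rtrunc_norm(1, config$setpoint_mean, config$setpoint_sd, 4, 20),
       ou_sigma = rtrunc_norm(1, config$ou_sigma_mean, config$ou_sigma_sd, 0.5),
       ou_tau = config$ou_tau_hours,
       circadian_amp = rtrunc_norm(1, config$circadian_amp_mean,
                                   config$circadian_amp_sd, 0),
       glycation_offset = stats::rnorm(1, 0, config$sigma_glycation),
       wear_prob = stats::runif(1, config$wear_prob_min, config$wear_prob_max))
}

#' Simulate one CGM wear window
#'
#' Exact discretization of an Ornstein-Uhlenbeck process around the
#' participant's setpoint (`x[t+1] = mu + phi (x[t] - mu) + innovation`,
#' `phi = exp(-dt/tau)`, stationary SD `ou_sigma`), plus a 24-hour sinusoid
#' of amplitude `circadian_amp`.  Each scheduled reading is independently
#' retained with probability `wear_prob`; values are clipped to the sensor
#' range 0.5-45 mmol/l.  Consumes the current RNG stream.
#'
#' @param profile A profile as returned by [draw_profile()].
#' @param start `Date` (or POSIXct) of the first scheduled reading.
#' @param days Window length in days.
#' @param interval_min Sampling interval in minutes.
#' @param participant_id Identifier stored in the returned trace.
#' @return A list with `trace` (a [cgm_trace()] of the retained readings)
#'   and `true_ag` (mean of the full, unthinned series: the latent chronic
#'   exposure over the window).
#' @export
simulate_trace <- function(profile, start, days = 90, interval_min = 5,
                           participant_id = "sim") {
  n <- as.integer(days * 1440 / interval_min)
  t0 <- as.POSIXct(as.Date(start), tz = "UTC")
  time <- t0 + (seq_len(n) - 1L) * interval_min * 60
  dt_h <- interval_min / 60
  phi <- exp(-dt_h / profile$ou_tau)
  z0 <- stats::rnorm(1)
  innov <- stats::rnorm(n, 0, sqrt(1 - phi^2))
  z <- as.numeric(stats::filter(innov, phi, method = "recursive", init = z0))
  tod_h <- (as.numeric(time - t0) / 3600 + 0) %% 24
  x <- profile$setpoint_mu + profile$ou_sigma * z +
    profile$circadian_amp * sin(2 * pi * tod_h / 24)
  rng <- glycemic_bands()$sensor
  x <- pmin(pmax(x, rng[1]), rng[2])
  keep <- stats::runif(n) < profile$wear_prob
  if (sum(keep) < 2L) keep[1:2] <- TRUE
  list(trace = cgm_trace(participant_id, time[keep], x[keep], interval_min,
                         quiet = TRUE),
       true_ag = mean(x))
}

#' Assign the case/control outcome for a profile
#'
#' `P(case) = plogis(beta0 + beta1 * setpoint_mu)`; cases receive a
#' diagnosis date uniform in the final simulated year.  Consumes the
#' current RNG stream.
#'
#' @param profile A profile as returned by [draw_profile()].
#' @param config A [simulation_config()].
#' @return A list with `group` (`"case"`/`"control"`) and `diagnosis_date`
#'   (`Date`, `NA` for controls).
#' @export
assign_outcome <- function(profile, config) {
  p <- stats::plogis(config$outcome_beta0 + config$outcome_beta1 * profile$setpoint_mu)
  if (stats::runif(1) < p) {
    offset <- stats::runif(1, 0, 365)
    list(group = "case",
         diagnosis_date = config$start_date + config$horizon_days -
           as.integer(floor(offset)))
  } else {
    list(group = "control", diagnosis_date = as.Date(NA))
  }
}

draw_visit_days <- function(config, k) {
  gap <- config$window_days + 1
  slack <- config$horizon_days - config$window_days - k * gap
  u <- sort(stats::runif(k, 0, slack))
  config$window_days + (seq_len(k) - 1L) * gap + u
}

#' Simulate one participant
#'
#' Draws a profile, assigns the outcome, schedules visits with
#' non-overlapping 90-day CGM windows across the horizon, simulates each
#' window, and links each visit's laboratory HbA1c to the window's true
#' mean glucose: `HbA1c = ugmi(true AG) + glycation_offset +
#' N(0, hba1c_assay_sd)`.  Post-diagnosis visits are simulated too, so the
#' censoring rule of [participant_aggregate()] is exercised.  Consumes the
#' current RNG stream.
#'
#' @param config A [simulation_config()].
#' @param id Identifier.
#' @return A list with `record` (a [participant_record()]) and `truth`
#'   (hidden parameters: the profile, per-visit true AG, and case
#'   probability).
#' @export
simulate_participant <- function(config, id = "sim") {
  profile <- draw_profile(config)
  outcome <- assign_outcome(profile, config)
  k <- if (config$visits_max > config$visits_min) {
    sample(seq(config$visits_min, config$visits_max), 1)
  } else config$visits_min
  visit_days <- draw_visit_days(config, k)
  visit_dates <- config$start_date + as.integer(floor(visit_days))
  windows <- lapply(visit_dates, function(d) {
    simulate_trace(profile, d - config$window_days, config$window_days,
                   config$interval_min, id)
  })
  true_ag <- vapply(windows, `[[`, numeric(1), "true_ag")
  hba1c <- ugmi(true_ag, "ifcc") + profile$glycation_offset +
    stats::rnorm(k, 0, config$hba1c_assay_sd)
  hba1c <- pmin(pmax(hba1c, 10), 240)  # keep within the valid assay range
  time <- do.call(c, lapply(windows, function(w) w$trace$time))
  glucose <- unlist(lapply(windows, function(w) w$trace$glucose))
  trace <- cgm_trace(id, time, glucose, config$interval_min, quiet = TRUE)
  record <- participant_record(id, outcome$group,
                               data.frame(date = visit_dates, hba1c = hba1c),
                               trace, outcome$diagnosis_date)
  truth <- list(id = id, profile = profile, true_ag = true_ag,
                p_case = stats::plogis(config$outcome_beta0 +
                                       config$outcome_beta1 * profile$setpoint_mu))
  list(record = record, truth = truth)
}

analyzable <- function(record) {
  if (record$group != "case") return(TRUE)
  any(record$visits$date < record$diagnosis_date)
}

#' Simulate a complete case-control cohort
#'
#' Rejection-samples participants until exactly `n_cases` analyzable cases
#' (at least one pre-diagnosis visit) and `n_controls` controls are
#' collected; participants beyond a filled quota are discarded.  The whole
#' dataset is reproducible from the seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed fixing the entire dataset.
#' @return An object of class `cohort_dataset`: a list with `records`,
#'   `truth` (hidden parameters, in record order), `config`, `seed`.
#' @export
#' @examples
#' coh <- simulate_cohort(simulation_config(n_cases = 3, n_controls = 4,
#'                                          interval_min = 60), seed = 1)
#' length(coh$records)
simulate_cohort <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(seed))
  records <- list(); truths <- list()
  got_case <- 0L; got_control <- 0L; draws <- 0L
  while (got_case < config$n_cases || got_control < config$n_controls) {
    draws <- draws + 1L
    if (draws > config$max_draws) {
      stop("rejection sampling exceeded ", config$max_draws, " draws (",
           got_case, "/", config$n_cases, " cases, ", got_control, "/",
           config$n_controls, " controls); outcome coefficients may be degenerate",
           call. = FALSE)
    }
    sim <- simulate_participant(config, sprintf("P%04d", draws))
    g <- sim$record$group
    if (!analyzable(sim$record)) next
    if (g == "case" && got_case < config$n_cases) {
      got_case <- got_case + 1L
    } else if (g == "control" && got_control < config$n_controls) {
      got_control <- got_control + 1L
    } else {
      next
    }
    records[[length(records) + 1L]] <- sim$record
    truths[[length(truths) + 1L]] <- sim$truth
  }
  structure(list(records = records, truth = truths, config = config,
                 seed = as.integer(seed)),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  groups <- vapply(x$records, `[[`, character(1), "group")
  cat("<cohort_dataset>", sum(groups == "case"), "cases /",
      sum(groups == "control"), "controls, seed", x$seed, "\n")
  invisible(x)
}
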