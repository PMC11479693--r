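# Seeded synthetic-data generators.
#
# Every stage of the pipeline has a generator producing inputs with the
# statistical structure the stage assumes: Fura-2-style traces (baseline +
# drift + Poisson-timed instant-rise/exponential-decay spikes + i.i.d.
# Gaussian noise), binomial cycle outcomes at configurable per-arm rates, and
# random ACMG evidence sets with known net points. All generators are
# deterministic given their seed.

#' Trace-simulation settings
#'
#' @param duration Recording length in hours (2 for a MOCA-like trace, 10 for
#'   HOCA-like).
#' @param dt Sampling interval in seconds.
#' @param baseline Resting ratio level (AU).
#' @param drift_per_hour Linear baseline drift (AU/h).
#' @param spike_rate Homogeneous Poisson event rate (spikes/hour) before
#'   refractory thinning.
#' @param refractory Minimum spacing between spikes in seconds; must exceed `dt`.
#' @param amplitude_mean,amplitude_sd Spike amplitude distribution (AU),
#'   Gaussian truncated to positive values.
#' @param decay_tau Exponential decay time constant of a spike (seconds).
#' @param noise_sd Additive Gaussian noise SD (AU).
#' @return An object of class `"trace_sim_params"`.
#' @export
trace_sim_params <- function(duration = 2, dt = 1, baseline = 1,
                             drift_per_hour = 0, spike_rate = 6,
                             refractory = 60, amplitude_mean = 2,
                             amplitude_sd = 0.2, decay_tau = 40,
                             noise_sd = 0.05) {
  if (duration <= 0 || dt <= 0 || decay_tau <= 0 || amplitude_mean <= 0) {
    stop_fertscreen("duration, dt, decay_tau, amplitude_mean must be positive")
  }
  if (spike_rate < 0 || noise_sd < 0 || amplitude_sd < 0) {
    stop_fertscreen("rates and SDs must be non-negative")
  }
  if (dt >= refractory) stop_fertscreen("dt must be smaller than refractory")
  structure(list(duration = duration, dt = dt, baseline = baseline,
                 drift_per_hour = drift_per_hour, spike_rate = spike_rate,
                 refractory = refractory, amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd, decay_tau = decay_tau,
                 noise_sd = noise_sd),
            class = "trace_sim_params")
}

#' Simulate a calcium trace with known ground truth
#'
#' Spike times are drawn from a homogeneous Poisson process thinned to the
#' refractory spacing (or taken verbatim from `spike_times`); each spike is an
#' instantaneous rise of its amplitude followed by exponential decay; i.i.d.
#' Gaussian noise is added on top of baseline and linear drift. The returned
#' ground truth enables parameter-recovery tests against [detect_spikes()].
#'
#' @param params A [trace_sim_params()].
#' @param seed Integer seed; identical seeds give bit-identical traces.
#' @param oocyte_id,assay Metadata for the generated [calcium_trace()].
#' @param spike_times Optional fixed spike schedule in seconds (overrides the
#'   Poisson draw).
#' @param amplitudes Optional fixed amplitudes paired with `spike_times`.
#' @return List with `trace` (a [calcium_trace()]) and `truth`
#'   (`data.frame(time, amplitude)`).
#' @export
simulate_trace <- function(params = trace_sim_params(), seed = 1,
                           oocyte_id = "sim", assay = c("MOCA", "HOCA"),
                           spike_times = NULL, amplitudes = NULL) {
  assay <- match.arg(assay)
  set.seed(seed)
  total_s <- params$duration * 3600
  times <- seq(0, total_s - params$dt, by = params$dt)
  if (is.null(spike_times)) {
    n_events <- stats::rpois(1, params$spike_rate * params$duration)
    cand <- sort(stats::runif(n_events, 0, total_s))
    spike_times <- numeric(0)
    for (tt in cand) {
      if (!length(spike_times) || tt - spike_times[length(spike_times)] >= params$refractory) {
        spike_times <- c(spike_times, tt)
      }
    }
  } else {
    spike_times <- sort(spike_times)
  }
  # snap spikes to the sampling grid so the instantaneous rise is observed
  spike_times <- times[pmin(length(times), floor(spike_times / params$dt) + 1L)]
  spike_times <- unique(spike_times)
  if (is.null(amplitudes)) {
    amplitudes <- abs(stats::rnorm(length(spike_times), params$amplitude_mean,
                                   params$amplitude_sd))
  } else if (length(amplitudes) != length(spike_times)) {
    stop_fertscreen("amplitudes must pair with spike_times")
  }
  v <- params$baseline + params$drift_per_hour * times / 3600
  for (j in seq_along(spike_times)) {
    after <- times >= spike_times[j]
    v[after] <- v[after] +
      amplitudes[j] * exp(-(times[after] - spike_times[j]) / params$decay_tau)
  }
  if (params$noise_sd > 0) {
    v <- v + stats::rnorm(length(v), 0, params$noise_sd)
  }
  list(trace = calcium_trace(times, v, oocyte_id, assay),
       truth = data.frame(time = spike_times, amplitude = amplitudes))
}

#' Cohort-simulation settings
#'
#' @param n_patients Patients per arm-indifferent roster (each patient has
#'   cycles in both arms).
#' @param cycles_per_patient Integer range `c(lo, hi)` of cycles per patient
#'   and arm.
#' @param mii_per_cycle Integer range of MII oocytes injected per cycle.
#' @param fert_rate Named per-arm fertilization probabilities,
#'   e.g. `c(ICSI = 0.11, ICSI_AOA = 0.62)`.
#' @param hcg_rate Named per-arm per-cycle positive-hCG probabilities.
#' @param lb_given_hcg Probability of live birth given a positive hCG.
#' @return An object of class `"cohort_sim_params"`.
#' @export
cohort_sim_params <- function(n_patients = 19,
                              cycles_per_patient = c(1L, 5L),
                              mii_per_cycle = c(4L, 20L),
                              fert_rate = c(ICSI = 0.11, ICSI_AOA = 0.62),
                              hcg_rate = c(ICSI = 0.11, ICSI_AOA = 0.60),
                              lb_given_hcg = 0.62) {
  rates <- c(fert_rate, hcg_rate, lb_given_hcg)
  if (any(rates < 0 | rates > 1)) stop_fertscreen("all rates must lie in [0, 1]")
  structure(list(n_patients = n_patients, cycles_per_patient = cycles_per_patient,
                 mii_per_cycle = mii_per_cycle, fert_rate = fert_rate,
                 hcg_rate = hcg_rate, lb_given_hcg = lb_given_hcg),
            class = "cohort_sim_params")
}

#' Simulate a two-arm cycle table
#'
#' Per cycle: `two_pn ~ Binomial(mii, fert_rate[arm])`, positive hCG
#' `~ Bernoulli(hcg_rate[arm])`, live birth `~ Bernoulli(lb_given_hcg)` given
#' a positive hCG. Blastocyst culture is left absent (the analysis treats it
#' as no-culture rows).
#'
#' @param params A [cohort_sim_params()].
#' @param seed Integer seed.
#' @return A cycle data.frame in the [read_cycle_table()] schema, one row per
#'   cycle (`n_cycles = 1`).
#' @export
simulate_cohort <- function(params = cohort_sim_params(), seed = 1) {
  set.seed(seed)
  # sample() treats a scalar first argument as 1:n; draw from the range safely
  draw_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)
  rows <- list()
  for (p in seq_len(params$n_patients)) {
    for (arm in c("ICSI", "ICSI_AOA")) {
      n_cyc <- draw_range(params$cycles_per_patient)
      for (cyc in seq_len(n_cyc)) {
        mii <- draw_range(params$mii_per_cycle)
        two_pn <- stats::rbinom(1, mii, params$fert_rate[[arm]])
        hcg <- stats::rbinom(1, 1, params$hcg_rate[[arm]])
        lb <- if (hcg == 1) stats::rbinom(1, 1, params$lb_given_hcg) else 0L
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sprintf("S%02d", p), arm = arm, n_cycles = 1L,
          mii = mii, two_pn = two_pn, blastocysts = NA_integer_,
          embryos_transferred = NA_integer_, transfer_day = NA_character_,
          hcg_positive = hcg,
          outcomes = if (lb == 1) "LB" else if (hcg == 1) "BP" else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate ACMG evidence sets with known net points
#'
#' Draws `n_variants` random criteria sets; each item's strength follows
#' `strength_distribution` and its direction is pathogenic with probability
#' `p_pathogenic`. The true net point total is returned per set for round-trip
#' tests of the classifier.
#'
#' @param n_variants Number of evidence sets.
#' @param items_per_variant Integer range of criteria per set.
#' @param strength_distribution Named probabilities over
#'   `supporting, moderate, strong, very_strong`; must sum to 1.
#' @param p_pathogenic Probability an item is pathogenic.
#' @param seed Integer seed.
#' @return List with `evidence` (named list of evidence lists) and
#'   `net_points` (named integer vector of true totals).
#' @export
simulate_evidence <- function(n_variants = 10, items_per_variant = c(0L, 6L),
                              strength_distribution = c(supporting = 0.4,
                                                        moderate = 0.3,
                                                        strong = 0.2,
                                                        very_strong = 0.1),
                              p_pathogenic = 0.7, seed = 1) {
  if (abs(sum(strength_distribution) - 1) > 1e-8) {
    stop_fertscreen("strength_distribution must sum to 1")
  }
  set.seed(seed)
  pts_of <- c(supporting = 1L, moderate = 2L, strong = 4L, very_strong = 8L)
  code_of <- function(direction, strength) {
    # representative codes per direction x strength
    if (direction == "pathogenic") {
      switch(strength, very_strong = "PVS1", strong = "PS3", moderate = "PM2",
             supporting = "PP3")
    } else {
      switch(strength, very_strong = "BS1", strong = "BS3", moderate = "BP4",
             supporting = "BP7")
    }
  }
  evidence <- list()
  totals <- integer(0)
  for (i in seq_len(n_variants)) {
    k <- sample(items_per_variant[1]:items_per_variant[2], 1)
    items <- list()
    total <- 0L
    if (k > 0) {
      for (j in seq_len(k)) {
        strength <- sample(names(strength_distribution), 1,
                           prob = strength_distribution)
        direction <- if (stats::runif(1) < p_pathogenic) "pathogenic" else "benign"
        items[[j]] <- evidence_item(code_of(direction, strength), direction,
                                    strength)
        total <- total + if (direction == "pathogenic") pts_of[[strength]] else -pts_of[[strength]]
      }
    }
    id <- sprintf("V%03d", i)
    evidence[[id]] <- items
    totals[id] <- total
  }
  list(evidence = evidence, net_points = totals)
}

#' Build an evidence set with a prescribed net point total
#'
#' Deterministic helper: expresses `points` as very-strong/strong/moderate/
#' supporting items (pathogenic for positive totals, benign for negative),
#' useful for reconstructing published point totals as classifiable evidence.
#'
#' @param points Signed integer net total.
#' @return List of [evidence_item()]s whose [net_points()] equals `points`.
#' @examples
#' net_points(evidence_for_points(7))  # 7
#' @export
evidence_for_points <- function(points) {
  stopifnot(is.numeric(points), length(points) == 1L, points == trunc(points))
  direction <- if (points >= 0) "pathogenic" else "benign"
  remaining <- abs(as.integer(points))
  strengths <- c(very_strong = 8L, strong = 4L, moderate = 2L, supporting = 1L)
  codes_p <- c(very_strong = "PVS1", strong = "PS3", moderate = "PM2",
               supporting = "PP3")
  codes_b <- c(very_strong = "BS1", strong = "BS3", moderate = "BP4",
               supporting = "BP7")
  items <- list()
  for (s in names(strengths)) {
    while (remaining >= strengths[[s]]) {
      code <- if (direction == "pathogenic") codes_p[[s]] else codes_b[[s]]
      items[[length(items) + 1L]] <- evidence_item(code, direction, s)
      remaining <- remaining - strengths[[s]]
    }
  }
  items
}
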