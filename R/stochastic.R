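#' Noise settings for the stochastic layers
#'
#' The model carries three stochastic layers, mirrored here by three
#' groups of settings: (1) truncated Gaussian white noise on
#' production/regulation rate constants - every secretion rate is
#' multiplied per step by `1 + sigma_production * xi` with `xi` standard
#' normal, truncated into `truncation` (relative bounds, default
#' `[0, 2]` i.e. `[0, 2 base]`); (2) sine-Wiener bounded noise on
#' proliferation and conversion rates - rates are multiplied by
#' `1 + sigma_rates * z(t)` with `z = sin(theta)`,
#' `dtheta = sqrt(2 / tau_n) dW`, so the perturbation never leaves
#' `[-1, 1]`; (3) Poisson jump events, configured separately via
#' [default_jump_processes()].
#'
#' @param sigma_production relative intensity of the truncated Gaussian
#'   layer (>= 0).
#' @param sigma_rates relative intensity of the bounded-noise layer
#'   (in `[0, 1]` so perturbed rates stay non-negative).
#' @param tau_n correlation time of the bounded noise, days.
#' @param truncation length-2 relative truncation bounds.
#' @return list of class `tme_noise`.
#' @export
tme_noise <- function(sigma_production = 0.1, sigma_rates = 0.15, tau_n = 5,
                      truncation = c(0, 2)) {
  stopifnot(sigma_production >= 0, sigma_rates >= 0, sigma_rates <= 1,
            tau_n > 0, length(truncation) == 2, truncation[1] <= truncation[2])
  structure(list(sigma_production = sigma_production,
                 sigma_rates = sigma_rates, tau_n = tau_n,
                 truncation = truncation),
            class = "tme_noise")
}

#' Default calibrated noise settings
#' @return a `tme_noise` with the shipped calibration.
#' @export
default_noise_spec <- function() tme_noise()

empty_jumps <- function() {
  tibble(id = character(), target = character(), source = character(),
         sign = character(), rate = numeric(), magnitude = numeric())
}

#' Jump processes: discrete stochastic events
#'
#' Builds the table of non-homogeneous Poisson jump processes. Each row
#' is one process: events arrive at `rate` per day (modulated by any
#' `recruitment` edges of the network that target the same cell), and
#' each event moves `1 + Poisson(magnitude - 1)` cells into `target`
#' (from `source` when given, conserving cell number; immigration when
#' `source` is `NA`). In the 1-ml control volume cell counts and
#' concentrations coincide numerically.
#'
#' The default set attaches jumps to microglia recruitment (immigration
#' driven by glioma-derived chemoattractants through the network's
#' recruitment edges) and to discrete stem-cell conversion events
#' (QSC to ASC activation bursts and ASC to GC seeding).
#'
#' @param spec a `tme_network`; jump targets are checked against it.
#' @return tibble with columns `id`, `target`, `source`, `sign`, `rate`
#'   (events/day), `magnitude` (mean cells per event).
#' @export
default_jump_processes <- function(spec = default_glioma_spec()) {
  j <- tibble(
    id = c("microglia_recruitment", "qsc_activation_burst", "asc_gc_seeding"),
    target = c("microglia", "ASC", "GC"),
    source = c(NA_character_, "QSC", "ASC"),
    sign = c("+", "+", "+"),
    rate = c(2, 1, 0.5),
    magnitude = c(1000, 20, 10))
  j <- j[j$target %in% cell_ids(spec) &
           (is.na(j$source) | j$source %in% cell_ids(spec)), ]
  j
}

#' Multiplicative truncated Gaussian perturbation of a rate
#'
#' One draw of the production-noise layer: `base * (1 + sigma * xi)`
#' truncated into `bounds` (absolute bounds on the perturbed rate,
#' default `[0, 2 base]`). With `sigma = 0` the base rate is returned
#' exactly.
#'
#' @param base basal rate (>= 0).
#' @param sigma relative noise intensity.
#' @param bounds length-2 absolute truncation bounds.
#' @param n number of draws.
#' @return numeric vector of perturbed rates.
#' @export
perturb_rate_truncated_gaussian <- function(base, sigma, bounds = c(0, 2 * base),
                                            n = 1) {
  stopifnot(base >= 0, sigma >= 0, length(bounds) == 2)
  pmin(pmax(base * (1 + sigma * stats::rnorm(n)), bounds[1]), bounds[2])
}

#' One step of sine-Wiener bounded noise
#'
#' Advances the bounded perturbation `z = sin(theta)` by integrating the
#' Brownian phase: `theta <- theta + sqrt(2 dt / tau_n) * xi`. The output
#' is confined to `[-1, 1]` for every step size and seed; its stationary
#' distribution is the arcsine law with mean zero. The effective rate is
#' applied as `base * (1 + sigma * z)`.
#'
#' @param theta current Brownian phase (use `asin(z)` to start from a
#'   given perturbation `z`).
#' @param dt step, days.
#' @param tau_n correlation time, days.
#' @return list with the updated `theta` and the perturbation `z`.
#' @export
bounded_noise_step <- function(theta, dt, tau_n) {
  stopifnot(dt > 0, tau_n > 0)
  theta <- theta + sqrt(2 * dt / tau_n) * stats::rnorm(length(theta))
  list(theta = theta, z = sin(theta))
}

#' Sample a non-homogeneous Poisson process by thinning
#'
#' Draws event times on `[t0, t1]` for an arrival-rate function
#' `lambda(t)` by thinning against a finite majorant `lambda_max`:
#' candidate events arrive at rate `lambda_max` and are accepted with
#' probability `lambda(t) / lambda_max`. When `lambda` does not depend on
#' past events the count is Poisson with mean `integral of lambda`.
#'
#' @param rate_function function of time returning events/day (>= 0).
#' @param t0,t1 interval, days.
#' @param lambda_max finite upper bound for `rate_function` on the interval.
#' @return list with `count` and sorted `times`.
#' @export
poisson_event_count <- function(rate_function, t0, t1, lambda_max) {
  if (!is.finite(lambda_max) || lambda_max <= 0) {
    if (identical(lambda_max, 0)) return(list(count = 0L, times = numeric()))
    stop("lambda_max must be finite and >= 0", call. = FALSE)
  }
  n_cand <- stats::rpois(1, lambda_max * (t1 - t0))
  if (n_cand == 0) return(list(count = 0L, times = numeric()))
  cand <- sort(stats::runif(n_cand, t0, t1))
  lam <- vapply(cand, rate_function, numeric(1))
  if (any(lam > lambda_max + 1e-12))
    stop("rate_function exceeds lambda_max", call. = FALSE)
  keep <- stats::runif(n_cand) < lam / lambda_max
  times <- cand[keep]
  list(count = length(times), times = times)
}

#' Integrate one stochastic realization
#'
#' Fixed-step hybrid advance of the full stochastic system: at every step
#' the noisy rates are refreshed (truncated Gaussian on secretion,
#' sine-Wiener bounded noise on proliferation/conversion), the
#' deterministic skeleton is advanced one classical Runge-Kutta step with
#' those rates frozen, Poisson jump events are applied, and negative
#' undershoots are clipped to zero. With all noise intensities zero and
#' no jump processes the result equals the deterministic `rk4`
#' trajectory at the same step size. Identical seeds give identical
#' trajectories.
#'
#' @param spec a validated `tme_network`.
#' @param t_span horizon, days.
#' @param patient optional `tme_patient`.
#' @param noise a `tme_noise` (default: shipped calibration).
#' @param jumps jump-process tibble (default: [default_jump_processes()]).
#' @param dt step, days. The per-step jump probability `lambda * dt`
#'   should stay below 0.1; a warning is issued otherwise.
#' @param seed integer seed for the run.
#' @param plan optional `tme_plan` therapy applied via its triggers.
#' @param record_every recording interval, days.
#' @return a `tme_trajectory`; metadata records seed, clip count, jump
#'   bookkeeping and therapy trigger times.
#' @export
integrate_stochastic <- function(spec, t_span = 365, patient = NULL,
                                 noise = default_noise_spec(),
                                 jumps = default_jump_processes(spec),
                                 dt = 0.01, seed = 1L, plan = NULL,
                                 record_every = 1) {
  if (t_span <= 0) stop("t_span must be > 0", call. = FALSE)
  m <- compile_model(spec, patient, noise, jumps)
  if (length(m$jump_rate) && max(m$jump_rate) * dt >= 0.1)
    warning("per-step jump probability lambda*dt >= 0.1; consider a smaller dt",
            call. = FALSE)
  therapy <- compile_therapy(m, plan, spec)
  set.seed(as.integer(seed))
  res <- engine_run(m, t_span, dt, max(1L, as.integer(round(record_every / dt))),
                    TRUE, therapy)
  meta <- list(spec_hash = spec_hash(spec), integrator = "rk4+noise",
               patient = if (is.null(patient)) "baseline" else patient$patient_id,
               seed = as.integer(seed), dt = dt, t_span = t_span,
               clip_count = res$clip_count,
               jump_added = stats::setNames(as.numeric(res$jump_added),
                                            m$jump_ids),
               jump_events = stats::setNames(as.numeric(res$jump_events),
                                             m$jump_ids),
               trigger_times = as.numeric(res$trigger_times),
               plan = if (is.null(plan)) NA_character_ else plan$plan_id,
               noise = unclass(noise))
  new_trajectory(res$time, res$states, m$species, meta)
}

derive_seeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a seeded Monte Carlo ensemble
#'
#' Runs `n_reps` stochastic realizations with per-run seeds derived
#' deterministically from `master_seed`, and summarizes them pointwise
#' (mean and 5/25/50/75/95% quantile bands per species) together with a
#' per-run endpoint table (activation, detection and saturation times,
#' plateau level).
#'
#' @inheritParams integrate_stochastic
#' @param n_reps number of replicates (>= 1).
#' @param master_seed master seed; per-run seeds are drawn from it.
#' @param detection_threshold passed to [detect_phases()].
#' @return object of class `tme_ensemble`: list with `trajectories`,
#'   `seeds`, `summary` (long tibble), `endpoints` (one row per run) and
#'   `master_seed`.
#' @export
run_ensemble <- function(spec, t_span = 365, patient = NULL,
                         noise = default_noise_spec(),
                         jumps = default_jump_processes(spec),
                         dt = 0.01, n_reps = 50, master_seed = 1L,
                         plan = NULL, record_every = 1,
                         detection_threshold = 1e6) {
  stopifnot(n_reps >= 1)
  seeds <- derive_seeds(master_seed, n_reps)
  trajs <- lapply(seeds, function(s)
    integrate_stochastic(spec, t_span, patient, noise, jumps, dt, s, plan,
                         record_every))
  summary <- summarise_trajectories(trajs)
  endpoints <- bind_rows(lapply(seq_along(trajs), function(i) {
    ph <- detect_phases(trajs[[i]], detection_threshold)
    mutate(ph, run = i, seed = seeds[i], .before = 1)
  }))
  structure(list(trajectories = trajs, seeds = seeds, summary = summary,
                 endpoints = endpoints, master_seed = as.integer(master_seed)),
            class = "tme_ensemble")
}

summarise_trajectories <- function(trajs) {
  long <- bind_rows(lapply(seq_along(trajs), function(i)
    mutate(tidyr::pivot_longer(as_tibble(trajs[[i]]), -"time",
                               names_to = "species", values_to = "value"),
           run = i)))
  long |>
    group_by(.data$time, .data$species) |>
    summarise(mean = mean(.data$value),
              q05 = stats::quantile(.data$value, 0.05, names = FALSE),
              q25 = stats::quantile(.data$value, 0.25, names = FALSE),
              q50 = stats::quantile(.data$value, 0.50, names = FALSE),
              q75 = stats::quantile(.data$value, 0.75, names = FALSE),
              q95 = stats::quantile(.data$value, 0.95, names = FALSE),
              .groups = "drop")
}

#' @export
print.tme_ensemble <- function(x, ...) {
  cat(sprintf("<tme_ensemble> %d runs, master seed %d, horizon %.0f days\n",
              length(x$trajectories), x$master_seed,
              max(x$trajectories[[1]]$time)))
  invisible(x)
}
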