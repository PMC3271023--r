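DAYS_PER_MONTH <- 30.4

#' Therapy building blocks: triggers, interventions, plans
#'
#' A trigger fires once, at a fixed time or at the first upward crossing
#' of a species threshold. An intervention multiplies a basal rate for
#' its duration (permanent by default): `apoptosis_multiplier` scales a
#' cell's decay rate (factor >= 1), `production_inhibition` /
#' `production_enhancement` scale all secretion rates of a cytokine
#' (factor <= 1 / >= 1), and `receptor_blockade` scales the K of every
#' edge sourced at a cytokine by the reciprocal of the remaining receptor
#' fraction (factor <= 1). A plan is a list of (trigger, interventions)
#' arms; interventions stacked on the same rate compose multiplicatively.
#'
#' @param species,threshold species id and density (cells/ml) for a
#'   threshold trigger.
#' @param time day for a fixed-time trigger.
#' @return trigger/intervention/plan objects consumed by
#'   [simulate_with_therapy()].
#' @export
trigger_threshold <- function(species, threshold) {
  stopifnot(threshold > 0)
  list(kind = "species_threshold", species = species, threshold = threshold)
}

#' @rdname trigger_threshold
#' @export
trigger_time <- function(time) {
  stopifnot(time >= 0)
  list(kind = "fixed_time", time = time)
}

#' @rdname trigger_threshold
#' @param kind intervention kind (see Description).
#' @param target species/cytokine id.
#' @param factor positive multiplier.
#' @export
intervention <- function(kind = c("apoptosis_multiplier", "production_inhibition",
                                  "receptor_blockade", "production_enhancement"),
                         target, factor) {
  kind <- match.arg(kind)
  stopifnot(factor > 0)
  if (kind %in% c("production_inhibition", "receptor_blockade") && factor > 1)
    stop("inhibition/blockade factor must be <= 1", call. = FALSE)
  if (kind %in% c("production_enhancement", "apoptosis_multiplier") && factor < 1)
    stop("enhancement/apoptosis factor must be >= 1", call. = FALSE)
  list(kind = kind, target = target, factor = factor)
}

#' @rdname trigger_threshold
#' @param plan_id identifier.
#' @param arms list of arms, each `list(trigger = , interventions = list(...),
#'   duration = Inf)`.
#' @export
tme_plan <- function(plan_id, arms) {
  structure(list(plan_id = plan_id, arms = arms), class = "tme_plan")
}

#' @export
print.tme_plan <- function(x, ...) {
  cat(sprintf("<tme_plan '%s'> %d arm(s)\n", x$plan_id, length(x$arms)))
  invisible(x)
}

#' Microglia depletion therapy plan
#'
#' One arm: when the glioma population first reaches `trigger_density`,
#' multiply the microglia apoptosis (decay) rate by `factor`,
#' permanently. The canonical stages are glioma densities of 5e4
#' (early), 2e5 (middle) and 1e6 cells/ml (late, the clinical detection
#' threshold), with a ten-fold apoptosis increase.
#'
#' @param trigger_density glioma density (cells/ml) at which to treat.
#' @param factor apoptosis multiplier (>= 1; 1 is a null therapy).
#' @param species glioma species id; `microglia` the depleted cell.
#' @return a `tme_plan`.
#' @export
microglia_depletion_plan <- function(trigger_density, factor = 10,
                                     species = "GC", microglia = "microglia") {
  tme_plan(sprintf("microglia_depletion_at_%g", trigger_density),
           list(list(trigger = trigger_threshold(species, trigger_density),
                     interventions = list(
                       intervention("apoptosis_multiplier", microglia, factor)),
                     duration = Inf)))
}

#' Cytokine (combination) blockade plan
#'
#' One arm: at the first upward crossing of `trigger_density` by the
#' glioma population, inhibit the production of every listed cytokine by
#' `inhibition_factor` (and/or blockade their receptors, per `mode`).
#' A single-element list gives a single-target therapy; an empty list is
#' a control.
#'
#' @param cytokine_ids character vector of cytokine ids.
#' @param inhibition_factor remaining production fraction (default 0.1,
#'   i.e. 90% inhibition).
#' @param trigger_density glioma density (cells/ml) at which to treat.
#' @param mode `"production"`, `"receptor"` or `"both"`.
#' @param spec network used to check the targets are cytokines.
#' @return a `tme_plan`.
#' @export
combination_plan <- function(cytokine_ids, inhibition_factor = 0.1,
                             trigger_density = 1e6,
                             mode = c("production", "receptor", "both"),
                             spec = NULL, species = "GC") {
  mode <- match.arg(mode)
  if (!is.null(spec)) {
    bad <- setdiff(cytokine_ids, cytokine_ids(spec))
    if (length(bad))
      stop("not cytokines in the network: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  ivs <- list()
  for (cy in cytokine_ids) {
    if (mode %in% c("production", "both"))
      ivs <- c(ivs, list(intervention("production_inhibition", cy, inhibition_factor)))
    if (mode %in% c("receptor", "both"))
      ivs <- c(ivs, list(intervention("receptor_blockade", cy, inhibition_factor)))
  }
  arms <- if (length(ivs))
    list(list(trigger = trigger_threshold(species, trigger_density),
              interventions = ivs, duration = Inf)) else list()
  tme_plan(sprintf("combination_%s", paste(cytokine_ids, collapse = "+")), arms)
}

#' Simulate a therapy against its paired control
#'
#' Runs the treated trajectory and an untreated control with the same
#' seed and noise stream, so any difference is attributable to the
#' therapy alone, and summarizes the outcome. The benefit metric follows
#' the stage of administration: when therapy fires before the control
#' reaches the detection threshold, benefit is the postponement of the
#' detection crossing; otherwise it is the change in the survival proxy
#' (time from `c_start` to `c_end`). Months are days / 30.4.
#'
#' @inheritParams integrate_stochastic
#' @param plan a `tme_plan`.
#' @param detection_threshold,objective_density detection (`c_start`) and
#'   objective (`c_end`) glioma densities, cells/ml.
#' @return list with `treated` and `control` trajectories and `outcome`,
#'   a one-row tibble (postponement in months, recurrence flag, survival
#'   proxies, trigger time).
#' @export
simulate_with_therapy <- function(spec, plan, t_span = 365, patient = NULL,
                                  noise = default_noise_spec(),
                                  jumps = default_jump_processes(spec),
                                  dt = 0.01, seed = 1L,
                                  detection_threshold = 1e6,
                                  objective_density = 1.5e7) {
  treated <- integrate_stochastic(spec, t_span, patient, noise, jumps, dt,
                                  seed, plan)
  control <- integrate_stochastic(spec, t_span, patient, noise, jumps, dt,
                                  seed, NULL)
  outcome <- outcome_row(treated, control, detection_threshold, objective_density)
  list(treated = treated, control = control, outcome = outcome)
}

surv_time <- function(traj, c_start, c_end, species = "GC") {
  t1 <- cross_time(traj$time, traj[[species]], c_start)
  t2 <- cross_time(traj$time, traj[[species]], c_end)
  if (is.na(t1) || is.na(t2)) NA_real_ else (t2 - t1) / DAYS_PER_MONTH
}

outcome_row <- function(treated, control, detection_threshold, objective_density,
                        species = "GC") {
  det_t <- cross_time(treated$time, treated[[species]], detection_threshold)
  det_c <- cross_time(control$time, control[[species]], detection_threshold)
  fire <- trajectory_meta(treated)$trigger_times[1]
  administered <- !is.na(fire)
  pre_detection <- administered && !is.na(det_c) && fire < det_c - 1e-9
  sp_t <- surv_time(treated, detection_threshold, objective_density, species)
  sp_c <- surv_time(control, detection_threshold, objective_density, species)
  horizon <- max(treated$time)
  postponement <- if (!administered) 0 else if (pre_detection) {
    ((if (is.na(det_t)) horizon else det_t) -
       (if (is.na(det_c)) horizon else det_c)) / DAYS_PER_MONTH
  } else {
    (ifelse(is.na(sp_t), (horizon - ifelse(is.na(det_t), horizon, det_t)) /
              DAYS_PER_MONTH, sp_t) -
       ifelse(is.na(sp_c), (horizon - ifelse(is.na(det_c), horizon, det_c)) /
                DAYS_PER_MONTH, sp_c))
  }
  tibble(administered = administered,
         trigger_day = fire,
         benefit_metric = if (!administered) "none" else
           if (pre_detection) "detection_postponement" else "survival_proxy_gain",
         postponement_months = postponement,
         detection_treated = det_t, detection_control = det_c,
         survival_proxy_treated = sp_t, survival_proxy_control = sp_c,
         recurrence_within_horizon = !is.na(det_t))
}

#' Compare treated and control ensembles
#'
#' Pairs runs by seed (ensembles must share `master_seed`) and summarizes
#' the therapy benefit: per-run postponement of the detection crossing
#' (runs where the treated tumor never reaches detection are credited
#' with the remaining horizon), its median and interquartile range in
#' months, and the fraction of treated runs with no recurrence within
#' the horizon.
#'
#' @param treated,control `tme_ensemble` objects run with identical seeds.
#' @return list with `per_run` (tibble) and `summary` (one-row tibble).
#' @export
compare_outcomes <- function(treated, control) {
  if (!identical(treated$seeds, control$seeds))
    stop("ensembles are not seed-paired; rerun with the same master_seed",
         call. = FALSE)
  horizon <- max(treated$trajectories[[1]]$time)
  per_run <- tibble(
    run = treated$endpoints$run,
    seed = treated$endpoints$seed,
    det_treated = treated$endpoints$detection_crossing_time,
    det_control = control$endpoints$detection_crossing_time) |>
    mutate(postponement_months =
             (ifelse(is.na(.data$det_treated), horizon, .data$det_treated) -
              ifelse(is.na(.data$det_control), horizon, .data$det_control)) /
             DAYS_PER_MONTH,
           no_recurrence = is.na(.data$det_treated))
  summary <- tibble(
    n = nrow(per_run),
    median_postponement_months = stats::median(per_run$postponement_months),
    iqr_lo = stats::quantile(per_run$postponement_months, 0.25, names = FALSE),
    iqr_hi = stats::quantile(per_run$postponement_months, 0.75, names = FALSE),
    no_recurrence_fraction = mean(per_run$no_recurrence))
  list(per_run = per_run, summary = summary)
}

#' Read or write a therapy plan file
#' @param path file path.
#' @return a `tme_plan` (for `load_plan`).
#' @export
load_plan <- function(path) {
  x <- yaml::read_yaml(path)
  num <- function(v) as.numeric(v)  # YAML "1.0e6" can arrive as character
  arms <- lapply(x$arms, function(a) {
    tr <- if (identical(a$trigger$kind, "fixed_time"))
      trigger_time(num(a$trigger$time))
    else trigger_threshold(a$trigger$species, num(a$trigger$threshold))
    ivs <- lapply(a$interventions, function(iv)
      intervention(iv$kind, iv$target, num(iv$factor)))
    list(trigger = tr, interventions = ivs,
         duration = num(a$duration %||% Inf))
  })
  tme_plan(x$plan_id, arms)
}

#' @rdname load_plan
#' @param plan a `tme_plan`.
#' @export
write_plan <- function(plan, path) {
  arms <- lapply(plan$arms, function(a) {
    out <- list(trigger = a$trigger,
                interventions = a$interventions)
    if (is.finite(a$duration %||% Inf)) out$duration <- a$duration
    out
  })
  writeLines(yaml::as.yaml(list(plan_id = plan$plan_id, arms = arms),
                           precision = 15), path)
  invisible(path)
}
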