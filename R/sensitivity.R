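#' Survival-proxy objective of a trajectory
#'
#' The length of time (months) taken by the glioma population to grow
#' from the detection threshold `c_start` to the objective density
#' `c_end`, both crossings linearly interpolated. A longer time reflects
#' a longer post-therapy survival. When either crossing is absent within
#' the horizon the objective is undefined and `NA` is returned.
#'
#' @param traj a `tme_trajectory`.
#' @param c_start,c_end glioma densities, cells/ml (`0 < c_start < c_end`).
#' @param species glioma species id.
#' @return months (numeric) or `NA` when undefined.
#' @export
survival_objective <- function(traj, c_start = 1e6, c_end = 1.5e7,
                               species = "GC") {
  stopifnot(c_start > 0, c_start < c_end)
  surv_time(traj, c_start, c_end, species)
}

# tumorigenesis time (months to first detection crossing): the fallback
# objective when the survival proxy is undefined for some run
tumorigenesis_time <- function(traj, c_start = 1e6, species = "GC") {
  t <- cross_time(traj$time, traj[[species]], c_start)
  if (is.na(t)) NA_real_ else t / DAYS_PER_MONTH
}

ensemble_objective <- function(spec, patient, mult, param_id, seeds, noise,
                               jumps, t_span, dt, c_start, c_end,
                               objective = c("survival_proxy", "tumorigenesis_time"),
                               statistic = stats::median) {
  objective <- match.arg(objective)
  spec2 <- if (is.null(param_id)) spec else
    apply_profile(spec, stats::setNames(mult, param_id))
  vals <- vapply(seeds, function(s) {
    tr <- integrate_stochastic(spec2, t_span, patient, noise, jumps, dt, s)
    if (objective == "survival_proxy") survival_objective(tr, c_start, c_end)
    else tumorigenesis_time(tr, c_start)
  }, numeric(1))
  vals
}

#' Sensitivity factor of one tunable parameter
#'
#' Local, normalized sensitivity of the survival-proxy objective to a
#' parameter multiplier, estimated by a central finite difference on the
#' ensemble statistic with common random numbers:
#' `S = (F(1 + delta) - F(1 - delta)) / (2 delta F(1))`, where `F` is the
#' ensemble median of the objective and all three ensembles share the
#' same per-run seeds. A negative `S` marks a pro-tumor parameter
#' (raising it shortens survival), so inhibition is expected to help.
#' When the survival proxy is undefined for any run the tumorigenesis
#' time is used instead for all three ensembles, and flagged.
#'
#' @inheritParams run_ensemble
#' @param param_id one tunable parameter id of `spec`.
#' @param delta relative perturbation (default 0.1).
#' @param c_start,c_end objective densities, cells/ml.
#' @return one-row tibble: `param_id`, `S`, `se` (Monte Carlo standard
#'   error of the per-run estimates), `delta`, `objective` used.
#' @export
sensitivity_factor <- function(spec, patient = NULL, param_id, delta = 0.1,
                               n_reps = 8, master_seed = 1L,
                               noise = default_noise_spec(),
                               jumps = default_jump_processes(spec),
                               t_span = 365, dt = 0.01,
                               c_start = 1e6, c_end = 1.5e7,
                               .base_cache = NULL) {
  stopifnot(delta > 0, delta < 1)
  if (!param_id %in% tunable_parameters(spec)$param_id)
    stop("not a tunable parameter: ", param_id, call. = FALSE)
  seeds <- derive_seeds(master_seed, n_reps)
  eval_all <- function(objective) {
    base <- if (!is.null(.base_cache) && !is.null(.base_cache[[objective]]))
      .base_cache[[objective]]
    else ensemble_objective(spec, patient, NULL, NULL, seeds,
                            noise, jumps, t_span, dt, c_start, c_end, objective)
    list(up = ensemble_objective(spec, patient, 1 + delta, param_id, seeds,
                                 noise, jumps, t_span, dt, c_start, c_end, objective),
         dn = ensemble_objective(spec, patient, 1 - delta, param_id, seeds,
                                 noise, jumps, t_span, dt, c_start, c_end, objective),
         base = base)
  }
  obj <- "survival_proxy"
  ev <- eval_all(obj)
  if (anyNA(c(ev$up, ev$dn, ev$base))) {
    obj <- "tumorigenesis_time"
    ev <- eval_all(obj)
  }
  if (anyNA(c(ev$up, ev$dn, ev$base)))
    return(tibble(param_id = param_id, S = NA_real_, se = NA_real_,
                  delta = delta, objective = "undefined"))
  F0 <- stats::median(ev$base)
  S <- (stats::median(ev$up) - stats::median(ev$dn)) / (2 * delta * F0)
  s_run <- (ev$up - ev$dn) / (2 * delta * F0)
  se <- stats::sd(s_run) / sqrt(length(s_run))
  tibble(param_id = param_id, S = S, se = se, delta = delta, objective = obj)
}

#' Full sensitivity profile of a patient
#'
#' Computes the sensitivity factor of every tunable parameter (29 on the
#' default glioma network) with shared seeds, and ranks them by signed
#' `S` (most negative - most pro-tumor - first). Deterministic given
#' `master_seed`.
#'
#' @inheritParams sensitivity_factor
#' @return object of class `tme_sensitivity`: tibble with one row per
#'   parameter (`param_id`, `S`, `se`, `delta`, `objective`, `rank`);
#'   attribute `patient_id`.
#' @export
sensitivity_profile <- function(spec, patient = NULL, delta = 0.1,
                                n_reps = 8, master_seed = 1L,
                                noise = default_noise_spec(),
                                jumps = default_jump_processes(spec),
                                t_span = 365, dt = 0.01,
                                c_start = 1e6, c_end = 1.5e7) {
  params <- tunable_parameters(spec)$param_id
  seeds <- derive_seeds(master_seed, n_reps)
  base_cache <- lapply(
    stats::setNames(nm = c("survival_proxy", "tumorigenesis_time")),
    function(obj) ensemble_objective(spec, patient, NULL, NULL, seeds,
                                     noise, jumps, t_span, dt, c_start, c_end,
                                     obj))
  rows <- lapply(params, function(p)
    sensitivity_factor(spec, patient, p, delta, n_reps, master_seed,
                       noise, jumps, t_span, dt, c_start, c_end,
                       .base_cache = base_cache))
  out <- bind_rows(rows) |>
    arrange(.data$S) |>
    mutate(rank = seq_len(n()))
  structure(out, class = c("tme_sensitivity", class(out)),
            patient_id = if (is.null(patient)) "baseline" else patient$patient_id,
            master_seed = as.integer(master_seed), n_reps = n_reps)
}

#' Design a combination therapy from a sensitivity profile
#'
#' Selects the `k` parameters with the most negative sensitivity factors
#' for inhibition (and optionally the most positive for enhancement).
#' Ties are broken by absolute sensitivity and then lexicographically by
#' parameter id; an all-zero profile yields a deterministic lexicographic
#' selection flagged as low confidence.
#'
#' @param report a `tme_sensitivity`.
#' @param k number of inhibition targets.
#' @param enhance_k number of enhancement targets (default 0).
#' @return tibble with `param_id`, `cytokine`, `kind`, `action`, `S`,
#'   `low_confidence`.
#' @export
design_combination <- function(report, k = 4, enhance_k = 0) {
  if (k + enhance_k > nrow(report))
    stop("k exceeds the number of tunable parameters", call. = FALSE)
  ord <- report[order(report$S, -abs(report$S), report$param_id), ]
  pick_inh <- utils::head(ord, k)
  pick_enh <- if (enhance_k > 0) utils::tail(ord, enhance_k)[enhance_k:1, ] else NULL
  out <- bind_rows(
    if (k > 0) mutate(pick_inh, action = "inhibit"),
    if (!is.null(pick_enh)) mutate(pick_enh, action = "enhance"))
  if (is.null(out) || nrow(out) == 0)
    return(tibble(param_id = character(), cytokine = character(),
                  kind = character(), action = character(), S = numeric(),
                  low_confidence = logical()))
  out |>
    mutate(kind = ifelse(substr(.data$param_id, 1, 1) == "p",
                         "production", "receptor"),
           cytokine = substr(.data$param_id, 3, nchar(.data$param_id)),
           low_confidence = all(report$S == 0, na.rm = TRUE)) |>
    select("param_id", "cytokine", "kind", "action", "S", "low_confidence")
}

#' Turn a designed target list into a therapy plan
#'
#' Inhibition targets become production inhibition or receptor blockade
#' (per the parameter kind) at `inhibition_factor`; enhancement targets
#' become production enhancement at `1 / inhibition_factor`.
#'
#' @param design tibble from [design_combination()].
#' @param inhibition_factor remaining fraction for inhibited targets.
#' @param trigger_density glioma density at which the plan fires.
#' @return a `tme_plan`.
#' @export
design_to_plan <- function(design, inhibition_factor = 0.1,
                           trigger_density = 1e6, species = "GC") {
  ivs <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    if (d$action == "inhibit") {
      if (d$kind == "production")
        intervention("production_inhibition", d$cytokine, inhibition_factor)
      else intervention("receptor_blockade", d$cytokine, inhibition_factor)
    } else intervention("production_enhancement", d$cytokine, 1 / inhibition_factor)
  })
  arms <- if (length(ivs))
    list(list(trigger = trigger_threshold(species, trigger_density),
              interventions = ivs, duration = Inf)) else list()
  tme_plan("designed_combination", arms)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy tme_sensitivity
#' @export
tidy.tme_sensitivity <- function(x, ...) {
  as_tibble(x)
}

#' @method glance tme_sensitivity
#' @export
glance.tme_sensitivity <- function(x, ...) {
  tibble(patient_id = attr(x, "patient_id"),
         n_params = nrow(x),
         n_negative = sum(x$S < 0, na.rm = TRUE),
         n_positive = sum(x$S > 0, na.rm = TRUE),
         top_negative = x$param_id[which.min(x$S)],
         master_seed = attr(x, "master_seed"))
}
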