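#' Parameter ranges for virtual-patient sampling
#'
#' Multiplier ranges for the tunable parameters of a network (cytokine
#' production rates `p_<id>` and receptor expression levels `r_<id>`).
#' Profiles are drawn uniformly on the stated scale (log by default, so
#' the median multiplier is the geometric midpoint).
#'
#' @param spec a `tme_network`.
#' @param lo,hi default range applied to every tunable parameter.
#' @param scale `"log"` or `"linear"`.
#' @return tibble with columns `param_id`, `lo`, `hi`, `scale`.
#' @export
parameter_ranges <- function(spec = default_glioma_spec(), lo = 0.5, hi = 2,
                             scale = c("log", "linear")) {
  scale <- match.arg(scale)
  stopifnot(lo > 0, lo <= hi)
  mutate(tunable_parameters(spec), lo = lo, hi = hi, scale = scale)
}

new_patient <- function(patient_id, multipliers, seed = NA_integer_,
                        provenance = "constructed") {
  structure(list(patient_id = patient_id, multipliers = multipliers,
                 seed = seed, provenance = provenance),
            class = "tme_patient")
}

#' @export
print.tme_patient <- function(x, ...) {
  cat(sprintf("<tme_patient '%s'> %d multipliers (seed %s)\n",
              x$patient_id, length(x$multipliers),
              ifelse(is.na(x$seed), "none", x$seed)))
  invisible(x)
}

#' Sample a virtual patient
#'
#' Draws one multiplier per tunable parameter, independently and
#' uniformly on the scale stated in `ranges`, reproducibly from `seed`.
#'
#' @param ranges a tibble from [parameter_ranges()].
#' @param seed integer seed.
#' @param patient_id identifier for the profile.
#' @return a `tme_patient`.
#' @export
sample_patient <- function(ranges, seed, patient_id = paste0("patient_seed", seed)) {
  stopifnot(all(ranges$lo > 0), all(ranges$lo <= ranges$hi))
  set.seed(as.integer(seed))
  u <- stats::runif(nrow(ranges))
  mult <- ifelse(ranges$scale == "log",
                 exp(log(ranges$lo) + u * (log(ranges$hi) - log(ranges$lo))),
                 ranges$lo + u * (ranges$hi - ranges$lo))
  new_patient(patient_id, stats::setNames(mult, ranges$param_id),
              seed = as.integer(seed), provenance = "sampled")
}

#' The baseline (all-ones) patient
#' @param spec a `tme_network`.
#' @return a `tme_patient` whose multipliers are all exactly 1.
#' @export
baseline_patient <- function(spec = default_glioma_spec()) {
  tp <- tunable_parameters(spec)
  new_patient("baseline", stats::setNames(rep(1, nrow(tp)), tp$param_id),
              provenance = "baseline")
}

#' Apply a patient profile to a network
#'
#' Production multipliers `p_<cytokine>` scale every basal secretion rate
#' of that cytokine; receptor multipliers `r_<cytokine>` scale the
#' half-saturation constant K of every edge sourced at that cytokine by
#' the reciprocal (higher receptor expression means a stronger response
#' at the same ligand level). The baseline profile leaves the network
#' numerically unchanged, and applying a profile followed by its
#' reciprocal restores the original network. Sampled patient profiles
#' carry strictly positive multipliers; a literal zero (a fully silenced
#' production or absent receptor) is accepted here for ablation
#' experiments.
#'
#' @param spec a `tme_network`.
#' @param profile a `tme_patient` (or a named numeric multiplier vector).
#' @return the modified `tme_network`.
#' @export
apply_profile <- function(spec, profile) {
  mult <- if (inherits(profile, "tme_patient")) profile$multipliers else profile
  if (any(mult < 0)) stop("multipliers must be >= 0", call. = FALSE)
  known <- tunable_parameters(spec)$param_id
  unknown <- setdiff(names(mult), known)
  if (length(unknown))
    stop("unknown parameter id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (pid in names(mult)) {
    kind <- substr(pid, 1, 1)
    cyt <- substr(pid, 3, nchar(pid))
    if (kind == "p") {
      rows <- spec$producers$cytokine == cyt
      spec$producers$rate[rows] <- spec$producers$rate[rows] * mult[[pid]]
    } else {
      rows <- spec$edges$source == cyt
      spec$edges$K[rows] <- spec$edges$K[rows] / mult[[pid]]
    }
  }
  spec
}

#' Invert a patient profile
#' @param profile a `tme_patient`.
#' @return a `tme_patient` with reciprocal multipliers.
#' @export
invert_profile <- function(profile) {
  new_patient(paste0(profile$patient_id, "_inverse"), 1 / profile$multipliers,
              provenance = "inverse")
}

#' Read or write a patient profile file
#'
#' Plain YAML: `patient_id`, `seed`, `provenance`, and a `multipliers`
#' map from parameter id to positive multiplier.
#'
#' @param path file path.
#' @return a `tme_patient` (for `load_patient`).
#' @export
load_patient <- function(path) {
  if (!file.exists(path)) stop("patient file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  mult <- unlist(x$multipliers)
  if (any(mult <= 0)) stop("patient multipliers must be > 0", call. = FALSE)
  new_patient(x$patient_id, mult,
              seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed),
              provenance = x$provenance %||% "file")
}

#' @rdname load_patient
#' @param profile a `tme_patient`.
#' @export
write_patient <- function(profile, path) {
  writeLines(yaml::as.yaml(list(
    patient_id = profile$patient_id, seed = profile$seed,
    provenance = profile$provenance,
    multipliers = as.list(profile$multipliers)), precision = 15), path)
  invisible(path)
}

#' The three shipped fixture patients
#'
#' Three reproducible virtual-patient profiles used by the therapy
#' examples. They are synthetic reconstructions: multipliers drawn with
#' fixed seeds from the default log-uniform ranges, standing in for
#' molecular profiles of individual patients.
#'
#' @param id 1, 2 or 3.
#' @return a `tme_patient`.
#' @export
fixture_patient <- function(id) {
  stopifnot(id %in% 1:3)
  path <- system.file("extdata", sprintf("patient%d.yaml", id),
                      package = "gliomaTME", mustWork = TRUE)
  load_patient(path)
}
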