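#' Classify cytokine temporal traces
#'
#' Assigns each cytokine trace of an ensemble (or single trajectory) to
#' one of three temporal classes observed in glioma microenvironment
#' dynamics: `early-peak` (global maximum before the glioma detection
#' crossing, followed by a decline of at least `decline_tol` of the
#' peak), `monotone-increase` (normalized trace non-decreasing within
#' `monotone_tol` of its range), and `phase-correlated` (everything
#' else: rapid rise during the expansion phase to a quasi-steady level).
#'
#' @param x a `tme_ensemble` (classification on the ensemble mean) or a
#'   `tme_trajectory`.
#' @param detection_threshold glioma detection density, cells/ml.
#' @param species glioma species id.
#' @param decline_tol fractional decline from the peak that counts as a
#'   peak-then-decline shape (default 0.10).
#' @param monotone_tol allowed fractional dip for the monotone class.
#' @return tibble with columns `species`, `class`, `peak_time`,
#'   `final_over_peak`.
#' @export
classify_cytokine_traces <- function(x, detection_threshold = 1e6,
                                     species = "GC", decline_tol = 0.10,
                                     monotone_tol = 0.02) {
  if (inherits(x, "tme_ensemble")) {
    wide <- x$summary |>
      select("time", "species", "mean") |>
      tidyr::pivot_wider(names_from = "species", values_from = "mean")
    spec_order <- unique(x$summary$species)
    wide <- wide[, c("time", spec_order)]
    cyts <- setdiff(names(wide), c("time", cell_like_columns(wide)))
  } else {
    wide <- as_tibble(x)
    cyts <- setdiff(names(wide), c("time", cell_like_columns(wide)))
  }
  det <- cross_time(wide$time, wide[[species]], detection_threshold)
  rows <- lapply(cyts, function(cy) {
    v <- wide[[cy]]
    rng <- max(v) - min(v)
    if (rng <= 0)
      return(tibble(species = cy, class = "monotone-increase",
                    peak_time = NA_real_, final_over_peak = 1))
    peak_i <- which.max(v)
    peak_t <- wide$time[peak_i]
    fin <- v[length(v)] / v[peak_i]
    early_peak <- !is.na(det) && peak_t < det && fin <= 1 - decline_tol
    monotone <- all(diff(v) >= -monotone_tol * rng)
    cls <- if (early_peak) "early-peak"
           else if (monotone) "monotone-increase"
           else "phase-correlated"
    tibble(species = cy, class = cls, peak_time = peak_t, final_over_peak = fin)
  })
  bind_rows(rows)
}

# heuristics only used to split trajectory columns into cells vs cytokines
# for classification display: cells are the columns named in the meta, or
# the canonical five when present
cell_like_columns <- function(wide) {
  canonical <- c("QSC", "ASC", "GC", "astrocyte", "microglia")
  intersect(names(wide), canonical)
}

#' Export a trajectory as CSV with a metadata sidecar
#'
#' Writes `time_days` plus one column per species, and a YAML sidecar
#' (`<path>.meta.yaml`) with the provenance needed to re-run it exactly:
#' spec hash, integrator, step, seed, patient, therapy plan. The CSV
#' number format is fixed (15 significant digits) so identical runs give
#' bitwise-identical files.
#'
#' @param traj a `tme_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  names(df)[1] <- "time_days"
  for (j in seq_along(df)) df[[j]] <- sprintf("%.15g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- trajectory_meta(traj)
  meta_clean <- lapply(meta, function(v) if (is.numeric(v)) as.list(v) else v)
  writeLines(yaml::as.yaml(meta_clean, precision = 15),
             paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Export an ensemble: per-run CSVs, a summary CSV and an endpoint table
#'
#' @param ens a `tme_ensemble`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return `dir`, invisibly.
#' @export
write_ensemble_csv <- function(ens, dir, prefix = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ens$trajectories))
    write_trajectory_csv(ens$trajectories[[i]],
                         file.path(dir, sprintf("%s_%03d.csv", prefix, i)))
  utils::write.csv(as.data.frame(ens$summary),
                   file.path(dir, paste0(prefix, "_summary.csv")),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(ens$endpoints),
                   file.path(dir, paste0(prefix, "_endpoints.csv")),
                   row.names = FALSE)
  invisible(dir)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trajectory
#'
#' Cell populations on a log10 axis, cytokines on a linear axis, faceted
#' by role.
#' @param object a `tme_trajectory`.
#' @param ... unused.
#' @method autoplot tme_trajectory
#' @export
autoplot.tme_trajectory <- function(object, ...) {
  cells <- cell_like_columns(object)
  long <- tidyr::pivot_longer(as_tibble(object), -"time",
                              names_to = "species", values_to = "value") |>
    mutate(role = ifelse(.data$species %in% cells, "cells (/ml)",
                         "cytokines (pg/ml)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time / DAYS_PER_MONTH,
                                     y = .data$value,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~role, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (months)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ensemble quantile bands
#' @param object a `tme_ensemble`.
#' @param species which species to show (default the glioma population).
#' @param ... unused.
#' @method autoplot tme_ensemble
#' @export
autoplot.tme_ensemble <- function(object, species = "GC", ...) {
  d <- filter(object$summary, .data$species %in% !!species)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time / DAYS_PER_MONTH)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                         alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$q50)) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (months)", y = "concentration") +
    ggplot2::theme_minimal()
}

#' Sensitivity landscape bar chart
#' @param object a `tme_sensitivity`.
#' @param ... unused.
#' @method autoplot tme_sensitivity
#' @export
autoplot.tme_sensitivity <- function(object, ...) {
  d <- mutate(as_tibble(object),
              param_id = stats::reorder(.data$param_id, .data$S))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$param_id, y = .data$S,
                                  fill = .data$S < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$S - .data$se,
                                        ymax = .data$S + .data$se),
                           width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "sensitivity factor S") +
    ggplot2::theme_minimal()
}
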