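#' Hill response function
#'
#' Saturating response `c^n / (K^n + c^n)`: 0 at `c = 0`, 1/2 at `c = K`,
#' approaching 1 as `c` grows. The building block of every cytokine
#' modulation in the model.
#'
#' @param c ligand concentration (>= 0); vectorized.
#' @param K half-saturation concentration (> 0).
#' @param n Hill coefficient (> 0).
#' @return numeric in `[0, 1)`.
#' @export
hill_response <- function(c, K, n) {
  if (any(c < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (any(K <= 0) || any(n <= 0)) stop("K and n must be > 0", call. = FALSE)
  cn <- c^n
  cn / (K^n + cn)
}

#' Rate modulation factor of a pathway edge
#'
#' Maps a Hill response onto a multiplicative rate factor. An up-edge with
#' amplitude `a >= 1` scales a rate by `1 + (a - 1) h(c)` (range
#' `[1, a]`); a down-edge with residual fraction `a` in `[0, 1]` scales it
#' by `1 - (1 - a) h(c)` (range `(a, 1]`). At `c = 0` both return 1.
#'
#' @param c ligand concentration.
#' @param hill list with elements `K`, `n`, `a`.
#' @param direction `"up"` or `"down"`.
#' @return positive numeric factor.
#' @export
modulation_factor <- function(c, hill, direction = c("up", "down")) {
  direction <- match.arg(direction)
  h <- hill_response(c, hill$K, hill$n)
  if (direction == "up") {
    if (hill$a < 1) stop("up-edge amplitude must be >= 1", call. = FALSE)
    1 + (hill$a - 1) * h
  } else {
    if (hill$a < 0 || hill$a > 1) stop("down-edge amplitude must be in [0, 1]", call. = FALSE)
    1 - (1 - hill$a) * h
  }
}

#' Logistic crowding factor
#'
#' `max(0, 1 - c_total / c_bar)`: the shared-space competition term that
#' slows proliferation as the total cell density approaches the
#' saturating concentration `c_bar`.
#'
#' @param c_total total cell density over all populations (cells/ml).
#' @param c_bar saturating concentration (cells/ml, > 0).
#' @return numeric in `[0, 1]`.
#' @export
logistic_factor <- function(c_total, c_bar) {
  if (any(c_bar <= 0)) stop("c_bar must be > 0", call. = FALSE)
  pmax(0, 1 - c_total / c_bar)
}

#' Angiogenesis factor
#'
#' Vascular-support multiplier on glioma proliferation:
#' `A_min + (1 - A_min) h(c_driver; K, n)` where the driver cytokine is
#' VEGF in the default network. Ranges from the avascular floor `A_min`
#' (no driver) to 1 (saturating driver).
#'
#' @param state named numeric state vector (or a one-row trajectory slice).
#' @param params list with `driver`, `A_min`, `K`, `n`.
#' @return numeric in `[A_min, 1]`.
#' @export
angiogenesis_factor <- function(state, params) {
  if (!params$driver %in% names(state))
    stop("angiogenesis driver '", params$driver, "' not present in state", call. = FALSE)
  params$A_min + (1 - params$A_min) *
    hill_response(unname(state[[params$driver]]), params$K, params$n)
}

#' Assemble the deterministic right-hand side of the coupled system
#'
#' Builds the derivative function of the full cell-cytokine system. Per
#' cell population: net conversion flux, plus logistic proliferation
#' (basal rate times the product of its up/down modulation factors, the
#' crowding factor and - for angiogenesis-dependent cells - the
#' angiogenesis factor), minus modulated decay. Per cytokine: the sum of
#' modulated per-cell secretion terms minus first-order decay at rate
#' `ln 2 / half_life`. The returned closure is pure R and serves both the
#' adaptive integrator and as an independent cross-check of the compiled
#' engine.
#'
#' @param spec a validated `tme_network`.
#' @param patient optional `tme_patient` profile applied before assembly.
#' @return function `(t, state)` returning the named derivative vector;
#'   the attribute `"species"` carries the state ordering.
#' @export
assemble_rhs <- function(spec, patient = NULL) {
  m <- compile_model(spec, patient)
  n_sp <- length(m$species); n_cell <- m$n_cell
  i_cell <- seq_len(n_cell)
  i_cyt <- seq.int(n_cell + 1L, n_sp)
  e_src <- m$edge_src + 1L; c_src <- m$conv_src + 1L; c_dst <- m$conv_dst + 1L
  p_cell <- m$prod_cell + 1L; p_cyt <- m$prod_cyt + 1L
  Kn <- m$edge_K^m$edge_n

  rhs <- function(t, state) {
    state <- pmax(as.numeric(state), 0)
    cn <- state[e_src]^m$edge_n
    h <- ifelse(cn > 0, cn / (Kn + cn), 0)
    mod <- ifelse(m$edge_dir > 0, 1 + (m$edge_a - 1) * h, 1 - (1 - m$edge_a) * h)

    mp <- rep(1, n_cell); mdc <- rep(1, n_cell); mdy <- rep(1, n_sp - n_cell)
    mpr <- rep(1, length(m$prod_rate)); mcv <- rep(1, length(m$conv_rate))
    for (e in seq_along(mod)) {
      tt <- m$edge_ttype[e]; ti <- m$edge_tidx[e] + 1L
      if (tt == 0L) mp[ti] <- mp[ti] * mod[e]
      else if (tt == 1L) {
        if (ti <= n_cell) mdc[ti] <- mdc[ti] * mod[e]
        else mdy[ti - n_cell] <- mdy[ti - n_cell] * mod[e]
      }
      else if (tt == 2L) mpr[ti] <- mpr[ti] * mod[e]
      else if (tt == 3L) mcv[ti] <- mcv[ti] * mod[e]
    }

    total <- sum(state[i_cell])
    hA <- hill_response(state[m$angio_driver + 1L], m$angio_K, m$angio_n)
    A <- m$angio_min + (1 - m$angio_min) * hA
    ang <- ifelse(m$angio_dep == 1L, A, 1)
    L <- pmax(0, 1 - total / m$cbar)

    d <- numeric(n_sp)
    d[i_cell] <- m$prolif * mp * L * ang * state[i_cell] - m$decay * mdc * state[i_cell]
    if (length(m$conv_rate)) {
      flux <- m$conv_rate * mcv * state[c_src]
      for (k in seq_along(flux)) {
        d[c_dst[k]] <- d[c_dst[k]] + flux[k]
        d[c_src[k]] <- d[c_src[k]] - flux[k]
      }
    }
    d[i_cyt] <- -m$cyt_decay * mdy * state[i_cyt]
    if (length(m$prod_rate)) {
      prod <- m$prod_rate * mpr * state[p_cell]
      for (p in seq_along(prod)) {
        j <- n_cell + p_cyt[p]
        d[j] <- d[j] + prod[p]
      }
    }
    stats::setNames(d, m$species)
  }
  attr(rhs, "species") <- m$species
  attr(rhs, "model") <- m
  rhs
}

new_trajectory <- function(time, states, species, meta) {
  tb <- as_tibble(as.data.frame(states))
  names(tb) <- species
  tb <- bind_cols(tibble(time = time), tb)
  structure(tb, class = c("tme_trajectory", class(tb)), meta = meta)
}

#' @export
print.tme_trajectory <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<tme_trajectory> %d samples over %.1f days (%s)\n",
              nrow(x), max(x$time), meta$integrator %||% "?"))
  NextMethod()
}

#' Trajectory metadata
#' @param traj a `tme_trajectory`.
#' @return list of provenance fields (spec hash, integrator, step, seed, ...).
#' @export
trajectory_meta <- function(traj) attr(traj, "meta")

#' Integrate the deterministic system
#'
#' Integrates the noise-free coupled ODE system with either the compiled
#' fixed-step classical Runge-Kutta scheme (`"rk4"`) or the adaptive
#' Dormand-Prince 5(4) method (`"dp5"`, via \pkg{deSolve}'s `ode45` on the
#' R-side derivative). Undershoots below zero are clipped to zero; the
#' clip count is recorded in the metadata.
#'
#' @param spec a validated `tme_network`.
#' @param t_span horizon in days.
#' @param patient optional `tme_patient`.
#' @param method `"rk4"` (fixed step `dt`) or `"dp5"` (adaptive, `rtol`).
#' @param dt fixed step in days (rk4).
#' @param rtol,atol adaptive tolerances (dp5).
#' @param record_every recording interval in days.
#' @return a `tme_trajectory` tibble: column `time` plus one column per
#'   species, cells first.
#' @export
integrate_deterministic <- function(spec, t_span = 365, patient = NULL,
                                    method = c("rk4", "dp5"), dt = 0.01,
                                    rtol = 1e-8, atol = 1e-6,
                                    record_every = 1) {
  method <- match.arg(method)
  if (t_span <= 0) stop("t_span must be > 0", call. = FALSE)
  m <- compile_model(spec, patient)
  meta <- list(spec_hash = spec_hash(spec), integrator = method,
               patient = if (is.null(patient)) "baseline" else patient$patient_id,
               seed = "deterministic", dt = dt, t_span = t_span)
  if (method == "rk4") {
    res <- engine_run(m, t_span, dt, max(1L, as.integer(round(record_every / dt))),
                      FALSE, list())
    if (res$clip_count > 0)
      warning("integrator clipped ", res$clip_count,
              " negative undershoot(s) to zero", call. = FALSE)
    meta$clip_count <- res$clip_count
    new_trajectory(res$time, res$states, m$species, meta)
  } else {
    rhs <- assemble_rhs(spec, patient)
    f <- function(t, y, parms) list(unname(rhs(t, y)))
    times <- seq(0, t_span, by = record_every)
    sol <- deSolve::ode(y = stats::setNames(m$init, m$species), times = times,
                        func = f, parms = NULL, method = "ode45",
                        rtol = rtol, atol = atol)
    states <- pmax(unclass(sol)[, -1, drop = FALSE], 0)
    meta$rtol <- rtol
    new_trajectory(sol[, 1], states, m$species, meta)
  }
}

# first upward crossing of `threshold`, linearly interpolated; NA if none
cross_time <- function(time, values, threshold) {
  above <- values >= threshold
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(time[1])
  t0 <- time[i - 1]; t1 <- time[i]
  v0 <- values[i - 1]; v1 <- values[i]
  if (v1 == v0) return(t1)
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

#' Detect the growth phases of a trajectory
#'
#' Reports the characteristic times of the three-phase glioma growth
#' pattern: completion of stem-cell activation (activated fraction
#' ASC/(QSC+ASC) first reaching `activation_fraction`), first upward
#' crossing of the clinical detection threshold by the glioma population,
#' and saturation (first time the glioma population reaches 95% of its
#' late-time plateau, estimated as the mean over the last
#' `plateau_window` days). Crossing times are linearly interpolated
#' between samples; absent crossings are reported as `NA`.
#'
#' @param traj a `tme_trajectory`.
#' @param detection_threshold clinical detection density, cells/ml.
#' @param species glioma species id.
#' @param qsc,asc stem-cell species ids.
#' @param activation_fraction activated fraction defining completion.
#' @param plateau_window days at the end of the horizon over which the
#'   plateau level is averaged.
#' @return one-row tibble (class `tme_phases`): `activation_complete_time`,
#'   `detection_crossing_time`, `saturation_time`, `plateau_level` and the
#'   phase windows in days.
#' @export
detect_phases <- function(traj, detection_threshold = 1e6, species = "GC",
                          qsc = "QSC", asc = "ASC",
                          activation_fraction = 0.85, plateau_window = 30) {
  t <- traj$time
  gc <- traj[[species]]
  act <- if (all(c(qsc, asc) %in% names(traj))) {
    tot <- traj[[qsc]] + traj[[asc]]
    frac <- ifelse(tot > 0, traj[[asc]] / tot, 0)
    cross_time(t, frac, activation_fraction)
  } else NA_real_
  det <- cross_time(t, gc, detection_threshold)
  tail_idx <- t >= max(t) - plateau_window
  plateau <- mean(gc[tail_idx])
  sat <- if (plateau > 0) cross_time(t, gc, 0.95 * plateau) else NA_real_
  # a saturation estimate earlier than detection means no plateau was reached
  if (!is.na(sat) && !is.na(det) && sat < det) sat <- NA_real_
  structure(
    tibble(activation_complete_time = act,
           detection_crossing_time = det,
           saturation_time = sat,
           plateau_level = plateau,
           pre_tumor_end = det,
           expansion_end = sat,
           horizon = max(t)),
    class = c("tme_phases", class(tibble())))
}
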