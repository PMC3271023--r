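test_that("hill_response matches its closed form and rejects bad input", {
  expect_equal(hill_response(0, K = 5, n = 2), 0)
  expect_equal(hill_response(7.3, K = 7.3, n = 3.1), 0.5)
  expect_equal(hill_response(10 * 4, K = 4, n = 2), 100 / 101)
  expect_error(hill_response(-1, 1, 1), "concentration")
  expect_error(hill_response(1, 0, 1), "K and n")
  expect_error(hill_response(1, 1, -2), "K and n")
})

test_that("hill_response and modulation factors are monotone in the ligand", {
  set.seed(101)
  grid <- seq(0, 500, length.out = 200)
  for (i in 1:25) {
    K <- runif(1, 0.5, 200); n <- runif(1, 0.3, 5)
    expect_true(all(diff(hill_response(grid, K, n)) >= 0))
    a_up <- runif(1, 1, 6)
    up <- modulation_factor(grid, list(K = K, n = n, a = a_up), "up")
    expect_true(all(diff(up) >= 0))
    expect_true(all(up >= 1 & up <= a_up))
    a_dn <- runif(1, 0, 1)
    dn <- modulation_factor(grid, list(K = K, n = n, a = a_dn), "down")
    expect_true(all(diff(dn) <= 0))
    expect_true(all(dn <= 1 & dn >= a_dn))
  }
})

test_that("modulation factor hits its closed-form anchor points", {
  expect_equal(modulation_factor(0, list(K = 3, n = 2, a = 4), "up"), 1)
  expect_equal(modulation_factor(0, list(K = 3, n = 2, a = 0.1), "down"), 1)
  expect_equal(modulation_factor(1e9, list(K = 3, n = 2, a = 3), "up"), 3,
               tolerance = 1e-6)
  expect_equal(modulation_factor(5, list(K = 5, n = 2, a = 0.2), "down"), 0.6)
  expect_error(modulation_factor(1, list(K = 1, n = 1, a = 0.5), "up"),
               "amplitude")
  expect_error(modulation_factor(1, list(K = 1, n = 1, a = 2), "down"),
               "amplitude")
})

test_that("logistic and angiogenesis factors follow their definitions", {
  expect_equal(logistic_factor(0, 1e7), 1)
  expect_equal(logistic_factor(1e7, 1e7), 0)
  expect_equal(logistic_factor(5e6, 1e7), 0.5)
  expect_equal(logistic_factor(2e7, 1e7), 0)   # clamped, never negative
  expect_error(logistic_factor(1, 0), "c_bar")

  p <- list(driver = "VEGF", A_min = 0.2, K = 30, n = 2)
  expect_equal(angiogenesis_factor(c(VEGF = 0), p), 0.2)
  expect_equal(angiogenesis_factor(c(VEGF = 30), p), 0.6)
  expect_equal(angiogenesis_factor(c(VEGF = 1e12), p), 1, tolerance = 1e-6)
  expect_error(angiogenesis_factor(c(IL6 = 1), p), "driver")
})

test_that("assembled system has one equation per species (20 on default)", {
  spec <- default_glioma_spec()
  rhs <- assemble_rhs(spec)
  state <- setNames(pmax(spec$species$initial, 10), attr(rhs, "species"))
  d <- rhs(0, state)
  expect_length(d, 20)
  expect_named(d, attr(rhs, "species"))
})

test_that("single-cell decay network reduces to dc/dt = -k c", {
  spec <- decay_spec(k = 0.37, c0 = 250)
  rhs <- assemble_rhs(spec)
  d <- rhs(0, c(C = 250, X = 0))
  expect_equal(unname(d["C"]), -0.37 * 250)
  expect_equal(unname(d["X"]), 0)
})

test_that("cytokine derivative assembles production and decay terms", {
  # VEGF produced by three cells, each secretion up-modulated by MIF and
  # TNFa: three production terms carrying both factors, plus decay
  cells <- toy_cells("GC", 0, 0, 1e12, FALSE,
                     "ASC", 0, 0, 1e12, FALSE,
                     "MG", 0, 0, 1e12, FALSE)
  prods <- tibble::tibble(cytokine = "VEGF", cell = c("GC", "ASC", "MG"),
                          rate = c(2e-5, 1e-5, 3e-5))
  edges <- dplyr::bind_rows(lapply(c("GC", "ASC", "MG"), function(cl)
    dplyr::bind_rows(
      toy_edge(paste0("m", cl), "MIF", "secretion", "up", 40, 2, 2,
               cytokine = "VEGF", cell = cl),
      toy_edge(paste0("t", cl), "TNFa", "secretion", "up", 60, 2, 1.5,
               cytokine = "VEGF", cell = cl))))
  spec <- toy_spec(cells, tibble::tibble(species = c("VEGF", "MIF", "TNFa"),
                                         half_life = c(0.5, 1, 1)),
                   producers = prods, edges = edges,
                   cell_init = c(1e6, 2e5, 3e6), cyt_init = c(10, 20, 30))
  rhs <- assemble_rhs(spec)
  st <- c(GC = 1e6, ASC = 2e5, MG = 3e6, VEGF = 10, MIF = 20, TNFa = 30)
  d <- rhs(0, st)
  mod_m <- 1 + (2 - 1) * hill_response(20, 40, 2)
  mod_t <- 1 + (1.5 - 1) * hill_response(30, 60, 2)
  expected <- (2e-5 * 1e6 + 1e-5 * 2e5 + 3e-5 * 3e6) * mod_m * mod_t -
    log(2) / 0.5 * 10
  expect_equal(unname(d["VEGF"]), expected, tolerance = 1e-12)
})

test_that("R-side derivative agrees with the compiled engine derivative", {
  spec <- default_glioma_spec()
  rhs <- assemble_rhs(spec)
  m <- gliomaTME:::compile_model(spec)
  set.seed(7)
  for (i in 1:5) {
    st <- setNames(runif(20, 0, 1) * c(rep(1e7, 5), rep(200, 15)), m$species)
    expect_equal(unname(rhs(0, st)), as.numeric(gliomaTME:::engine_deriv(m, st)),
                 tolerance = 1e-12)
  }
})

test_that("integrators reproduce exponential and logistic closed forms", {
  # exponential decay, half-life 1 day: c(3) = 12.5
  spec <- decay_spec(k = log(2), c0 = 100)
  tr <- integrate_deterministic(spec, 3, method = "rk4", dt = 0.01,
                                record_every = 1)
  expect_rel_equal(tr$C[nrow(tr)], 12.5, 1e-6)
  tr45 <- integrate_deterministic(spec, 3, method = "dp5", rtol = 1e-9,
                                  atol = 1e-9)
  expect_rel_equal(tr45$C[nrow(tr45)], 12.5, 1e-6)

  # logistic growth from cbar/100 at r = 1/day
  spec2 <- logistic_spec(r = 1, cbar = 1e6, c0 = 1e4)
  analytic <- function(t, r = 1, cbar = 1e6, c0 = 1e4)
    cbar * c0 * exp(r * t) / (cbar + c0 * (exp(r * t) - 1))
  tr2 <- integrate_deterministic(spec2, 10, method = "rk4", dt = 0.01)
  expect_rel_equal(tr2$C, analytic(tr2$time), 1e-6)
  tr2b <- integrate_deterministic(spec2, 10, method = "dp5", rtol = 1e-9,
                                  atol = 1e-6)
  expect_rel_equal(tr2b$C[nrow(tr2b)], analytic(10), 1e-6)
})

test_that("fixed-step rk4 and adaptive dp5 agree on the default model", {
  spec <- default_glioma_spec()
  tr4 <- integrate_deterministic(spec, 365, method = "rk4", dt = 0.01,
                                 record_every = 5)
  tr5 <- integrate_deterministic(spec, 365, method = "dp5", rtol = 1e-8,
                                 atol = 1e-4, record_every = 5)
  rel <- abs(tr4$GC - tr5$GC) / pmax(tr5$GC, 1)
  expect_lt(max(rel), 1e-3)
})

test_that("phase detection interpolates crossings and flags their absence", {
  # no crossing: flat low trajectory
  flat <- tibble::tibble(time = 0:100, GC = rep(10, 101),
                         QSC = rep(100, 101), ASC = rep(900, 101))
  ph <- detect_phases(flat)
  expect_true(is.na(ph$detection_crossing_time))

  # GC = t * 1e5/day crosses 1e6 at exactly t = 10
  lin <- tibble::tibble(time = seq(0, 40, by = 4), GC = seq(0, 40, by = 4) * 1e5)
  ph2 <- detect_phases(lin)
  expect_equal(ph2$detection_crossing_time, 10)
})

test_that("the calibrated deterministic run shows the three-phase shape", {
  spec <- default_glioma_spec()
  tr <- integrate_deterministic(spec, 365, method = "rk4", dt = 0.01)
  ph <- detect_phases(tr)
  expect_lt(ph$activation_complete_time, 30.4)           # within month 1
  expect_gt(ph$detection_crossing_time, 6 * 30.4)        # rapid-expansion window
  expect_lt(ph$detection_crossing_time, 10 * 30.4)
  expect_true(ph$saturation_time > ph$detection_crossing_time)
  expect_gt(ph$plateau_level, 1e7)
})

test_that("removing an edge perturbs only the equations that cite it", {
  spec <- default_glioma_spec()
  # e01 is an IL1b -> GC proliferation edge: only the GC equation changes
  e <- spec$edges[1, ]
  expect_equal(e$process, "proliferation")
  spec2 <- spec
  spec2$edges <- spec2$edges[-1, ]
  st <- setNames(c(1e4, 1e4, 1e5, 2.8e7, 2e6, rep(50, 15)),
                 c(gliomaTME:::cell_ids(spec), gliomaTME:::cytokine_ids(spec)))
  d1 <- assemble_rhs(spec)(0, st)
  d2 <- assemble_rhs(spec2)(0, st)
  changed <- names(d1)[abs(d1 - d2) > 1e-12]
  expect_equal(changed, e$target)
})
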