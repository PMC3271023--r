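test_that("truncated Gaussian rate perturbation honors moments and bounds", {
  expect_identical(perturb_rate_truncated_gaussian(3.2, sigma = 0), 3.2)
  set.seed(5)
  draws <- perturb_rate_truncated_gaussian(10, sigma = 0.1, n = 1e5)
  expect_lt(abs(mean(draws) - 10) / 10, 0.01)
  expect_true(all(draws >= 0 & draws <= 20))
  capped <- perturb_rate_truncated_gaussian(10, sigma = 0.5,
                                            bounds = c(0, 10), n = 1e4)
  expect_true(all(capped <= 10))
})

test_that("sine-Wiener bounded noise stays in [-1, 1] with arcsine statistics", {
  set.seed(9)
  n <- 1e6; dt <- 0.01; tau <- 0.1
  theta <- cumsum(sqrt(2 * dt / tau) * rnorm(n))
  z <- sin(theta)  # closed-form path of the recursion in bounded_noise_step
  st <- bounded_noise_step(0, dt, tau)
  expect_true(abs(st$z) <= 1)
  expect_true(all(z >= -1 & z <= 1))
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(mean(z^2) - 0.5), 0.02)  # stationary arcsine second moment

  # frozen-noise limit: tau -> Inf leaves the phase (hence z) unchanged
  frozen <- bounded_noise_step(rep(0.3, 10), dt = 1, tau_n = 1e12)
  expect_equal(frozen$z, rep(sin(0.3), 10), tolerance = 1e-5)
})

test_that("thinned Poisson sampling matches analytic count moments", {
  expect_equal(poisson_event_count(function(t) 0, 0, 10, 0)$count, 0L)

  set.seed(11)
  counts <- replicate(1e4, poisson_event_count(function(t) 5, 0, 10, 5)$count)
  expect_lt(abs(mean(counts) - 50) / 50, 0.02)
  expect_lt(abs(var(counts) - 50) / 50, 0.05)

  counts2 <- replicate(1e4, poisson_event_count(function(t) t, 0, 2, 2)$count)
  expect_lt(abs(mean(counts2) - 2) / 2, 0.03)

  expect_error(poisson_event_count(function(t) t, 0, 1, Inf), "finite")
  expect_error(poisson_event_count(function(t) 10, 0, 1, 2), "exceeds")
})

test_that("stochastic integrator reduces to the deterministic rk4 limit", {
  spec <- default_glioma_spec()
  quiet <- tme_noise(sigma_production = 0, sigma_rates = 0)
  none <- default_jump_processes(spec)[0, ]
  trs <- integrate_stochastic(spec, 60, noise = quiet, jumps = none,
                              dt = 0.01, seed = 1)
  trd <- integrate_deterministic(spec, 60, method = "rk4", dt = 0.01)
  for (sp in setdiff(names(trd), "time")) {
    scale <- pmax(abs(trd[[sp]]), 1e-6)
    expect_lt(max(abs(trs[[sp]] - trd[[sp]]) / scale), 1e-9)
  }
})

test_that("identical seeds give bitwise-identical exports; seeds differ runs", {
  spec <- default_glioma_spec()
  a <- integrate_stochastic(spec, 40, dt = 0.01, seed = 123)
  b <- integrate_stochastic(spec, 40, dt = 0.01, seed = 123)
  d <- integrate_stochastic(spec, 40, dt = 0.01, seed = 124)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(a, fa)
  write_trajectory_csv(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_true(file.exists(paste0(fa, ".meta.yaml")))
  expect_false(identical(a$GC, d$GC))
})

test_that("jump bookkeeping conserves cells for a pure immigration process", {
  spec <- toy_spec(toy_cells("M", 0, 0, 1e12, FALSE),
                   tibble::tibble(species = "X", half_life = 1),
                   cell_init = 1000)
  jumps <- tibble::tibble(id = "imm", target = "M", source = NA_character_,
                          sign = "+", rate = 5, magnitude = 40)
  tr <- integrate_stochastic(spec, 50, noise = tme_noise(0, 0), jumps = jumps,
                             dt = 0.01, seed = 31)
  meta <- trajectory_meta(tr)
  expect_gt(meta$jump_events[["imm"]], 0)
  # cells added by events (count / 1-ml volume) equal the net census change
  expect_equal(tr$M[nrow(tr)] - 1000, unname(meta$jump_added[["imm"]]))
  # mean arrivals near rate * horizon
  expect_lt(abs(meta$jump_events[["imm"]] - 250) / 250, 0.25)
})

test_that("ensembles are reproducible and degenerate correctly at n = 1", {
  spec <- default_glioma_spec()
  e1 <- run_ensemble(spec, 30, n_reps = 1, master_seed = 5, dt = 0.02)
  expect_length(e1$trajectories, 1)
  one <- e1$summary[e1$summary$species == "GC", ]
  expect_equal(one$mean, one$q50)
  expect_equal(one$q05, one$q95)

  e2 <- run_ensemble(spec, 30, n_reps = 3, master_seed = 77, dt = 0.02)
  e3 <- run_ensemble(spec, 30, n_reps = 3, master_seed = 77, dt = 0.02)
  expect_identical(e2$seeds, e3$seeds)
  expect_equal(e2$endpoints, e3$endpoints)
  expect_equal(e2$summary, e3$summary)
})
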