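test_that("survival objective interpolates threshold-to-objective time", {
  # linear growth 1e6 -> 1.5e7 over exactly 100 days
  lin <- tibble::tibble(time = seq(0, 200, by = 2),
                        GC = 1e6 + seq(0, 200, by = 2) * 1.4e5)
  expect_equal(survival_objective(lin, 1e6, 1.5e7), 100 / 30.4)

  plateaued <- tibble::tibble(time = 0:100, GC = pmin(0:100 * 1e5, 5e6))
  expect_true(is.na(survival_objective(plateaued, 1e6, 1.5e7)))

  # degenerate window shrinks to zero
  expect_lt(survival_objective(lin, 1e6, 1e6 + 1), 0.01)
  expect_error(survival_objective(lin, 2e6, 1e6), "c_start")
})

test_that("a parameter with no causal path to the tumor has S exactly 0", {
  spec <- growth_toy()
  s <- sensitivity_factor(spec, param_id = "p_Z", n_reps = 2, master_seed = 3,
                          noise = tme_noise(0, 0),
                          jumps = default_jump_processes(spec)[0, ],
                          t_span = 120, dt = 0.02)
  expect_equal(s$S, 0)
  expect_equal(s$se, 0)
})

test_that("finite-difference S matches the closed form on the growth toy", {
  # GC grows exponentially at rate r * (1 + (a-1) h(m * L*; K)); the
  # survival proxy is ln(c_end/c_start) / rate, so S has a closed form
  r <- 0.03; K <- 50; n <- 1; a <- 3
  spec <- growth_toy(r = r, K = K, n = n, a = a)
  Lstar <- attr(spec, "Lstar")
  delta <- 0.1
  f <- function(m) 1 + (a - 1) * hill_response(m * Lstar, K, n)
  Fm <- function(m) log(1e7 / 1e6) / (r * f(m)) / 30.4
  S_analytic <- (Fm(1 + delta) - Fm(1 - delta)) / (2 * delta * Fm(1))

  s <- sensitivity_factor(spec, param_id = "p_X", delta = delta, n_reps = 1,
                          master_seed = 1, noise = tme_noise(0, 0),
                          jumps = default_jump_processes(spec)[0, ],
                          t_span = 250, dt = 0.02, c_start = 1e6, c_end = 1e7)
  expect_equal(s$objective, "survival_proxy")
  expect_lt(abs(s$S - S_analytic) / abs(S_analytic), 0.02)
  expect_lt(s$S, 0)  # growth promoter: inhibiting it prolongs survival

  # receptor scaling K/m is mathematically equivalent to scaling the ligand
  sr <- sensitivity_factor(spec, param_id = "r_X", delta = delta, n_reps = 1,
                           master_seed = 1, noise = tme_noise(0, 0),
                           jumps = default_jump_processes(spec)[0, ],
                           t_span = 250, dt = 0.02, c_start = 1e6, c_end = 1e7)
  expect_equal(sr$S, s$S, tolerance = 0.01)
})

test_that("sensitivity reports are deterministic given the master seed", {
  spec <- growth_toy()
  args <- list(spec = spec, param_id = "p_X", n_reps = 2, master_seed = 9,
               t_span = 120, dt = 0.02, c_start = 1e6, c_end = 1e7)
  s1 <- do.call(sensitivity_factor, args)
  s2 <- do.call(sensitivity_factor, args)
  expect_identical(s1, s2)
})

test_that("combination design ranks by signed S with stable tie-breaks", {
  rep <- structure(tibble::tibble(
    param_id = c("p_A", "p_B", "p_C", "r_A", "p_D"),
    S = c(-2, -2, 0.5, -0.1, 3),
    se = 0.01, delta = 0.1, objective = "survival_proxy"),
    class = c("tme_sensitivity", class(tibble::tibble())))
  d <- design_combination(rep, k = 3)
  expect_equal(d$param_id, c("p_A", "p_B", "r_A"))  # |S| then lexicographic
  expect_equal(d$action, rep("inhibit", 3))
  expect_equal(design_combination(rep, k = 0)$param_id, character())
  expect_error(design_combination(rep, k = 6), "exceeds")

  both <- design_combination(rep, k = 2, enhance_k = 1)
  expect_equal(both$param_id[both$action == "enhance"], "p_D")

  ties <- rep; ties$S <- rep(0, 5)
  d0 <- design_combination(ties, k = 2)
  expect_equal(d0$param_id, c("p_A", "p_B"))
  expect_true(all(d0$low_confidence))

  plan <- design_to_plan(d, inhibition_factor = 0.1, trigger_density = 1e6)
  expect_length(plan$arms[[1]]$interventions, 3)
  kinds <- vapply(plan$arms[[1]]$interventions, `[[`, "", "kind")
  expect_setequal(unique(kinds), c("production_inhibition", "receptor_blockade"))
})

test_that("tidy and glance summarize a sensitivity report", {
  rep <- structure(tibble::tibble(param_id = c("p_A", "p_B"), S = c(-1, 2),
                                  se = 0.1, delta = 0.1,
                                  objective = "survival_proxy"),
                   class = c("tme_sensitivity", class(tibble::tibble())),
                   patient_id = "toy", master_seed = 1L)
  expect_s3_class(tidy(rep), "tbl_df")
  g <- glance(rep)
  expect_equal(g$n_negative, 1)
  expect_equal(g$top_negative, "p_A")
})
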