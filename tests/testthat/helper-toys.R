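# Toy networks with closed-form behavior, built in code at test time.

toy_spec <- function(cells, cytokines, producers = NULL, edges = NULL,
                     conversions = NULL, angiogenesis = NULL,
                     cell_init = NULL, cyt_init = NULL, name = "toy") {
  n_cell <- nrow(cells); n_cyt <- nrow(cytokines)
  species <- tibble::tibble(
    id = c(cells$species, cytokines$species),
    name = c(cells$species, cytokines$species),
    role = c(rep("cell", n_cell), rep("cytokine", n_cyt)),
    initial = c(cell_init %||% rep(100, n_cell), cyt_init %||% rep(0, n_cyt)),
    unit = c(rep("cells/ml", n_cell), rep("pg/ml", n_cyt)),
    description = NA_character_)
  if (is.null(producers))
    producers <- tibble::tibble(cytokine = character(), cell = character(),
                                rate = numeric())
  if (is.null(edges))
    edges <- tibble::tibble(id = character(), source = character(),
                            process = character(), target = character(),
                            cytokine = character(), cell = character(),
                            conversion = character(), direction = character(),
                            K = numeric(), n = numeric(), a = numeric(),
                            receptor_param = character())
  if (is.null(conversions))
    conversions <- tibble::tibble(id = character(), source = character(),
                                  target = character(), kind = character(),
                                  rate = numeric())
  if (is.null(angiogenesis))
    angiogenesis <- list(driver = cytokines$species[1], A_min = 1, K = 1, n = 1)
  tme_network(species, cells, conversions, cytokines, producers, edges,
              angiogenesis, name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_cells <- function(...) {
  tibble::tribble(~species, ~proliferation, ~decay, ~saturating_concentration,
                  ~angiogenesis_dependent, ...)
}

toy_edge <- function(id, source, process, direction, K, n, a,
                     target = NA, cytokine = NA, cell = NA, conversion = NA,
                     receptor_param = NA) {
  tibble::tibble(id = id, source = source, process = process, target = target,
                 cytokine = cytokine, cell = cell, conversion = conversion,
                 direction = direction, K = K, n = n, a = a,
                 receptor_param = receptor_param)
}

# single cell with pure exponential decay at rate k
decay_spec <- function(k = log(2), c0 = 100) {
  toy_spec(toy_cells("C", 0, k, 1e9, FALSE),
           tibble::tibble(species = "X", half_life = 1),
           cell_init = c0)
}

# single cell with logistic growth (rate r, capacity cbar), no decay
logistic_spec <- function(r = 1, cbar = 1e6, c0 = 1e4) {
  toy_spec(toy_cells("C", r, 0, cbar, FALSE),
           tibble::tibble(species = "X", half_life = 1),
           cell_init = c0)
}

# tumor growth gated by one cytokine X held at steady state; a second
# cytokine Z is produced but wired to nothing (no causal path to GC)
growth_toy <- function(r = 0.03, K = 50, n = 1, a = 3,
                       q = 1e-4, n_src = 5e6, tau = 0.1) {
  Lstar <- q * n_src * tau / log(2)
  spec <- toy_spec(
    toy_cells("SRC", 0, 0, 1e12, FALSE,
              "GC",  r, 0, 1e12, FALSE),
    tibble::tibble(species = c("X", "Z"), half_life = tau),
    producers = tibble::tibble(cytokine = c("X", "Z"), cell = "SRC", rate = q),
    edges = toy_edge("eX", "X", "proliferation", "up", K, n, a, target = "GC",
                     receptor_param = "r_X"),
    cell_init = c(n_src, 9e5),
    cyt_init = c(Lstar, Lstar))
  attr(spec, "Lstar") <- Lstar
  spec
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), .Machine$double.eps)), tol)
}
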