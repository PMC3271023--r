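test_that("default glioma network has the expected structure", {
  spec <- default_glioma_spec()
  expect_equal(sum(spec$species$role == "cell"), 5)
  expect_equal(sum(spec$species$role == "cytokine"), 15)
  expect_equal(nrow(spec$edges), 69)
  cyts <- spec$species$id[spec$species$role == "cytokine"]
  expect_true(all(spec$edges$source %in% cyts))
  init <- setNames(spec$species$initial, spec$species$id)
  expect_equal(unname(init["astrocyte"]), 2.8e7)
  expect_equal(unname(init["microglia"]), 2e6)
  expect_equal(unname(init["QSC"]), 1e4)
  expect_equal(unname(init["GC"]), 0)
  expect_equal(nrow(validate_network(spec)), 0)
})

test_that("tunable parameters enumerate 15 production + 14 receptor levels", {
  tp <- tunable_parameters(default_glioma_spec())
  expect_equal(nrow(tp), 29)
  expect_equal(sum(tp$kind == "production"), 15)
  expect_equal(sum(tp$kind == "receptor"), 14)
  # MMP9 is the terminal marker: produced, but no receptor-mediated edge
  expect_false("r_MMP9" %in% tp$param_id)
  expect_true("p_MMP9" %in% tp$param_id)
})

test_that("default network is weakly connected as a bipartite graph", {
  expect_true(network_connected(default_glioma_spec()))
})

test_that("a minimal toy network validates with counts (1, 1, 1)", {
  spec <- toy_spec(toy_cells("C", 0.1, 0.01, 1e8, FALSE),
                   tibble::tibble(species = "X", half_life = 0.5),
                   producers = tibble::tibble(cytokine = "X", cell = "C",
                                              rate = 1e-5),
                   edges = toy_edge("e1", "X", "proliferation", "up",
                                    10, 2, 1.5, target = "C"))
  expect_equal(nrow(validate_network(spec)), 0)
  expect_equal(sum(spec$species$role == "cell"), 1)
  expect_equal(sum(spec$species$role == "cytokine"), 1)
  expect_equal(nrow(spec$edges), 1)
})

test_that("validation reports dangling references and bad parameters", {
  spec <- default_glioma_spec()

  bad <- spec
  bad$edges$source[1] <- "IL99"
  rep <- validate_network(bad)
  expect_gt(nrow(rep), 0)
  expect_true(any(grepl(bad$edges$id[1], rep$field) & grepl("IL99", rep$message)))
  expect_error(assert_valid <- gliomaTME:::assert_valid(bad), "IL99")

  bad2 <- spec
  bad2$cytokines$half_life[bad2$cytokines$species == "IL6"] <- 0
  rep2 <- validate_network(bad2)
  expect_equal(nrow(rep2), 1)
  expect_match(rep2$field, "CytokineParams\\(IL6\\)")

  bad3 <- spec
  bad3$edges <- bad3$edges[-1, ]
  expect_equal(nrow(bad3$edges), 68)  # count invariant only holds for default
  expect_equal(nrow(validate_network(bad3)), 0)
})

test_that("serialization round-trips the shipped network exactly", {
  spec <- default_glioma_spec()
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_network_spec(spec, tf)
  spec2 <- load_network_spec(tf)
  expect_equal(spec2$species, spec$species)
  expect_equal(spec2$cells, spec$cells)
  expect_equal(spec2$conversions, spec$conversions)
  expect_equal(spec2$producers, spec$producers)
  expect_equal(spec2$edges, spec$edges)
  expect_equal(spec2$angiogenesis, spec$angiogenesis)
  expect_identical(spec_hash(spec2), spec_hash(spec))
})

test_that("loading a nonexistent or mangled file fails with a clear error", {
  expect_error(load_network_spec("no/such/file.yaml"), "not found")
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines("species: [oops", tf)
  expect_error(load_network_spec(tf), "parse")
  tf2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("schema_version: 1\nname: x", tf2)
  expect_error(load_network_spec(tf2), "missing fields")
})
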