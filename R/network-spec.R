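#' @useDynLib gliomaTME, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom dplyr filter mutate select arrange bind_rows bind_cols group_by summarise ungroup left_join across all_of n
#' @importFrom rlang .data
NULL

CELL_PROCESSES <- c("proliferation", "decay", "secretion", "conversion", "recruitment")
CONVERSION_KINDS <- c("mutation", "differentiation", "dedifferentiation",
                      "activation", "deactivation")

#' Construct a cell-cytokine network specification
#'
#' A `tme_network` is the complete declarative model behind a simulation:
#' the species roster (cells and cytokines), basal cell kinetics,
#' cell-to-cell conversions, cytokine production/decay, and the Hill-type
#' pathway edges through which cytokines modulate rates. The shipped
#' default glioma network is returned by [default_glioma_spec()]; this
#' constructor is for building toy or custom networks programmatically.
#'
#' @param species tibble with columns `id`, `name`, `role`
#'   (`"cell"`/`"cytokine"`), `initial` (cells/ml for cells, pg/ml for
#'   cytokines), `unit`, `description`.
#' @param cells tibble with columns `species`, `proliferation` (1/day),
#'   `decay` (1/day), `saturating_concentration` (cells/ml),
#'   `angiogenesis_dependent` (logical).
#' @param conversions tibble with columns `id`, `source`, `target`, `kind`
#'   (one of mutation, differentiation, dedifferentiation, activation,
#'   deactivation), `rate` (1/day). A conversion moves cells from `source`
#'   into `target`; both flux terms are generated automatically.
#' @param cytokines tibble with columns `species`, `half_life` (days).
#' @param producers tibble with columns `cytokine`, `cell`, `rate`
#'   (pg per cell per day).
#' @param edges tibble of pathway edges; columns `id`, `source` (cytokine),
#'   `process`, `target`, `cytokine`, `cell`, `conversion`, `direction`
#'   (`"up"`/`"down"`), `K`, `n`, `a`, `receptor_param`.
#' @param angiogenesis list with `driver` (cytokine id), `A_min`, `K`, `n`.
#' @param name,schema_version metadata.
#' @return object of class `tme_network`.
#' @export
tme_network <- function(species, cells, conversions, cytokines, producers,
                        edges, angiogenesis,
                        name = "custom", schema_version = 1L) {
  spec <- structure(
    list(schema_version = as.integer(schema_version), name = name,
         species = as_tibble(species), cells = as_tibble(cells),
         conversions = as_tibble(conversions),
         cytokines = as_tibble(cytokines), producers = as_tibble(producers),
         edges = as_tibble(edges), angiogenesis = angiogenesis),
    class = "tme_network")
  spec
}

#' @export
print.tme_network <- function(x, ...) {
  n_cell <- sum(x$species$role == "cell")
  n_cyt <- sum(x$species$role == "cytokine")
  cat(sprintf("<tme_network '%s'> %d cells, %d cytokines, %d pathway edges, %d conversions\n",
              x$name, n_cell, n_cyt, nrow(x$edges), nrow(x$conversions)))
  invisible(x)
}

cell_ids <- function(spec) spec$species$id[spec$species$role == "cell"]
cytokine_ids <- function(spec) spec$species$id[spec$species$role == "cytokine"]

#' Validate a network specification
#'
#' Checks every structural invariant the dynamics assembler relies on:
#' unique species ids, non-negative initial concentrations and rates,
#' positive half-lives and carrying capacities, edge sources being
#' cytokines, edge targets resolving to existing species/processes,
#' Hill parameters in range (`K > 0`, `n > 0`, amplitude `>= 1` for
#' up-edges and in `[0, 1]` for down-edges), and conversion sources being
#' cells. Returns an empty tibble when the specification is usable.
#'
#' @param spec a `tme_network`.
#' @return tibble with columns `field` and `message`, one row per
#'   violation; zero rows means valid.
#' @export
validate_network <- function(spec) {
  v <- list()
  add <- function(field, message) v[[length(v) + 1L]] <<- tibble(field = field, message = message)

  sp <- spec$species
  if (anyDuplicated(sp$id)) add("species", paste("duplicate species ids:",
      paste(unique(sp$id[duplicated(sp$id)]), collapse = ", ")))
  bad <- sp$id[sp$initial < 0]
  if (length(bad)) add("species", paste("negative initial concentration:", paste(bad, collapse = ", ")))
  if (!all(sp$role %in% c("cell", "cytokine")))
    add("species", "role must be 'cell' or 'cytokine'")

  cells <- cell_ids(spec); cyts <- cytokine_ids(spec)

  for (i in seq_len(nrow(spec$cells))) {
    cp <- spec$cells[i, ]
    lbl <- paste0("CellParams(", cp$species, ")")
    if (!cp$species %in% cells) add(lbl, "species is not a declared cell")
    if (cp$proliferation < 0 || cp$decay < 0) add(lbl, "rates must be >= 0")
    if (!is.finite(cp$saturating_concentration) || cp$saturating_concentration <= 0)
      add(lbl, "saturating_concentration must be > 0")
  }
  miss <- setdiff(cells, spec$cells$species)
  if (length(miss)) add("cells", paste("missing CellParams for:", paste(miss, collapse = ", ")))

  for (i in seq_len(nrow(spec$conversions))) {
    cv <- spec$conversions[i, ]
    lbl <- paste0("Conversion(", cv$id, ")")
    if (!cv$source %in% cells) add(lbl, paste("source", cv$source, "is not a cell"))
    if (!cv$target %in% cells) add(lbl, paste("target", cv$target, "is not a cell"))
    if (!cv$kind %in% CONVERSION_KINDS) add(lbl, paste("unknown kind", cv$kind))
    if (cv$rate < 0) add(lbl, "rate must be >= 0")
  }

  for (i in seq_len(nrow(spec$cytokines))) {
    ck <- spec$cytokines[i, ]
    lbl <- paste0("CytokineParams(", ck$species, ")")
    if (!ck$species %in% cyts) add(lbl, "species is not a declared cytokine")
    if (!is.finite(ck$half_life) || ck$half_life <= 0) add(lbl, "half_life must be > 0")
  }
  miss <- setdiff(cyts, spec$cytokines$species)
  if (length(miss)) add("cytokines", paste("missing CytokineParams for:", paste(miss, collapse = ", ")))

  for (i in seq_len(nrow(spec$producers))) {
    pr <- spec$producers[i, ]
    lbl <- paste0("Producer(", pr$cytokine, " by ", pr$cell, ")")
    if (!pr$cytokine %in% cyts) add(lbl, "produced species is not a cytokine")
    if (!pr$cell %in% cells) add(lbl, "producing species is not a cell")
    if (pr$rate < 0) add(lbl, "secretion rate must be >= 0")
  }

  prod_key <- paste(spec$producers$cytokine, spec$producers$cell)
  conv_key <- spec$conversions$id
  for (i in seq_len(nrow(spec$edges))) {
    e <- spec$edges[i, ]
    lbl <- paste0("Edge(", e$id, ")")
    if (!e$source %in% cyts) add(lbl, paste("source", e$source, "is not a cytokine"))
    if (!e$direction %in% c("up", "down")) add(lbl, "direction must be 'up' or 'down'")
    if (!is.finite(e$K) || e$K <= 0) add(lbl, "K must be > 0")
    if (!is.finite(e$n) || e$n <= 0) add(lbl, "n must be > 0")
    if (identical(e$direction, "up") && e$a < 1)
      add(lbl, "up-edge amplitude must be >= 1 (maximum fold-change)")
    if (identical(e$direction, "down") && (e$a < 0 || e$a > 1))
      add(lbl, "down-edge amplitude must be in [0, 1] (residual fraction)")
    switch(e$process,
      proliferation = , decay = {
        if (!e$target %in% sp$id) add(lbl, paste("unknown target species", e$target))
      },
      secretion = {
        if (!paste(e$cytokine, e$cell) %in% prod_key)
          add(lbl, paste("no producer", e$cytokine, "by", e$cell))
      },
      conversion = {
        if (!e$conversion %in% conv_key) add(lbl, paste("unknown conversion", e$conversion))
      },
      recruitment = {
        if (!e$target %in% cells) add(lbl, paste("recruitment target", e$target, "is not a cell"))
      },
      add(lbl, paste("unknown process", e$process)))
  }
  if (anyDuplicated(spec$edges$id)) add("edges", "duplicate edge ids")

  ang <- spec$angiogenesis
  if (!ang$driver %in% cyts) add("angiogenesis", "driver must be a cytokine")
  if (ang$A_min <= 0 || ang$A_min > 1) add("angiogenesis", "A_min must be in (0, 1]")
  if (ang$K <= 0 || ang$n <= 0) add("angiogenesis", "K and n must be > 0")

  if (length(v)) bind_rows(v) else tibble(field = character(), message = character())
}

assert_valid <- function(spec) {
  rep <- validate_network(spec)
  if (nrow(rep) > 0)
    stop("invalid network specification:\n",
         paste0("  - ", rep$field, ": ", rep$message, collapse = "\n"),
         call. = FALSE)
  invisible(spec)
}

# ---- serialization -------------------------------------------------------

spec_to_list <- function(spec) {
  conv_by_target <- split(spec$conversions, spec$conversions$target)
  cells <- lapply(seq_len(nrow(spec$cells)), function(i) {
    cp <- spec$cells[i, ]
    out <- list(species = cp$species,
                proliferation = cp$proliferation, decay = cp$decay,
                saturating_concentration = cp$saturating_concentration,
                angiogenesis_dependent = cp$angiogenesis_dependent)
    cv <- conv_by_target[[cp$species]]
    if (!is.null(cv) && nrow(cv))
      out$conversions <- lapply(seq_len(nrow(cv)), function(j)
        list(source = cv$source[j], kind = cv$kind[j], rate = cv$rate[j]))
    out
  })
  prod_by_cyt <- split(spec$producers, spec$producers$cytokine)
  cytokines <- lapply(seq_len(nrow(spec$cytokines)), function(i) {
    ck <- spec$cytokines[i, ]
    pr <- prod_by_cyt[[ck$species]]
    list(species = ck$species, half_life = ck$half_life,
         producers = if (!is.null(pr)) lapply(seq_len(nrow(pr)), function(j)
           list(cell = pr$cell[j], rate = pr$rate[j])) else list())
  })
  edges <- lapply(seq_len(nrow(spec$edges)), function(i) {
    e <- spec$edges[i, ]
    out <- list(id = e$id, source = e$source, process = e$process)
    if (e$process %in% c("proliferation", "decay", "recruitment")) out$target <- e$target
    if (e$process == "secretion") { out$cytokine <- e$cytokine; out$cell <- e$cell }
    if (e$process == "conversion") out$conversion <- e$conversion
    out$direction <- e$direction
    out$K <- e$K; out$n <- e$n; out$a <- e$a
    if (!is.na(e$receptor_param)) out$receptor_param <- e$receptor_param
    out
  })
  list(schema_version = spec$schema_version, name = spec$name,
       species = lapply(seq_len(nrow(spec$species)), function(i) {
         s <- spec$species[i, ]
         list(id = s$id, name = s$name, role = s$role, initial = s$initial,
              unit = s$unit, description = s$description)
       }),
       cells = cells, cytokines = cytokines, edges = edges,
       angiogenesis = spec$angiogenesis)
}

list_to_spec <- function(x, path = "<list>") {
  need <- c("schema_version", "species", "cells", "cytokines", "edges", "angiogenesis")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("network spec ", path, " is missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  gv <- function(item, field, default = NA) {
    if (is.null(item[[field]])) default else item[[field]]
  }
  species <- bind_rows(lapply(x$species, function(s) tibble(
    id = s$id, name = gv(s, "name", s$id), role = s$role,
    initial = as.numeric(s$initial), unit = gv(s, "unit", NA_character_),
    description = gv(s, "description", NA_character_))))
  cells <- bind_rows(lapply(x$cells, function(cp) tibble(
    species = cp$species, proliferation = as.numeric(cp$proliferation),
    decay = as.numeric(cp$decay),
    saturating_concentration = as.numeric(cp$saturating_concentration),
    angiogenesis_dependent = isTRUE(cp$angiogenesis_dependent))))
  conversions <- bind_rows(lapply(x$cells, function(cp) {
    if (is.null(cp$conversions)) return(NULL)
    bind_rows(lapply(cp$conversions, function(cv) tibble(
      id = paste0(cv$kind, ":", cv$source, ">", cp$species),
      source = cv$source, target = cp$species, kind = cv$kind,
      rate = as.numeric(cv$rate))))
  }))
  if (nrow(conversions) == 0)
    conversions <- tibble(id = character(), source = character(),
                          target = character(), kind = character(), rate = numeric())
  cytokines <- bind_rows(lapply(x$cytokines, function(ck) tibble(
    species = ck$species, half_life = as.numeric(ck$half_life))))
  producers <- bind_rows(lapply(x$cytokines, function(ck) {
    if (is.null(ck$producers) || !length(ck$producers)) return(NULL)
    bind_rows(lapply(ck$producers, function(pr) tibble(
      cytokine = ck$species, cell = pr$cell, rate = as.numeric(pr$rate))))
  }))
  if (is.null(producers) || nrow(producers) == 0)
    producers <- tibble(cytokine = character(), cell = character(), rate = numeric())
  edges <- bind_rows(lapply(x$edges, function(e) tibble(
    id = e$id, source = e$source, process = e$process,
    target = gv(e, "target", NA_character_),
    cytokine = gv(e, "cytokine", NA_character_),
    cell = gv(e, "cell", NA_character_),
    conversion = gv(e, "conversion", NA_character_),
    direction = e$direction, K = as.numeric(e$K), n = as.numeric(e$n),
    a = as.numeric(e$a),
    receptor_param = gv(e, "receptor_param", NA_character_))))
  if (nrow(edges) == 0)
    edges <- tibble(id = character(), source = character(), process = character(),
                    target = character(), cytokine = character(), cell = character(),
                    conversion = character(), direction = character(),
                    K = numeric(), n = numeric(), a = numeric(),
                    receptor_param = character())
  ang <- x$angiogenesis
  tme_network(species, cells, conversions, cytokines, producers, edges,
              angiogenesis = list(driver = ang$driver,
                                  A_min = as.numeric(ang$A_min),
                                  K = as.numeric(ang$K), n = as.numeric(ang$n)),
              name = if (is.null(x$name)) "unnamed" else x$name,
              schema_version = x$schema_version)
}

#' Read a network specification from a YAML file
#'
#' @param path file path to a network spec in the documented YAML schema.
#' @param validate validate after parsing (default TRUE); an invalid spec
#'   raises an error listing every violation.
#' @return a `tme_network`.
#' @export
load_network_spec <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("network spec file not found: ", path, call. = FALSE)
  x <- tryCatch(yaml::read_yaml(path),
                error = function(e) stop("failed to parse ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  spec <- list_to_spec(x, path)
  if (validate) assert_valid(spec)
  spec
}

#' Write a network specification to a YAML file
#'
#' The serialization is canonical: fields appear in a fixed order so that
#' load-write round trips are stable.
#'
#' @param spec a `tme_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_spec <- function(spec, path) {
  writeLines(yaml::as.yaml(spec_to_list(spec), precision = 15), path)
  invisible(path)
}

#' The shipped default glioma microenvironment network
#'
#' Loads the default glioblastoma network: 5 cell populations (quiescent
#' stem-like cells QSC, activated stem-like cells ASC, glioma cells GC,
#' astrocytes, microglia), 15 cytokines/growth factors, and 69
#' Hill-modulated pathway edges reconstructed from the interactions
#' described in the glioma literature (growth-promoting loops for IL-6,
#' IL-10, TGF-beta, EGF, VEGF, HGF, G-CSF, SCF and MIF; PGE2 inhibition of
#' glioma proliferation; astrocyte-derived IL-1beta; MIF/TNF-alpha
#' induction of VEGF secretion; microglia recruitment by glioma-derived
#' factors). The edge roster is a data file
#' (`inst/extdata/glioma_network.yaml`), not code, so it can be edited or
#' replaced wholesale.
#'
#' @return a validated `tme_network` with 5 cells, 15 cytokines, 69 edges.
#' @export
default_glioma_spec <- function() {
  path <- system.file("extdata", "glioma_network.yaml", package = "gliomaTME",
                      mustWork = TRUE)
  load_network_spec(path)
}

#' Hash of a network specification
#'
#' MD5 of the canonical serialization; recorded in trajectory metadata so
#' any exported artifact can be traced to the exact model that produced it.
#' @param spec a `tme_network`.
#' @return character scalar.
#' @export
spec_hash <- function(spec) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_network_spec(spec, tf)
  unname(tools::md5sum(tf))
}

#' Enumerate the tunable parameters of a network
#'
#' The tunable parameters are (a) one production-rate multiplier per
#' cytokine (`p_<id>`), scaling all of that cytokine's basal secretion
#' rates, and (b) one receptor-expression multiplier per cytokine that
#' appears as the source of at least one pathway edge (`r_<id>`), scaling
#' the half-saturation constant K of those edges by its reciprocal. On the
#' default glioma network this yields 29 parameters (15 production + 14
#' receptor levels; MMP-9 has no receptor-mediated edge).
#'
#' @param spec a `tme_network`.
#' @return tibble with columns `param_id`, `kind`, `cytokine`.
#' @export
tunable_parameters <- function(spec) {
  cyts <- cytokine_ids(spec)
  prod <- tibble(param_id = paste0("p_", cyts), kind = "production", cytokine = cyts)
  rec_cyts <- cyts[cyts %in% unique(spec$edges$source)]
  rec <- tibble(param_id = paste0("r_", rec_cyts), kind = "receptor", cytokine = rec_cyts)
  bind_rows(prod, rec) |> arrange(.data$param_id)
}

#' Is the cell-cytokine graph weakly connected?
#'
#' Views the network as a bipartite graph (cells linked to the cytokines
#' they produce; cytokines linked to the species/processes they modulate;
#' conversions linking cells) and checks weak connectivity, i.e. no
#' orphan species.
#' @param spec a `tme_network`.
#' @return logical scalar.
#' @export
network_connected <- function(spec) {
  ids <- spec$species$id
  adj <- stats::setNames(lapply(ids, function(i) character()), ids)
  link <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b); adj[[b]] <<- c(adj[[b]], a)
  }
  for (i in seq_len(nrow(spec$producers)))
    link(spec$producers$cell[i], spec$producers$cytokine[i])
  for (i in seq_len(nrow(spec$conversions)))
    link(spec$conversions$source[i], spec$conversions$target[i])
  conv_tgt <- stats::setNames(spec$conversions$target, spec$conversions$id)
  for (i in seq_len(nrow(spec$edges))) {
    e <- spec$edges[i, ]
    other <- switch(e$process,
                    proliferation = , decay = , recruitment = e$target,
                    secretion = e$cell,
                    conversion = unname(conv_tgt[e$conversion]))
    if (!is.na(other)) link(e$source, other)
  }
  seen <- character(); queue <- ids[1]
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    queue <- c(queue, setdiff(adj[[cur]], seen))
  }
  length(seen) == length(ids)
}
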