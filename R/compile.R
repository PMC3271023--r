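# Compilation of a tme_network (plus patient profile, noise settings and
# jump processes) into the flat index/rate arrays consumed by the C++
# engine. Species are ordered cells first, then cytokines, preserving the
# within-role order of the spec file; trajectory columns follow the same
# order. All indices passed to the engine are 0-based.

compile_model <- function(spec, patient = NULL, noise = NULL, jumps = NULL) {
  assert_valid(spec)
  if (!is.null(patient)) spec <- apply_profile(spec, patient)
  if (is.null(noise)) noise <- tme_noise(sigma_production = 0, sigma_rates = 0)
  if (is.null(jumps)) jumps <- empty_jumps()

  cells <- cell_ids(spec); cyts <- cytokine_ids(spec)
  ord <- c(cells, cyts)
  idx <- stats::setNames(seq_along(ord) - 1L, ord)  # 0-based
  n_cell <- length(cells)

  sp <- spec$species[match(ord, spec$species$id), ]
  cp <- spec$cells[match(cells, spec$cells$species), ]
  ck <- spec$cytokines[match(cyts, spec$cytokines$species), ]

  cv <- spec$conversions
  pr <- spec$producers
  ed <- spec$edges

  jump_target <- integer(0); jump_src <- integer(0); jump_sign <- integer(0)
  jump_rate <- numeric(0); jump_mag <- numeric(0); jump_ids <- character(0)
  if (nrow(jumps)) {
    jump_target <- unname(idx[jumps$target])
    jump_src <- ifelse(is.na(jumps$source), -1L, unname(idx[jumps$source]))
    jump_sign <- ifelse(jumps$sign == "+", 1L, -1L)
    jump_rate <- jumps$rate
    jump_mag <- jumps$magnitude
    jump_ids <- jumps$id
  }

  edge_ttype <- integer(nrow(ed)); edge_tidx <- integer(nrow(ed))
  prod_key <- paste(pr$cytokine, pr$cell)
  for (i in seq_len(nrow(ed))) {
    e <- ed[i, ]
    if (e$process == "proliferation") {
      edge_ttype[i] <- 0L; edge_tidx[i] <- unname(idx[e$target])
    } else if (e$process == "decay") {
      edge_ttype[i] <- 1L; edge_tidx[i] <- unname(idx[e$target])
    } else if (e$process == "secretion") {
      edge_ttype[i] <- 2L
      edge_tidx[i] <- match(paste(e$cytokine, e$cell), prod_key) - 1L
    } else if (e$process == "conversion") {
      edge_ttype[i] <- 3L
      edge_tidx[i] <- match(e$conversion, cv$id) - 1L
    } else { # recruitment: bind to the jump process targeting that cell
      edge_ttype[i] <- 4L
      j <- which(jump_ids != "" & jump_target == unname(idx[e$target]) & jump_sign == 1L)
      edge_tidx[i] <- if (length(j)) j[1] - 1L else -1L
    }
  }

  list(
    species = ord, n_cell = n_cell,
    init = sp$initial,
    prolif = cp$proliferation, decay = cp$decay,
    cbar = cp$saturating_concentration,
    angio_dep = as.integer(cp$angiogenesis_dependent),
    conv_ids = cv$id,
    conv_src = unname(idx[cv$source]), conv_dst = unname(idx[cv$target]),
    conv_rate = cv$rate,
    prod_ids = paste(pr$cytokine, "<-", pr$cell),
    prod_cell = unname(idx[pr$cell]),
    prod_cyt = unname(idx[pr$cytokine]) - n_cell,
    prod_rate = pr$rate,
    prod_cytokine = pr$cytokine,
    cyt_decay = log(2) / ck$half_life,
    edge_ids = ed$id,
    edge_src = unname(idx[ed$source]),
    edge_dir = ifelse(ed$direction == "up", 1L, -1L),
    edge_K = ed$K, edge_n = ed$n, edge_a = ed$a,
    edge_ttype = edge_ttype, edge_tidx = edge_tidx,
    edge_source = ed$source,
    angio_driver = unname(idx[spec$angiogenesis$driver]),
    angio_min = spec$angiogenesis$A_min,
    angio_K = spec$angiogenesis$K, angio_n = spec$angiogenesis$n,
    jump_ids = jump_ids,
    jump_target = jump_target, jump_src = jump_src, jump_sign = jump_sign,
    jump_rate = jump_rate, jump_mag = jump_mag,
    sigma_prod = noise$sigma_production,
    sigma_rate = noise$sigma_rates,
    tau_n = noise$tau_n,
    trunc_lo = noise$truncation[1], trunc_hi = noise$truncation[2]
  )
}

# Compile a therapy plan against a compiled model: one engine trigger per
# (trigger, interventions) pair, with multiplier vectors over the flat
# rate arrays. Stacked interventions compose multiplicatively.
compile_therapy <- function(model, plan, spec) {
  if (is.null(plan) || length(plan$arms) == 0) return(list())
  idx <- stats::setNames(seq_along(model$species) - 1L, model$species)
  lapply(plan$arms, function(arm) {
    tr <- arm$trigger
    m_prolif <- rep(1, model$n_cell); m_decay <- rep(1, model$n_cell)
    m_prod <- rep(1, length(model$prod_rate))
    m_conv <- rep(1, length(model$conv_rate))
    m_K <- rep(1, length(model$edge_K))
    for (iv in arm$interventions) {
      if (iv$kind == "apoptosis_multiplier") {
        i <- idx[iv$target] + 1L
        if (is.na(i) || i > model$n_cell)
          stop("apoptosis_multiplier target must be a cell: ", iv$target, call. = FALSE)
        m_decay[i] <- m_decay[i] * iv$factor
      } else if (iv$kind %in% c("production_inhibition", "production_enhancement")) {
        rows <- which(model$prod_cytokine == iv$target)
        if (!length(rows))
          stop("no producers for cytokine: ", iv$target, call. = FALSE)
        m_prod[rows] <- m_prod[rows] * iv$factor
      } else if (iv$kind == "receptor_blockade") {
        rows <- which(model$edge_source == iv$target)
        if (!length(rows))
          stop("no receptor-mediated edges for cytokine: ", iv$target, call. = FALSE)
        m_K[rows] <- m_K[rows] / iv$factor
      } else stop("unknown intervention kind: ", iv$kind, call. = FALSE)
    }
    list(kind = if (tr$kind == "fixed_time") 0L else 1L,
         species = if (tr$kind == "species_threshold") unname(idx[tr$species]) else -1L,
         value = if (tr$kind == "fixed_time") tr$time else tr$threshold,
         duration = arm$duration %||% Inf,
         m_prolif = m_prolif, m_decay = m_decay, m_prod = m_prod,
         m_conv = m_conv, m_K = m_K)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
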