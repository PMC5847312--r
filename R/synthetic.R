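# Synthetic toy-model generators. These produce fully specified, valid
# model bundles (as efcm_model objects; write_model() serializes them) with
# known network structure, so every pipeline stage is testable at toy scale.
# A fixed seed fully determines the output.

#' Sample kinetic constants for a set of reactions
#'
#' Log-uniform draws: `kcat_fwd` in \[1, 100\] 1/s, `K_M` in \[0.01, 1\] mM,
#' enzyme mass in \[1e4, 1e5\] Da, `Keq` in `keq_range`. A K_M is drawn for
#' every participant of every reaction (external participants included, so
#' transporter saturation responds to external substrate levels).
#'
#' @param stoich named list of stoichiometry maps (one per reaction, as from
#'   [parse_reaction_formula()]).
#' @param seed integer seed; fully determines the draw.
#' @param keq_range range for log-uniform Keq sampling.
#' @return list with `kinetics` (tibble: `id`, `kcat_fwd_per_s`, `keq`,
#'   `enzyme_mass_da`) and `km` (tibble: `reaction_id`, `compound_id`,
#'   `km_mM`).
#' @export
sample_kinetics <- function(stoich, seed = 1, keq_range = c(10, 1000)) {
  .with_seed(seed, {
    n <- length(stoich)
    kin <- tibble::tibble(
      id = names(stoich),
      kcat_fwd_per_s = exp(stats::runif(n, log(1), log(100))),
      keq = exp(stats::runif(n, log(keq_range[1]), log(keq_range[2]))),
      enzyme_mass_da = exp(stats::runif(n, log(1e4), log(1e5)))
    )
    km <- dplyr::bind_rows(lapply(names(stoich), function(r) {
      ids <- names(stoich[[r]])
      tibble::tibble(
        reaction_id = r,
        compound_id = ids,
        km_mM = exp(stats::runif(length(ids), log(0.01), log(1)))
      )
    }))
    list(kinetics = kin, km = km)
  })
}

# Shared assembly: build an efcm_model from structure + sampled kinetics,
# resampling Keq until every biomass-producing EFM admits a nonempty
# metabolite polytope (feasibility by construction, not post-hoc filtering).
.assemble_toy <- function(compounds, reactions_struct, config, seed,
                          keq_range = c(10, 1000), fixed = NULL,
                          ensure_feasible = TRUE, max_tries = 50) {
  for (try in seq_len(max_tries)) {
    stoich <- lapply(reactions_struct$formula,
                     function(f) parse_reaction_formula(f)$stoich)
    names(stoich) <- reactions_struct$id
    kin <- sample_kinetics(stoich, seed = seed + (try - 1) * 1000,
                           keq_range = keq_range)
    rx <- dplyr::left_join(reactions_struct, kin$kinetics, by = "id")
    km <- kin$km
    # fixed overrides pin chosen constants (e.g. a non-limiting biomass kcat)
    if (!is.null(fixed)) {
      for (col in intersect(names(fixed), c("kcat_fwd_per_s", "keq",
                                            "enzyme_mass_da"))) {
        pin <- !is.na(fixed[[col]])
        rx[[col]][match(fixed$id[pin], rx$id)] <- fixed[[col]][pin]
      }
    }
    model <- efcm_model(compounds, rx, km, config)
    if (!ensure_feasible) return(model)
    efms <- enumerate_efms(model)
    bm <- which(efms$meta$biomass_producing)
    feasible <- all(vapply(bm, function(j) {
      net <- .active_network(model, efms$fluxes[, j])
      .max_min_theta(net)$min_theta > 1e-6
    }, logical(1)))
    if (feasible) return(model)
  }
  stop("could not sample feasible kinetics in ", max_tries, " attempts",
       call. = FALSE)
}

.toy_config <- function(...) {
  utils::modifyList(
    list(
      biomass_flux_convention_mM_per_s = 1,
      v_bm_mass_mg_per_l_per_h = 216000,
      growth_params = list(a = 0.27, b = 0.2, f_prot = 0.5,
                           v_bm_mass = 216000)
    ),
    list(...)
  )
}

#' Linear-chain toy model
#'
#' `uptake -> M1 -> ... -> Mn -> biomass`: exactly one elementary flux
#' mode, thermodynamically feasible by construction (every Keq is at least
#' 10, so the flat metabolite profile already has positive driving force on
#' every step). The external substrate carries 6 carbons and the default
#' biomass mass-flux constant is chosen so the single mode's yield is
#' 10 g/C-mol at unit uptake.
#'
#' @param n number of internal chain metabolites (>= 1).
#' @param seed integer seed for the kinetics draw.
#' @return an `efcm_model`.
#' @export
make_chain_model <- function(n = 3, seed = 1) {
  stopifnot(n >= 1)
  mets <- paste0("M", seq_len(n))
  compounds <- tibble::tibble(
    id = c("S", mets),
    is_external = c(TRUE, rep(FALSE, n)),
    fixed_conc_mM = c(100, rep(NA_real_, n)),
    c_min_mM = NA_real_, c_max_mM = NA_real_,
    carbon_count = 6L
  )
  rxn <- tibble::tibble(
    id = c("upt", if (n > 1) paste0("r", seq_len(n - 1)), "bm"),
    formula = c(
      "S -> M1",
      if (n > 1) paste(mets[-n], "->", mets[-1]),
      paste(mets[n], "->")
    ),
    tags = ""
  )
  .assemble_toy(
    compounds, rxn,
    .toy_config(biomass_reaction_id = "bm",
                glucose_uptake_reaction_id = "upt",
                glucose_compound_id = "S"),
    seed = seed,
    fixed = tibble::tibble(id = "bm", kcat_fwd_per_s = 1e6, keq = 1e6)
  )
}

#' Diamond toy model
#'
#' Two parallel conversions of A into B plus uptake and biomass: exactly
#' two elementary flux modes, one per branch.
#'
#' @param seed integer seed for the kinetics draw.
#' @return an `efcm_model`.
#' @export
make_diamond_model <- function(seed = 1) {
  compounds <- tibble::tibble(
    id = c("S", "A", "B"),
    is_external = c(TRUE, FALSE, FALSE),
    fixed_conc_mM = c(100, NA, NA),
    c_min_mM = NA_real_, c_max_mM = NA_real_,
    carbon_count = 6L
  )
  rxn <- tibble::tibble(
    id = c("upt", "p1", "p2", "bm"),
    formula = c("S -> A", "A -> B", "A -> B", "B ->"),
    tags = ""
  )
  .assemble_toy(
    compounds, rxn,
    .toy_config(biomass_reaction_id = "bm",
                glucose_uptake_reaction_id = "upt",
                glucose_compound_id = "S"),
    seed = seed,
    fixed = tibble::tibble(id = "bm", kcat_fwd_per_s = 1e6, keq = 1e6)
  )
}

#' Branch trade-off toy model (certified rate/yield trade-off)
#'
#' Two routes from external glucose to biomass: route H (`rH`, carbon
#' conserving: high yield, but slow and weakly driven, hence expensive) and
#' route L (`rL`, secretes half its carbon as waste: low yield, but fast
#' and strongly driven, hence cheap). The kinetic constants are fixed, not
#' sampled, so the fixture is certified: route H wins on yield
#' (10 vs 5 g/C-mol) and route L wins on growth rate. Exactly two
#' biomass-producing elementary flux modes.
#'
#' @param seed accepted for interface uniformity; the fixture is fully
#'   deterministic and ignores it.
#' @return an `efcm_model`.
#' @export
make_branch_tradeoff_model <- function(seed = 1) {
  compounds <- tibble::tibble(
    id = c("glc", "A", "B", "waste"),
    is_external = c(TRUE, FALSE, FALSE, TRUE),
    fixed_conc_mM = c(100, NA, NA, 1),
    c_min_mM = NA_real_, c_max_mM = NA_real_,
    carbon_count = c(6L, 6L, 6L, 3L)
  )
  rxn <- tibble::tibble(
    id = c("pts", "rH", "rL", "bm"),
    formula = c("glc -> A", "A -> B", "2 A -> B + 2 waste", "B ->"),
    kcat_fwd_per_s = c(50, 2, 100, 1e6),
    keq = c(1000, 10, 1e6, 1e6),
    enzyme_mass_da = c(3e4, 5e4, 2e4, 1e4),
    tags = ""
  )
  km <- tibble::tibble(
    reaction_id = c("pts", "pts", "rH", "rH", "rL", "rL", "rL", "bm"),
    compound_id = c("glc", "A", "A", "B", "A", "B", "waste", "B"),
    km_mM = c(0.2, 0.5, 0.5, 0.5, 0.5, 0.5, 1, 0.5)
  )
  efcm_model(
    compounds, rxn, km,
    .toy_config(biomass_reaction_id = "bm",
                glucose_uptake_reaction_id = "pts",
                glucose_compound_id = "glc")
  )
}

#' Random toy network
#'
#' Draws a random internal network on top of an uptake -> ... -> biomass
#' backbone: extra reactions with 1-2 substrates and 1-2 products, unit or
#' double coefficients, reversible with probability `p_rev`. Intended for
#' property tests of the enumeration machinery (oracle comparisons on
#' networks of at most ~12 reactions).
#'
#' @param n_internal number of internal metabolites (>= 2).
#' @param n_extra number of random internal reactions beyond the backbone.
#' @param seed integer seed; fully determines the topology and kinetics.
#' @param p_rev probability that an extra reaction is reversible.
#' @param ensure_feasible resample Keq until every biomass EFM has a
#'   nonempty metabolite polytope (needed for ECM tests; enumeration-only
#'   tests can skip it).
#' @return an `efcm_model`.
#' @export
make_random_model <- function(n_internal = 4, n_extra = 3, seed = 1,
                              p_rev = 0.3, ensure_feasible = FALSE) {
  stopifnot(n_internal >= 2)
  mets <- paste0("M", seq_len(n_internal))
  topo <- .with_seed(seed, {
    extra <- character(n_extra)
    for (k in seq_len(n_extra)) {
      ns <- sample(1:2, 1)
      subs <- sample(mets, ns)
      avail <- setdiff(mets, subs)
      np <- sample(seq_len(min(2, length(avail))), 1)
      prods <- sample(avail, np)
      coef <- function(ids) paste(
        ifelse(stats::runif(length(ids)) < 0.25, "2 ", ""), ids,
        sep = "", collapse = " + ")
      arrow <- if (stats::runif(1) < p_rev) "<=>" else "->"
      extra[k] <- paste(coef(subs), arrow, coef(prods))
    }
    extra
  })
  compounds <- tibble::tibble(
    id = c("S", mets),
    is_external = c(TRUE, rep(FALSE, n_internal)),
    fixed_conc_mM = c(100, rep(NA_real_, n_internal)),
    c_min_mM = NA_real_, c_max_mM = NA_real_,
    carbon_count = 6L
  )
  rxn <- tibble::tibble(
    id = c("upt", paste0("x", seq_len(n_extra)), "chain", "bm"),
    formula = c("S -> M1", topo,
                paste0("M1 -> M", n_internal),
                paste0("M", n_internal, " ->")),
    tags = ""
  )
  .assemble_toy(
    compounds, rxn,
    .toy_config(biomass_reaction_id = "bm",
                glucose_uptake_reaction_id = "upt",
                glucose_compound_id = "S"),
    seed = seed + 7,
    fixed = tibble::tibble(id = "bm", kcat_fwd_per_s = 1e6, keq = 1e6),
    ensure_feasible = ensure_feasible
  )
}
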