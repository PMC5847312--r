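# Toy fixtures built in code. The generators in the package cover the
# standard topologies; these add purpose-built variants (oxygen tags, dead
# ends, hand-solvable kinetics).

# Two routes to biomass, one oxygen-dependent (resp), one oxygen-free but
# half-yield (ferm, tagged oxygen_sensitive so the condition classes are
# all exercised). Oxygen enters resp's saturation and driving force.
make_oxygen_toy <- function() {
  compounds <- tibble::tibble(
    id = c("glc", "o2", "A", "B", "waste"),
    is_external = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    fixed_conc_mM = c(100, 0.21, NA, NA, 1),
    c_min_mM = NA_real_, c_max_mM = NA_real_,
    carbon_count = c(6L, 0L, 6L, 6L, 3L)
  )
  rxn <- tibble::tibble(
    id = c("pts", "resp", "ferm", "bm"),
    formula = c("glc -> A", "A + o2 -> B", "2 A -> B + 2 waste", "B ->"),
    kcat_fwd_per_s = c(50, 20, 100, 1e6),
    keq = c(1000, 1e6, 1e6, 1e6),
    enzyme_mass_da = c(3e4, 4e4, 2e4, 1e4),
    tags = c("", "oxygen_dependent", "oxygen_sensitive", "")
  )
  km <- tibble::tibble(
    reaction_id = c("pts", "pts", "resp", "resp", "resp",
                    "ferm", "ferm", "ferm", "bm"),
    compound_id = c("glc", "A", "A", "o2", "B", "A", "B", "waste", "B"),
    km_mM = c(0.2, 0.5, 0.5, 0.05, 0.5, 0.5, 0.5, 1, 0.5)
  )
  efcm_model(compounds, rxn, km, list(
    biomass_reaction_id = "bm",
    glucose_uptake_reaction_id = "pts",
    glucose_compound_id = "glc",
    oxygen_compound_id = "o2",
    biomass_flux_convention_mM_per_s = 1,
    v_bm_mass_mg_per_l_per_h = 216000,
    growth_params = list(a = 0.27, b = 0.2, f_prot = 0.5,
                         v_bm_mass = 216000)
  ))
}

# Branch trade-off model plus a reaction no elementary mode can use (a dead
# end: its product has no consumer).
make_deadend_toy <- function() {
  m <- make_branch_tradeoff_model()
  compounds <- dplyr::bind_rows(
    m$compounds,
    tibble::tibble(id = "D", is_external = FALSE, fixed_conc_mM = NA,
                   c_min_mM = 1e-3, c_max_mM = 10, carbon_count = 6L,
                   name = "D"))
  rxn <- dplyr::bind_rows(
    m$reactions[, c("id", "formula", "kcat_fwd_per_s", "keq",
                    "enzyme_mass_da", "tags")],
    tibble::tibble(id = "dead", formula = "A -> D", kcat_fwd_per_s = 10,
                   keq = 100, enzyme_mass_da = 2e4, tags = ""))
  km <- dplyr::bind_rows(
    m$km,
    tibble::tibble(reaction_id = "dead", compound_id = c("A", "D"),
                   km_mM = c(0.5, 0.5)))
  efcm_model(compounds, rxn, km, m$config)
}

# Route H of the branch model split into two sequential steps, so two
# reactions are exclusive to the same single mode.
make_split_branch_toy <- function() {
  m <- make_branch_tradeoff_model()
  compounds <- dplyr::bind_rows(
    m$compounds,
    tibble::tibble(id = "C", is_external = FALSE, fixed_conc_mM = NA,
                   c_min_mM = 1e-3, c_max_mM = 10, carbon_count = 6L,
                   name = "C"))
  rxn <- m$reactions[, c("id", "formula", "kcat_fwd_per_s", "keq",
                         "enzyme_mass_da", "tags")]
  rxn <- rxn[rxn$id != "rH", ]
  rxn <- dplyr::bind_rows(
    rxn,
    tibble::tibble(id = c("rH1", "rH2"), formula = c("A -> C", "C -> B"),
                   kcat_fwd_per_s = c(2, 2), keq = c(10, 10),
                   enzyme_mass_da = c(5e4, 5e4), tags = ""))
  km <- m$km[m$km$reaction_id != "rH", ]
  km <- dplyr::bind_rows(
    km,
    tibble::tibble(reaction_id = c("rH1", "rH1", "rH2", "rH2"),
                   compound_id = c("A", "C", "C", "B"),
                   km_mM = 0.5))
  efcm_model(compounds, rxn, km, m$config)
}

# One costly reaction and a non-limiting biomass sink: the optimal
# metabolite level sits at the box bound that maximizes the costly
# reaction's driving force (1-D calculus case).
make_single_reaction_toy <- function() {
  compounds <- tibble::tibble(
    id = c("S", "M1"),
    is_external = c(TRUE, FALSE),
    fixed_conc_mM = c(100, NA),
    c_min_mM = c(NA, 1e-3), c_max_mM = c(NA, 10),
    carbon_count = 6L
  )
  rxn <- tibble::tibble(
    id = c("upt", "bm"),
    formula = c("S -> M1", "M1 ->"),
    kcat_fwd_per_s = c(10, 1e12),
    keq = c(100, 1e6),
    enzyme_mass_da = c(5e4, 1e4),
    tags = ""
  )
  km <- tibble::tibble(
    reaction_id = c("upt", "upt", "bm"),
    compound_id = c("S", "M1", "M1"),
    km_mM = c(0.2, 0.5, 0.5)
  )
  efcm_model(compounds, rxn, km, list(
    biomass_reaction_id = "bm",
    glucose_uptake_reaction_id = "upt",
    glucose_compound_id = "S",
    biomass_flux_convention_mM_per_s = 1,
    v_bm_mass_mg_per_l_per_h = 216000,
    growth_params = list(a = 0.27, b = 0.2, f_prot = 0.5,
                         v_bm_mass = 216000)
  ))
}

# Hand-solvable demand case for reaction "r" (A -> P, external P at 1 mM):
# K_A = 1 mM and Keq = 3, so at c_A = 2/3 mM: theta = ln(3 * (2/3)/1) =
# ln 2 (eta_rev = 1/2), s = c/K = 2/3 (eta_sat = s/(1+s) = 0.4, the product
# has no K_M entry), kcat = 10 => E = 1 / (10 * 0.5 * 0.4) = 0.5 mM.
make_hand_demand_toy <- function() {
  compounds <- tibble::tibble(
    id = c("S", "A", "P"),
    is_external = c(TRUE, FALSE, TRUE),
    fixed_conc_mM = c(100, NA, 1),
    c_min_mM = c(NA, 1e-3, NA), c_max_mM = c(NA, 10, NA),
    carbon_count = 6L
  )
  rxn <- tibble::tibble(
    id = c("feed", "r"),
    formula = c("S -> A", "A -> P"),
    kcat_fwd_per_s = c(10, 10),
    keq = c(100, 3),
    enzyme_mass_da = c(1e4, 1e4),
    tags = ""
  )
  km <- tibble::tibble(
    reaction_id = c("feed", "feed", "r"),
    compound_id = c("S", "A", "A"),
    km_mM = c(0.5, 0.5, 1)
  )
  efcm_model(compounds, rxn, km, list(
    biomass_reaction_id = "r",
    glucose_uptake_reaction_id = "feed",
    glucose_compound_id = "S",
    biomass_flux_convention_mM_per_s = 1,
    v_bm_mass_mg_per_l_per_h = 216000,
    growth_params = list(a = 0.27, b = 0.2, f_prot = 0.5,
                         v_bm_mass = 216000)
  ))
}
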