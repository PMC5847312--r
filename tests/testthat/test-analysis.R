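test_that("the branch fixture shows a strict rate/yield trade-off", {
  m <- make_branch_tradeoff_model()
  efms <- enumerate_efms(m)
  spec <- rate_yield_spectrum(m, efms)
  expect_identical(nrow(spec), 2L)
  expect_true(all(spec$status == "ok"))
  low <- which.min(spec$yield_g_per_cmol)
  high <- which.max(spec$yield_g_per_cmol)
  expect_gt(spec$mu[low], spec$mu[high])        # cheap route grows faster
  expect_equal(spec$yield_g_per_cmol[high], 10)
  expect_equal(spec$yield_g_per_cmol[low], 5)
  # both modes are Pareto-optimal, returned in descending-yield order
  front <- pareto_front(spec)
  expect_identical(nrow(front), 2L)
  expect_true(all(diff(front$yield_g_per_cmol) < 0))
})

test_that("a single-mode spectrum equals a direct solve plus conversion", {
  m <- make_chain_model(3, seed = 1)
  efms <- enumerate_efms(m)
  spec <- rate_yield_spectrum(m, efms)
  expect_identical(nrow(spec), 1L)
  sol <- minimize_enzyme_cost(m, efms$fluxes[, 1])
  expect_equal(spec$E_met, sol$E_met)
  expect_equal(spec$mu,
               growth_rate_from_cost(sol$E_met, m$config$growth_params))
})

test_that("pareto extraction matches the pairwise-domination oracle", {
  expect_identical(nrow(pareto_front(
    tibble::tibble(efm_id = 1L, mu = 0.5, yield_g_per_cmol = 3))), 1L)
  withr::with_seed(31, {
    for (k in 1:5) {
      pts <- tibble::tibble(
        efm_id = 1:100,
        mu = stats::runif(100),
        yield_g_per_cmol = stats::runif(100))
      # include ties to exercise the duplicate rule
      pts$mu[11] <- pts$mu[12]
      pts$yield_g_per_cmol[13] <- pts$yield_g_per_cmol[14]
      front <- pareto_front(pts)
      expect_identical(sort(front$efm_id), oracle_pareto_ids(pts))
      # mutual non-domination inside the front
      expect_identical(sort(front$efm_id), oracle_pareto_ids(front))
    }
  })
})

test_that("a monod grid equals its independent single-condition cells", {
  m <- make_branch_tradeoff_model()
  efms <- enumerate_efms(m)
  glc <- c(0.05, 1, 50)
  surf <- monod_scan(m, efms, glc)
  expect_identical(nrow(surf), 3L)
  for (i in seq_along(glc)) {
    spec <- rate_yield_spectrum(m, efms,
                                efcm_condition(c(glc = glc[i])))
    expect_equal(surf$mu[i], max(spec$mu))
    expect_identical(surf$winner_efm[i],
                     spec$efm_id[which.max(spec$mu)])
  }
})

test_that("growth is non-decreasing in glucose for every mode", {
  m <- make_branch_tradeoff_model()
  efms <- enumerate_efms(m)
  glc <- exp(seq(log(1e-3), log(100), length.out = 6))
  for (j in 1:2) {
    mu <- vapply(glc, function(g) {
      sol <- minimize_enzyme_cost(m, efms$fluxes[, j],
                                  efcm_condition(c(glc = g)))
      growth_rate_from_cost(sol$E_met, m$config$growth_params)
    }, numeric(1))
    expect_true(all(diff(mu) > -1e-10))
  }
})

test_that("anaerobic modes are oxygen-independent; aerobic ones are not", {
  m <- make_oxygen_toy()
  efms <- enumerate_efms(m)
  cache <- new_ecm_cache()
  surf <- monod_scan(m, efms, glucose_grid = 100,
                     oxygen_grid = c(0.01, 0.21, 5), cache = cache)
  expect_identical(nrow(surf), 3L)
  ferm_id <- efms$meta$efm_id[efms$fluxes["ferm", ] != 0 &
                                efms$meta$biomass_producing]
  mu_ferm <- vapply(c(0.01, 0.21, 5), function(o2) {
    sol <- minimize_enzyme_cost(
      m, efms$fluxes[, ferm_id],
      efcm_condition(c(glc = 100, o2 = o2)))
    growth_rate_from_cost(sol$E_met, m$config$growth_params)
  }, numeric(1))
  expect_equal(mu_ferm[1], mu_ferm[2], tolerance = 1e-10)
  expect_equal(mu_ferm[2], mu_ferm[3], tolerance = 1e-10)
  resp_id <- efms$meta$efm_id[efms$fluxes["resp", ] != 0 &
                                efms$meta$biomass_producing]
  mu_resp <- vapply(c(0.01, 0.21, 5), function(o2) {
    sol <- minimize_enzyme_cost(
      m, efms$fluxes[, resp_id],
      efcm_condition(c(glc = 100, o2 = o2)))
    growth_rate_from_cost(sol$E_met, m$config$growth_params)
  }, numeric(1))
  expect_true(all(diff(mu_resp) > 0))
  # at zero oxygen only the anaerobic-feasible class competes
  surf0 <- monod_scan(m, efms, glucose_grid = 100, oxygen_grid = 0,
                      cache = cache)
  expect_identical(surf0$winner_efm, ferm_id)
})

test_that("envelope sensitivities match re-optimized finite differences", {
  m <- make_branch_tradeoff_model()
  efms <- enumerate_efms(m)
  gp <- m$config$growth_params
  for (j in 1:2) {
    flux <- efms$fluxes[, j]
    sol <- minimize_enzyme_cost(m, flux)
    sens <- growth_sensitivities(m, sol)
    mu0 <- growth_rate_from_cost(sol$E_met, gp)
    fd_mu <- function(po_row, base) {
      h <- 1e-4
      vals <- vapply(c(1 + h, 1 - h), function(f) {
        po <- po_row
        po$value <- base * f
        s <- minimize_enzyme_cost(m, flux, efcm_condition(
          param_overrides = po))
        growth_rate_from_cost(s$E_met, gp)
      }, numeric(1))
      (vals[1] - vals[2]) / (log(1 + h) - log(1 - h))
    }
    check <- function(param, rid, cpd = NA_character_) {
      row <- sens[sens$param == param &
                    (is.na(rid) | sens$reaction_id %in% rid) &
                    (is.na(cpd) | sens$compound_id %in% cpd), ]
      expect_identical(nrow(row), 1L)
      base <- switch(param,
        kcat_fwd = m$reactions$kcat_fwd_per_s[m$reactions$id == rid],
        keq = m$reactions$keq[m$reactions$id == rid],
        km = m$km$km_mM[m$km$reaction_id == rid & m$km$compound_id == cpd])
      po <- tibble::tibble(reaction_id = rid, param = param,
                           compound_id = cpd, value = NA_real_)
      fd <- fd_mu(po, base)
      # tight relative agreement for non-negligible sensitivities; absolute
      # agreement (FD noise floor) for the near-zero ones
      if (abs(row$dmu_dlnp) > 1e-8 * mu0) {
        expect_equal(row$dmu_dlnp, fd, tolerance = 1e-3)
      } else {
        expect_lt(abs(row$dmu_dlnp - fd), 1e-8 * mu0 + 1e-12)
      }
    }
    active <- sol$reactions$reaction_id
    for (rid in active) {
      check("kcat_fwd", rid)
      check("keq", rid)
    }
    check("km", "pts", "glc")
    check("km", "pts", "A")
  }
})

test_that("external-concentration sensitivity matches finite differences", {
  m <- make_branch_tradeoff_model()
  efms <- enumerate_efms(m)
  gp <- m$config$growth_params
  flux <- efms$fluxes[, 1]
  base_cond <- efcm_condition(c(glc = 1))
  sol <- minimize_enzyme_cost(m, flux, base_cond)
  sens <- growth_sensitivities(m, sol, base_cond)
  row <- sens[sens$param == "external_conc" & sens$compound_id == "glc", ]
  h <- 1e-4
  mu_at <- function(g) {
    s <- minimize_enzyme_cost(m, flux, efcm_condition(c(glc = g)))
    growth_rate_from_cost(s$E_met, gp)
  }
  fd <- (mu_at(1 + h) - mu_at(1 - h)) / (log(1 + h) - log(1 - h))
  expect_equal(row$dmu_dlnp, fd, tolerance = 1e-3)
  expect_gt(row$dmu_dlnp, 0)  # more glucose, faster growth
})

test_that("sensitivities vanish off-support and obey the kcat sum rule", {
  m <- make_branch_tradeoff_model()
  efms <- enumerate_efms(m)
  j_low <- which(efms$fluxes["rL", ] != 0)
  sol <- minimize_enzyme_cost(m, efms$fluxes[, j_low])
  sens <- growth_sensitivities(m, sol)
  off <- sens[sens$reaction_id %in% "rH", ]
  expect_true(all(off$dEmet_dlnp == 0))
  kcat_sens <- sens$dEmet_dlnp[sens$param == "kcat_fwd"]
  expect_equal(sum(kcat_sens), -sol$E_met, tolerance = 1e-10)
  # halving a kcat costs (2 - 1) x the reaction's current cost share
  cost_pts <- sol$reactions$cost_mg_per_l[
    sol$reactions$reaction_id == "pts"]
  d <- sens$dEmet_dlnp[sens$param == "kcat_fwd" &
                         sens$reaction_id %in% "pts"]
  expect_equal(-d, cost_pts)  # dE/dln kcat = -cost => Delta ~ +cost at /2
})

test_that("knockout analysis reuses the spectrum and ranks correctly", {
  m <- make_deadend_toy()
  efms <- enumerate_efms(m)
  spec <- rate_yield_spectrum(m, efms)
  # a reaction no mode uses: zero advantage
  res <- knockout_analysis(m, efms, "dead", spectrum = spec)
  expect_identical(res$advantage, 0)
  expect_false(res$lethal)
  # knocking out the cheap route forces the expensive one
  res <- knockout_analysis(m, efms, "rL", spectrum = spec)
  mu_low <- max(spec$mu)
  mu_high <- max(spec$mu[spec$efm_id %in%
                           efms$meta$efm_id[efms$fluxes["rL", ] == 0]])
  expect_equal(res$advantage, mu_low / mu_high - 1)
  expect_gt(res$advantage, 0)
  # the survivor has the higher yield
  surv <- knockout_filter(efms, "rL")
  expect_gt(max(surv$meta$yield_g_per_cmol),
            max(efms$meta$yield_g_per_cmol[efms$fluxes["rL", ] != 0]))
  # the sole transporter is lethal
  res <- knockout_analysis(m, efms, "pts", spectrum = spec)
  expect_true(res$lethal)
  expect_identical(res$advantage, Inf)
  # knockout growth never exceeds wild type
  for (rid in rownames(efms$fluxes)) {
    r <- knockout_analysis(m, efms, rid, spectrum = spec)
    expect_lte(ifelse(r$lethal, 0, r$mu_ko), r$mu_wt)
  }
})

test_that("epistasis is symmetric, neutral for unused reactions", {
  m <- make_deadend_toy()
  efms <- enumerate_efms(m)
  spec <- rate_yield_spectrum(m, efms)
  e1 <- epistasis(m, efms, "rH", "dead", spectrum = spec)
  expect_identical(e1$score, 1)
  e_ab <- epistasis(m, efms, "rH", "rL", spectrum = spec)
  e_ba <- epistasis(m, efms, "rL", "rH", spectrum = spec)
  expect_identical(e_ab$score, e_ba$score)
  expect_true(e_ab$lethal_ab)
})

test_that("co-located knockouts on one mode collapse to mu_wt over mu_A", {
  m <- make_split_branch_toy()
  efms <- enumerate_efms(m)
  expect_identical(length(efms), 2L)
  spec <- rate_yield_spectrum(m, efms)
  e <- epistasis(m, efms, "rH1", "rH2", spectrum = spec)
  expect_equal(e$mu_a, e$mu_b)
  expect_equal(e$mu_a, e$mu_ab)
  expect_equal(e$score, e$mu_wt / e$mu_a)
})
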