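test_that("driving force reproduces equilibrium and unit cases", {
  m <- make_hand_demand_toy()
  # A -> P with Keq = 3, c_P = 1: theta = ln(3 c_A)
  expect_equal(driving_force(m, "r", c(A = log(1 / 3))), 0)
  expect_equal(driving_force(m, "r", c(A = log(exp(1) / 3))), 1)
})

test_that("driving force agrees with a mass-action free-energy oracle", {
  m <- make_branch_tradeoff_model()
  cp <- m$compounds
  withr::with_seed(11, {
    for (k in 1:100) {
      conc_int <- stats::setNames(exp(stats::runif(2, log(1e-3), log(10))),
                                  c("A", "B"))
      conc_all <- c(conc_int,
                    stats::setNames(cp$fixed_conc_mM[cp$is_external],
                                    cp$id[cp$is_external]))
      rid <- sample(m$reactions$id, 1)
      expect_equal(driving_force(m, rid, log(conc_int)),
                   oracle_theta(m, rid, conc_all),
                   tolerance = 1e-12)
    }
  })
})

test_that("efficiency factors hit their closed-form special cases", {
  m <- make_hand_demand_toy()
  # theta = ln 2 at c_A = 2/3 -> eta_rev = 1/2
  ef <- efficiency_factors(m, "r", c(A = log(2 / 3)))
  expect_equal(ef$theta, log(2))
  expect_equal(ef$eta_rev, 0.5)
  expect_equal(ef$eta_sat, 0.4)  # s/(1+s) with s = 2/3, product unbound
  # single substrate at c = K_M: eta_sat = 1/2
  ef <- efficiency_factors(m, "r", c(A = log(1)))
  expect_equal(ef$eta_sat, 0.5)
  # saturating substrate: eta_sat -> 1 monotonically
  ratios <- c(1, 10, 100, 1e4)
  sats <- vapply(ratios, function(rho)
    efficiency_factors(m, "r", c(A = log(rho)))$eta_sat, numeric(1))
  expect_true(all(diff(sats) > 0))
  expect_equal(sats[4], 1, tolerance = 1e-3)
  # infeasible direction errors
  expect_error(efficiency_factors(m, "r", c(A = log(0.01))),
               "thermodynamically infeasible")
})

test_that("enzyme demand matches the hand-computed worked example", {
  m <- make_hand_demand_toy()
  x <- c(A = log(2 / 3))
  E <- enzyme_demand(m, c(r = 1), x)
  expect_equal(unname(E["r"]), 0.5)   # 1 / (10 * 0.5 * 0.4)
  expect_equal(unname(E["feed"]), 0)  # zero flux, zero demand
})

test_that("halving kcat at fixed metabolite levels exactly doubles demand", {
  m <- make_branch_tradeoff_model()
  efms <- enumerate_efms(m)
  sol <- minimize_enzyme_cost(m, efms$fluxes[, 1])
  E_old <- enzyme_demand(m, sol$flux, sol$x)
  for (rid in names(E_old)[E_old > 0]) {
    kc <- m$reactions$kcat_fwd_per_s[m$reactions$id == rid]
    cond <- efcm_condition(param_overrides = tibble::tibble(
      reaction_id = rid, param = "kcat_fwd", compound_id = NA, value = kc / 2))
    E_new <- enzyme_demand(m, sol$flux, sol$x, cond)
    expect_identical(unname(E_new[rid] / E_old[rid]), 2)
    # other reactions untouched
    others <- setdiff(names(E_old)[E_old > 0], rid)
    expect_identical(unname(E_new[others]), unname(E_old[others]))
  }
})

test_that("total cost is the mass-weighted demand, order-independent", {
  m <- make_branch_tradeoff_model()
  x <- c(A = log(5), B = log(0.01))
  flux <- c(pts = 1, rH = 1, bm = 1)
  E <- enzyme_demand(m, flux, x)
  w <- stats::setNames(m$reactions$enzyme_mass_da, m$reactions$id)
  expect_equal(total_enzyme_cost(m, flux, x), sum(w * E))
  expect_equal(total_enzyme_cost(m, rev(flux), x),
               total_enzyme_cost(m, flux, x))
  # all-equal masses make cost equal the demand sum
  m1 <- m
  m1$reactions$enzyme_mass_da <- rep(1, nrow(m1$reactions))
  expect_equal(total_enzyme_cost(m1, flux, x),
               sum(enzyme_demand(m1, flux, x)))
})

test_that("the ECM optimum matches an exhaustive 400x400 grid search", {
  for (seed in c(3, 8)) {
    m <- make_chain_model(2, seed = seed)
    efms <- enumerate_efms(m)
    flux <- efms$fluxes[, 1]
    sol <- minimize_enzyme_cost(m, flux)
    expect_true(sol$converged)
    grid_min <- oracle_grid_min(m, flux, n_grid = 400)
    expect_lte(sol$E_met, grid_min * (1 + 1e-12))
    expect_lt((grid_min - sol$E_met) / sol$E_met, 1e-4)
  }
})

test_that("solver cost is below the oracle cost at random feasible points", {
  m <- make_branch_tradeoff_model()
  efms <- enumerate_efms(m)
  for (j in 1:2) {
    flux <- efms$fluxes[, j]
    sol <- minimize_enzyme_cost(m, flux)
    pts <- sample_feasible_conc(m, flux, n = 1000, seed = 100 + j,
                                max_tries = 20000)
    expect_gte(length(pts), 500)
    vals <- vapply(pts, function(conc) oracle_cost(m, flux, conc),
                   numeric(1))
    expect_true(all(sol$E_met <= vals * (1 + 1e-9)))
  }
})

test_that("cost is convex along random segments in log space", {
  m <- make_branch_tradeoff_model()
  efms <- enumerate_efms(m)
  flux <- efms$fluxes[, 2]
  pts <- sample_feasible_conc(m, flux, n = 200, seed = 5, max_tries = 5000)
  cost_x <- function(x) oracle_cost(m, flux, exp(x))
  ok <- 0
  for (k in seq_len(100)) {
    x1 <- log(pts[[2 * k - 1]])
    x2 <- log(pts[[2 * k]])
    f1 <- cost_x(x1)
    f2 <- cost_x(x2)
    for (lam in c(0.25, 0.5, 0.75)) {
      xm <- lam * x1 + (1 - lam) * x2
      expect_lte(cost_x(xm), lam * f1 + (1 - lam) * f2 + 1e-9)
      ok <- ok + 1
    }
  }
  expect_identical(ok, 300)
})

test_that("widening metabolite bounds never increases the optimum", {
  m <- make_chain_model(3, seed = 2)
  efms <- enumerate_efms(m)
  flux <- efms$fluxes[, 1]
  widen <- function(model, f) {
    int <- !model$compounds$is_external
    model$compounds$c_min_mM[int] <- model$compounds$c_min_mM[int] / f
    model$compounds$c_max_mM[int] <- model$compounds$c_max_mM[int] * f
    model
  }
  costs <- vapply(c(1, 2, 10, 100), function(f)
    minimize_enzyme_cost(widen(m, f), flux)$E_met, numeric(1))
  expect_true(all(diff(costs) <= 1e-9 * costs[-length(costs)]))
})

test_that("optimal cost scales linearly with the flux and x is unchanged", {
  m <- make_branch_tradeoff_model()
  efms <- enumerate_efms(m)
  flux <- efms$fluxes[, 1]
  s1 <- minimize_enzyme_cost(m, flux)
  s3 <- minimize_enzyme_cost(m, flux * 3.5)
  expect_equal(s3$E_met, 3.5 * s1$E_met, tolerance = 1e-8)
  expect_equal(s3$x, s1$x, tolerance = 1e-5)
})

test_that("raising a pure-substrate external level weakly lowers the cost", {
  m <- make_branch_tradeoff_model()
  efms <- enumerate_efms(m)
  flux <- efms$fluxes[, 1]
  costs <- vapply(c(0.01, 0.1, 1, 10, 100), function(g)
    minimize_enzyme_cost(m, flux,
                         efcm_condition(c(glc = g)))$E_met, numeric(1))
  expect_true(all(diff(costs) < 0))
})

test_that("an empty metabolite polytope raises a typed error", {
  m <- make_chain_model(3, seed = 1)
  efms <- enumerate_efms(m)
  # collapse every Keq so no profile can be thermodynamically consistent
  po <- tibble::tibble(reaction_id = c("upt", "r1", "r2"), param = "keq",
                       compound_id = NA, value = 1e-12)
  err <- expect_error(
    minimize_enzyme_cost(m, efms$fluxes[, 1],
                         efcm_condition(param_overrides = po)),
    class = "efcm_infeasible_error")
  expect_true(nzchar(err$reaction))
})

test_that("capacity utilization equals ideal over actual demand", {
  m <- make_branch_tradeoff_model()
  efms <- enumerate_efms(m)
  sol <- minimize_enzyme_cost(m, efms$fluxes[, 2])
  cu <- capacity_utilization(sol)
  expect_true(all(cu > 0 & cu < 1))
  kcat <- stats::setNames(m$reactions$kcat_fwd_per_s, m$reactions$id)
  for (rid in names(cu)) {
    E_ideal <- sol$reactions$flux[sol$reactions$reaction_id == rid] /
      kcat[[rid]]
    E_actual <- sol$reactions$enzyme_mM[sol$reactions$reaction_id == rid]
    expect_equal(unname(cu[rid]), E_ideal / E_actual)
  }
  # near-saturating, strongly driven reaction approaches full utilization
  mh <- make_hand_demand_toy()
  ef <- efficiency_factors(mh, "r", c(A = log(10)))
  expect_gt(ef$eta_rev * ef$eta_sat, 0.85)
})
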