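#' Simulation conditions
#'
#' A condition fixes external metabolite concentrations and optionally
#' overrides kinetic parameters. Externals not named keep the model's
#' `fixed_conc_mM`.
#'
#' @param external_conc named numeric, concentrations in mM (> 0), e.g.
#'   `c(glc = 100, o2 = 0.21)`.
#' @param param_overrides optional tibble/data.frame with columns
#'   `reaction_id`, `param` (one of `"kcat_fwd"`, `"keq"`, `"km"`,
#'   `"enzyme_mass"`), `compound_id` (`NA` except for `"km"`), `value`.
#' @return object of class `efcm_condition`.
#' @export
efcm_condition <- function(external_conc = NULL, param_overrides = NULL) {
  if (!is.null(external_conc)) {
    stopifnot(is.numeric(external_conc), !is.null(names(external_conc)))
    if (any(external_conc < 0))
      stop("external concentrations must be >= 0", call. = FALSE)
  }
  if (!is.null(param_overrides)) {
    param_overrides <- tibble::as_tibble(param_overrides)
    stopifnot(all(c("reaction_id", "param", "value") %in%
                    names(param_overrides)))
    if (!"compound_id" %in% names(param_overrides))
      param_overrides$compound_id <- NA_character_
  }
  structure(list(external_conc = external_conc,
                 param_overrides = param_overrides),
            class = "efcm_condition")
}

# Apply a condition to a model: fix external concentrations and apply
# kinetic parameter overrides. Returns the modified model.
.condition_model <- function(model, condition = NULL) {
  if (is.null(condition)) return(model)
  stopifnot(inherits(condition, "efcm_condition"))
  ec <- condition$external_conc
  if (!is.null(ec)) {
    unknown <- setdiff(names(ec),
                       model$compounds$id[model$compounds$is_external])
    if (length(unknown) > 0)
      stop("condition names non-external or unknown compound(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    i <- match(names(ec), model$compounds$id)
    model$compounds$fixed_conc_mM[i] <- unname(ec)
  }
  po <- condition$param_overrides
  if (!is.null(po)) {
    for (k in seq_len(nrow(po))) {
      r <- po$reaction_id[k]
      ri <- match(r, model$reactions$id)
      if (is.na(ri))
        stop("param override references unknown reaction '", r, "'",
             call. = FALSE)
      val <- po$value[k]
      switch(po$param[k],
        kcat_fwd = { model$reactions$kcat_fwd_per_s[ri] <- val },
        keq = { model$reactions$keq[ri] <- val },
        enzyme_mass = { model$reactions$enzyme_mass_da[ri] <- val },
        km = {
          ki <- which(model$km$reaction_id == r &
                        model$km$compound_id == po$compound_id[k])
          if (length(ki) == 0)
            stop("param override references unknown K_M (", r, ", ",
                 po$compound_id[k], ")", call. = FALSE)
          model$km$km_mM[ki] <- val
        },
        stop("unknown parameter '", po$param[k], "' in override",
             call. = FALSE)
      )
    }
  }
  model
}

# Build the oriented active network for a flux vector: per active reaction,
# everything needed to evaluate driving force, efficiency factors, demand,
# and their gradients in log-concentration space.
#
# Reactions are oriented along their flux: for a reversible reaction running
# backward the stoichiometry is negated and Keq inverted (the factorized
# parameterization uses only kcat_fwd, so the same turnover applies).
.active_network <- function(model, flux, condition = NULL,
                            zero_tol = 1e-12) {
  model <- .condition_model(model, condition)
  cp <- model$compounds
  int_ids <- cp$id[!cp$is_external]
  ext_ln <- log(cp$fixed_conc_mM)
  names(ext_ln) <- cp$id

  flux <- flux[abs(flux) > zero_tol]
  active_int <- character(0)
  rxns <- list()
  for (r in names(flux)) {
    ri <- match(r, model$reactions$id)
    if (is.na(ri)) stop("unknown reaction '", r, "' in flux", call. = FALSE)
    s <- sign(flux[[r]])
    if (s < 0 && !model$reactions$reversible[ri])
      stop("negative flux through irreversible reaction '", r, "'",
           call. = FALSE)
    st <- model$stoich[[r]] * s
    keq <- model$reactions$keq[ri]^s
    ints <- intersect(names(st), int_ids)
    exts <- setdiff(names(st), ints)
    active_int <- union(active_int, ints)
    kmr <- model$km[model$km$reaction_id == r, ]
    sat_entry <- function(ids) {
      out <- list()
      for (id in ids) {
        k <- kmr$km_mM[match(id, kmr$compound_id)]
        if (is.na(k)) next  # no K_M: contributes to theta only
        out[[length(out) + 1]] <- list(
          id = id,
          a = abs(st[[id]]),
          lnK = log(k),
          fixed = if (id %in% int_ids) NA_real_ else ext_ln[[id]]
        )
      }
      out
    }
    rxns[[r]] <- list(
      id = r,
      v = abs(flux[[r]]),
      kcat = model$reactions$kcat_fwd_per_s[ri],
      w = model$reactions$enzyme_mass_da[ri],
      int_ids = ints,
      int_coef = if (length(ints) > 0) st[ints] else numeric(0),
      theta_const = log(keq) -
        (if (length(exts) > 0) sum(st[exts] * ext_ln[exts]) else 0),
      sat_sub = sat_entry(names(st)[st < 0]),
      sat_prod = sat_entry(names(st)[st > 0])
    )
  }
  vars <- intersect(int_ids, active_int)
  for (r in names(rxns)) {
    rxns[[r]]$int_idx <- match(rxns[[r]]$int_ids, vars)
    for (side in c("sat_sub", "sat_prod")) {
      rxns[[r]][[side]] <- lapply(rxns[[r]][[side]], function(e) {
        e$idx <- if (is.na(e$fixed)) match(e$id, vars) else NA_integer_
        e
      })
    }
  }
  list(
    rxns = rxns,
    vars = vars,
    lb = log(cp$c_min_mM[match(vars, cp$id)]),
    ub = log(cp$c_max_mM[match(vars, cp$id)]),
    model = model
  )
}

# Evaluate one oriented reaction at log-concentration vector x.
# Returns theta, eta_rev, eta_sat, E (mM), and optionally the gradient of
# ln E wrt x and the saturation bookkeeping needed for sensitivities.
.eval_reaction <- function(rx, x, grad = FALSE) {
  theta <- rx$theta_const -
    (if (length(rx$int_idx) > 0) sum(rx$int_coef * x[rx$int_idx]) else 0)
  if (theta <= 0) {
    return(list(theta = theta, eta_rev = NA_real_, eta_sat = NA_real_,
                E = Inf))
  }
  em <- exp(-theta)
  eta_rev <- 1 - em

  side_eval <- function(entries) {
    lnS <- 0; lnP <- 0
    sig <- numeric(length(entries))
    for (i in seq_along(entries)) {
      e <- entries[[i]]
      lx <- if (is.na(e$fixed)) x[e$idx] else e$fixed
      ls <- lx - e$lnK
      lnS <- lnS + e$a * ls
      lnP <- lnP + e$a * log1p(exp(ls))
      sig[i] <- 1 / (1 + exp(-ls))  # s/(1+s)
    }
    list(lnS = lnS, lnP = lnP, sig = sig)
  }
  sub <- side_eval(rx$sat_sub)
  prod_ <- side_eval(rx$sat_prod)
  P <- exp(sub$lnP)
  Q <- exp(prod_$lnP)
  D <- P + Q - 1
  eta_sat <- exp(sub$lnS) / D
  E <- rx$v / (rx$kcat * eta_rev * eta_sat)

  out <- list(theta = theta, eta_rev = eta_rev, eta_sat = eta_sat, E = E,
              P = P, Q = Q, D = D, sub = sub, prod = prod_)
  if (grad) {
    # d lnE / dx over the variable vector
    g <- numeric(length(x))
    thfac <- em / eta_rev  # e^-theta / (1 - e^-theta)
    if (length(rx$int_idx) > 0)
      g[rx$int_idx] <- g[rx$int_idx] + thfac * rx$int_coef
    for (i in seq_along(rx$sat_sub)) {
      e <- rx$sat_sub[[i]]
      if (is.na(e$fixed))
        g[e$idx] <- g[e$idx] - e$a + P * e$a * sub$sig[i] / D
    }
    for (i in seq_along(rx$sat_prod)) {
      e <- rx$sat_prod[[i]]
      if (is.na(e$fixed))
        g[e$idx] <- g[e$idx] + Q * e$a * prod_$sig[i] / D
    }
    out$dlnE_dx <- g
  }
  out
}

#' Thermodynamic driving force of a reaction
#'
#' `theta = ln Keq - sum_i n_i ln c_i` in units of RT, with the reaction
#' oriented along `orientation` (use -1 for a reversible reaction running
#' backward; Keq is inverted and stoichiometry negated). External
#' metabolites contribute their fixed concentrations.
#'
#' @param model an `efcm_model`.
#' @param reaction_id reaction.
#' @param x named log-concentration vector (ln mM) covering the reaction's
#'   internal reactants.
#' @param condition optional [efcm_condition()].
#' @param orientation +1 or -1.
#' @return theta (dimensionless).
#' @export
driving_force <- function(model, reaction_id, x, condition = NULL,
                          orientation = 1) {
  model <- .condition_model(model, condition)
  ri <- match(reaction_id, model$reactions$id)
  if (is.na(ri)) stop("unknown reaction '", reaction_id, "'", call. = FALSE)
  st <- model$stoich[[reaction_id]] * orientation
  keq <- model$reactions$keq[ri]^orientation
  cp <- model$compounds
  lnc <- vapply(names(st), function(id) {
    i <- match(id, cp$id)
    if (cp$is_external[i]) log(cp$fixed_conc_mM[i])
    else {
      if (!id %in% names(x))
        stop("x is missing internal metabolite '", id, "'", call. = FALSE)
      x[[id]]
    }
  }, numeric(1))
  log(keq) - sum(st * lnc)
}

#' Efficiency factors of a reaction at a metabolite profile
#'
#' Factorizes the common modular rate law into a thermodynamic efficiency
#' `eta_rev = 1 - exp(-theta)` and a saturation efficiency
#' `eta_sat = prod_sub (c/K)^a / (prod_sub (1+c/K)^a +
#' prod_prod (1+c/K)^b - 1)`, both in (0, 1] for a forward-driven reaction.
#'
#' @inheritParams driving_force
#' @return list with `theta`, `eta_rev`, `eta_sat`.
#' @export
efficiency_factors <- function(model, reaction_id, x, condition = NULL,
                               orientation = 1) {
  flux <- stats::setNames(as.numeric(orientation), reaction_id)
  net <- .active_network(model, flux, condition)
  xv <- .match_x(x, net$vars)
  ev <- .eval_reaction(net$rxns[[reaction_id]], xv)
  if (ev$theta <= 0)
    stop("driving force is non-positive (theta = ", format(ev$theta),
         ") for reaction '", reaction_id, "'; the direction is ",
         "thermodynamically infeasible at this metabolite profile",
         call. = FALSE)
  list(theta = ev$theta, eta_rev = ev$eta_rev, eta_sat = ev$eta_sat)
}

.match_x <- function(x, vars) {
  if (length(vars) == 0) return(numeric(0))
  if (is.null(names(x)))
    stop("x must be a named log-concentration vector", call. = FALSE)
  miss <- setdiff(vars, names(x))
  if (length(miss) > 0)
    stop("x is missing internal metabolite(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  unname(x[vars])
}

#' Enzyme demand of a flux mode at a metabolite profile
#'
#' `E_r = v_r / (kcat_fwd_r * eta_rev_r * eta_sat_r)` in mM for every
#' active reaction; zero-flux reactions have zero demand. Demand is linear
#' in the flux and inversely proportional to kcat at fixed metabolite
#' levels (halving a kcat exactly doubles the demand).
#'
#' @param model an `efcm_model`.
#' @param flux named flux vector (mM/s).
#' @param x named log-concentration vector (ln mM) for internal metabolites.
#' @param condition optional [efcm_condition()].
#' @return named numeric vector of enzyme concentrations (mM) over all
#'   model reactions.
#' @export
enzyme_demand <- function(model, flux, x, condition = NULL) {
  net <- .active_network(model, flux, condition)
  xv <- .match_x(x, net$vars)
  E <- stats::setNames(numeric(nrow(model$reactions)), model$reactions$id)
  for (r in names(net$rxns)) {
    ev <- .eval_reaction(net$rxns[[r]], xv)
    if (!is.finite(ev$E))
      stop("driving force is non-positive for reaction '", r,
           "' (theta = ", format(ev$theta), "); demand undefined",
           call. = FALSE)
    E[r] <- ev$E
  }
  E
}

#' Total enzyme cost of a flux mode at a metabolite profile
#'
#' Mass-weighted enzyme demand `E_met = sum_r w_r E_r` in mg/l.
#'
#' @inheritParams enzyme_demand
#' @return total cost (mg/l).
#' @export
total_enzyme_cost <- function(model, flux, x, condition = NULL) {
  E <- enzyme_demand(model, flux, x, condition)
  w <- stats::setNames(model$reactions$enzyme_mass_da, model$reactions$id)
  sum(w[names(E)] * E)
}

# Feasibility pre-solve: maximize the minimal driving force over the box by
# annealed softmin (log-sum-exp) ascent. Returns x and the hard minimum.
.max_min_theta <- function(net) {
  nv <- length(net$vars)
  rxns <- net$rxns
  thetas <- function(x) vapply(rxns, function(rx) {
    rx$theta_const -
      (if (length(rx$int_idx) > 0) sum(rx$int_coef * x[rx$int_idx]) else 0)
  }, numeric(1))
  if (nv == 0) {
    th <- thetas(numeric(0))
    return(list(x = numeric(0), min_theta = min(th), thetas = th))
  }
  x <- (net$lb + net$ub) / 2
  for (tau in c(1, 0.3, 0.1, 0.03, 0.01, 0.003, 0.001)) {
    fn <- function(x) tau * .logsumexp(-thetas(x) / tau)
    gr <- function(x) {
      th <- thetas(x)
      p <- exp((-th / tau) - .logsumexp(-th / tau))
      g <- numeric(nv)
      for (k in seq_along(rxns)) {
        rx <- rxns[[k]]
        if (length(rx$int_idx) > 0)
          g[rx$int_idx] <- g[rx$int_idx] + p[k] * rx$int_coef
      }
      g
    }
    res <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        lower = net$lb, upper = net$ub,
                        control = list(maxit = 200))
    x <- res$par
  }
  th <- thetas(x)
  list(x = x, min_theta = min(th), thetas = th)
}

#' Minimize the enzyme cost of a flux mode (ECM)
#'
#' Minimizes `E_met = sum_r w_r E_r` over log-metabolite concentrations
#' within the model's concentration box, subject to positive driving force
#' along every active reaction. The objective is strictly convex in
#' log-concentration space for the common modular rate law, so a single
#' gradient-based solve from a feasible interior point finds the global
#' minimum; the cost itself diverges as any driving force approaches zero,
#' which keeps iterates interior.
#'
#' A feasibility pre-solve maximizes the minimal driving force; if even
#' that maximum is below `theta_floor` the metabolite polytope is empty and
#' a `efcm_infeasible_error` is raised naming the most constrained
#' reaction.
#'
#' @param model an `efcm_model`.
#' @param flux named flux vector (mM/s), typically an EFM column.
#' @param condition optional [efcm_condition()].
#' @param theta_floor strict positivity floor for driving forces (RT units).
#' @param control passed to [stats::optim()] (L-BFGS-B); defaults tighten
#'   `factr` to 1e3.
#' @return an `ecm_solution`: optimal `x` (named, ln mM), per-reaction
#'   tibble (`reactions`: flux, theta, eta_rev, eta_sat, enzyme demand in
#'   mM, cost share in mg/l), total `E_met` (mg/l), `converged`,
#'   `diagnostics`.
#' @export
minimize_enzyme_cost <- function(model, flux, condition = NULL,
                                 theta_floor = 1e-6, control = list()) {
  net <- .active_network(model, flux, condition)
  pre <- .max_min_theta(net)
  if (pre$min_theta <= theta_floor) {
    worst <- names(net$rxns)[which.min(pre$thetas)]
    rlang::abort(
      paste0("metabolite polytope is empty: best achievable minimal ",
             "driving force is ", format(pre$min_theta, digits = 4),
             " RT (most constrained reaction: '", worst, "')"),
      class = "efcm_infeasible_error",
      reaction = worst, min_theta = pre$min_theta
    )
  }
  nv <- length(net$vars)
  rxns <- net$rxns
  w <- vapply(rxns, `[[`, numeric(1), "w")

  eval_all <- function(x, grad = FALSE) {
    Emet <- 0
    g <- if (grad) numeric(nv) else NULL
    viol <- 0
    gviol <- if (grad) numeric(nv) else NULL
    for (k in seq_along(rxns)) {
      rx <- rxns[[k]]
      ev <- .eval_reaction(rx, x, grad = grad)
      if (ev$theta <= theta_floor) {
        viol <- viol + (theta_floor - ev$theta)
        if (grad && length(rx$int_idx) > 0)
          gviol[rx$int_idx] <- gviol[rx$int_idx] + rx$int_coef
        next
      }
      Emet <- Emet + w[k] * ev$E
      if (grad) g <- g + w[k] * ev$E * ev$dlnE_dx
    }
    list(Emet = Emet, g = g, viol = viol, gviol = gviol)
  }

  x0 <- pre$x
  f0 <- eval_all(x0)$Emet
  pen <- max(f0, 1) * 1e8
  fn <- function(x) {
    ev <- eval_all(x)
    if (ev$viol > 0) pen * (1 + ev$viol) else ev$Emet
  }
  gr <- function(x) {
    ev <- eval_all(x, grad = TRUE)
    if (ev$viol > 0) pen * ev$gviol else ev$g
  }

  ctrl <- utils::modifyList(list(maxit = 1000, factr = 1e3), control)
  if (nv > 0) {
    res <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                        lower = net$lb, upper = net$ub, control = ctrl)
    # a restart from the solution guards against premature line-search
    # stops; keep it only on strict improvement
    res2 <- stats::optim(res$par, fn, gr, method = "L-BFGS-B",
                         lower = net$lb, upper = net$ub, control = ctrl)
    if (res2$value < res$value) res <- res2
    x_opt <- res$par
    # authoritative first-order check: projected gradient at the solution
    # (bounds-aware), scaled by the cost
    pg <- gr(x_opt)
    pg[x_opt <= net$lb + 1e-10 & pg > 0] <- 0
    pg[x_opt >= net$ub - 1e-10 & pg < 0] <- 0
    converged <- res$convergence == 0 ||
      max(abs(pg)) <= 1e-6 * max(res$value, 1)
    diag_msg <- res$message %||% ""
    counts <- res$counts
  } else {
    x_opt <- numeric(0)
    converged <- TRUE
    diag_msg <- "no internal metabolites to optimize"
    counts <- c(`function` = 1, gradient = 0)
  }

  per <- lapply(rxns, function(rx) {
    ev <- .eval_reaction(rx, x_opt)
    tibble::tibble(
      reaction_id = rx$id,
      flux = rx$v,
      theta = ev$theta,
      eta_rev = ev$eta_rev,
      eta_sat = ev$eta_sat,
      capacity_utilization = ev$eta_rev * ev$eta_sat,
      enzyme_mM = ev$E,
      cost_mg_per_l = rx$w * ev$E
    )
  })
  per <- dplyr::bind_rows(per)
  structure(
    list(
      x = stats::setNames(x_opt, net$vars),
      conc_mM = stats::setNames(exp(x_opt), net$vars),
      reactions = per,
      E_met = sum(per$cost_mg_per_l),
      converged = converged,
      diagnostics = list(message = diag_msg, counts = counts,
                         min_theta = min(per$theta),
                         presolve_min_theta = pre$min_theta,
                         theta_floor = theta_floor),
      flux = flux,
      condition = condition,
      model_fingerprint = rlang::hash(model$stoich)
    ),
    class = "ecm_solution"
  )
}

#' @export
print.ecm_solution <- function(x, ...) {
  cat("<ecm_solution> E_met = ", format(x$E_met, digits = 6), " mg/l over ",
      nrow(x$reactions), " active reactions (converged: ",
      x$converged, ")\n", sep = "")
  invisible(x)
}

#' Tidy an ECM solution into a per-reaction tibble
#' @param x an `ecm_solution`.
#' @param ... unused.
#' @return tibble with one row per active reaction: driving force,
#'   efficiency factors, enzyme demand (mM) and cost share (mg/l).
#' @method tidy ecm_solution
#' @export
tidy.ecm_solution <- function(x, ...) x$reactions

#' One-row summary of an ECM solution
#' @param x an `ecm_solution`.
#' @param ... unused.
#' @return tibble with `E_met`, `n_active`, `min_theta`, `converged`.
#' @method glance ecm_solution
#' @export
glance.ecm_solution <- function(x, ...) {
  tibble::tibble(
    E_met = x$E_met,
    n_active = nrow(x$reactions),
    min_theta = min(x$reactions$theta),
    converged = x$converged
  )
}

#' Capacity utilization of active reactions
#'
#' The ratio of apparent to maximal catalytic rate per active reaction,
#' `eta_rev * eta_sat`, equal to `(v/kcat) / E` (ideal demand over actual
#' demand). Strictly in (0, 1) for any finite driving force.
#'
#' @param solution an `ecm_solution`.
#' @return named numeric vector over active reactions.
#' @export
capacity_utilization <- function(solution) {
  stats::setNames(solution$reactions$capacity_utilization,
                  solution$reactions$reaction_id)
}
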