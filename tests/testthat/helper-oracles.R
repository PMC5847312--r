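# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: costs are computed straight from the model
# tables with plain arithmetic, EFM supports by exhaustive subset testing,
# Pareto sets by O(n^2) pairwise domination.

# Exhaustive support-subset EFM oracle for networks of <= ~14 reactions:
# a signed support is an EFM iff its column submatrix has nullspace
# dimension 1, the kernel vector is nonzero on the whole support, it can be
# oriented to respect irreversibilities, and no smaller such support is
# contained in it. Returns sorted signature strings over all reactions.
oracle_efm_signatures <- function(model) {
  S <- stoich_matrix(model, internal_only = TRUE)
  n <- ncol(S)
  rev <- model$reactions$reversible
  null_dim1_vec <- function(Ssub) {
    sv <- svd(Ssub, nu = 0, nv = ncol(Ssub))
    tol <- 1e-9 * max(sv$d[1], 1)
    if (sum(sv$d < tol) + (ncol(Ssub) - length(sv$d)) != 1) return(NULL)
    sv$v[, ncol(Ssub)]
  }
  found <- list()
  for (mask in seq_len(2^n - 1)) {
    supp <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    v <- null_dim1_vec(S[, supp, drop = FALSE])
    if (is.null(v) || any(abs(v) < 1e-9)) next
    ok <- function(v) all(v[!rev[supp]] > 1e-9)
    # a fully reversible support carries two distinct modes (both
    # orientations); record each feasible orientation
    for (w in list(v, -v)) {
      if (ok(w))
        found[[length(found) + 1]] <- list(supp = supp, sgn = sign(w))
    }
  }
  # minimality on signed (split-network) supports: j disqualifies i only if
  # its support is properly contained in i's with matching orientations
  keep <- rep(TRUE, length(found))
  for (i in seq_along(found)) {
    for (j in seq_along(found)) {
      if (i == j || !keep[i]) next
      fi <- found[[i]]
      fj <- found[[j]]
      if (length(fj$supp) >= length(fi$supp)) next
      if (!all(fj$supp %in% fi$supp)) next
      if (all(fj$sgn == fi$sgn[match(fj$supp, fi$supp)]))
        keep[i] <- FALSE
    }
  }
  sigs <- vapply(found[keep], function(o) {
    s <- rep(0, n)
    s[o$supp] <- o$sgn
    paste(s, collapse = "")
  }, character(1))
  sort(unname(sigs))
}

efm_signatures <- function(efms) {
  sort(unname(apply(sign(efms$fluxes), 2, paste, collapse = "")))
}

# Independent total-cost oracle: driving force, efficiency factors and
# enzyme demand recomputed from the model tables with direct (non-log)
# arithmetic. conc: named vector of internal concentrations in mM.
oracle_cost <- function(model, flux, conc, external_conc = NULL) {
  cp <- model$compounds
  get_conc <- function(id) {
    i <- match(id, cp$id)
    if (cp$is_external[i]) {
      if (!is.null(external_conc) && id %in% names(external_conc))
        external_conc[[id]]
      else cp$fixed_conc_mM[i]
    } else {
      conc[[id]]
    }
  }
  total <- 0
  for (r in names(flux)) {
    v <- flux[[r]]
    if (abs(v) < 1e-12) next
    ri <- match(r, model$reactions$id)
    s <- sign(v)
    st <- model$stoich[[r]] * s
    keq <- model$reactions$keq[ri]^s
    theta <- log(keq) -
      sum(vapply(names(st), function(id) st[[id]] * log(get_conc(id)),
                 numeric(1)))
    if (theta <= 0) return(Inf)
    eta_rev <- 1 - exp(-theta)
    kmr <- model$km[model$km$reaction_id == r, ]
    side_terms <- function(ids) {
      Snum <- 1
      Pden <- 1
      for (id in ids) {
        k <- kmr$km_mM[match(id, kmr$compound_id)]
        if (is.na(k)) next
        ratio <- get_conc(id) / k
        a <- abs(st[[id]])
        Snum <- Snum * ratio^a
        Pden <- Pden * (1 + ratio)^a
      }
      c(Snum, Pden)
    }
    sub <- side_terms(names(st)[st < 0])
    prd <- side_terms(names(st)[st > 0])
    eta_sat <- sub[1] / (sub[2] + prd[2] - 1)
    E <- abs(v) / (model$reactions$kcat_fwd_per_s[ri] * eta_rev * eta_sat)
    total <- total + model$reactions$enzyme_mass_da[ri] * E
  }
  total
}

# Exhaustive grid-search minimum of the oracle cost over the concentration
# box for models with exactly two free internal metabolites.
oracle_grid_min <- function(model, flux, n_grid = 400) {
  cp <- model$compounds
  int <- cp[!cp$is_external, ]
  act <- names(flux)[abs(flux) > 1e-12]
  used <- unique(unlist(lapply(model$stoich[act], names)))
  int <- int[int$id %in% used, ]
  stopifnot(nrow(int) == 2)
  g1 <- exp(seq(log(int$c_min_mM[1]), log(int$c_max_mM[1]),
                length.out = n_grid))
  g2 <- exp(seq(log(int$c_min_mM[2]), log(int$c_max_mM[2]),
                length.out = n_grid))
  best <- Inf
  for (c1 in g1) {
    for (c2 in g2) {
      conc <- stats::setNames(c(c1, c2), int$id)
      val <- oracle_cost(model, flux, conc)
      if (val < best) best <- val
    }
  }
  best
}

# O(n^2) pairwise-domination Pareto oracle on (mu, yield) points.
oracle_pareto_ids <- function(points) {
  n <- nrow(points)
  dominated <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (points$mu[j] >= points$mu[i] &&
          points$yield_g_per_cmol[j] >= points$yield_g_per_cmol[i] &&
          (points$mu[j] > points$mu[i] ||
             points$yield_g_per_cmol[j] > points$yield_g_per_cmol[i])) {
        dominated[i] <- TRUE
        break
      }
    }
  }
  sort(points$efm_id[!dominated])
}

# Independent mass-action free-energy oracle: -DeltaG/RT from
# concentrations and the equilibrium constant.
oracle_theta <- function(model, reaction_id, conc_all, orientation = 1) {
  ri <- match(reaction_id, model$reactions$id)
  st <- model$stoich[[reaction_id]] * orientation
  keq <- model$reactions$keq[ri]^orientation
  dG_RT <- sum(vapply(names(st),
                      function(id) st[[id]] * log(conc_all[[id]]),
                      numeric(1))) - log(keq)
  -dG_RT
}

# Sample feasible interior points (named concentration vectors) for a flux
# mode by rejection against positive driving forces.
sample_feasible_conc <- function(model, flux, n = 10, seed = 1,
                                 max_tries = 5000) {
  cp <- model$compounds
  int <- cp[!cp$is_external, ]
  out <- list()
  withr::with_seed(seed, {
    tries <- 0
    while (length(out) < n && tries < max_tries) {
      tries <- tries + 1
      conc <- stats::setNames(
        exp(stats::runif(nrow(int), log(int$c_min_mM), log(int$c_max_mM))),
        int$id)
      if (is.finite(oracle_cost(model, flux, conc)))
        out[[length(out) + 1]] <- conc
    }
  })
  out
}
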