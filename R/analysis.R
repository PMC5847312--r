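# Rate/yield analyses built on the EFM + ECM core. All results are tibbles
# so they compose with dplyr/ggplot2; expensive ECM solves can be shared
# across scans and knockout screens through an explicit cache.

#' Create an ECM solution cache
#'
#' Solutions are keyed by a content hash of (flux mode, condition, model
#' fingerprint), so scans and knockout analyses built on the same spectrum
#' never re-run an optimization.
#'
#' @return an environment usable as the `cache` argument of the analysis
#'   functions.
#' @export
new_ecm_cache <- function() new.env(parent = emptyenv())

.ecm_cached <- function(model, flux, condition, cache = NULL, ...) {
  if (is.null(cache)) return(minimize_enzyme_cost(model, flux, condition, ...))
  key <- rlang::hash(list(flux, condition, model$stoich,
                          model$reactions$kcat_fwd_per_s,
                          model$reactions$keq, model$km$km_mM,
                          model$compounds$fixed_conc_mM))
  if (!is.null(cache[[key]])) return(cache[[key]])
  sol <- minimize_enzyme_cost(model, flux, condition, ...)
  cache[[key]] <- sol
  sol
}

# Net exchange of every external compound, per C-mol of glucose uptake:
# carbon compounds in carbon moles, carbon-free species (e.g. O2) in plain
# moles. Negative values are consumption, positive secretion.
.exchange_fluxes <- function(flux, model) {
  cp <- model$compounds
  ext <- cp$id[cp$is_external]
  up <- .glucose_uptake_rate(flux, model)
  glc <- .glucose_compound(model)
  cc_glc <- cp$carbon_count[match(glc, cp$id)]
  out <- stats::setNames(numeric(length(ext)), paste0("ex_", ext))
  for (e in ext) {
    prod <- 0
    for (r in names(model$stoich)) {
      st <- model$stoich[[r]]
      if (e %in% names(st)) prod <- prod + st[[e]] * flux[[r]]
    }
    cc <- cp$carbon_count[match(e, cp$id)]
    scale <- if (cc > 0) cc else 1
    out[paste0("ex_", e)] <- if (up > 0) prod * scale / (up * cc_glc) else NA_real_
  }
  out
}

#' Rate/yield spectrum of a set of flux modes
#'
#' Runs ECM on every biomass-producing mode, converts minimal enzyme cost
#' into growth rate, and returns one row per mode with its yield, growth
#' rate, cost, and exchange fluxes (per C-mol glucose). Modes with an empty
#' metabolite polytope are reported with `status = "infeasible"` rather
#' than dropped.
#'
#' @param model an `efcm_model`.
#' @param efms an `efm_set` (pre-filtered for the condition if desired).
#' @param condition optional [efcm_condition()].
#' @param params growth-conversion constants; defaults to the model's.
#' @param cache optional [new_ecm_cache()].
#' @return a tibble (class `efcm_spectrum`): `efm_id`, `yield_g_per_cmol`,
#'   `E_met`, `mu`, `status`, `converged`, exchange-flux columns.
#' @export
rate_yield_spectrum <- function(model, efms, condition = NULL,
                                params = NULL, cache = NULL) {
  if (is.null(params)) params <- model$config$growth_params
  keep <- which(efms$meta$biomass_producing)
  rows <- lapply(keep, function(j) {
    flux <- efms$fluxes[, j]
    base <- tibble::tibble(
      efm_id = efms$meta$efm_id[j],
      yield_g_per_cmol = efms$meta$yield_g_per_cmol[j]
    )
    sol <- tryCatch(.ecm_cached(model, flux, condition, cache),
                    efcm_infeasible_error = function(e) e)
    if (inherits(sol, "efcm_infeasible_error")) {
      res <- dplyr::bind_cols(base, tibble::tibble(
        E_met = NA_real_, mu = NA_real_, status = "infeasible",
        converged = FALSE))
    } else {
      res <- dplyr::bind_cols(base, tibble::tibble(
        E_met = sol$E_met,
        mu = growth_rate_from_cost(sol$E_met, params),
        status = "ok",
        converged = sol$converged))
    }
    dplyr::bind_cols(res, tibble::as_tibble(as.list(
      .exchange_fluxes(flux, model))))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("efcm_spectrum", class(out))
  out
}

#' Pareto front of a rate/yield spectrum
#'
#' The maximal subset of points not dominated under (maximize growth rate,
#' maximize yield), returned in descending-yield order. Infeasible rows
#' (`NA` growth rate) are ignored.
#'
#' @param points tibble with columns `mu` and `yield_g_per_cmol` (e.g. from
#'   [rate_yield_spectrum()]).
#' @return the non-dominated subset of `points`, ordered by descending
#'   yield.
#' @export
pareto_front <- function(points) {
  pts <- points[!is.na(points$mu) & !is.na(points$yield_g_per_cmol), ]
  if (nrow(pts) == 0) return(pts)
  ord <- order(-pts$yield_g_per_cmol, -pts$mu)
  pts <- pts[ord, ]
  keep <- logical(nrow(pts))
  best_mu <- -Inf
  best_yield <- NA_real_
  for (i in seq_len(nrow(pts))) {
    if (pts$mu[i] > best_mu) {
      keep[i] <- TRUE
      best_mu <- pts$mu[i]
      best_yield <- pts$yield_g_per_cmol[i]
    } else if (pts$mu[i] == best_mu &&
               identical(pts$yield_g_per_cmol[i], best_yield)) {
      keep[i] <- TRUE  # exact duplicate of a front point: not dominated
    }
  }
  pts[keep, ]
}

#' Growth over a grid of external substrate concentrations (Monod surface)
#'
#' For every grid cell the external levels are fixed, condition-feasible
#' modes are selected (anaerobic feasibility rules at zero oxygen, aerobic
#' otherwise), ECM is run per mode (cached across cells), and the
#' best-growing mode is recorded. Ties within `mu_tol` are broken by higher
#' yield, then lower mode id, so winner maps are deterministic.
#'
#' @param model an `efcm_model` with `config$glucose_compound_id` (and
#'   `config$oxygen_compound_id` when an oxygen grid is given).
#' @param efms an `efm_set`.
#' @param glucose_grid glucose concentrations (mM), e.g. log-spaced.
#' @param oxygen_grid oxygen concentrations (mM); `NULL` scans glucose only.
#' @param condition baseline condition; per-cell levels override it.
#' @param params growth-conversion constants; defaults to the model's.
#' @param cache optional [new_ecm_cache()]; one is created per call if
#'   absent.
#' @param mu_tol tie tolerance on growth rate.
#' @return a tibble (class `efcm_monod`): `glucose_mM`, `oxygen_mM`, best
#'   `mu`, `winner_efm`, winner yield and exchange fluxes, `status`.
#' @export
monod_scan <- function(model, efms, glucose_grid, oxygen_grid = NULL,
                       condition = NULL, params = NULL, cache = NULL,
                       mu_tol = 1e-10) {
  if (is.null(params)) params <- model$config$growth_params
  if (is.null(cache)) cache <- new_ecm_cache()
  glc_id <- .glucose_compound(model)
  o2_id <- model$config$oxygen_compound_id
  if (!is.null(oxygen_grid) && is.null(o2_id))
    stop("oxygen_grid given but config$oxygen_compound_id is not set",
         call. = FALSE)
  o2_levels <- if (is.null(oxygen_grid)) NA_real_ else oxygen_grid
  base_ext <- if (!is.null(condition)) condition$external_conc else NULL
  overrides <- if (!is.null(condition)) condition$param_overrides else NULL

  rows <- list()
  for (o2 in o2_levels) {
    cell_efms <- if (!is.na(o2)) {
      filter_efms_by_condition(efms, model,
                               if (o2 > 0) "aerobic" else "anaerobic")
    } else {
      filter_efms_by_condition(efms, model, "all")
    }
    for (g in glucose_grid) {
      ext <- base_ext
      ext[glc_id] <- g
      if (!is.na(o2)) ext[o2_id] <- o2
      cond <- efcm_condition(ext, overrides)
      if (length(cell_efms) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          glucose_mM = g, oxygen_mM = o2, mu = NA_real_,
          winner_efm = NA_integer_, winner_yield = NA_real_,
          status = "no_feasible_efm")
        next
      }
      spec <- rate_yield_spectrum(model, cell_efms, cond, params, cache)
      ok <- spec[spec$status == "ok", ]
      if (nrow(ok) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          glucose_mM = g, oxygen_mM = o2, mu = NA_real_,
          winner_efm = NA_integer_, winner_yield = NA_real_,
          status = "no_feasible_efm")
        next
      }
      best_mu <- max(ok$mu)
      tied <- ok[ok$mu >= best_mu - mu_tol, ]
      tied <- tied[order(-tied$yield_g_per_cmol, tied$efm_id), ]
      win <- tied[1, ]
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(glucose_mM = g, oxygen_mM = o2, mu = win$mu,
                       winner_efm = win$efm_id,
                       winner_yield = win$yield_g_per_cmol,
                       status = "ok"),
        win[, grep("^ex_", names(win)), drop = FALSE])
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("efcm_monod", class(out))
  out
}

#' Growth-rate sensitivities to kinetic parameters (envelope theorem)
#'
#' At an ECM optimum, the first-order effect of a parameter change on the
#' minimal cost equals its effect at fixed metabolite levels: a slowdown of
#' one reaction is compensated by raising that enzyme alone, and coordinated
#' re-optimization only helps at second order. Sensitivities are reported
#' per log-parameter: `dE_met/d ln p` from the rate law's partial
#' derivatives (e.g. `dE_met/d ln kcat_r = -cost_r`), and
#' `dmu/d ln p = -A/(E_met+B)^2 * dE_met/d ln p`. Parameters of reactions
#' outside the mode's support have exactly zero sensitivity.
#'
#' @param model an `efcm_model`.
#' @param solution a converged [minimize_enzyme_cost()] result.
#' @param condition the condition the solution was computed under.
#' @param params growth-conversion constants; defaults to the model's.
#' @return tibble: `reaction_id`, `param` (`kcat_fwd`, `keq`, `km`,
#'   `external_conc`), `compound_id`, `dEmet_dlnp`, `dmu_dlnp`.
#' @export
growth_sensitivities <- function(model, solution, condition = NULL,
                                 params = NULL) {
  if (is.null(params)) params <- model$config$growth_params
  net <- .active_network(model, solution$flux, condition)
  x <- .match_x(solution$x, net$vars)
  A <- params$a * params$f_prot * params$v_bm_mass
  B <- params$b * params$f_prot * params$v_bm_mass
  dmu_fac <- -A / (solution$E_met + B)^2

  cm <- net$model
  ext_ids <- cm$compounds$id[cm$compounds$is_external]
  ext_acc <- stats::setNames(numeric(length(ext_ids)), ext_ids)
  rows <- list()
  add <- function(reaction_id, param, compound_id, dE) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      reaction_id = reaction_id, param = param,
      compound_id = compound_id, dEmet_dlnp = dE)
  }

  for (rid in cm$reactions$id) {
    rx <- net$rxns[[rid]]
    if (is.null(rx)) {  # outside the support: exactly zero
      add(rid, "kcat_fwd", NA_character_, 0)
      add(rid, "keq", NA_character_, 0)
      for (cpd in cm$km$compound_id[cm$km$reaction_id == rid])
        add(rid, "km", cpd, 0)
      next
    }
    ev <- .eval_reaction(rx, x)
    cost <- rx$w * ev$E
    thfac <- exp(-ev$theta) / ev$eta_rev
    add(rid, "kcat_fwd", NA_character_, -cost)
    add(rid, "keq", NA_character_, -cost * thfac)
    for (side in c("sat_sub", "sat_prod")) {
      entries <- rx[[side]]
      sig <- if (side == "sat_sub") ev$sub$sig else ev$prod$sig
      PQ <- if (side == "sat_sub") ev$P else ev$Q
      for (i in seq_along(entries)) {
        e <- entries[[i]]
        dlnE <- if (side == "sat_sub") e$a - PQ * e$a * sig[i] / ev$D
                else -PQ * e$a * sig[i] / ev$D
        add(rid, "km", e$id, cost * dlnE)
        if (!is.na(e$fixed)) {  # external participant: conc sensitivity
          dlnE_c <- if (side == "sat_sub") -e$a + PQ * e$a * sig[i] / ev$D
                    else PQ * e$a * sig[i] / ev$D
          ext_acc[e$id] <- ext_acc[e$id] + cost * dlnE_c
        }
      }
    }
    # theta contribution of external reactants to concentration sensitivity
    st <- cm$stoich[[rid]] * sign(solution$flux[[rid]])
    for (e_id in intersect(names(st), ext_ids)) {
      ext_acc[e_id] <- ext_acc[e_id] + cost * thfac * st[[e_id]]
    }
  }
  for (e_id in ext_ids)
    add(NA_character_, "external_conc", e_id, ext_acc[[e_id]])

  out <- dplyr::bind_rows(rows)
  out$dmu_dlnp <- dmu_fac * out$dEmet_dlnp
  out
}

.best_mu <- function(spectrum) {
  ok <- spectrum$mu[spectrum$status == "ok"]
  if (length(ok) == 0) 0 else max(ok)
}

#' Knockout analysis from a precomputed spectrum
#'
#' Reaction deletions discard every mode using the deleted reactions; no
#' new optimization is needed. The wild-type growth rate is the best over
#' all modes, the knockout rate the best over survivors, and the advantage
#' `mu_wt/mu_ko - 1` (infinite for a lethal knockout: no surviving mode).
#'
#' @param model an `efcm_model`.
#' @param efms an `efm_set`.
#' @param knockouts character vector of reaction ids to delete.
#' @param condition optional [efcm_condition()].
#' @param spectrum optional precomputed [rate_yield_spectrum()] for `efms`
#'   under `condition` (computed if absent).
#' @param cache optional ECM cache used when the spectrum is computed here.
#' @return tibble: `knockout`, `mu_wt`, `mu_ko`, `advantage`, `lethal`.
#' @export
knockout_analysis <- function(model, efms, knockouts, condition = NULL,
                              spectrum = NULL, cache = NULL) {
  if (is.null(spectrum))
    spectrum <- rate_yield_spectrum(model, efms, condition, cache = cache)
  mu_wt <- .best_mu(spectrum)
  surv <- knockout_filter(efms, knockouts)
  keep <- spectrum$efm_id %in% surv$meta$efm_id
  mu_ko <- .best_mu(spectrum[keep, ])
  lethal <- mu_ko == 0
  tibble::tibble(
    knockout = paste(knockouts, collapse = "+"),
    mu_wt = mu_wt,
    mu_ko = if (lethal) NA_real_ else mu_ko,
    advantage = if (lethal) Inf else mu_wt / mu_ko - 1,
    lethal = lethal
  )
}

#' Epistasis between two reaction knockouts
#'
#' Multiplicative-model score `eps = (mu_AB * mu_wt) / (mu_A * mu_B)` where
#' `mu_X` is the best growth rate after deleting reaction set X. All four
#' growth rates are returned so alternative epistasis definitions can be
#' recomputed; lethal single knockouts give an `NaN` score (0/0) flagged by
#' `lethal_*` columns. The score is symmetric in A and B and equals 1 when
#' either reaction is unused by every mode.
#'
#' @param model an `efcm_model`.
#' @param efms an `efm_set`.
#' @param rxnA,rxnB reaction ids.
#' @inheritParams knockout_analysis
#' @return one-row tibble: `score`, `mu_wt`, `mu_a`, `mu_b`, `mu_ab`, and
#'   lethality flags.
#' @export
epistasis <- function(model, efms, rxnA, rxnB, condition = NULL,
                      spectrum = NULL, cache = NULL) {
  if (is.null(spectrum))
    spectrum <- rate_yield_spectrum(model, efms, condition, cache = cache)
  mu_of <- function(kos) {
    surv <- knockout_filter(efms, kos)
    .best_mu(spectrum[spectrum$efm_id %in% surv$meta$efm_id, ])
  }
  mu_wt <- .best_mu(spectrum)
  mu_a <- mu_of(rxnA)
  mu_b <- mu_of(rxnB)
  mu_ab <- mu_of(c(rxnA, rxnB))
  tibble::tibble(
    rxnA = rxnA, rxnB = rxnB,
    score = (mu_ab * mu_wt) / (mu_a * mu_b),
    mu_wt = mu_wt, mu_a = mu_a, mu_b = mu_b, mu_ab = mu_ab,
    lethal_a = mu_a == 0, lethal_b = mu_b == 0, lethal_ab = mu_ab == 0
  )
}
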