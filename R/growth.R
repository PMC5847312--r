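#' Growth-conversion constants
#'
#' Parameters of the semi-empirical map from metabolic enzyme cost to cell
#' growth rate. With total enzyme cost `E_met` (mg/l) at a fixed biomass
#' production rate, the growth rate is
#'
#'   mu = a * f_prot * v_bm_mass / (E_met + b * f_prot * v_bm_mass)
#'
#' where `a` (dimensionless) and `b` (hours) describe the linear decline of
#' the metabolic-enzyme fraction of protein with growth rate, `f_prot` is
#' the protein fraction of cell dry mass, and `v_bm_mass` is the biomass
#' production rate (mg/l/h) corresponding to the model's unit biomass flux.
#' Defaults are the E. coli values used throughout: a = 0.27, b = 0.2 h,
#' f_prot = 0.5, v_bm_mass = 7.45e7 mg/l/h.
#'
#' @param a dimensionless slope parameter.
#' @param b time parameter (h).
#' @param f_prot protein mass fraction of dry mass.
#' @param v_bm_mass biomass production mass rate (mg/l/h) at unit biomass flux.
#' @return object of class `growth_params`.
#' @export
growth_params <- function(a = 0.27, b = 0.2, f_prot = 0.5,
                          v_bm_mass = 7.45e7) {
  stopifnot(a > 0, b > 0, f_prot > 0, f_prot <= 1, v_bm_mass > 0)
  structure(list(a = a, b = b, f_prot = f_prot, v_bm_mass = v_bm_mass),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params> a =", x$a, ", b =", x$b, "h, f_prot =", x$f_prot,
      ", v_bm_mass =", format(x$v_bm_mass), "mg/l/h\n")
  cat("  mu = ", format(x$a * x$f_prot * x$v_bm_mass, digits = 4),
      " / (E_met + ", format(x$b * x$f_prot * x$v_bm_mass, digits = 4),
      ")  [E_met in mg/l, mu in 1/h]\n", sep = "")
  invisible(x)
}

#' Growth rate from enzyme cost
#'
#' `mu = A / (E_met + B)` with `A = a f_prot v_bm_mass` and
#' `B = b f_prot v_bm_mass`; strictly decreasing in `E_met` with supremum
#' `a/b` at zero cost.
#'
#' @param E_met total enzyme cost (mg/l), vectorized.
#' @param params a [growth_params()] object.
#' @return growth rate(s) in 1/h.
#' @export
growth_rate_from_cost <- function(E_met, params = growth_params()) {
  if (any(E_met < 0)) stop("E_met must be >= 0", call. = FALSE)
  A <- params$a * params$f_prot * params$v_bm_mass
  B <- params$b * params$f_prot * params$v_bm_mass
  A / (E_met + B)
}

#' Enzyme cost from growth rate (inverse map)
#'
#' @param mu growth rate (1/h), must satisfy `0 < mu < a/b`.
#' @param params a [growth_params()] object.
#' @return enzyme cost (mg/l).
#' @export
cost_from_growth_rate <- function(mu, params = growth_params()) {
  if (any(mu <= 0) || any(mu >= params$a / params$b))
    stop("mu must lie in (0, a/b)", call. = FALSE)
  A <- params$a * params$f_prot * params$v_bm_mass
  B <- params$b * params$f_prot * params$v_bm_mass
  A / mu - B
}

#' Doubling times from enzyme cost
#'
#' Computes the enzyme-specific biomass rate `r_bm = v_bm_mass / E_met`, the
#' metabolic-enzyme doubling time `tau_met = ln(2) / r_bm`, the growth rate
#' `mu`, and the cell doubling time `T = ln(2)/mu`, which equals
#' `tau_met / (a f_prot) + ln(2) b / a` (a linear law in `tau_met`).
#'
#' @param E_met total enzyme cost (mg/l), vectorized.
#' @param params a [growth_params()] object.
#' @return tibble with columns `E_met`, `mu`, `r_bm`, `tau_met`,
#'   `doubling_time_h`.
#' @export
doubling_time_from_cost <- function(E_met, params = growth_params()) {
  mu <- growth_rate_from_cost(E_met, params)
  r_bm <- ifelse(E_met > 0, params$v_bm_mass / E_met, Inf)
  tau_met <- log(2) * E_met / params$v_bm_mass
  tibble::tibble(
    E_met = E_met,
    mu = mu,
    r_bm = r_bm,
    tau_met = tau_met,
    doubling_time_h = log(2) / mu
  )
}

#' Coefficients of the growth-conversion law
#'
#' Returns the composite constants of the cost-to-growth map in the form
#' they are usually quoted: the numerator `A = a f_prot v_bm_mass` (mg/l/h),
#' the offset `B = b f_prot v_bm_mass` (mg/l), the doubling-time slope
#' `ln2/A` (h l/mg), the doubling-time offset `ln2 b/a` (h), and the
#' `tau_met` multiplier `1/(a f_prot)`.
#'
#' @param params a [growth_params()] object.
#' @return named list of the five coefficients.
#' @export
growth_law_coefficients <- function(params = growth_params()) {
  A <- params$a * params$f_prot * params$v_bm_mass
  B <- params$b * params$f_prot * params$v_bm_mass
  list(
    numerator_mg_per_l_per_h = A,
    offset_mg_per_l = B,
    doubling_slope_h_l_per_mg = log(2) / A,
    doubling_offset_h = log(2) * params$b / params$a,
    tau_met_factor = 1 / (params$a * params$f_prot)
  )
}
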