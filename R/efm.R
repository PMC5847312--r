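#' Enumerate elementary flux modes
#'
#' Computes the complete set of elementary flux modes (EFMs) of the internal
#' stoichiometry: minimal steady-state flux vectors, unique up to scaling,
#' respecting declared irreversibilities. The combinatorial phase runs the
#' classical tableau (double description) algorithm on integer arithmetic:
#' reversible reactions are split into forward/backward halves, metabolite
#' balances are imposed one at a time, candidate rays are combined pairwise
#' and pruned by support minimality, and spurious forward/backward two-cycles
#' are removed after merging the split halves back. Fluxes are reported in
#' the net orientation of each reaction.
#'
#' Biomass-producing modes are normalized so the biomass flux equals the
#' model's convention (default 1 mM/s); modes that do not produce biomass
#' are kept for diagnostics (flagged `biomass_producing = FALSE`, scaled to
#' unit maximum flux) but excluded from rate/yield analyses downstream.
#'
#' @param model an `efcm_model`.
#' @param max_rays cap on intermediate tableau rows; exceeding it raises an
#'   explicit overflow error (never silent truncation).
#' @param zero_tol fluxes below this magnitude (relative to the mode's
#'   largest flux) are treated as structural zeros.
#' @return an `efm_set`: list with `fluxes` (reactions x modes matrix),
#'   `meta` (tibble: `efm_id`, `biomass_producing`, `yield_g_per_cmol`,
#'   `feasibility`, tag usage flags), and `model_fingerprint`.
#' @export
enumerate_efms <- function(model, max_rays = 1e5, zero_tol = 1e-12) {
  S <- stoich_matrix(model, internal_only = TRUE)
  rxn_ids <- colnames(S)
  n <- ncol(S)
  rev <- model$reactions$reversible
  rev_idx <- which(rev)

  # split reversible reactions into forward + backward half-reactions
  Ssplit <- cbind(S, -S[, rev_idx, drop = FALSE])
  orig_of <- c(seq_len(n), rev_idx)
  dir_of <- c(rep(1, n), rep(-1, length(rev_idx)))
  Ssplit <- .integerize_rows(Ssplit)
  ns <- ncol(Ssplit)
  m <- nrow(Ssplit)

  # tableau: [rays over split fluxes | remaining balance constraints]
  Tm <- cbind(diag(ns), t(Ssplit))
  for (k in seq_len(m)) {
    col <- Tm[, ns + k]
    keep <- Tm[abs(col) < 0.5, , drop = FALSE]
    pos <- which(col > 0.5)
    neg <- which(col < -0.5)
    new_rows <- vector("list", length(pos) * length(neg))
    cnt <- 0
    for (i in pos) {
      for (j in neg) {
        r <- col[i] * Tm[j, ] - col[j] * Tm[i, ]
        g <- .gcd(r)
        if (g > 1) r <- r / g
        if (max(abs(r)) > .INT_GUARD)
          stop("integer overflow guard tripped during EFM enumeration; ",
               "rescale the model stoichiometry", call. = FALSE)
        cnt <- cnt + 1
        new_rows[[cnt]] <- r
      }
    }
    if (cnt > 0) {
      new_mat <- do.call(rbind, new_rows[seq_len(cnt)])
      cand <- rbind(keep, new_mat)
    } else {
      cand <- keep
    }
    if (nrow(cand) > max_rays)
      stop("EFM enumeration exceeded max_rays = ", max_rays,
           " intermediate rays; raise the cap explicitly", call. = FALSE)
    # support-minimality pruning on the ray part
    supp <- cand[, seq_len(ns), drop = FALSE] != 0
    keep_row <- rep(TRUE, nrow(cand))
    sizes <- rowSums(supp)
    ord <- order(sizes)
    for (a_pos in seq_along(ord)) {
      a <- ord[a_pos]
      if (!keep_row[a]) next
      sa <- supp[a, ]
      for (b_pos in seq_along(ord)) {
        b <- ord[b_pos]
        if (b == a || !keep_row[b]) next
        if (sizes[b] < sizes[a]) next
        # drop b if support(a) subset of support(b); equality = duplicate ray
        if (!any(sa & !supp[b, ])) {
          if (sizes[b] > sizes[a] || b > a) keep_row[b] <- FALSE
        }
      }
    }
    Tm <- cand[keep_row, , drop = FALSE]
    if (nrow(Tm) == 0) break
  }

  rays <- Tm[, seq_len(ns), drop = FALSE]
  # final elementarity audit: support must give a rank-deficiency-1 subnetwork
  ok <- vapply(seq_len(nrow(rays)), function(i) {
    supp <- which(rays[i, ] != 0)
    length(supp) > 0 &&
      .mat_rank(Ssplit[, supp, drop = FALSE]) == length(supp) - 1
  }, logical(1))
  rays <- rays[ok, , drop = FALSE]

  # merge split halves back to net fluxes over original reactions
  net <- matrix(0, nrow(rays), n, dimnames = list(NULL, rxn_ids))
  for (jc in seq_len(ns)) {
    net[, orig_of[jc]] <- net[, orig_of[jc]] + dir_of[jc] * rays[, jc]
  }
  nonzero <- apply(abs(net), 1, max) > 0  # drops futile two-cycles
  net <- net[nonzero, , drop = FALSE]

  if (nrow(net) > 0) {
    # zero out numerically negligible entries, deterministic ordering
    scale <- apply(abs(net), 1, max)
    net[abs(net) < zero_tol * scale] <- 0
    sig <- apply(net, 1, function(v) paste(sign(v), collapse = ""))
    net <- net[order(sig), , drop = FALSE]
  }

  bm_id <- model$config$biomass_reaction_id
  conv <- model$config$biomass_flux_convention_mM_per_s
  fluxes <- t(net)  # reactions x modes
  meta <- vector("list", ncol(fluxes))
  for (j in seq_len(ncol(fluxes))) {
    v <- fluxes[, j]
    if (v[bm_id] > 0) {
      v <- v * conv / v[bm_id]
      bm <- TRUE
    } else {
      v <- v / max(abs(v))
      bm <- FALSE
    }
    fluxes[, j] <- v
    meta[[j]] <- tibble::tibble(biomass_producing = bm)
  }
  meta <- if (length(meta) > 0) dplyr::bind_rows(meta) else
    tibble::tibble(biomass_producing = logical(0))
  meta$efm_id <- seq_len(ncol(fluxes))
  meta <- meta[, c("efm_id", "biomass_producing")]
  colnames(fluxes) <- paste0("efm_", meta$efm_id)

  out <- structure(
    list(fluxes = fluxes, meta = meta,
         model_fingerprint = rlang::hash(list(model$stoich,
                                              model$reactions$reversible))),
    class = "efm_set"
  )
  out$meta$yield_g_per_cmol <- vapply(seq_len(ncol(fluxes)), function(j) {
    if (!meta$biomass_producing[j]) return(NA_real_)
    efm_yield(fluxes[, j], model)
  }, numeric(1))
  out$meta <- dplyr::bind_cols(out$meta, .classify_oxygen(out, model))
  out
}

# Oxygen-rule classification per mode: which tagged reactions it uses and
# the resulting feasibility class.
.classify_oxygen <- function(efms, model,
                             rules = list(sensitive = "oxygen_sensitive",
                                          dependent = "oxygen_dependent")) {
  tags <- reaction_tags(model)
  sens <- names(tags)[vapply(tags, function(t) rules$sensitive %in% t,
                             logical(1))]
  dep <- names(tags)[vapply(tags, function(t) rules$dependent %in% t,
                            logical(1))]
  uses <- function(j, set) any(efms$fluxes[set, j] != 0)
  n <- ncol(efms$fluxes)
  us <- vapply(seq_len(n), uses, logical(1), set = sens)
  ud <- vapply(seq_len(n), uses, logical(1), set = dep)
  feas <- dplyr::case_when(
    us & ud ~ "infeasible",
    us ~ "anaerobic_only",
    ud ~ "aerobic_only",
    TRUE ~ "both"
  )
  tibble::tibble(uses_oxygen_sensitive = us, uses_oxygen_dependent = ud,
                 feasibility = feas)
}

#' @export
print.efm_set <- function(x, ...) {
  cat("<efm_set> ", ncol(x$fluxes), " elementary flux modes (",
      sum(x$meta$biomass_producing), " biomass-producing)\n", sep = "")
  invisible(x)
}

#' @export
length.efm_set <- function(x) ncol(x$fluxes)

#' Tidy an EFM set into a wide tibble
#'
#' One row per mode: id, biomass/feasibility flags, yield, then one flux
#' column per reaction (mM/s, biomass normalized to the model convention).
#' With `cmol = TRUE` reaction fluxes are instead reported relative to the
#' mode's glucose uptake in carbon-moles (flux in mmol per C-mmol of
#' glucose taken up); exchange fluxes in proper carbon-mole units come from
#' [rate_yield_spectrum()].
#'
#' @param x an `efm_set`.
#' @param model the model (required for `cmol = TRUE`).
#' @param cmol report carbon-mole-normalized fluxes.
#' @param ... unused.
#' @return a tibble.
#' @method tidy efm_set
#' @export
tidy.efm_set <- function(x, model = NULL, cmol = FALSE, ...) {
  fl <- t(x$fluxes)
  if (cmol) {
    stopifnot(!is.null(model))
    fl <- t(apply(fl, 1, function(v) .cmol_normalize(v, model)))
    colnames(fl) <- rownames(x$fluxes)
  }
  dplyr::bind_cols(x$meta, tibble::as_tibble(fl))
}

# Carbon-mole normalization of a flux vector: each reaction flux times the
# carbon count of its reference reactant, divided by C-moles of glucose
# uptake. Used for reporting, not for computation.
.cmol_normalize <- function(v, model) {
  up <- .glucose_uptake_rate(v, model)
  if (!is.finite(up) || up <= 0) return(v * NA_real_)
  glc <- .glucose_compound(model)
  cc <- model$compounds$carbon_count[match(glc, model$compounds$id)]
  v / (up * cc)
}

.glucose_compound <- function(model) {
  id <- model$config$glucose_compound_id
  if (!is.null(id)) return(id)
  st <- model$stoich[[model$config$glucose_uptake_reaction_id]]
  ext <- model$compounds$id[model$compounds$is_external]
  carbons <- model$compounds$carbon_count[match(names(st), model$compounds$id)]
  cand <- names(st)[st < 0 & names(st) %in% ext & carbons > 0]
  if (length(cand) == 0)
    stop("cannot infer the glucose compound; set config$glucose_compound_id",
         call. = FALSE)
  cand[1]
}

# Glucose consumption rate (mM/s of glucose molecules) implied by flux v.
.glucose_uptake_rate <- function(v, model) {
  glc <- .glucose_compound(model)
  rate <- 0
  for (r in names(model$stoich)) {
    st <- model$stoich[[r]]
    if (glc %in% names(st)) rate <- rate - st[[glc]] * v[[r]]
  }
  rate
}

#' Normalize a flux mode to the biomass convention
#'
#' Scales all fluxes so the biomass reaction carries exactly the model's
#' biomass flux convention. Idempotent.
#'
#' @param flux named flux vector (mM/s).
#' @param model an `efcm_model`.
#' @return rescaled named flux vector.
#' @export
normalize_efm <- function(flux, model) {
  bm <- flux[[model$config$biomass_reaction_id]]
  if (bm == 0)
    stop("flux mode does not produce biomass; cannot normalize",
         call. = FALSE)
  flux * model$config$biomass_flux_convention_mM_per_s / bm
}

#' Biomass yield of a flux mode
#'
#' Grams of biomass produced per carbon mole of glucose consumed:
#' `yield = v_bm_mass * (v_bm / convention) / (carbon_count * uptake)` with
#' the uptake converted to mmol/l/h.
#'
#' @param flux named flux vector (mM/s), biomass-normalized or not (the
#'   yield is scale-invariant).
#' @param model an `efcm_model`.
#' @return yield in g per C-mol, or `NA` if the mode consumes no glucose.
#' @export
efm_yield <- function(flux, model) {
  up <- .glucose_uptake_rate(flux, model)
  if (up <= 0) return(NA_real_)
  glc <- .glucose_compound(model)
  cc <- model$compounds$carbon_count[match(glc, model$compounds$id)]
  v_bm <- flux[[model$config$biomass_reaction_id]]
  conv <- model$config$biomass_flux_convention_mM_per_s
  vbm_mass <- model$config$growth_params$v_bm_mass
  vbm_mass * (v_bm / conv) / (cc * up * 3600)
}

# subset an efm_set by mode index, keeping metadata aligned
.efm_subset <- function(efms, keep) {
  structure(
    list(fluxes = efms$fluxes[, keep, drop = FALSE],
         meta = efms$meta[keep, , drop = FALSE],
         model_fingerprint = efms$model_fingerprint),
    class = "efm_set"
  )
}

#' Filter flux modes by oxygen-condition feasibility
#'
#' Modes that use an oxygen-sensitive reaction together with an
#' oxygen-dependent one are infeasible everywhere and always removed.
#' `condition = "aerobic"` keeps modes using no oxygen-sensitive reaction;
#' `"anaerobic"` keeps modes using no oxygen-dependent reaction; `"both"`
#' keeps the intersection; `"all"` removes only the always-infeasible class.
#'
#' @param efms an `efm_set`.
#' @param model the model supplying reaction tags.
#' @param condition one of `"aerobic"`, `"anaerobic"`, `"both"`, `"all"`.
#' @param rules tag names for the two classes; must belong to the model's
#'   tag vocabulary (`config$tag_vocabulary`, defaulting to the two standard
#'   names plus any tag used in the model).
#' @param biomass_only restrict to biomass-producing modes first.
#' @return filtered `efm_set`.
#' @export
filter_efms_by_condition <- function(efms, model,
                                     condition = c("aerobic", "anaerobic",
                                                   "both", "all"),
                                     rules = list(sensitive = "oxygen_sensitive",
                                                  dependent = "oxygen_dependent"),
                                     biomass_only = TRUE) {
  condition <- match.arg(condition)
  vocab <- unique(c("oxygen_sensitive", "oxygen_dependent",
                    unlist(reaction_tags(model)),
                    unlist(model$config$tag_vocabulary)))
  unknown <- setdiff(unlist(rules), vocab)
  if (length(unknown) > 0)
    stop("unknown tag(s) in condition rules: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cls <- .classify_oxygen(efms, model, rules)
  keep <- switch(condition,
    aerobic = !cls$uses_oxygen_sensitive,
    anaerobic = !cls$uses_oxygen_dependent,
    both = !cls$uses_oxygen_sensitive & !cls$uses_oxygen_dependent,
    all = !(cls$uses_oxygen_sensitive & cls$uses_oxygen_dependent)
  )
  if (biomass_only) keep <- keep & efms$meta$biomass_producing
  .efm_subset(efms, which(keep))
}

#' Remove flux modes using knocked-out reactions
#'
#' Gene/reaction deletions restrict the usable mode set: every mode whose
#' support intersects the knockout set is discarded; no re-enumeration is
#' needed.
#'
#' @param efms an `efm_set`.
#' @param reactions character vector of reaction ids to knock out.
#' @return filtered `efm_set` (possibly empty).
#' @export
knockout_filter <- function(efms, reactions) {
  unknown <- setdiff(reactions, rownames(efms$fluxes))
  if (length(unknown) > 0)
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(reactions) == 0) return(efms)
  hit <- colSums(abs(efms$fluxes[reactions, , drop = FALSE])) > 0
  .efm_subset(efms, which(!hit))
}
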