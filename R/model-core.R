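#' Kinetic metabolic model objects
#'
#' An `efcm_model` bundles everything needed to enumerate elementary flux
#' modes and minimize enzyme cost: network stoichiometry, reaction
#' reversibilities, kinetic constants (forward turnover numbers `kcat_fwd`,
#' equilibrium constants `keq`, per-reactant Michaelis constants `K_M`),
#' enzyme molecular masses, metabolite concentration bounds, fixed external
#' concentrations, the identity of the biomass and glucose-uptake reactions,
#' and the constants used to convert enzyme cost into growth rate.
#'
#' All concentrations are in mM and equilibrium constants follow the mM
#' convention. Fluxes are in mM/s; enzyme masses in Da (mg/mmol), so total
#' enzyme cost comes out in mg/l.
#'
#' @param compounds tibble with columns `id`, `name`, `is_external`,
#'   `fixed_conc_mM` (required for external compounds), `c_min_mM`,
#'   `c_max_mM` (internal compounds; defaults 1e-3 and 10 mM when `NA`),
#'   `carbon_count`.
#' @param reactions tibble with columns `id`, `formula` (see
#'   [parse_reaction_formula()]), `kcat_fwd_per_s`, `keq`, `enzyme_mass_da`,
#'   and `tags` (character, `;`-separated labels such as
#'   `"oxygen_sensitive"`).
#' @param km tibble with columns `reaction_id`, `compound_id`, `km_mM`. Every
#'   internal reactant of every reaction must have an entry; entries for
#'   external reactants are optional but needed for saturation effects of
#'   external substrates (e.g. Monod behaviour of a transporter).
#' @param config list with `biomass_reaction_id`, `glucose_uptake_reaction_id`,
#'   `v_bm_mass_mg_per_l_per_h`, optional `biomass_flux_convention_mM_per_s`
#'   (default 1), optional `growth_params` (see [growth_params()]), optional
#'   `glucose_compound_id` / `oxygen_compound_id` for condition scans.
#' @return an object of class `efcm_model`.
#' @export
efcm_model <- function(compounds, reactions, km, config) {
  compounds <- tibble::as_tibble(compounds)
  reactions <- tibble::as_tibble(reactions)
  km <- tibble::as_tibble(km)

  if (!"carbon_count" %in% names(compounds)) compounds$carbon_count <- 0L
  if (!"name" %in% names(compounds)) compounds$name <- compounds$id
  if (!"tags" %in% names(reactions)) reactions$tags <- ""
  compounds$is_external <- as.logical(compounds$is_external)

  # default concentration bounds for internal metabolites
  if (!"c_min_mM" %in% names(compounds)) compounds$c_min_mM <- NA_real_
  if (!"c_max_mM" %in% names(compounds)) compounds$c_max_mM <- NA_real_
  if (!"fixed_conc_mM" %in% names(compounds)) compounds$fixed_conc_mM <- NA_real_
  int <- !compounds$is_external
  compounds$c_min_mM[int & is.na(compounds$c_min_mM)] <- 1e-3
  compounds$c_max_mM[int & is.na(compounds$c_max_mM)] <- 10

  parsed <- lapply(reactions$formula, parse_reaction_formula)
  reactions$reversible <- vapply(parsed, `[[`, logical(1), "reversible")
  stoich <- lapply(parsed, `[[`, "stoich")
  names(stoich) <- reactions$id

  gp <- config$growth_params
  config$growth_params <- do.call(growth_params, c(
    if (is.null(gp)) list() else gp,
    if (is.null(gp$v_bm_mass) && !is.null(config$v_bm_mass_mg_per_l_per_h))
      list(v_bm_mass = config$v_bm_mass_mg_per_l_per_h)
  ))
  if (is.null(config$biomass_flux_convention_mM_per_s))
    config$biomass_flux_convention_mM_per_s <- 1

  model <- structure(
    list(compounds = compounds, reactions = reactions, km = km,
         stoich = stoich, config = config),
    class = "efcm_model"
  )
  issues <- validate_model(model)
  if (nrow(issues) > 0) {
    stop("invalid model:\n", paste0("  - ", issues$message, collapse = "\n"),
         call. = FALSE)
  }
  model
}

#' @export
print.efcm_model <- function(x, ...) {
  n_int <- sum(!x$compounds$is_external)
  cat("<efcm_model> ", nrow(x$reactions), " reactions, ",
      n_int, " internal / ", sum(x$compounds$is_external),
      " external metabolites\n", sep = "")
  cat("  biomass reaction: ", x$config$biomass_reaction_id,
      " (convention ", x$config$biomass_flux_convention_mM_per_s,
      " mM/s)\n", sep = "")
  invisible(x)
}

#' Parse a reaction formula string
#'
#' Grammar: `"a A + b B <=> c C"` (reversible) or `"... -> ..."`
#' (irreversible), with positive rational coefficients (`1` implicit).
#' An empty side is allowed (pure uptake/secretion written against external
#' species is the usual style, but sinks like `"B ->"` also parse).
#'
#' @param text formula string.
#' @return list with `stoich` (named numeric, substrates negative, products
#'   positive) and `reversible` (logical).
#' @examples
#' parse_reaction_formula("2 A + B -> C")
#' @export
parse_reaction_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  rev <- grepl("<=>", text, fixed = TRUE)
  sides <- if (rev) strsplit(text, "<=>", fixed = TRUE)[[1]]
           else strsplit(text, "->", fixed = TRUE)[[1]]
  if (!rev && !grepl("->", text, fixed = TRUE))
    stop("malformed formula (no '->' or '<=>'): ", text, call. = FALSE)
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(s, sgn) {
    s <- trimws(s)
    if (s == "") return(numeric(0))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    n_plus <- lengths(regmatches(s, gregexpr("+", s, fixed = TRUE)))
    if (n_plus != length(terms) - 1)  # leading/trailing/doubled '+'
      stop("malformed token '+' in formula: ", text, call. = FALSE)
    out <- numeric(0)
    for (term in terms) {
      if (term == "") stop("malformed token '' in formula: ", text, call. = FALSE)
      parts <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(parts) == 1) {
        coef <- 1; id <- parts[1]
      } else if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stop("malformed coefficient '", parts[1],
                              "' in formula: ", text, call. = FALSE)
        id <- parts[2]
      } else {
        stop("malformed token '", term, "' in formula: ", text, call. = FALSE)
      }
      if (coef <= 0) stop("non-positive coefficient in formula: ", text,
                          call. = FALSE)
      if (!grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", id))
        stop("malformed token '", id, "' in formula: ", text, call. = FALSE)
      out[id] <- (if (is.na(out[id])) 0 else out[id]) + sgn * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  stoich <- c(lhs, numeric(0))
  for (id in names(rhs)) {
    stoich[id] <- (if (id %in% names(stoich)) stoich[id] else 0) + rhs[id]
  }
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0)
    stop("formula has empty net stoichiometry: ", text, call. = FALSE)
  list(stoich = stoich, reversible = rev)
}

#' Render a stoichiometry map back to a canonical formula string
#'
#' Inverse of [parse_reaction_formula()]: substrates sorted by id on the
#' left, products on the right, unit coefficients omitted.
#'
#' @param stoich named numeric (negative substrates, positive products).
#' @param reversible logical.
#' @return formula string.
#' @export
render_reaction_formula <- function(stoich, reversible = FALSE) {
  fmt_side <- function(v) {
    if (length(v) == 0) return("")
    v <- v[order(names(v))]
    paste(ifelse(abs(v) == 1, names(v),
                 paste(format(abs(v), trim = TRUE, scientific = FALSE),
                       names(v))),
          collapse = " + ")
  }
  subs <- stoich[stoich < 0]
  prods <- stoich[stoich > 0]
  arrow <- if (reversible) "<=>" else "->"
  trimws(paste(fmt_side(subs), arrow, fmt_side(prods)))
}

#' Validate a metabolic model
#'
#' Checks type invariants (positive kinetic constants, ordered concentration
#' bounds, fixed concentrations for externals), referential integrity
#' (stoichiometry and K_M tables referring to declared compounds and
#' reactions, no duplicate ids), K_M coverage of internal reactants, and
#' that the internal stoichiometric matrix has a nontrivial nullspace.
#'
#' Issues are returned as data, not raised; [efcm_model()] raises them.
#'
#' @param model an `efcm_model` (or an unvalidated structure of the same shape).
#' @return tibble with columns `where` and `message`; zero rows if valid.
#' @export
validate_model <- function(model) {
  issues <- list()
  add <- function(where, message)
    issues[[length(issues) + 1]] <<- tibble::tibble(where = where,
                                                    message = message)
  cp <- model$compounds
  rx <- model$reactions

  dup <- cp$id[duplicated(cp$id)]
  for (d in unique(dup)) {
    add("compounds", paste0("duplicate compound id '", d, "' (rows ",
        paste(which(cp$id == d), collapse = ", "), ")"))
  }
  dup <- rx$id[duplicated(rx$id)]
  for (d in unique(dup)) {
    add("reactions", paste0("duplicate reaction id '", d, "' (rows ",
        paste(which(rx$id == d), collapse = ", "), ")"))
  }

  for (i in seq_len(nrow(cp))) {
    if (cp$is_external[i]) {
      if (is.na(cp$fixed_conc_mM[i]) || cp$fixed_conc_mM[i] <= 0)
        add("compounds", paste0("external compound '", cp$id[i],
            "' needs fixed_conc_mM > 0"))
    } else {
      if (is.na(cp$c_min_mM[i]) || is.na(cp$c_max_mM[i]) ||
          cp$c_min_mM[i] <= 0 || cp$c_min_mM[i] > cp$c_max_mM[i])
        add("compounds", paste0("internal compound '", cp$id[i],
            "' needs 0 < c_min_mM <= c_max_mM"))
    }
    if (is.na(cp$carbon_count[i]) || cp$carbon_count[i] < 0)
      add("compounds", paste0("compound '", cp$id[i],
          "' has invalid carbon_count"))
  }

  for (i in seq_len(nrow(rx))) {
    id <- rx$id[i]
    if (is.na(rx$kcat_fwd_per_s[i]) || rx$kcat_fwd_per_s[i] <= 0)
      add("reactions", paste0("reaction '", id, "' needs kcat_fwd_per_s > 0"))
    if (is.na(rx$keq[i]) || rx$keq[i] <= 0)
      add("reactions", paste0("reaction '", id, "' needs keq > 0"))
    if (is.na(rx$enzyme_mass_da[i]) || rx$enzyme_mass_da[i] <= 0)
      add("reactions", paste0("reaction '", id, "' needs enzyme_mass_da > 0"))
    st <- model$stoich[[id]]
    unknown <- setdiff(names(st), cp$id)
    if (length(unknown) > 0)
      add("reactions", paste0("reaction '", id,
          "' references unknown compound(s): ",
          paste(unknown, collapse = ", ")))
    # K_M coverage: every internal reactant must have an entry
    internal_ids <- cp$id[!cp$is_external]
    need <- intersect(names(st), internal_ids)
    have <- model$km$compound_id[model$km$reaction_id == id]
    missing <- setdiff(need, have)
    for (m in missing)
      add("km", paste0("reaction '", id, "': missing K_M for internal ",
          "reactant '", m, "'"))
  }

  bad_km <- model$km[!is.na(model$km$km_mM) & model$km$km_mM <= 0, ]
  for (i in seq_len(nrow(bad_km)))
    add("km", paste0("non-positive K_M for ('", bad_km$reaction_id[i], "', '",
        bad_km$compound_id[i], "')"))
  unknown_km <- model$km[!(model$km$reaction_id %in% rx$id) |
                         !(model$km$compound_id %in% cp$id), ]
  for (i in seq_len(nrow(unknown_km)))
    add("km", paste0("K_M row references unknown ids ('",
        unknown_km$reaction_id[i], "', '", unknown_km$compound_id[i], "')"))

  for (field in c("biomass_reaction_id", "glucose_uptake_reaction_id")) {
    v <- model$config[[field]]
    if (is.null(v) || !(v %in% rx$id))
      add("config", paste0(field, " ('", v %||% "NULL",
          "') not among reaction ids"))
  }

  if (length(issues) == 0 || !any(grepl("unknown compound", vapply(issues, function(x) x$message, character(1))))) {
    s <- try(stoich_matrix(model, internal_only = TRUE), silent = TRUE)
    if (!inherits(s, "try-error") && nrow(s) > 0 &&
        .mat_rank(s) >= ncol(s))
      add("stoichiometry",
          "internal stoichiometric matrix has a trivial nullspace")
  }

  if (length(issues) == 0) {
    tibble::tibble(where = character(0), message = character(0))
  } else {
    dplyr::bind_rows(issues)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stoichiometric matrix of a model
#'
#' @param model an `efcm_model`.
#' @param internal_only drop rows of external (fixed-concentration) compounds.
#' @return numeric matrix, metabolites x reactions, signed coefficients.
#' @export
stoich_matrix <- function(model, internal_only = TRUE) {
  cp <- model$compounds
  ids <- if (internal_only) cp$id[!cp$is_external] else cp$id
  m <- matrix(0, length(ids), nrow(model$reactions),
              dimnames = list(ids, model$reactions$id))
  for (r in model$reactions$id) {
    st <- model$stoich[[r]]
    keep <- intersect(names(st), ids)
    m[keep, r] <- st[keep]
  }
  m
}

#' Reaction tags as a named list
#' @param model an `efcm_model`.
#' @return named list of character vectors, one per reaction.
#' @export
reaction_tags <- function(model) {
  tags <- strsplit(model$reactions$tags %||% "", ";", fixed = TRUE)
  tags <- lapply(tags, function(t) trimws(t[nzchar(trimws(t))]))
  names(tags) <- model$reactions$id
  tags
}

#' Read a model bundle from disk
#'
#' A bundle is a directory holding `compounds.tsv`, `reactions.tsv`,
#' `km.tsv` and `config.json` (see [efcm_model()] for column contracts).
#'
#' @param path bundle directory.
#' @return an `efcm_model`.
#' @export
load_model <- function(path) {
  req <- c("compounds.tsv", "reactions.tsv", "km.tsv", "config.json")
  missing <- req[!file.exists(file.path(path, req))]
  if (length(missing) > 0)
    stop("model bundle at '", path, "' is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  # read everything as character and convert with base parsers: strtod is
  # correctly rounded, so numeric fields survive the round-trip bit-exactly
  read_exact <- function(file, dbl = character(0), int = character(0),
                         lgl = character(0)) {
    d <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
    for (col in intersect(dbl, names(d))) d[[col]] <- as.numeric(d[[col]])
    for (col in intersect(int, names(d))) d[[col]] <- as.integer(d[[col]])
    for (col in intersect(lgl, names(d))) d[[col]] <- as.logical(d[[col]])
    d
  }
  compounds <- read_exact(file.path(path, "compounds.tsv"),
                          dbl = c("fixed_conc_mM", "c_min_mM", "c_max_mM"),
                          int = "carbon_count", lgl = "is_external")
  reactions <- read_exact(file.path(path, "reactions.tsv"),
                          dbl = c("kcat_fwd_per_s", "keq",
                                  "enzyme_mass_da"))
  km <- read_exact(file.path(path, "km.tsv"), dbl = "km_mM")
  if (!"tags" %in% names(reactions)) reactions$tags <- ""
  reactions$tags[is.na(reactions$tags)] <- ""
  config <- jsonlite::read_json(file.path(path, "config.json"),
                                simplifyVector = TRUE)
  efcm_model(compounds, reactions, km, config)
}

#' Write a model bundle to disk
#'
#' Inverse of [load_model()]; a written bundle reloads to a numerically
#' identical model.
#'
#' @param model an `efcm_model`.
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  # %.17g is the shortest decimal form that survives a double round-trip,
  # so a written bundle reloads bit-identically
  tsv_exact <- function(df, file) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(v)
      ifelse(is.na(v), NA_character_, sprintf("%.17g", v)))
    readr::write_tsv(df, file)
  }
  tsv_exact(model$compounds, file.path(path, "compounds.tsv"))
  rx <- model$reactions
  rx$reversible <- NULL
  tsv_exact(rx, file.path(path, "reactions.tsv"))
  tsv_exact(model$km, file.path(path, "km.tsv"))
  cfg <- model$config
  cfg$growth_params <- unclass(cfg$growth_params)
  jsonlite::write_json(cfg, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Import stoichiometry from an SBML file
#'
#' Reads species and reactions from an SBML (level 2/3 core) document and
#' returns skeleton tables: compounds (with `is_external` taken from the
#' species' boundary-condition flag) and reactions (id, formula,
#' reversibility). Kinetic laws are deliberately ignored — kinetics always
#' come from the bundle's TSV tables; merge these skeletons with kinetic
#' constants and call [efcm_model()].
#'
#' @param path SBML file.
#' @return list with `compounds` and `reactions` tibbles.
#' @export
load_sbml_stoichiometry <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("SBML import needs the 'xml2' package", call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  compounds <- tibble::tibble(
    id = xml2::xml_attr(sp, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"),
                           xml2::xml_attr(sp, "id")),
    is_external = xml2::xml_attr(sp, "boundaryCondition") %in%
      c("true", "1")
  )
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  side <- function(node, which) {
    refs <- xml2::xml_find_all(
      node, paste0("./", which, "/speciesReference"))
    if (length(refs) == 0) return(numeric(0))
    coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    coef[is.na(coef)] <- 1
    stats::setNames(coef, xml2::xml_attr(refs, "species"))
  }
  reactions <- dplyr::bind_rows(lapply(rx, function(node) {
    subs <- side(node, "listOfReactants")
    prods <- side(node, "listOfProducts")
    st <- c(-subs, prods)
    rev <- !(xml2::xml_attr(node, "reversible") %in% c("false", "0"))
    tibble::tibble(
      id = xml2::xml_attr(node, "id"),
      formula = render_reaction_formula(st, rev))
  }))
  list(compounds = compounds, reactions = reactions)
}
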