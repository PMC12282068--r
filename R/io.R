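## Model I/O.
##
## Two on-disk dialects: SBML Level 3 (core + fbc attributes) for plain
## stoichiometric models, and a JSON dialect that covers both plain and
## enzyme-constrained models. Infinite bounds are serialized as "INF" in
## SBML and as +-1e308 sentinels in JSON.

.sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
.fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
.morp_ns <- "https://morp-package.invalid/sbml/kind"

.num_out <- function(x) ifelse(is.finite(x), x, sign(x) * 1e308)
.num_in <- function(x) ifelse(abs(x) >= 1e300, sign(x) * Inf, x)

#' Load a metabolic model from file
#'
#' Reads SBML Level 3 (plain stoichiometric models) or the package's
#' JSON dialect (plain or enzyme-constrained models, as written by
#' [save_model()]).
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension: `.xml`/`.sbml` vs `.json`),
#'   `"sbml"` or `"json"`.
#' @return A `stoich_model` or `ec_model`.
#' @export
load_gem <- function(path, dialect = c("auto", "sbml", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "morp_io_error")
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml"
    } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
      "json"
    } else {
      abort_format(paste0("cannot infer dialect from extension: ", path))
    }
  }
  if (dialect == "sbml") .read_sbml(path) else .read_model_json(path)
}

#' Save a model to file
#'
#' @param model A `stoich_model` or `ec_model`. Enzyme-constrained
#'   models can only be written to the JSON dialect (the enzyme layer
#'   has no SBML counterpart here).
#' @param path Destination file.
#' @param dialect `"auto"`, `"sbml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, dialect = c("auto", "sbml", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml"
    } else "json"
  }
  if (dialect == "sbml") {
    if (inherits(model, "ec_model")) {
      abort_format("enzyme-constrained models are saved as JSON, not SBML")
    }
    .write_sbml(model, path)
  } else {
    .write_model_json(model, path)
  }
  invisible(path)
}

.model_to_list <- function(net) {
  list(
    metabolites = lapply(seq_len(nrow(net$metabolites)), function(i) {
      as.list(net$metabolites[i, c("id", "name", "formula", "compartment",
                                   "is_boundary")])
    }),
    reactions = lapply(seq_len(nrow(net$reactions)), function(j) {
      st <- net$reactions$stoichiometry[[j]]
      list(id = net$reactions$id[j],
           lb = .num_out(net$reactions$lb[j]),
           ub = .num_out(net$reactions$ub[j]),
           kind = net$reactions$kind[j],
           stoichiometry = as.list(st))
    }),
    biomass_id = net$biomass_id,
    objective_default = net$objective_default)
}

.write_model_json <- function(model, path) {
  if (inherits(model, "ec_model")) {
    body <- list(format = "morp-model", version = 1L, type = "ec_model",
                 network = .model_to_list(model$network),
                 enzymes = model$enzymes,
                 kcats = model$kcats,
                 enzyme_usage_ids = model$enzyme_usage_ids,
                 pool_exchange_id = model$pool_exchange_id,
                 pool_capacity = model$pool_capacity,
                 split_map = model$split_map)
  } else {
    body <- c(list(format = "morp-model", version = 1L,
                   type = "stoichiometric_model"),
              .model_to_list(model))
  }
  tryCatch(
    jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                         null = "null"),
    error = function(e) {
      rlang::abort(paste0("cannot write ", path, ": ",
                          conditionMessage(e)), class = "morp_io_error")
    })
}

.list_to_model <- function(x) {
  mets <- dplyr::bind_rows(lapply(x$metabolites, tibble::as_tibble))
  rxns <- tibble::tibble(
    id = vapply(x$reactions, function(r) r$id, ""),
    lb = .num_in(vapply(x$reactions, function(r) as.numeric(r$lb), 1)),
    ub = .num_in(vapply(x$reactions, function(r) as.numeric(r$ub), 1)),
    kind = vapply(x$reactions, function(r) r$kind, ""),
    stoichiometry = lapply(x$reactions, function(r) {
      unlist(r$stoichiometry)
    }))
  stoichiometric_model(mets, rxns, biomass_id = x$biomass_id,
                       objective_default = x$objective_default)
}

.read_model_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) {
                  abort_format(paste0("JSON parse failure in ", path, ": ",
                                      conditionMessage(e)))
                })
  if (is.null(x$format) || x$format != "morp-model") {
    abort_format(paste0(path, " is not a morp-model JSON file"))
  }
  if (identical(x$type, "stoichiometric_model")) {
    return(.list_to_model(x))
  }
  if (!identical(x$type, "ec_model")) {
    abort_format(paste0("unknown model type: ", x$type))
  }
  network <- .list_to_model(x$network)
  structure(
    list(network = network,
         enzymes = dplyr::bind_rows(lapply(x$enzymes, tibble::as_tibble)),
         kcats = dplyr::bind_rows(lapply(x$kcats, tibble::as_tibble)),
         enzyme_usage_ids = unlist(x$enzyme_usage_ids) %||% character(0),
         pool_exchange_id = x$pool_exchange_id,
         pool_capacity = x$pool_capacity,
         split_map = dplyr::bind_rows(lapply(x$split_map,
                                             tibble::as_tibble))),
    class = "ec_model")
}

.write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = .sbml_ns, "xmlns:fbc" = .fbc_ns,
    "xmlns:morp" = .morp_ns, level = "3", version = "1",
    "fbc:required" = "false")
  mod <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "false")
  ann <- xml2::xml_add_child(mod, "annotation")
  xml2::xml_add_child(ann, "morp:biomass", model$biomass_id)
  comps <- unique(model$metabolites$compartment)
  lc <- xml2::xml_add_child(mod, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  }
  ls <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(
      ls, "species", id = m$id, name = m$name, compartment = m$compartment,
      boundaryCondition = tolower(as.character(m$is_boundary)),
      hasOnlySubstanceUnits = "false", constant = "false")
    if (!is.na(m$formula) && m$formula != "") {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
  }
  lp <- xml2::xml_add_child(mod, "listOfParameters")
  fmt_num <- function(x) {
    if (!is.finite(x)) {
      if (x > 0) "INF" else "-INF"
    } else {
      format(x, digits = 17, scientific = TRUE)
    }
  }
  for (j in seq_len(nrow(model$reactions))) {
    xml2::xml_add_child(lp, "parameter", id = paste0("lb_", j),
                        value = fmt_num(model$reactions$lb[j]),
                        constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0("ub_", j),
                        value = fmt_num(model$reactions$ub[j]),
                        constant = "true")
  }
  lr <- xml2::xml_add_child(mod, "listOfReactions")
  for (j in seq_len(nrow(model$reactions))) {
    r <- model$reactions[j, ]
    rn <- xml2::xml_add_child(
      lr, "reaction", id = r$id,
      reversible = tolower(as.character(r$lb < 0)), fast = "false",
      "fbc:lowerFluxBound" = paste0("lb_", j),
      "fbc:upperFluxBound" = paste0("ub_", j))
    ra <- xml2::xml_add_child(rn, "annotation")
    xml2::xml_add_child(ra, "morp:kind", r$kind)
    st <- r$stoichiometry[[1]]
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (met in names(reac)) {
        xml2::xml_add_child(lre, "speciesReference", species = met,
                            stoichiometry = format(-reac[[met]],
                                                   digits = 17),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (met in names(prod)) {
        xml2::xml_add_child(lpr, "speciesReference", species = met,
                            stoichiometry = format(prod[[met]],
                                                   digits = 17),
                            constant = "true")
      }
    }
  }
  lo <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lf, "fbc:fluxObjective",
                      "fbc:reaction" = model$objective_default,
                      "fbc:coefficient" = "1")
  tryCatch(xml2::write_xml(doc, path),
           error = function(e) {
             rlang::abort(paste0("cannot write ", path, ": ",
                                 conditionMessage(e)),
                          class = "morp_io_error")
           })
}

.read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    abort_format(paste0("SBML parse failure in ", path,
                                        ": ", conditionMessage(e)))
                  })
  ns <- c(s = .sbml_ns, fbc = .fbc_ns, morp = .morp_ns)
  num_in <- function(x) {
    ifelse(x == "INF", Inf, ifelse(x == "-INF", -Inf,
                                   suppressWarnings(as.numeric(x))))
  }
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(sp_nodes) == 0) abort_format("no species found (is this SBML?)")
  mets <- tibble::tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"),
                           xml2::xml_attr(sp_nodes, "id")),
    formula = dplyr::coalesce(xml2::xml_attr(sp_nodes, "chemicalFormula"),
                              ""),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    is_boundary = xml2::xml_attr(sp_nodes, "boundaryCondition") == "true")
  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter",
                                  ns)
  pars <- stats::setNames(num_in(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  get_sto <- function(node) {
    rs <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference",
                             ns)
    ps <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference",
                             ns)
    st <- numeric(0)
    for (x in rs) {
      met <- xml2::xml_attr(x, "species")
      st[met] <- (if (met %in% names(st)) st[[met]] else 0) -
        as.numeric(xml2::xml_attr(x, "stoichiometry"))
    }
    for (x in ps) {
      met <- xml2::xml_attr(x, "species")
      st[met] <- (if (met %in% names(st)) st[[met]] else 0) +
        as.numeric(xml2::xml_attr(x, "stoichiometry"))
    }
    st
  }
  bound_of <- function(node, which) {
    ref <- xml2::xml_attr(node, which)
    if (!is.na(ref) && ref %in% names(pars)) return(pars[[ref]])
    if (which == "lowerFluxBound") {
      if (identical(xml2::xml_attr(node, "reversible"), "true")) -Inf else 0
    } else {
      Inf
    }
  }
  kind_of <- function(node, st) {
    k <- xml2::xml_find_first(node, "./s:annotation/morp:kind", ns)
    if (!inherits(k, "xml_missing")) return(xml2::xml_text(k))
    if (length(st) == 1) "exchange" else "metabolic"
  }
  stos <- lapply(rx_nodes, get_sto)
  rxns <- tibble::tibble(
    id = xml2::xml_attr(rx_nodes, "id"),
    lb = vapply(rx_nodes, bound_of, 1, which = "lowerFluxBound"),
    ub = vapply(rx_nodes, bound_of, 1, which = "upperFluxBound"),
    kind = mapply(kind_of, rx_nodes, stos),
    stoichiometry = stos)
  bm <- xml2::xml_find_first(doc, ".//s:model/s:annotation/morp:biomass",
                             ns)
  obj <- xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns)
  obj_id <- if (!inherits(obj, "xml_missing")) {
    xml2::xml_attr(obj, "reaction")
  }
  biomass_id <- if (!inherits(bm, "xml_missing")) {
    xml2::xml_text(bm)
  } else if (!is.null(obj_id) && obj_id %in% rxns$id &&
             rxns$kind[rxns$id == obj_id] == "biomass") {
    obj_id
  } else {
    abort_config(paste0("no biomass reaction identified in ", path))
  }
  stoichiometric_model(mets, rxns, biomass_id = biomass_id,
                       objective_default = obj_id %||% biomass_id)
}

#' Read an enzyme annotation table
#'
#' TSV with columns `enzyme_id`, `reaction_id`, `kcat_per_h`,
#' `mw_g_per_mmol`; one row per (enzyme, reaction) pair.
#'
#' @param path TSV file path.
#' @return Tibble for [build_ec_model()].
#' @export
read_enzyme_table <- function(path) {
  tb <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      abort_format(paste0("cannot read enzyme table ", path, ": ",
                          conditionMessage(e)))
    })
  need <- c("enzyme_id", "reaction_id", "kcat_per_h", "mw_g_per_mmol")
  if (!all(need %in% names(tb))) {
    abort_format(paste0("enzyme table must have columns: ",
                        paste(need, collapse = ", ")))
  }
  tb
}

#' Write a flux solution to CSV or JSON
#'
#' @param sol A `flux_solution`.
#' @param path Destination; `.csv` writes `reaction_id, flux`, `.json`
#'   a full record (fluxes, enzyme usage, objective, status).
#' @return `path`, invisibly.
#' @export
write_solution <- function(sol, path) {
  stopifnot(inherits(sol, "flux_solution"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(status = sol$status, objective_kind = sol$objective_kind,
           objective_value = sol$objective_value,
           fluxes = as.list(sol$fluxes),
           enzyme_usage = as.list(sol$enzyme_usage)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(tibble::tibble(reaction_id = names(sol$fluxes),
                                    flux = unname(sol$fluxes)), path,
                     progress = FALSE)
  }
  invisible(path)
}

#' Read a flux solution written by [write_solution()] (JSON form)
#'
#' @param path JSON file path.
#' @return A `flux_solution`.
#' @export
read_solution <- function(path) {
  x <- jsonlite::read_json(path)
  structure(
    list(fluxes = unlist(x$fluxes),
         enzyme_usage = if (length(x$enzyme_usage)) unlist(x$enzyme_usage)
                        else stats::setNames(numeric(0), character(0)),
         objective_value = x$objective_value, status = x$status,
         objective_kind = x$objective_kind),
    class = "flux_solution")
}

#' Export a trajectory as tidy CSV files
#'
#' Writes `states.csv` (`time, variable, value`; biomass and each
#' tracked concentration), `fluxes.csv` (`interval, time, phase,
#' reaction_id, flux` for every interval solution) and `usage.csv`
#' (same layout for enzyme-usage fluxes).
#'
#' @param traj A `dfba_trajectory`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  states <- tidyr::pivot_longer(traj$states, -"t", names_to = "variable",
                                values_to = "value")
  names(states)[1] <- "time"
  readr::write_csv(states, file.path(dir, "states.csv"), progress = FALSE)
  fl <- purrr::imap_dfr(traj$solutions, function(s, k) {
    tibble::tibble(interval = k, time = traj$states$t[k],
                   phase = traj$phase_labels[k],
                   reaction_id = names(s$fluxes),
                   flux = unname(s$fluxes))
  })
  readr::write_csv(fl, file.path(dir, "fluxes.csv"), progress = FALSE)
  us <- purrr::imap_dfr(traj$solutions, function(s, k) {
    tibble::tibble(interval = k, time = traj$states$t[k],
                   phase = traj$phase_labels[k],
                   enzyme_usage_id = names(s$enzyme_usage),
                   usage = unname(s$enzyme_usage))
  })
  readr::write_csv(us, file.path(dir, "usage.csv"), progress = FALSE)
  invisible(dir)
}

#' Read a simulation scenario from YAML
#'
#' The YAML lays out a full dynamic simulation: the model (either an
#' enzyme-constrained JSON model, or a plain model plus `enzyme_table`
#' and `pool_capacity`), the Monod `kinetics`, the tracked `species`
#' map, the `schedule` of phases, the initial state and the numerics:
#'
#' ```yaml
#' model: model.json          # or model.xml
#' enzyme_table: enzymes.tsv  # with pool_capacity, for plain models
#' pool_capacity: 0.024
#' dt: 0.1
#' t_end: 14
#' uptake_bound: equality
#' init:
#'   biomass: 0.1
#'   concentrations: {glc_e: 20, tre_e: 20, lac_e: 0}
#' species:
#'   - {species: glc_e, exchange_id: EX_glc, mw: 0.18016}
#' kinetics:
#'   - {substrate: glc_e, uptake_reaction: EX_glc, v_max: 10, km: 0.05}
#' schedule:
#'   - objective: {kind: max_growth}
#'     until: {species: glc_e, threshold: 1.0}
#'     bounds: [{reaction_id: EX_tre, lb: 0, ub: 0}]
#'   - objective: {kind: morp}
#' ```
#'
#' Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return List with `model`, `schedule`, `kinetics`, `species`,
#'   `init`, `dt`, `t_end`, `uptake_bound` ready for [simulate_dfba()].
#' @export
read_scenario <- function(path) {
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) {
                  abort_format(paste0("YAML parse failure in ", path, ": ",
                                      conditionMessage(e)))
                })
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  for (k in c("model", "dt", "t_end", "init", "species", "kinetics",
              "schedule")) {
    if (is.null(y[[k]])) {
      abort_config(paste0("scenario is missing field '", k, "'"))
    }
  }
  model <- load_gem(resolve(y$model))
  if (!inherits(model, "ec_model")) {
    if (is.null(y$enzyme_table) || is.null(y$pool_capacity)) {
      abort_config(paste0("plain model needs 'enzyme_table' and ",
                          "'pool_capacity' in the scenario"))
    }
    model <- build_ec_model(model, read_enzyme_table(resolve(y$enzyme_table)),
                            y$pool_capacity)
  }
  species <- dplyr::bind_rows(lapply(y$species, tibble::as_tibble))
  kin <- dplyr::bind_rows(lapply(y$kinetics, tibble::as_tibble))
  kinetics <- monod_kinetics(kin$substrate, kin$uptake_reaction,
                             kin$v_max, kin$km)
  schedule <- lapply(y$schedule, function(ph) {
    ob <- ph$objective
    obj <- objective(ob$kind, target = ob$target,
                     reference = if (!is.null(ob$reference)) {
                       read_solution(resolve(ob$reference))
                     })
    phase(obj,
          until_species = ph$until$species,
          until_threshold = ph$until$threshold %||% 0.01,
          until_time = ph$until$time %||% Inf,
          bounds = if (!is.null(ph$bounds)) {
            dplyr::bind_rows(lapply(ph$bounds, tibble::as_tibble))
          })
  })
  conc <- unlist(y$init$concentrations)
  init <- culture_state(t = y$init$t %||% 0, biomass = y$init$biomass,
                        concentrations = conc)
  list(model = model, schedule = schedule, kinetics = kinetics,
       species = species, init = init, dt = y$dt, t_end = y$t_end,
       uptake_bound = y$uptake_bound %||% "equality")
}
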