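## Model containers.
##
## A stoichiometric model is held as three tibbles (metabolites, reactions,
## long-format stoichiometry) plus the biomass/objective ids; an
## enzyme-constrained model wraps an augmented copy of the network in which
## enzyme pseudo-metabolites, enzyme-usage reactions and a protein pool
## exchange encode the GECKO coupling v_j <= kcat_ij * e_i.

.reaction_kinds <- c("metabolic", "exchange", "biomass", "ngam",
                     "enzyme_usage", "pool_exchange")

abort_validation <- function(msg) rlang::abort(msg, class = "morp_validation_error")
abort_format <- function(msg) rlang::abort(msg, class = "morp_format_error")
abort_config <- function(msg) rlang::abort(msg, class = "morp_config_error")
abort_infeasible <- function(msg, data = NULL) {
  rlang::abort(msg, class = "morp_infeasible_error", data = data)
}

#' Construct a stoichiometric metabolic model
#'
#' @param metabolites Tibble with columns `id`, `name`, `formula`,
#'   `compartment`, `is_boundary`. Missing optional columns are filled
#'   (`name = id`, `formula = ""`, `compartment = "c"`,
#'   `is_boundary = FALSE`).
#' @param reactions Tibble with columns `id`, `lb`, `ub`, `kind`
#'   (one of metabolic, exchange, biomass, ngam, enzyme_usage,
#'   pool_exchange) and either a list-column `stoichiometry` of named
#'   numeric vectors or an `equation` column of reaction strings such as
#'   `"glc_e + atp -> g6p + adp"` (coefficients prefix the species:
#'   `"2 pyr -> actn_e + 2 co2_e"`).
#' @param biomass_id Reaction id of the biomass reaction (kind `biomass`).
#' @param objective_default Reaction id optimized when no objective is
#'   given; defaults to `biomass_id`.
#'
#' @return An object of class `stoich_model`.
#' @examples
#' m <- stoichiometric_model(
#'   metabolites = tibble::tibble(id = c("a", "b")),
#'   reactions = tibble::tibble(
#'     id = c("EX_a", "r1", "EX_b", "bio"),
#'     equation = c("-> a", "a -> b", "b ->", "b ->"),
#'     lb = c(0, 0, 0, 0), ub = c(10, 1000, 1000, 1000),
#'     kind = c("exchange", "metabolic", "exchange", "biomass")),
#'   biomass_id = "bio")
#' m
#' @export
stoichiometric_model <- function(metabolites, reactions, biomass_id,
                                 objective_default = biomass_id) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"formula" %in% names(metabolites)) metabolites$formula <- ""
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  if (!"is_boundary" %in% names(metabolites)) metabolites$is_boundary <- FALSE
  metabolites$formula[is.na(metabolites$formula)] <- ""
  if (!"stoichiometry" %in% names(reactions)) {
    if (!"equation" %in% names(reactions)) {
      abort_validation("reactions need a `stoichiometry` or `equation` column")
    }
    reactions$stoichiometry <- lapply(reactions$equation,
                                      parse_reaction_string)
    reactions$equation <- NULL
  }
  if (!"kind" %in% names(reactions)) reactions$kind <- "metabolic"
  model <- structure(
    list(metabolites = metabolites,
         reactions = reactions[, c("id", "lb", "ub", "kind", "stoichiometry")],
         biomass_id = biomass_id,
         objective_default = objective_default),
    class = "stoich_model")
  validate_model(model)
  model
}

#' Parse a reaction-equation string
#'
#' Accepts `"a + 2 b -> c"`; an empty side (`"-> a"`, `"a ->"`) denotes a
#' boundary/drain reaction. Fractional coefficients are allowed
#' (`"0.5 o2 -> x"`).
#'
#' @param eq Equation string with `->` separating substrates and products.
#' @return Named numeric vector of signed stoichiometric coefficients.
#' @examples
#' parse_reaction_string("glc + atp -> g6p + adp")
#' @export
parse_reaction_string <- function(eq) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2) abort_format(paste0("malformed equation: ", eq))
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (txt == "") return(numeric(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      parts <- strsplit(tm, "\\s+")[[1]]
      if (length(parts) == 1) {
        coef <- 1; met <- parts
      } else if (length(parts) == 2 &&
                 grepl("^[0-9.]+$", parts[1])) {
        coef <- as.numeric(parts[1]); met <- parts[2]
      } else {
        abort_format(paste0("malformed term '", tm, "' in: ", eq))
      }
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  co <- lhs
  for (met in names(rhs)) {
    co[met] <- (if (met %in% names(co)) co[[met]] else 0) + rhs[[met]]
  }
  co[co != 0]
}

validate_model <- function(model) {
  mets <- model$metabolites; rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    abort_validation(paste0("duplicate metabolite id: ",
                            mets$id[duplicated(mets$id)][1]))
  }
  if (anyDuplicated(rxns$id)) {
    abort_validation(paste0("duplicate reaction id: ",
                            rxns$id[duplicated(rxns$id)][1]))
  }
  bad_kind <- setdiff(unique(rxns$kind), .reaction_kinds)
  if (length(bad_kind)) {
    abort_validation(paste0("unknown reaction kind: ", bad_kind[1]))
  }
  if (any(rxns$lb > rxns$ub)) {
    abort_validation(paste0("lb > ub for reaction ",
                            rxns$id[which(rxns$lb > rxns$ub)[1]]))
  }
  used <- unique(unlist(lapply(rxns$stoichiometry, names)))
  missing <- setdiff(used, mets$id)
  if (length(missing)) {
    abort_format(paste0("reaction references undeclared metabolite: ",
                        missing[1]))
  }
  if (!model$biomass_id %in% rxns$id) {
    abort_config(paste0("biomass reaction '", model$biomass_id,
                        "' not found in model"))
  }
  if (rxns$kind[rxns$id == model$biomass_id] != "biomass") {
    abort_config(paste0("reaction '", model$biomass_id,
                        "' is not of kind 'biomass'"))
  }
  if (!model$objective_default %in% rxns$id) {
    abort_config(paste0("default objective reaction '",
                        model$objective_default, "' not found"))
  }
  invisible(model)
}

#' Dense stoichiometric matrix of a model
#'
#' @param model A `stoich_model` or `ec_model`.
#' @return Numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  if (inherits(model, "ec_model")) model <- model$network
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (j in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[j]]
    S[names(st), j] <- st
  }
  S
}

#' Parse an elemental formula
#'
#' @param formula String such as `"C6H12O6"`; element symbols may carry an
#'   integer count (absent count = 1).
#' @return Named numeric vector of element counts; empty for `""`.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || formula == "") return(numeric(0))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    abort_validation(paste0("unparseable formula: '", formula, "'"))
  }
  out <- numeric(0)
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    ct <- sub("^[A-Za-z]+", "", tk)
    n <- if (ct == "") 1 else as.numeric(ct)
    out[el] <- (if (el %in% names(out)) out[[el]] else 0) + n
  }
  out
}

# bounds of one reaction
reaction_bounds <- function(model, id) {
  net <- if (inherits(model, "ec_model")) model$network else model
  i <- match(id, net$reactions$id)
  if (is.na(i)) abort_validation(paste0("unknown reaction: ", id))
  c(lb = net$reactions$lb[i], ub = net$reactions$ub[i])
}

#' Set flux bounds on a model
#'
#' Returns a modified copy; works on both plain and enzyme-constrained
#' models (for the latter the augmented network is modified).
#'
#' @param model A `stoich_model` or `ec_model`.
#' @param reaction_id Reaction id(s).
#' @param lb,ub New bounds, recycled along `reaction_id`; `NA` keeps the
#'   current value.
#' @return The modified model.
#' @export
set_flux_bounds <- function(model, reaction_id, lb = NA, ub = NA) {
  is_ec <- inherits(model, "ec_model")
  net <- if (is_ec) model$network else model
  idx <- match(reaction_id, net$reactions$id)
  if (anyNA(idx)) {
    abort_validation(paste0("unknown reaction: ",
                            reaction_id[which(is.na(idx))[1]]))
  }
  lb <- rep_len(lb, length(idx)); ub <- rep_len(ub, length(idx))
  keep_lb <- is.na(lb); keep_ub <- is.na(ub)
  net$reactions$lb[idx] <- ifelse(keep_lb, net$reactions$lb[idx], lb)
  net$reactions$ub[idx] <- ifelse(keep_ub, net$reactions$ub[idx], ub)
  if (any(net$reactions$lb[idx] > net$reactions$ub[idx])) {
    abort_validation("lb > ub after update")
  }
  if (is_ec) { model$network <- net; model } else net
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("<stoich_model> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions\n", sep = "")
  cat("  biomass: ", x$biomass_id,
      "; default objective: ", x$objective_default, "\n", sep = "")
  invisible(x)
}

#' @export
print.ec_model <- function(x, ...) {
  cat("<ec_model> ", nrow(x$network$metabolites), " metabolites, ",
      nrow(x$network$reactions), " reactions (",
      length(x$enzyme_usage_ids), " enzyme-usage)\n", sep = "")
  cat("  protein pool capacity: ", x$pool_capacity, " g/gDW\n", sep = "")
  invisible(x)
}
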