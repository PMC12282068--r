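## GECKO-style conversion: couple reaction fluxes to enzyme amounts via
## 1/kcat coefficients on enzyme pseudo-metabolites, draw enzyme mass from
## a finite protein pool.

.pool_met <- "prot_pool"

#' Build an enzyme-constrained model
#'
#' Augments a stoichiometric model with one pseudo-metabolite and one
#' usage reaction per enzyme, and a protein-pool exchange bounded by
#' `pool_capacity`. Each catalyzed reaction j consumes `1/kcat_ij` of
#' enzyme pseudo-metabolite i per unit flux, so the steady-state balance
#' enforces `v_j <= kcat_ij * e_i` with `e_i` the usage-reaction flux
#' (mmol/gDW/h). Usage reaction i draws `mw_i` grams of pool per mmol of
#' enzyme, and the pool exchange is bounded above by the capacity
#' (g/gDW). Reversible catalyzed reactions are split into `__fwd`/`__rev`
#' irreversible pairs; reactions catalyzed by several isozymes are split
#' into parallel arms `__iso1..k` (or collapsed onto the fastest isozyme
#' when `isozyme_policy = "fastest"`).
#'
#' @param gem A `stoich_model`.
#' @param enzymes Enzyme table: tibble with columns `enzyme_id`,
#'   `reaction_id`, `kcat_per_h` (turnover, 1/h) and `mw_g_per_mmol`
#'   (molecular weight, g/mmol), one row per (enzyme, reaction) pair;
#'   see [read_enzyme_table()].
#' @param pool_capacity Total catalytic protein budget (g/gDW), > 0.
#' @param isozyme_policy `"parallel"` (default, one arm per isozyme) or
#'   `"fastest"` (keep only the highest-kcat isozyme).
#' @return An object of class `ec_model` with fields `network` (the
#'   augmented `stoich_model`), `enzymes` (tibble `enzyme_id`, `mw`),
#'   `kcats` (tibble `enzyme_id`, `reaction_id`, `kcat` after
#'   split/arm renaming), `enzyme_usage_ids`, `pool_exchange_id`,
#'   `pool_capacity` and `split_map`.
#' @examples
#' gem <- stoichiometric_model(
#'   metabolites = tibble::tibble(id = c("s", "p")),
#'   reactions = tibble::tibble(
#'     id = c("EX_s", "CAT", "EX_p", "bio"),
#'     equation = c("-> s", "s -> p", "p ->", "p ->"),
#'     lb = 0, ub = c(10, 1000, 1000, 1000),
#'     kind = c("exchange", "metabolic", "exchange", "biomass")),
#'   biomass_id = "bio")
#' enz <- tibble::tibble(enzyme_id = "E1", reaction_id = "CAT",
#'                       kcat_per_h = 100, mw_g_per_mmol = 0.05)
#' ec <- build_ec_model(gem, enz, pool_capacity = 0.1)
#' # flux through CAT is capped at kcat * pool / mw = 200
#' fba(ec, objective("custom_linear", target = "EX_p"))$objective_value
#' @export
build_ec_model <- function(gem, enzymes, pool_capacity,
                           isozyme_policy = c("parallel", "fastest")) {
  isozyme_policy <- match.arg(isozyme_policy)
  stopifnot(inherits(gem, "stoich_model"))
  if (!is.numeric(pool_capacity) || pool_capacity <= 0) {
    abort_validation("pool_capacity must be > 0")
  }
  enzymes <- tibble::as_tibble(enzymes)
  need <- c("enzyme_id", "reaction_id", "kcat_per_h", "mw_g_per_mmol")
  if (!all(need %in% names(enzymes))) {
    abort_validation(paste0("enzyme table needs columns: ",
                            paste(need, collapse = ", ")))
  }
  if (nrow(enzymes) > 0) {
    if (any(enzymes$kcat_per_h <= 0)) abort_validation("kcat must be > 0")
    if (any(enzymes$mw_g_per_mmol <= 0)) abort_validation("mw must be > 0")
    bad <- setdiff(enzymes$reaction_id, gem$reactions$id)
    if (length(bad)) {
      abort_validation(paste0("enzyme table references unknown reaction: ",
                              bad[1]))
    }
    mw_tab <- dplyr::distinct(enzymes, .data$enzyme_id, .data$mw_g_per_mmol)
    if (anyDuplicated(mw_tab$enzyme_id)) {
      abort_validation("inconsistent molecular weight for an enzyme_id")
    }
    if (anyDuplicated(enzymes[, c("enzyme_id", "reaction_id")])) {
      abort_validation("duplicate (enzyme_id, reaction_id) pair")
    }
  }

  net <- gem
  catalyzed <- unique(enzymes$reaction_id)

  # isozyme policy
  if (isozyme_policy == "fastest" && nrow(enzymes) > 0) {
    enzymes <- enzymes |>
      dplyr::group_by(.data$reaction_id) |>
      dplyr::arrange(dplyr::desc(.data$kcat_per_h), .data$enzyme_id,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }

  rxns <- net$reactions
  split_map <- tibble::tibble(orig = character(), part = character(),
                              sign = numeric())
  new_rows <- list(); kc_rows <- list()
  for (j in seq_len(nrow(rxns))) {
    rid <- rxns$id[j]
    ez <- enzymes[enzymes$reaction_id == rid, , drop = FALSE]
    if (nrow(ez) == 0) {
      new_rows[[length(new_rows) + 1L]] <- rxns[j, ]
      next
    }
    reversible <- rxns$lb[j] < 0 && rxns$ub[j] > 0
    dirs <- if (reversible) c("fwd", "rev") else "one"
    arms <- if (nrow(ez) > 1) seq_len(nrow(ez)) else 0L
    ez <- ez[order(ez$enzyme_id), , drop = FALSE]
    for (d in dirs) {
      for (a in arms) {
        pid <- rid
        if (d != "one") pid <- paste0(pid, "__", d)
        if (a > 0) pid <- paste0(pid, "__iso", a)
        st <- rxns$stoichiometry[[j]]
        sgn <- 1
        lb <- max(rxns$lb[j], 0); ub <- rxns$ub[j]
        if (d == "rev") {
          st <- -st; sgn <- -1
          lb <- 0; ub <- -rxns$lb[j]
        }
        row <- tibble::tibble(id = pid, lb = lb, ub = ub,
                              kind = rxns$kind[j],
                              stoichiometry = list(st))
        new_rows[[length(new_rows) + 1L]] <- row
        split_map <- dplyr::bind_rows(
          split_map, tibble::tibble(orig = rid, part = pid, sign = sgn))
        ei <- if (a > 0) a else 1L
        kc_rows[[length(kc_rows) + 1L]] <- tibble::tibble(
          enzyme_id = ez$enzyme_id[ei], reaction_id = pid,
          kcat = ez$kcat_per_h[ei])
      }
    }
    # parallel arms must share the original capacity window: with several
    # arms each keeps the full [lb, ub]; lower bounds > 0 on a multi-arm
    # reaction would over-constrain, keep them on the first arm only
    if (length(arms) > 1 && rxns$lb[j] > 0) {
      k <- length(new_rows) - length(arms) * length(dirs) + 1L
      for (z in (k + 1L):length(new_rows)) new_rows[[z]]$lb <- 0
    }
  }
  rxns2 <- dplyr::bind_rows(new_rows)
  kcats <- if (length(kc_rows)) dplyr::bind_rows(kc_rows) else
    tibble::tibble(enzyme_id = character(), reaction_id = character(),
                   kcat = numeric())

  enz_tab <- if (nrow(enzymes) > 0) {
    enzymes |>
      dplyr::distinct(.data$enzyme_id, mw = .data$mw_g_per_mmol) |>
      dplyr::arrange(.data$enzyme_id)
  } else {
    tibble::tibble(enzyme_id = character(), mw = numeric())
  }

  # enzyme pseudo-metabolites and usage reactions
  mets2 <- net$metabolites
  usage_ids <- character(0)
  if (nrow(enz_tab) > 0) {
    pseu <- tibble::tibble(
      id = paste0("prot_", enz_tab$enzyme_id),
      name = paste0("enzyme ", enz_tab$enzyme_id),
      formula = "", compartment = "c", is_boundary = FALSE)
    pool <- tibble::tibble(id = .pool_met, name = "protein pool",
                           formula = "", compartment = "c",
                           is_boundary = FALSE)
    mets2 <- dplyr::bind_rows(mets2, pseu, pool)
    # couple catalyzed reactions to enzyme pseudo-metabolites
    for (i in seq_len(nrow(kcats))) {
      jj <- match(kcats$reaction_id[i], rxns2$id)
      st <- rxns2$stoichiometry[[jj]]
      st[paste0("prot_", kcats$enzyme_id[i])] <- -1 / kcats$kcat[i]
      rxns2$stoichiometry[[jj]] <- st
    }
    usage_ids <- paste0("usage_", enz_tab$enzyme_id)
    usage <- tibble::tibble(
      id = usage_ids, lb = 0, ub = Inf, kind = "enzyme_usage",
      stoichiometry = lapply(seq_len(nrow(enz_tab)), function(i) {
        st <- c(-enz_tab$mw[i], 1)
        names(st) <- c(.pool_met, paste0("prot_", enz_tab$enzyme_id[i]))
        st
      }))
    pool_ex <- tibble::tibble(
      id = "pool_exchange", lb = 0, ub = pool_capacity,
      kind = "pool_exchange",
      stoichiometry = list(c(prot_pool = 1)))
    rxns2 <- dplyr::bind_rows(rxns2, usage, pool_ex)
  }

  network <- structure(
    list(metabolites = mets2, reactions = rxns2,
         biomass_id = net$biomass_id,
         objective_default = net$objective_default),
    class = "stoich_model")
  validate_model(network)
  structure(
    list(network = network, enzymes = enz_tab, kcats = kcats,
         enzyme_usage_ids = usage_ids,
         pool_exchange_id = if (nrow(enz_tab) > 0) "pool_exchange" else NA,
         pool_capacity = pool_capacity,
         split_map = split_map),
    class = "ec_model")
}

#' Check elemental mass balance of internal reactions
#'
#' Sums element counts over each internal (non-exchange, non-biomass,
#' non-pseudo) reaction. Reactions touching a metabolite without a formula
#' are skipped with a warning and listed in the `skipped` attribute.
#'
#' @param model A `stoich_model` or `ec_model`.
#' @param elements Elements to check; `NULL` checks every element that
#'   occurs in the formulas.
#' @return Tibble `reaction_id`, `element`, `residual` of the imbalanced
#'   internal reactions (empty when balanced), with attribute `skipped`.
#' @export
check_mass_balance <- function(model, elements = NULL) {
  net <- if (inherits(model, "ec_model")) model$network else model
  counts <- lapply(net$metabolites$formula, function(f) {
    tryCatch(parse_formula(f), error = function(e) {
      abort_validation(conditionMessage(e))
    })
  })
  names(counts) <- net$metabolites$id
  has_formula <- vapply(counts, length, 1L) > 0
  internal <- net$reactions$kind == "metabolic"
  out <- list(); skipped <- character(0)
  for (j in which(internal)) {
    st <- net$reactions$stoichiometry[[j]]
    # enzyme-coupling pseudo-metabolites never carry formulas; ignore them
    st <- st[!grepl("^prot_", names(st))]
    if (!all(has_formula[names(st)])) {
      skipped <- c(skipped, net$reactions$id[j])
      next
    }
    bal <- numeric(0)
    for (met in names(st)) {
      cm <- counts[[met]]
      for (el in names(cm)) {
        bal[el] <- (if (el %in% names(bal)) bal[[el]] else 0) +
          st[[met]] * cm[[el]]
      }
    }
    if (!is.null(elements)) bal <- bal[names(bal) %in% elements]
    bad <- which(abs(bal) > 1e-9)
    for (k in bad) {
      out[[length(out) + 1L]] <- tibble::tibble(
        reaction_id = net$reactions$id[j], element = names(bal)[k],
        residual = bal[[k]])
    }
  }
  if (length(skipped)) {
    warning(length(skipped),
            " reaction(s) skipped (formula-less metabolites): ",
            paste(utils::head(skipped, 3), collapse = ", "),
            if (length(skipped) > 3) ", ..." else "")
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(reaction_id = character(), element = character(),
                   residual = numeric())
  attr(res, "skipped") <- skipped
  res
}

#' Collapse split/arm fluxes back onto original reaction ids
#'
#' Sums `__fwd`/`__rev` pairs (rev negated) and parallel isozyme arms so
#' that fluxes of an enzyme-constrained model can be reported on the
#' reactions of the base model.
#'
#' @param model An `ec_model`.
#' @param fluxes Named flux vector over the augmented network.
#' @return Named numeric vector over original reaction ids (pseudo
#'   reactions dropped).
#' @export
collapse_fluxes <- function(model, fluxes) {
  stopifnot(inherits(model, "ec_model"))
  sm <- model$split_map
  out <- numeric(0)
  plain <- setdiff(
    model$network$reactions$id[
      !model$network$reactions$kind %in% c("enzyme_usage", "pool_exchange")],
    sm$part)
  out[plain] <- fluxes[plain]
  if (nrow(sm)) {
    agg <- vapply(split(seq_len(nrow(sm)), sm$orig), function(ii) {
      sum(sm$sign[ii] * fluxes[sm$part[ii]])
    }, 1)
    out[names(agg)] <- agg
  }
  out
}
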