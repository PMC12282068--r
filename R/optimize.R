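## Static optimization on enzyme-constrained models.
##
## Everything is assembled as min/max c'v subject to S v = 0 and bounds;
## MORP adds auxiliary columns linearizing the L1 distance on the
## enzyme-usage subvector.

#' Specify an optimization objective
#'
#' @param kind One of `"max_growth"`, `"max_lactate"`, `"max_ngam"`,
#'   `"morp"`, `"min_total_proteome"`, `"custom_linear"`.
#' @param target Reaction id for `max_*`/`custom_linear`. `max_growth`
#'   defaults to the model's biomass reaction; `max_lactate` and
#'   `max_ngam` need the reaction id named explicitly (the
#'   ATP-maintenance reaction id is configuration, never inferred).
#' @param reference For `kind = "morp"`: a [fba()]/[morp()] solution or a
#'   numeric enzyme-usage vector aligned to the model's
#'   `enzyme_usage_ids`.
#' @return An `objective_spec`.
#' @export
objective <- function(kind = c("max_growth", "max_lactate", "max_ngam",
                               "morp", "min_total_proteome",
                               "custom_linear"),
                      target = NULL, reference = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("max_lactate", "max_ngam", "custom_linear") &&
      is.null(target)) {
    abort_config(paste0("objective '", kind, "' needs a target reaction id"))
  }
  # a morp objective may be built without a reference: inside a phase
  # schedule the rolling reference is attached by the simulator, and
  # morp()/dfba_step() reject a missing reference at solve time
  structure(list(kind = kind, target = target, reference = reference),
            class = "objective_spec")
}

# usage vector out of a reference (solution or numeric), checked against m
.usage_reference <- function(model, reference) {
  m <- length(model$enzyme_usage_ids)
  if (inherits(reference, "flux_solution")) {
    reference <- reference$enzyme_usage
  }
  if (!is.numeric(reference) || length(reference) != m) {
    abort_validation(paste0("reference must have length ", m,
                            " (one entry per enzyme-usage reaction)"))
  }
  if (!is.null(names(reference)) &&
      !identical(names(reference), model$enzyme_usage_ids)) {
    if (!setequal(names(reference), model$enzyme_usage_ids)) {
      abort_validation("reference names do not match enzyme_usage_ids")
    }
    reference <- reference[model$enzyme_usage_ids]
  }
  unname(reference)
}

.lp_parts <- function(model) {
  net <- if (inherits(model, "ec_model")) model$network else model
  list(S = stoich_matrix(net), lb = net$reactions$lb, ub = net$reactions$ub,
       ids = net$reactions$id)
}

.flux_solution <- function(model, x, objective_value, status, kind) {
  parts <- .lp_parts(model)
  fx <- stats::setNames(if (status == "optimal") x[seq_along(parts$ids)]
                        else rep(NA_real_, length(parts$ids)), parts$ids)
  usage <- if (inherits(model, "ec_model") &&
               length(model$enzyme_usage_ids)) {
    fx[model$enzyme_usage_ids]
  } else {
    stats::setNames(numeric(0), character(0))
  }
  structure(list(fluxes = fx, enzyme_usage = usage,
                 objective_value = objective_value, status = status,
                 objective_kind = kind),
            class = "flux_solution")
}

#' Flux balance analysis
#'
#' Maximizes the target reaction flux subject to `S v = 0` and bounds.
#' Ties among alternate optima are broken (by default) by a second
#' lexicographic stage that fixes the optimal objective and minimizes
#' total enzyme usage, making the solution a deterministic reference
#' for [morp()].
#'
#' @param model An `ec_model` (a plain `stoich_model` also works; the
#'   tie-break stage is then skipped).
#' @param objective An [objective()] of kind `max_*` or `custom_linear`;
#'   default maximizes growth.
#' @param tie_break `"min_usage"` (default) or `"none"`.
#' @return A `flux_solution` with fields `fluxes`, `enzyme_usage`,
#'   `objective_value`, `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`).
#' @export
fba <- function(model, objective = NULL, tie_break = c("min_usage", "none")) {
  tie_break <- match.arg(tie_break)
  net <- if (inherits(model, "ec_model")) model$network else model
  if (is.null(objective)) {
    objective <- objective("max_growth")
  }
  stopifnot(inherits(objective, "objective_spec"))
  if (!objective$kind %in% c("max_growth", "max_lactate", "max_ngam",
                             "custom_linear")) {
    abort_config("fba() handles max_* / custom_linear objectives; use morp() or min_total_proteome()")
  }
  target <- objective$target
  if (objective$kind == "max_growth" && is.null(target)) {
    target <- net$biomass_id
  }
  parts <- .lp_parts(model)
  jt <- match(target, parts$ids)
  if (is.na(jt)) abort_validation(paste0("unknown objective reaction: ", target))
  cc <- numeric(length(parts$ids)); cc[jt] <- 1
  res <- lp_solve(cc, parts$S, rep(0, nrow(parts$S)), parts$lb, parts$ub,
                  maximize = TRUE)
  if (res$status != "optimal") {
    return(.flux_solution(model, NULL, NA_real_, res$status, objective$kind))
  }
  x <- res$x; obj <- res$objval
  if (tie_break == "min_usage" && inherits(model, "ec_model") &&
      length(model$enzyme_usage_ids)) {
    lb2 <- parts$lb; ub2 <- parts$ub
    lb2[jt] <- obj - 1e-9 * max(1, abs(obj)); ub2[jt] <- parts$ub[jt]
    cc2 <- numeric(length(parts$ids))
    cc2[match(model$enzyme_usage_ids, parts$ids)] <- 1
    res2 <- lp_solve(cc2, parts$S, rep(0, nrow(parts$S)), lb2, ub2)
    if (res2$status == "optimal") x <- res2$x
  }
  .flux_solution(model, x, obj, "optimal", objective$kind)
}

#' Minimal proteome reallocation (MORP)
#'
#' Finds the flux distribution minimizing the L1 distance
#' `sum_i |v_enzyme,i - v_enzyme,i,ref|` between the enzyme-usage fluxes
#' and a reference condition, subject to `S v = 0` and the current
#' bounds. The absolute values are linearized exactly; two equivalent
#' formulations are available (they agree to solver tolerance and are
#' cross-checked in the test suite).
#'
#' @param model An `ec_model` with at least one enzyme-usage reaction.
#' @param reference A `flux_solution` from the reference condition or a
#'   numeric usage vector aligned to `enzyme_usage_ids`.
#' @param linearization `"aux"` (default; one auxiliary distance variable
#'   `d_i >= +-(u_i - ref_i)` per enzyme) or `"split"`
#'   (`u_i = ref_i + p_i - q_i`, `p, q >= 0`).
#' @return A `flux_solution`; `objective_value` is the minimal L1
#'   distance (mmol/gDW/h).
#' @export
morp <- function(model, reference, linearization = c("aux", "split")) {
  linearization <- match.arg(linearization)
  stopifnot(inherits(model, "ec_model"))
  m <- length(model$enzyme_usage_ids)
  if (m == 0) abort_validation("model has no enzyme-usage reactions")
  ref <- .usage_reference(model, reference)
  parts <- .lp_parts(model)
  n <- length(parts$ids)
  iu <- match(model$enzyme_usage_ids, parts$ids)
  nmet <- nrow(parts$S)
  if (linearization == "aux") {
    # columns: v (n), d (m), s1 (m), s2 (m)
    # rows:    S v = 0 ;  d - u - s1 = -ref ;  d + u - s2 = ref
    ntot <- n + 3 * m
    A <- matrix(0, nmet + 2 * m, ntot)
    A[seq_len(nmet), seq_len(n)] <- parts$S
    for (i in seq_len(m)) {
      r1 <- nmet + i; r2 <- nmet + m + i
      A[r1, n + i] <- 1; A[r1, iu[i]] <- -1; A[r1, n + m + i] <- -1
      A[r2, n + i] <- 1; A[r2, iu[i]] <- 1; A[r2, n + 2 * m + i] <- -1
    }
    rhs <- c(rep(0, nmet), -ref, ref)
    lb <- c(parts$lb, rep(0, 3 * m))
    ub <- c(parts$ub, rep(Inf, 3 * m))
    cc <- c(rep(0, n), rep(1, m), rep(0, 2 * m))
  } else {
    # columns: v (n), p (m), q (m);  rows: S v = 0 ; u - p + q = ref
    ntot <- n + 2 * m
    A <- matrix(0, nmet + m, ntot)
    A[seq_len(nmet), seq_len(n)] <- parts$S
    for (i in seq_len(m)) {
      A[nmet + i, iu[i]] <- 1
      A[nmet + i, n + i] <- -1
      A[nmet + i, n + m + i] <- 1
    }
    rhs <- c(rep(0, nmet), ref)
    lb <- c(parts$lb, rep(0, 2 * m))
    ub <- c(parts$ub, rep(Inf, 2 * m))
    cc <- c(rep(0, n), rep(1, 2 * m))
  }
  res <- lp_solve(cc, A, rhs, lb, ub)
  if (res$status != "optimal") {
    return(.flux_solution(model, NULL, NA_real_, res$status, "morp"))
  }
  sol <- .flux_solution(model, res$x[seq_len(n)],
                        max(res$objval, 0), "optimal", "morp")
  sol
}

#' Minimize total proteome usage under measured exchange bounds
#'
#' Applies measurement-derived bounds to exchange reactions and minimizes
#' the protein-pool exchange flux, estimating the most efficient enzyme
#' usage compatible with the observed extracellular state.
#'
#' @param model An `ec_model`.
#' @param exchange_bounds Tibble with columns `reaction_id`, `lb`, `ub`
#'   (mmol/gDW/h); each id must be an exchange reaction. `NULL` applies
#'   no extra bounds.
#' @return A `flux_solution`; `objective_value` is the pool draw (g/gDW).
#' @export
min_total_proteome <- function(model, exchange_bounds = NULL) {
  stopifnot(inherits(model, "ec_model"))
  if (is.na(model$pool_exchange_id)) {
    abort_validation("model has no protein pool (enzyme table was empty)")
  }
  if (!is.null(exchange_bounds)) {
    exchange_bounds <- tibble::as_tibble(exchange_bounds)
    kinds <- model$network$reactions$kind[
      match(exchange_bounds$reaction_id, model$network$reactions$id)]
    if (anyNA(kinds) || any(kinds != "exchange")) {
      abort_validation("exchange_bounds must reference exchange reactions only")
    }
    model <- set_flux_bounds(model, exchange_bounds$reaction_id,
                             exchange_bounds$lb, exchange_bounds$ub)
  }
  parts <- .lp_parts(model)
  cc <- numeric(length(parts$ids))
  cc[match(model$pool_exchange_id, parts$ids)] <- 1
  res <- lp_solve(cc, parts$S, rep(0, nrow(parts$S)), parts$lb, parts$ub)
  .flux_solution(model,
                 if (res$status == "optimal") res$x else NULL,
                 if (res$status == "optimal") res$objval else NA_real_,
                 res$status, "min_total_proteome")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux under the model's constraints.
#'
#' @param model A `stoich_model` or `ec_model`.
#' @param reaction_ids Reactions to scan; default all.
#' @return Tibble `reaction_id`, `min`, `max`; attribute `status` is
#'   `"infeasible"` (with all-NA ranges) when the model is infeasible.
#' @export
fva <- function(model, reaction_ids = NULL) {
  parts <- .lp_parts(model)
  if (is.null(reaction_ids)) reaction_ids <- parts$ids
  idx <- match(reaction_ids, parts$ids)
  if (anyNA(idx)) {
    abort_validation(paste0("unknown reaction: ",
                            reaction_ids[which(is.na(idx))[1]]))
  }
  lo <- hi <- rep(NA_real_, length(idx))
  status <- "optimal"
  for (k in seq_along(idx)) {
    cc <- numeric(length(parts$ids)); cc[idx[k]] <- 1
    rmin <- lp_solve(cc, parts$S, rep(0, nrow(parts$S)), parts$lb, parts$ub)
    if (rmin$status == "infeasible") { status <- "infeasible"; break }
    rmax <- lp_solve(cc, parts$S, rep(0, nrow(parts$S)), parts$lb, parts$ub,
                     maximize = TRUE)
    lo[k] <- if (rmin$status == "optimal") rmin$objval else -Inf
    hi[k] <- if (rmax$status == "optimal") rmax$objval else Inf
  }
  out <- tibble::tibble(reaction_id = reaction_ids, min = lo, max = hi)
  attr(out, "status") <- status
  out
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (x$status == "optimal") {
    cat("; objective (", x$objective_kind, "): ",
        format(x$objective_value, digits = 6), sep = "")
  }
  cat("\n  ", length(x$fluxes), " fluxes, ", length(x$enzyme_usage),
      " enzyme-usage entries\n", sep = "")
  invisible(x)
}
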