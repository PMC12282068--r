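## Post-processing of simulated trajectories and flux solutions:
## product yields per phase, relative fluxes normalized to substrate
## uptake (with disaccharide-to-hexose conversion), enzyme-usage fold
## changes and RMSE scoring against measured concentration series.

# concentration of a species at time t (linear interpolation)
.conc_at <- function(traj, species, t) {
  if (!species %in% names(traj$states)) {
    abort_validation(paste0("species not tracked: ", species))
  }
  stats::approx(traj$states$t, traj$states[[species]], xout = t,
                rule = 2)$y
}

#' Product yield over a time window
#'
#' `(C_product(t1) - C_product(t0)) / (C_substrate(t0) -
#' C_substrate(t1))`, both in g/L, i.e. grams of product formed per
#' gram of substrate consumed.
#'
#' @param traj A `dfba_trajectory`.
#' @param product,substrate Tracked species ids.
#' @param t0,t1 Window (h), `t0 < t1`.
#' @return Yield (g/g).
#' @export
compute_yield <- function(traj, product, substrate, t0, t1) {
  if (t0 >= t1) abort_validation("t0 must be < t1")
  consumed <- .conc_at(traj, substrate, t0) - .conc_at(traj, substrate, t1)
  if (consumed <= 1e-12) {
    abort_validation(paste0(
      "no ", substrate, " consumed in [", t0, ", ", t1, "] h; pick a ",
      "window where the substrate is actually drawn down"))
  }
  (.conc_at(traj, product, t1) - .conc_at(traj, product, t0)) / consumed
}

#' Per-phase yield report for a trajectory
#'
#' Convenience wrapper over [compute_yield()]: one row per phase x
#' product, with the phase's dominant consumed substrate supplied by
#' the caller.
#'
#' @param traj A `dfba_trajectory`.
#' @param products Tracked product species ids.
#' @param substrates Named character: phase label -> substrate id, e.g.
#'   `c("1" = "glc_e", "2" = "tre_e")`.
#' @return Tibble `phase`, `substrate`, `product`, `yield`.
#' @export
yield_report <- function(traj, products, substrates) {
  out <- list()
  for (ph in names(substrates)) {
    idx <- which(traj$phase_labels == as.integer(ph))
    if (length(idx) == 0) next
    t0 <- traj$states$t[idx[1]]
    t1 <- traj$states$t[idx[length(idx)] + 1]
    for (pr in products) {
      y <- tryCatch(compute_yield(traj, pr, substrates[[ph]], t0, t1),
                    morp_validation_error = function(e) NA_real_)
      out[[length(out) + 1L]] <- tibble::tibble(
        phase = as.integer(ph), substrate = substrates[[ph]],
        product = pr, yield = y)
    }
  }
  dplyr::bind_rows(out)
}

#' Relative fluxes normalized to substrate uptake
#'
#' Expresses each reaction's absolute flux as a percentage of the
#' glucose-equivalent substrate uptake. Uptake through a disaccharide
#' (trehalose) reaction is converted to hexose units: one unit of
#' trehalose uptake counts as two units of glucose uptake.
#'
#' @param sol A `flux_solution` (or any named flux vector).
#' @param substrate_uptake_id Uptake (exchange) reaction id(s); their
#'   absolute fluxes, after conversion, form the denominator.
#' @param trehalose_ids Subset of uptake ids counted twice.
#' @param reaction_ids Reactions to report; default all in `sol`.
#' @return Tibble `reaction_id`, `relative_flux` (percent).
#' @export
relative_fluxes <- function(sol, substrate_uptake_id,
                            trehalose_ids = character(0),
                            reaction_ids = NULL) {
  fl <- if (inherits(sol, "flux_solution")) sol$fluxes else sol
  miss <- setdiff(substrate_uptake_id, names(fl))
  if (length(miss)) {
    abort_validation(paste0("unknown uptake reaction: ", miss[1]))
  }
  mult <- ifelse(substrate_uptake_id %in% trehalose_ids, 2, 1)
  denom <- sum(abs(fl[substrate_uptake_id]) * mult)
  if (denom <= 1e-12) {
    abort_validation("substrate uptake flux is zero; relative fluxes undefined")
  }
  if (is.null(reaction_ids)) reaction_ids <- names(fl)
  tibble::tibble(reaction_id = reaction_ids,
                 relative_flux = 100 * abs(unname(fl[reaction_ids])) / denom)
}

#' Log2 fold change of enzyme usage between two solutions
#'
#' `log2((u_i + pseudo) / (u_ref,i + pseudo))` per enzyme-usage
#' reaction; the pseudo-count handles zero usage.
#'
#' @param sol,ref `flux_solution`s over the same model (aligned
#'   `enzyme_usage` vectors).
#' @param pseudo Small positive usage floor (default 1e-9 mmol/gDW/h).
#' @return Tibble `enzyme_usage_id`, `log2fc`.
#' @export
log2fc_enzyme_usage <- function(sol, ref, pseudo = 1e-9) {
  u <- sol$enzyme_usage; ur <- ref$enzyme_usage
  if (length(u) != length(ur) || !identical(names(u), names(ur))) {
    abort_validation("enzyme_usage vectors are not aligned")
  }
  if (any(u < -1e-9) || any(ur < -1e-9)) {
    abort_validation("negative enzyme usage")
  }
  u <- pmax(u, 0); ur <- pmax(ur, 0)
  tibble::tibble(enzyme_usage_id = names(u),
                 log2fc = log2((unname(u) + pseudo) /
                                 (unname(ur) + pseudo)))
}

#' Root mean square error between predicted and measured concentrations
#'
#' Interpolates the prediction linearly onto the measurement time grid
#' and pools squared deviations over all listed products and time
#' points (`mode = "pooled"`, the default) or averages per-product
#' RMSEs (`mode = "per_product"`).
#'
#' @param predicted A `dfba_trajectory` or a tibble `time`, `species`,
#'   `conc`.
#' @param measured Tibble `time`, `species`, `conc` (e.g. from
#'   [make_synthetic_measurements()]).
#' @param products Species ids to score.
#' @param mode Pooling mode.
#' @return RMSE (g/L).
#' @export
rmse_products <- function(predicted, measured,
                          products = unique(measured$species),
                          mode = c("pooled", "per_product")) {
  mode <- match.arg(mode)
  if (length(products) == 0) abort_validation("products must be non-empty")
  if (inherits(predicted, "dfba_trajectory")) {
    predicted <- tidyr::pivot_longer(predicted$states, -"t",
                                     names_to = "species",
                                     values_to = "conc") |>
      dplyr::rename(time = "t")
  }
  per <- vapply(products, function(sp) {
    pr <- predicted[predicted$species == sp, ]
    ms <- measured[measured$species == sp, ]
    if (nrow(pr) < 2 || nrow(ms) == 0) {
      abort_validation(paste0("no data to score for species: ", sp))
    }
    if (min(ms$time) > max(pr$time) || max(ms$time) < min(pr$time)) {
      abort_validation(paste0("prediction and measurements cover ",
                              "disjoint time ranges for ", sp))
    }
    keep <- ms$time >= min(pr$time) - 1e-9 & ms$time <= max(pr$time) + 1e-9
    ms <- ms[keep, ]
    hat <- stats::approx(pr$time, pr$conc, xout = ms$time)$y
    c(sse = sum((hat - ms$conc)^2), n = nrow(ms))
  }, c(sse = 1, n = 1))
  if (mode == "pooled") {
    sqrt(sum(per["sse", ]) / sum(per["n", ]))
  } else {
    mean(sqrt(per["sse", ] / per["n", ]))
  }
}
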