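## Dynamic FBA by the static optimization approach: each interval solves a
## static LP whose sugar-uptake bounds come from Monod kinetics evaluated
## at the previous interval's concentrations, then biomass and tracked
## concentrations are advanced by an explicit Euler step. dMORP is the
## schedule whose interval objective is MORP with the previous interval's
## enzyme usage as reference.

#' Monod uptake rate
#'
#' `v = v_s_max * s / (km + s)` (mmol/gDW/h), the maximum sugar uptake
#' rate at extracellular concentration `s`.
#'
#' @param v_s_max Maximum uptake rate (mmol/gDW/h).
#' @param km Saturation constant (g/L).
#' @param s Substrate concentration (g/L); vectorized.
#' @return Uptake rate(s), monotone non-decreasing in `s`.
#' @examples
#' monod_uptake(10, 0.5, 4.5)  # 9
#' @export
monod_uptake <- function(v_s_max, km, s) {
  if (any(c(v_s_max, km, s) < 0)) {
    abort_validation("monod_uptake() arguments must be non-negative")
  }
  v_s_max * s / (km + s)
}

#' Monod kinetics table
#'
#' One row per substrate whose uptake is driven dynamically.
#'
#' @param substrate Tracked species id (must appear in the species map).
#' @param uptake_reaction Exchange reaction id of the substrate.
#' @param v_max Maximum uptake rate (mmol/gDW/h), > 0.
#' @param km Saturation constant (g/L), > 0.
#' @return Tibble of class usable by [simulate_dfba()].
#' @export
monod_kinetics <- function(substrate, uptake_reaction, v_max, km) {
  if (any(v_max <= 0) || any(km <= 0)) {
    abort_validation("v_max and km must be > 0")
  }
  tibble::tibble(substrate = substrate, uptake_reaction = uptake_reaction,
                 v_max = v_max, km = km)
}

#' Culture state
#'
#' @param t Time (h).
#' @param biomass Biomass density (gDW/L), >= 0.
#' @param concentrations Named numeric vector of species concentrations
#'   (g/L), all >= 0.
#' @return A `culture_state`.
#' @export
culture_state <- function(t = 0, biomass, concentrations) {
  if (biomass < 0 || any(concentrations < 0)) {
    abort_validation("biomass and concentrations must be >= 0")
  }
  structure(list(t = t, biomass = biomass,
                 concentrations = concentrations),
            class = "culture_state")
}

#' Simulation phase
#'
#' A phase pairs an interval objective with a switch condition and
#' optional phase-specific flux bounds (e.g. closing a transporter to
#' represent catabolite repression).
#'
#' @param objective An [objective()]; for kind `"morp"` the rolling
#'   reference is managed by [simulate_dfba()] (each interval uses the
#'   previous interval's enzyme usage; the first MORP interval uses the
#'   last solution of the preceding phase).
#' @param until_species,until_threshold Switch to the next phase once
#'   this species' concentration falls to `until_threshold` (g/L;
#'   default 0.01).
#' @param until_time Alternative switch at a fixed time (h).
#' @param bounds Optional tibble `reaction_id`, `lb`, `ub` applied while
#'   the phase is active.
#' @return A `phase_spec`.
#' @export
phase <- function(objective, until_species = NULL, until_threshold = 0.01,
                  until_time = Inf, bounds = NULL) {
  stopifnot(inherits(objective, "objective_spec"))
  if (until_threshold < 0) abort_validation("until_threshold must be >= 0")
  structure(list(objective = objective, until_species = until_species,
                 until_threshold = until_threshold,
                 until_time = until_time, bounds = bounds),
            class = "phase_spec")
}

# solve one interval LP after imposing Monod uptake bounds; returns the
# solution plus the advanced state
.dfba_interval <- function(model, state, kinetics, species, objective,
                           dt, uptake_bound, morp_ref,
                           extra_bounds = NULL) {
  X <- state$biomass
  for (i in seq_len(nrow(kinetics))) {
    sp <- kinetics$substrate[i]
    conc <- state$concentrations[[sp]]
    mw <- species$mw[match(sp, species$species)]
    v <- monod_uptake(kinetics$v_max[i], kinetics$km[i], conc)
    # availability cap: an Euler step may not consume more than is there
    if (X > 0 && dt > 0) v <- min(v, conc / (mw * X * dt))
    lb <- -v
    ub <- if (uptake_bound == "equality") -v else 0
    model <- set_flux_bounds(model, kinetics$uptake_reaction[i], lb, ub)
  }
  if (!is.null(extra_bounds)) {
    # phase bounds (e.g. catabolite repression) override kinetic bounds
    model <- set_flux_bounds(model, extra_bounds$reaction_id,
                             extra_bounds$lb, extra_bounds$ub)
  }
  sol <- switch(objective$kind,
    morp = morp(model, morp_ref),
    min_total_proteome = min_total_proteome(model),
    fba(model, objective))
  if (sol$status != "optimal") {
    abort_infeasible(
      paste0("interval LP ", sol$status, " at t = ", state$t, " h"),
      data = list(t = state$t, status = sol$status))
  }
  net <- if (inherits(model, "ec_model")) model$network else model
  mu <- unname(sol$fluxes[[net$biomass_id]])
  conc2 <- state$concentrations
  for (i in seq_len(nrow(species))) {
    ex <- species$exchange_id[i]
    dC <- unname(sol$fluxes[[ex]]) * species$mw[i] * X * dt
    cv <- conc2[[species$species[i]]] + dC
    if (cv < -1e-6) {
      rlang::abort(paste0("concentration of ", species$species[i],
                          " fell below zero at t = ", state$t + dt,
                          " h; use a smaller dt"),
                   class = "morp_step_error")
    }
    conc2[[species$species[i]]] <- max(cv, 0)
  }
  st2 <- culture_state(t = state$t + dt, biomass = X * (1 + mu * dt),
                       concentrations = conc2)
  list(solution = sol, state = st2)
}

#' Advance one dFBA interval
#'
#' Sets each substrate's uptake bound from [monod_uptake()] evaluated at
#' the current state, solves the interval LP, and advances biomass
#' (`X <- X * (1 + mu * dt)`) and tracked concentrations
#' (`C <- C + v_exchange * mw * X * dt`).
#'
#' @param model An `ec_model`.
#' @param state A [culture_state()].
#' @param kinetics A [monod_kinetics()] table.
#' @param species Species map: tibble `species`, `exchange_id`, `mw`
#'   (g/mmol) for every tracked species.
#' @param objective An [objective()]; for kind `"morp"` the reference
#'   must be carried in the objective.
#' @param dt Step (h), > 0.
#' @param uptake_bound `"equality"` (uptake fixed at the Monod value,
#'   the default) or `"upper"` (Monod value as an upper bound only).
#' @return List with `solution` (a `flux_solution`) and `state` (the
#'   advanced `culture_state`).
#' @export
dfba_step <- function(model, state, kinetics, species, objective, dt,
                      uptake_bound = c("equality", "upper")) {
  uptake_bound <- match.arg(uptake_bound)
  if (dt <= 0) abort_validation("dt must be > 0")
  ref <- if (objective$kind == "morp") {
    .usage_reference(model, objective$reference)
  }
  .dfba_interval(model, state, kinetics, species, objective, dt,
                 uptake_bound, ref)
}

#' Simulate a batch culture by dynamic FBA
#'
#' Runs the phases of `schedule` in order, switching when a phase's
#' condition fires, and integrates biomass and tracked extracellular
#' concentrations with an explicit Euler step of width `dt`. Within a
#' MORP phase each interval's reference is the previous interval's
#' enzyme usage (dMORP); the first MORP interval takes the last solution
#' of the preceding phase as reference.
#'
#' @inheritParams dfba_step
#' @param schedule List of [phase()] specs, run in order.
#' @param init Initial [culture_state()].
#' @param t_end End time (h), > 0.
#' @param dt Interval width (h); default 0.1.
#' @param morp_reference Optional explicit reference for a MORP phase
#'   that has no preceding interval.
#' @param measured_bounds Optional tibble `time`, `reaction_id`, `lb`,
#'   `ub`: exchange bounds linearly interpolated to each interval start
#'   and applied before solving.
#' @return A `dfba_trajectory`: `states` (tibble `t`, `biomass`, one
#'   column per species), `solutions` (one `flux_solution` per
#'   interval), `phase_labels` (integer per interval), `dt`, `species`.
#' @export
simulate_dfba <- function(model, schedule, kinetics, species, init,
                          t_end, dt = 0.1,
                          uptake_bound = c("equality", "upper"),
                          morp_reference = NULL,
                          measured_bounds = NULL) {
  uptake_bound <- match.arg(uptake_bound)
  if (t_end <= 0 || dt <= 0) abort_validation("t_end and dt must be > 0")
  if (length(schedule) == 0) abort_validation("schedule must be non-empty")
  if (inherits(schedule, "phase_spec")) schedule <- list(schedule)
  state <- init
  n_steps <- floor(round((t_end - init$t) / dt, 9))
  states <- vector("list", n_steps + 1)
  sols <- vector("list", n_steps)
  phases <- integer(n_steps)
  states[[1]] <- state
  ph <- 1L
  ref <- if (!is.null(morp_reference)) {
    .usage_reference(model, morp_reference)
  }
  for (k in seq_len(n_steps)) {
    # phase switch check at interval start
    while (ph < length(schedule)) {
      p <- schedule[[ph]]
      fired <- (!is.null(p$until_species) &&
                  state$concentrations[[p$until_species]] <=
                    p$until_threshold) ||
        state$t >= p$until_time - 1e-9
      if (fired) ph <- ph + 1L else break
    }
    p <- schedule[[ph]]
    mod_k <- model
    if (!is.null(measured_bounds)) {
      for (rid in unique(measured_bounds$reaction_id)) {
        mb <- measured_bounds[measured_bounds$reaction_id == rid, ]
        lbk <- stats::approx(mb$time, mb$lb, xout = state$t, rule = 2)$y
        ubk <- stats::approx(mb$time, mb$ub, xout = state$t, rule = 2)$y
        mod_k <- set_flux_bounds(mod_k, rid, lbk, ubk)
      }
    }
    obj <- p$objective
    if (obj$kind == "morp") {
      if (is.null(ref) && !is.null(obj$reference)) {
        ref <- .usage_reference(model, obj$reference)
      }
      if (is.null(ref)) {
        abort_config(paste0(
          "MORP phase at t = ", state$t, " h has no reference: provide ",
          "a preceding phase or morp_reference"))
      }
    }
    step <- tryCatch(
      .dfba_interval(mod_k, state, kinetics, species, obj, dt,
                     uptake_bound, ref, extra_bounds = p$bounds),
      morp_infeasible_error = function(e) {
        rlang::abort(paste0(conditionMessage(e), " (phase ", ph, ")"),
                     class = "morp_step_error", parent = e)
      })
    sols[[k]] <- step$solution
    phases[k] <- ph
    state <- step$state
    states[[k + 1]] <- state
    ref <- step$solution$enzyme_usage   # rolling dMORP reference
  }
  if (ph < length(schedule)) {
    warning("schedule completed at t_end with ", length(schedule) - ph,
            " phase switch(es) never fired")
  }
  st_tbl <- dplyr::bind_rows(lapply(states, function(s) {
    tibble::as_tibble(c(list(t = s$t, biomass = s$biomass),
                        as.list(s$concentrations)))
  }))
  structure(list(states = st_tbl, solutions = sols,
                 phase_labels = phases, dt = dt, species = species),
            class = "dfba_trajectory")
}

#' First time a species falls to a threshold
#'
#' @param traj A `dfba_trajectory`.
#' @param species Tracked species id.
#' @param threshold Concentration threshold (g/L).
#' @return Time (h) of the first state at or below the threshold, or
#'   `Inf` when the species never depletes within the trajectory.
#' @export
detect_depletion <- function(traj, species, threshold = 0.01) {
  if (!species %in% names(traj$states)) {
    abort_validation(paste0("species not tracked: ", species))
  }
  hit <- which(traj$states[[species]] <= threshold)
  if (length(hit) == 0) return(Inf)
  traj$states$t[hit[1]]
}

#' @export
print.dfba_trajectory <- function(x, ...) {
  cat("<dfba_trajectory> ", nrow(x$states) - 1, " intervals, dt = ",
      x$dt, " h, ", length(unique(x$phase_labels)), " phase(s)\n", sep = "")
  cat("  species: ", paste(x$species$species, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
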