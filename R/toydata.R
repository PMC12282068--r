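## Synthetic fixture: a lumped central-carbon model of a lactic acid
## bacterium with competing homolactic (EMP glycolysis -> lactate) and
## heterolactic (phosphoketolase -> lactate + acetate/ethanol + CO2)
## routes, glucose and trehalose uptake, an acetoin branch, lumped
## biomass, NGAM and a GECKO enzyme layer. Cofactor stoichiometry is
## lumped (carbon is exactly balanced; ATP/NAD bookkeeping is simplified
## but internally consistent). Default kinetic parameters are calibrated
## so that growth maximization on fast glucose uptake is
## homolactic-dominant while minimal proteome reallocation at the slow
## trehalose-driven flux shifts the flux share onto the phosphoketolase
## branch.

#' Parameters of the synthetic central-carbon model
#'
#' Defaults define the packaged study conditions; see the methods
#' vignette for the calibration rationale.
#'
#' @param kcat,mw Named numeric vectors (1/h and g/mmol) over the lumped
#'   enzymes `glct`, `tret`, `emp`, `ldh`, `pk`, `acka`, `adhp`, `als`.
#' @param pool_capacity Protein pool (g/gDW).
#' @param biomass_g6p,biomass_atp Hexose-phosphate (mmol/gDW) and ATP
#'   (mmol/gDW) demand per unit biomass.
#' @param ngam NGAM floor (mmol ATP/gDW/h).
#' @param glc_vmax,glc_km,tre_vmax,tre_km Monod uptake parameters
#'   (mmol/gDW/h and g/L).
#' @param noise_sd Measurement noise s.d. (g/L) for
#'   [make_synthetic_measurements()].
#' @param seed Base seed for synthetic measurements.
#' @return Parameter list of class `toy_params`.
#' @export
toy_params <- function(kcat = c(glct = 200, tret = 150, emp = 60,
                                ldh = 300, pk = 40, acka = 200,
                                adhp = 150, als = 250),
                       mw = c(glct = 0.05, tret = 0.06, emp = 0.20,
                              ldh = 0.04, pk = 0.02, acka = 0.03,
                              adhp = 0.04, als = 0.05),
                       pool_capacity = 0.024,
                       biomass_g6p = 6.5, biomass_atp = 30,
                       ngam = 1,
                       glc_vmax = 10, glc_km = 0.05,
                       tre_vmax = 1, tre_km = 1,
                       noise_sd = 0.3, seed = 1L) {
  p <- list(kcat = kcat, mw = mw, pool_capacity = pool_capacity,
            biomass_g6p = biomass_g6p, biomass_atp = biomass_atp,
            ngam = ngam, glc_vmax = glc_vmax, glc_km = glc_km,
            tre_vmax = tre_vmax, tre_km = tre_km,
            noise_sd = noise_sd, seed = seed)
  nm <- c("glct", "tret", "emp", "ldh", "pk", "acka", "adhp", "als")
  if (!setequal(names(kcat), nm) || !setequal(names(mw), nm)) {
    abort_validation(paste0("kcat and mw must be named over: ",
                            paste(nm, collapse = ", ")))
  }
  num <- unlist(p[c("kcat", "mw", "pool_capacity", "biomass_g6p",
                    "biomass_atp", "ngam", "glc_vmax", "glc_km",
                    "tre_vmax", "tre_km")])
  if (any(num <= 0)) abort_validation("all kinetic parameters must be > 0")
  if (noise_sd < 0) abort_validation("noise_sd must be >= 0")
  structure(p, class = "toy_params")
}

# molecular weights used for g/L bookkeeping (g/mmol)
.toy_mw <- c(glc_e = 0.18016, tre_e = 0.34230, lac_e = 0.09008,
             ac_e = 0.06005, etoh_e = 0.04607, actn_e = 0.08811,
             co2_e = 0.04401)

#' Build the synthetic enzyme-constrained central-carbon model
#'
#' @param params A [toy_params()] list.
#' @param check Run the calibration self-check (carbon balance of the
#'   internal reactions and the homolactic-to-heterolactic shift);
#'   aborts with a configuration error when the parameter set fails.
#' @return List with `model` (an `ec_model`), `kinetics`
#'   (a [monod_kinetics()] table), `species` (species map for
#'   [simulate_dfba()]) and `params`.
#' @export
make_toy_ccm <- function(params = toy_params(), check = TRUE) {
  stopifnot(inherits(params, "toy_params"))
  mets <- tibble::tibble(
    id = c("glc_e", "tre_e", "lac_e", "ac_e", "etoh_e", "actn_e",
           "co2_e", "g6p", "pyr", "axp", "atp", "adp", "nadh", "nad"),
    formula = c("C6H12O6", "C12H22O11", "C3H6O3", "C2H4O2", "C2H6O",
                "C4H8O2", "CO2", "C6H13O9P", "C3H3O3", "C2H5O5P",
                "X", "X", "XH", "X"),
    compartment = c(rep("e", 7), rep("c", 7)))
  rx <- tibble::tibble(
    id = c("EX_glc", "EX_tre", "EX_lac", "EX_ac", "EX_etoh", "EX_actn",
           "EX_co2",
           "GLCt", "TREt", "EMP", "LDH", "PK", "ACKA", "ADHP", "ALS",
           "BIOMASS", "NGAM"),
    equation = c(
      "glc_e ->", "tre_e ->", "lac_e ->", "ac_e ->", "etoh_e ->",
      "actn_e ->", "co2_e ->",
      "glc_e + atp -> g6p + adp",
      "tre_e + atp -> 2 g6p + adp",
      "g6p + 3 adp + 2 nad -> 2 pyr + 3 atp + 2 nadh",
      "pyr + nadh -> lac_e + nad",
      "g6p + 2 adp + 2 nad -> axp + pyr + co2_e + 2 atp + 2 nadh",
      "axp + adp -> ac_e + atp",
      "axp + 2 nadh -> etoh_e + 2 nad",
      "2 pyr -> actn_e + 2 co2_e",
      paste0(params$biomass_g6p, " g6p + ", params$biomass_atp,
             " atp -> ", params$biomass_atp, " adp"),
      "atp -> adp"),
    lb = c(0, 0, 0, 0, 0, 0, 0,
           0, 0, 0, 0, 0, 0, 0, 0, 0, params$ngam),
    ub = c(0, 0, rep(1000, 5), rep(1000, 9), 1000),
    kind = c(rep("exchange", 7), rep("metabolic", 8), "biomass", "ngam"))
  gem <- stoichiometric_model(mets, rx, biomass_id = "BIOMASS")
  enz_rxn <- c(glct = "GLCt", tret = "TREt", emp = "EMP", ldh = "LDH",
               pk = "PK", acka = "ACKA", adhp = "ADHP", als = "ALS")
  enzymes <- tibble::tibble(
    enzyme_id = paste0("E_", names(enz_rxn)),
    reaction_id = unname(enz_rxn),
    kcat_per_h = unname(params$kcat[names(enz_rxn)]),
    mw_g_per_mmol = unname(params$mw[names(enz_rxn)]))
  model <- build_ec_model(gem, enzymes, params$pool_capacity)
  kinetics <- monod_kinetics(
    substrate = c("glc_e", "tre_e"),
    uptake_reaction = c("EX_glc", "EX_tre"),
    v_max = c(params$glc_vmax, params$tre_vmax),
    km = c(params$glc_km, params$tre_km))
  species <- tibble::tibble(
    species = names(.toy_mw),
    exchange_id = c("EX_glc", "EX_tre", "EX_lac", "EX_ac", "EX_etoh",
                    "EX_actn", "EX_co2"),
    mw = unname(.toy_mw))
  out <- list(model = model, kinetics = kinetics, species = species,
              params = params)
  if (check) .check_toy_calibration(out)
  out
}

# static proxy for the packaged scenario: growth maximization at the
# glucose-phase Monod uptake must be homolactic-dominant, and a MORP
# solve at the trehalose-phase uptake (reference = the glucose-phase
# optimum) must raise the phosphoketolase flux share materially
.check_toy_calibration <- function(toy) {
  bal <- check_mass_balance(toy$model, elements = "C")
  if (nrow(bal) > 0) {
    abort_config(paste0("toy model is not carbon-balanced: ",
                        bal$reaction_id[1]))
  }
  shares <- toy_route_shares(toy)
  if (!(shares$glucose_emp_share > 0.5)) {
    abort_config(paste0(
      "toy calibration failed: glucose-phase growth optimum is not ",
      "homolactic-dominant (EMP share ",
      round(shares$glucose_emp_share, 3), ")"))
  }
  if (!(shares$trehalose_pk_share > shares$glucose_pk_share + 0.2)) {
    abort_config(paste0(
      "toy calibration failed: MORP does not shift flux onto the ",
      "phosphoketolase branch (share ",
      round(shares$glucose_pk_share, 3), " -> ",
      round(shares$trehalose_pk_share, 3), ")"))
  }
  invisible(shares)
}

#' Hexose-flux route shares of the two fermentation modes
#'
#' Solves the glucose-phase growth maximization (uptake at the Monod
#' rate for 20 g/L glucose, trehalose transport closed) and a MORP
#' problem at the trehalose-phase uptake with the glucose-phase optimum
#' as reference, and reports the share of hexose-phosphate flux carried
#' by EMP glycolysis vs the phosphoketolase branch in each.
#'
#' @param toy A [make_toy_ccm()] result.
#' @param glc,tre Concentrations (g/L) at which the two condition LPs
#'   are posed.
#' @return List `glucose_emp_share`, `glucose_pk_share`,
#'   `trehalose_emp_share`, `trehalose_pk_share`, plus the two
#'   `flux_solution`s.
#' @export
toy_route_shares <- function(toy, glc = 20, tre = 20) {
  p <- toy$params
  v_glc <- monod_uptake(p$glc_vmax, p$glc_km, glc)
  m1 <- set_flux_bounds(toy$model, c("EX_glc", "EX_tre"),
                        lb = c(-v_glc, 0), ub = c(-v_glc, 0))
  s1 <- fba(m1, objective("max_growth"))
  if (s1$status != "optimal") abort_config("glucose-phase LP infeasible")
  v_tre <- monod_uptake(p$tre_vmax, p$tre_km, tre)
  m2 <- set_flux_bounds(toy$model, c("EX_glc", "EX_tre"),
                        lb = c(0, -v_tre), ub = c(0, -v_tre))
  s2 <- morp(m2, s1)
  if (s2$status != "optimal") abort_config("trehalose-phase LP infeasible")
  share <- function(sol) {
    emp <- unname(sol$fluxes[["EMP"]]); pk <- unname(sol$fluxes[["PK"]])
    tot <- emp + pk
    if (tot <= 1e-9) c(emp = NA_real_, pk = NA_real_)
    else c(emp = emp / tot, pk = pk / tot)
  }
  a <- share(s1); b <- share(s2)
  list(glucose_emp_share = a[["emp"]], glucose_pk_share = a[["pk"]],
       trehalose_emp_share = b[["emp"]], trehalose_pk_share = b[["pk"]],
       glucose_solution = s1, trehalose_solution = s2)
}

#' Packaged batch-fermentation scenario
#'
#' The study conditions used throughout the tests: 20 g/L glucose plus
#' 20 g/L trehalose, hierarchical utilization (trehalose transport
#' repressed while glucose is present), growth maximization during the
#' glucose phase, then dMORP after glucose depletion. The
#' `co_utilization` variant emulates an evolved strain without
#' catabolite repression: growth maximization on both sugars until
#' trehalose depletes, then dMORP on the remaining glucose.
#'
#' @param params A [toy_params()] list.
#' @param variant `"hierarchical"` (default) or `"co_utilization"`.
#' @param objective_kind Interval objective of the post-depletion phase:
#'   `"morp"` (default), `"max_growth"`, `"max_lactate"` or
#'   `"max_ngam"`.
#' @param t_end,dt Horizon and step (h).
#' @return List ready for [simulate_dfba()]: `model`, `schedule`,
#'   `kinetics`, `species`, `init`, `t_end`, `dt`, plus `toy`.
#' @export
toy_scenario <- function(params = toy_params(),
                         variant = c("hierarchical", "co_utilization"),
                         objective_kind = c("morp", "max_growth",
                                            "max_lactate", "max_ngam"),
                         t_end = 14, dt = 0.1) {
  variant <- match.arg(variant)
  objective_kind <- match.arg(objective_kind)
  toy <- make_toy_ccm(params, check = FALSE)
  obj2 <- switch(objective_kind,
                 morp = objective("morp"),   # rolling dMORP reference
                 max_growth = objective("max_growth"),
                 max_lactate = objective("max_lactate", target = "EX_lac"),
                 max_ngam = objective("max_ngam", target = "NGAM"))
  repression <- tibble::tibble(reaction_id = "EX_tre", lb = 0, ub = 0)
  # the switch threshold sits above the Euler-step consumption per
  # interval (~0.7 g/L at peak biomass) so the dMORP reference is the
  # high-flux late-glucose state, not a collapsing final sliver
  schedule <- if (variant == "hierarchical") {
    list(phase(objective("max_growth"), until_species = "glc_e",
               until_threshold = 1, bounds = repression),
         phase(obj2))
  } else {
    list(phase(objective("max_growth"), until_species = "tre_e",
               until_threshold = 0.5),
         phase(obj2))
  }
  init <- culture_state(
    t = 0, biomass = 0.1,
    concentrations = c(glc_e = 20, tre_e = 20, lac_e = 0, ac_e = 0,
                       etoh_e = 0, actn_e = 0, co2_e = 0))
  list(model = toy$model, schedule = schedule, kinetics = toy$kinetics,
       species = toy$species, init = init, t_end = t_end, dt = dt,
       toy = toy)
}

#' Noisy synthetic measurement series from a trajectory
#'
#' Samples the tracked species of a simulated trajectory at the given
#' times and adds zero-truncated Gaussian noise, emulating measured
#' extracellular concentration data.
#'
#' @param traj A `dfba_trajectory`.
#' @param noise_sd Noise standard deviation (g/L), >= 0.
#' @param seed Integer seed (RNG state is restored afterwards).
#' @param times Sampling times (h); default every hour over the
#'   trajectory span.
#' @return Tibble `time`, `species`, `conc` (class
#'   `measurement_series`).
#' @export
make_synthetic_measurements <- function(traj, noise_sd = 0.3, seed = 1L,
                                        times = NULL) {
  if (noise_sd < 0) abort_validation("noise_sd must be >= 0")
  if (nrow(traj$states) < 2) abort_validation("trajectory is empty")
  if (is.null(times)) {
    times <- seq(min(traj$states$t), max(traj$states$t), by = 1)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  out <- list()
  for (sp in traj$species$species) {
    conc <- stats::approx(traj$states$t, traj$states[[sp]],
                          xout = times, rule = 2)$y
    noisy <- pmax(0, conc + stats::rnorm(length(times), 0, noise_sd))
    out[[sp]] <- tibble::tibble(time = times, species = sp, conc = noisy)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("measurement_series", class(res))
  res
}
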