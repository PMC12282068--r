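# Hand-sized fixture models and independent oracles used across the
# test files. Everything is built in code; no binary fixtures.

# chain: EX_s -> CAT -> EX_p with one enzyme; v_max = kcat * pool / mw
chain_model <- function(kcat = 100, mw = 0.05, pool = 0.1,
                        uptake_max = 1000) {
  gem <- stoichiometric_model(
    metabolites = tibble::tibble(id = c("s", "p")),
    reactions = tibble::tibble(
      id = c("EX_s", "CAT", "EX_p", "bio"),
      equation = c("s ->", "s -> p", "p ->", "p ->"),
      lb = c(-uptake_max, 0, 0, 0), ub = c(0, 1000, 1000, 1000),
      kind = c("exchange", "metabolic", "exchange", "biomass")),
    biomass_id = "bio")
  enz <- tibble::tibble(enzyme_id = "E1", reaction_id = "CAT",
                        kcat_per_h = kcat, mw_g_per_mmol = mw)
  build_ec_model(gem, enz, pool_capacity = pool)
}

# shared uptake splitting into two catalyzed routes A and B; uptake is a
# free variable in [0, u_max]; route A additionally capped at a_max.
# All fluxes are affine in (vA, vB): EX_s = -(vA+vB), EX_p = vA+vB,
# usage_A = vA/ka, usage_B = vB/kb.
two_path_model <- function(ka = 10, kb = 20, mwa = 0.01, mwb = 0.01,
                           pool = 1, u_max = 5, a_max = Inf,
                           ngam_floor = 0) {
  gem <- stoichiometric_model(
    metabolites = tibble::tibble(id = c("s", "m", "p")),
    reactions = tibble::tibble(
      id = c("EX_s", "UPT", "A", "B", "EX_p", "bio"),
      equation = c("s ->", "s -> m", "m -> p", "m -> p", "p ->", "p ->"),
      lb = c(-u_max, 0, 0, 0, ngam_floor, 0),
      ub = c(0, 1000, min(a_max, 1000), 1000, 1000, 1000),
      kind = c("exchange", "metabolic", "metabolic", "metabolic",
               "exchange", "biomass")),
    biomass_id = "bio")
  enz <- tibble::tibble(
    enzyme_id = c("EA", "EB"), reaction_id = c("A", "B"),
    kcat_per_h = c(ka, kb), mw_g_per_mmol = c(mwa, mwb))
  build_ec_model(gem, enz, pool_capacity = pool)
}

# Independent L1 oracle: minimize sum_i |u_i(x) - ref_i| over a box in
# the free coordinates x, where usage is affine (u = U %*% x + u0) and
# feasibility adds linear constraints G x <= h. The objective is convex
# piecewise linear, so multiscale grid refinement converges; three
# rounds at 201 points per axis reach ~1e-8 of the box scale.
grid_min_l1 <- function(U, u0, ref, lower, upper,
                        G = NULL, h = NULL, rounds = 4, pts = 201) {
  d <- length(lower)
  lo <- lower; hi <- upper
  best <- Inf
  for (r in seq_len(rounds)) {
    axes <- lapply(seq_len(d), function(i) seq(lo[i], hi[i],
                                               length.out = pts))
    grid <- as.matrix(expand.grid(axes))
    ok <- rep(TRUE, nrow(grid))
    if (!is.null(G)) {
      ok <- apply(grid %*% t(G), 1, function(z) all(z <= h + 1e-12))
    }
    if (!any(ok)) stop("oracle grid found no feasible point")
    gg <- grid[ok, , drop = FALSE]
    vals <- apply(gg, 1, function(x) {
      sum(abs(U %*% x + u0 - ref))
    })
    k <- which.min(vals)
    best <- vals[k]
    ctr <- gg[k, ]
    span <- (hi - lo) / (pts - 1)
    lo <- pmax(lower, ctr - 2 * span)
    hi <- pmin(upper, ctr + 2 * span)
  }
  best
}

# carbon bookkeeping of the synthetic model: mmol C per g of species
toy_carbon_per_g <- c(glc_e = 6 / 0.18016, tre_e = 12 / 0.34230,
                      lac_e = 3 / 0.09008, ac_e = 2 / 0.06005,
                      etoh_e = 2 / 0.04607, actn_e = 4 / 0.08811,
                      co2_e = 1 / 0.04401)

# mmol C fixed per gDW of biomass (biomass_g6p hexose units)
toy_biomass_carbon <- function(params) 6 * params$biomass_g6p

# carbon closure (%) of a trajectory over [t0, t1]
toy_carbon_closure <- function(traj, params, t0, t1) {
  at <- function(v, t) stats::approx(traj$states$t, traj$states[[v]],
                                     xout = t, rule = 2)$y
  consumed <- sum(vapply(c("glc_e", "tre_e"), function(sp) {
    (at(sp, t0) - at(sp, t1)) * toy_carbon_per_g[[sp]]
  }, 1))
  produced <- sum(vapply(c("lac_e", "ac_e", "etoh_e", "actn_e", "co2_e"),
                         function(sp) {
    (at(sp, t1) - at(sp, t0)) * toy_carbon_per_g[[sp]]
  }, 1))
  produced <- produced +
    (at("biomass", t1) - at("biomass", t0)) * toy_biomass_carbon(params)
  100 * produced / consumed
}

# cumulative enzyme-usage reallocation sum over the post-switch phase
total_reallocation <- function(traj) {
  idx <- which(traj$phase_labels == 2)
  sum(vapply(idx, function(k) {
    prev <- traj$solutions[[k - 1]]$enzyme_usage
    sum(abs(traj$solutions[[k]]$enzyme_usage - prev))
  }, 1))
}

# oracle wrapper for two_path_model(): x = (vA, vB)
two_path_oracle <- function(ka, kb, mwa, mwb, pool, u_max, a_max,
                            ngam_floor, ref) {
  U <- diag(c(1 / ka, 1 / kb))
  G <- rbind(c(1, 1),                    # uptake capacity
             c(-1, -1),                  # demand floor
             c(mwa / ka, mwb / kb))      # protein pool
  h <- c(u_max, -ngam_floor, pool)
  grid_min_l1(U, c(0, 0), ref, lower = c(0, 0),
              upper = c(min(a_max, u_max), u_max), G = G, h = h)
}

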