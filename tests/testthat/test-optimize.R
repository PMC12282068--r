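# The MORP brute-force oracle: each hand model is parameterized by its
# free route fluxes (vA, vB); enzyme usage is affine in those, and the
# polytope is a small set of linear inequalities, so multiscale grid
# minimization of the convex L1 objective is an independent check.

test_that("fixed glucose uptake yields 2 lactate, a mass yield of 1 g/g", {
  toy <- toy_fixture()
  m <- set_flux_bounds(toy$model, "EX_glc", lb = -1, ub = -1)
  m <- set_flux_bounds(m, c("PK", "ALS", "BIOMASS"), ub = 0)
  m <- set_flux_bounds(m, "NGAM", lb = 0)
  sol <- fba(m, objective("max_lactate", target = "EX_lac"))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 2, tolerance = 1e-9)
  expect_equal(2 * 90.08 / 180.16, 1, tolerance = 1e-3)
})

test_that("with all uptakes closed the optimum is the zero flux vector", {
  toy <- toy_fixture()
  m <- set_flux_bounds(toy$model, "NGAM", lb = 0)  # drop the ATP floor
  sol <- fba(m, objective("max_lactate", target = "EX_lac"))
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
  expect_lte(max(abs(sol$fluxes)), 1e-9)
})

test_that("the phosphoketolase route gives 1 lactate + 1 two-carbon unit", {
  toy <- toy_fixture()
  m <- set_flux_bounds(toy$model, "EX_glc", lb = -1, ub = -1)
  m <- set_flux_bounds(m, c("EMP", "ALS", "BIOMASS"), ub = 0)
  m <- set_flux_bounds(m, "NGAM", lb = 0)
  sol <- fba(m, objective("max_lactate", target = "EX_lac"))
  expect_equal(sol$objective_value, 1, tolerance = 1e-8)
  two_carbon <- sol$fluxes[["EX_ac"]] + sol$fluxes[["EX_etoh"]]
  expect_equal(unname(two_carbon), 1, tolerance = 1e-8)
})

test_that("morp with its own optimum as reference returns distance zero", {
  for (ec in list(chain_model(),
                  two_path_model(u_max = 4, ngam_floor = 1))) {
    ref <- fba(ec, objective("custom_linear", target = "EX_p"))
    sol <- morp(ec, ref)
    expect_equal(sol$objective_value, 0, tolerance = 1e-9)
    expect_equal(sol$enzyme_usage, ref$enzyme_usage, tolerance = 1e-7)
  }
})

test_that("morp equals the brute-force L1 minimum on hand-sized models", {
  # (1) route A capacity halved after the reference used only A
  ec1 <- two_path_model(ka = 10, kb = 20, u_max = 4, a_max = 2,
                        ngam_floor = 1)
  ref1 <- c(usage_EA = 4 / 10, usage_EB = 0)  # reference ran all-A at 4
  s1 <- morp(ec1, ref1)
  o1 <- two_path_oracle(10, 20, 0.01, 0.01, 1, 4, 2, 1, ref1)
  expect_equal(s1$objective_value, o1, tolerance = 1e-6)

  # (2) tight pool forces a mixed solution
  ec2 <- two_path_model(ka = 10, kb = 50, mwa = 1, mwb = 1,
                        pool = 0.25, u_max = 6, ngam_floor = 2)
  ref2 <- c(usage_EA = 0.5, usage_EB = 0.01)
  s2 <- morp(ec2, ref2)
  o2 <- two_path_oracle(10, 50, 1, 1, 0.25, 6, Inf, 2, ref2)
  expect_equal(s2$objective_value, o2, tolerance = 1e-6)

  # (3) single-route chain against its closed form: capacity halved
  ec3 <- chain_model(kcat = 100, mw = 0.05, pool = 0.05)
  ref3 <- c(usage_E1 = 2)   # usage of the full-pool optimum (flux 200)
  s3 <- morp(ec3, ref3)
  # best the halved pool can do is usage 1 (flux 100): distance 1
  expect_equal(s3$objective_value, 1, tolerance = 1e-9)

  # (4) demand floor above the reference: must scale usage up
  ec4 <- two_path_model(ka = 10, kb = 20, u_max = 5, ngam_floor = 3)
  ref4 <- c(usage_EA = 0.05, usage_EB = 0)
  s4 <- morp(ec4, ref4)
  o4 <- two_path_oracle(10, 20, 0.01, 0.01, 1, 5, Inf, 3, ref4)
  expect_equal(s4$objective_value, o4, tolerance = 1e-6)
})

test_that("morp with an all-zero reference equals the min-usage LP", {
  ec <- two_path_model(ka = 10, kb = 20, u_max = 5, ngam_floor = 2)
  ref <- c(usage_EA = 0, usage_EB = 0)
  s <- morp(ec, ref)
  # independent route: minimize sum of usage columns directly
  parts <- morp:::.lp_parts(ec)
  cc <- numeric(length(parts$ids))
  cc[match(ec$enzyme_usage_ids, parts$ids)] <- 1
  direct <- lp_solve(cc, parts$S, rep(0, nrow(parts$S)), parts$lb,
                     parts$ub)
  expect_equal(s$objective_value, direct$objval, tolerance = 1e-9)
  # the floor of 2 must run through B (kcat 20): min usage 0.1
  expect_equal(s$objective_value, 2 / 20, tolerance = 1e-9)
})

test_that("no uniformly sampled feasible point beats the morp optimum", {
  ec <- two_path_model(ka = 10, kb = 20, u_max = 4, a_max = 2,
                       ngam_floor = 1)
  ref <- c(usage_EA = 0.4, usage_EB = 0)
  opt <- morp(ec, ref)$objective_value
  fs <- sample_flux_space(ec, n = 1000, seed = 7, thinning = 20)
  u <- fs$matrix[, ec$enzyme_usage_ids, drop = FALSE]
  dists <- rowSums(abs(sweep(u, 2, ref)))
  expect_gte(min(dists), opt - 1e-6)
})

test_that("morp objective scales linearly with the problem", {
  mk <- function(c0) {
    two_path_model(ka = 10, kb = 20, u_max = 4 * c0, a_max = 2 * c0,
                   pool = 1 * c0, ngam_floor = 1 * c0)
  }
  ref <- c(usage_EA = 0.4, usage_EB = 0)
  d1 <- morp(mk(1), ref)$objective_value
  for (c0 in c(0.5, 2, 7)) {
    dc <- morp(mk(c0), c0 * ref)$objective_value
    expect_equal(dc, c0 * d1, tolerance = 1e-7)
  }
})

test_that("the two L1 linearizations agree to 1e-8", {
  cases <- list(
    list(ec = two_path_model(ka = 10, kb = 20, u_max = 4, a_max = 2,
                             ngam_floor = 1),
         ref = c(usage_EA = 0.4, usage_EB = 0)),
    list(ec = two_path_model(ka = 10, kb = 50, mwa = 1, mwb = 1,
                             pool = 0.25, u_max = 6, ngam_floor = 2),
         ref = c(usage_EA = 0.5, usage_EB = 0.01)),
    list(ec = chain_model(pool = 0.05), ref = c(usage_E1 = 2)),
    list(ec = toy_fixture()$model |>
           set_flux_bounds("EX_tre", lb = -1, ub = -1),
         ref = setNames(rep(0.05, 8), toy_fixture()$model$enzyme_usage_ids)))
  for (cs in cases) {
    a <- morp(cs$ec, cs$ref, linearization = "aux")$objective_value
    b <- morp(cs$ec, cs$ref, linearization = "split")$objective_value
    expect_equal(a, b, tolerance = 1e-8)
  }
})

test_that("morp validates its reference", {
  ec <- chain_model()
  expect_error(morp(ec, c(1, 2, 3)), class = "morp_validation_error")
  expect_error(morp(ec, NULL), class = "morp_validation_error")
  expect_error(morp(ec, c(bogus_name = 1)),
               class = "morp_validation_error")
})

test_that("min_total_proteome matches the FBA pool draw at fixed output", {
  toy <- toy_fixture()
  m <- set_flux_bounds(toy$model, "EX_glc", lb = -1, ub = -1)
  m <- set_flux_bounds(m, c("PK", "ALS", "BIOMASS"), ub = 0)
  m <- set_flux_bounds(m, "NGAM", lb = 0)
  ref <- fba(m, objective("max_lactate", target = "EX_lac"))
  m2 <- set_flux_bounds(m, "EX_lac", lb = ref$objective_value,
                        ub = ref$objective_value)
  sol <- min_total_proteome(m2)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value,
               unname(ref$fluxes[["pool_exchange"]]), tolerance = 1e-8)
})

test_that("min_total_proteome handles trivial and infeasible bounds", {
  toy <- toy_fixture()
  m <- set_flux_bounds(toy$model, "NGAM", lb = 0)
  sol <- min_total_proteome(m)   # all exchanges closed, no maintenance
  expect_equal(sol$objective_value, 0, tolerance = 1e-10)
  # lactate out above what one glucose can give
  m2 <- set_flux_bounds(toy$model, "EX_glc", lb = -1, ub = -1)
  bad <- tibble::tibble(reaction_id = "EX_lac", lb = 5, ub = 10)
  expect_equal(min_total_proteome(m2, bad)$status, "infeasible")
  # non-exchange ids are rejected
  expect_error(
    min_total_proteome(m2, tibble::tibble(reaction_id = "EMP",
                                          lb = 0, ub = 1)),
    class = "morp_validation_error")
})

test_that("fva brackets fixed, blocked and optimal fluxes", {
  toy <- toy_fixture()
  m <- set_flux_bounds(toy$model, "EX_glc", lb = -2, ub = -2)
  m <- set_flux_bounds(m, "NGAM", lb = 0)
  rng <- fva(m, c("EX_glc", "ALS", "LDH"))
  expect_equal(rng$min[1], -2, tolerance = 1e-9)
  expect_equal(rng$max[1], -2, tolerance = 1e-9)
  blocked <- fva(set_flux_bounds(m, "ALS", ub = 0), "ALS")
  expect_equal(c(blocked$min, blocked$max), c(0, 0), tolerance = 1e-12)
  sol <- fba(m, objective("max_lactate", target = "EX_lac"))
  ldh <- rng[rng$reaction_id == "LDH", ]
  expect_gte(sol$fluxes[["LDH"]], ldh$min - 1e-8)
  expect_lte(sol$fluxes[["LDH"]], ldh$max + 1e-8)
})

test_that("optimal solutions satisfy mass balance to tight tolerance", {
  toy <- toy_fixture()
  m <- set_flux_bounds(toy$model, c("EX_glc", "EX_tre"), lb = c(-5, -1))
  S <- stoich_matrix(m)
  for (obj in list(objective("max_growth"),
                   objective("max_lactate", target = "EX_lac"),
                   objective("max_ngam", target = "NGAM"))) {
    sol <- fba(m, obj)
    expect_equal(sol$status, "optimal")
    resid <- max(abs(S %*% sol$fluxes))
    expect_lte(resid, 1e-9 * max(abs(sol$fluxes)) + 1e-9)
  }
  sol <- min_total_proteome(m)
  expect_lte(max(abs(S %*% sol$fluxes)),
             1e-9 * max(abs(sol$fluxes)) + 1e-9)
})

test_that("fba is deterministic and reports status without exceptions", {
  toy <- toy_fixture()
  m <- set_flux_bounds(toy$model, "EX_glc", lb = -5)
  s1 <- fba(m); s2 <- fba(m)
  expect_identical(s1$fluxes, s2$fluxes)
  # infeasible bounds -> status, not error
  bad <- set_flux_bounds(m, "EX_lac", lb = 500)
  expect_equal(fba(bad)$status, "infeasible")
  # unknown target
  expect_error(fba(m, objective("max_lactate", target = "GHOST")),
               class = "morp_validation_error")
  # wrong objective kind routed to fba
  expect_error(fba(m, objective("morp")), class = "morp_config_error")
})
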