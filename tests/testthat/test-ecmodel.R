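test_that("reaction strings parse to signed coefficients", {
  expect_equal(parse_reaction_string("glc + atp -> g6p + adp"),
               c(glc = -1, atp = -1, g6p = 1, adp = 1))
  expect_equal(parse_reaction_string("2 pyr -> actn + 2 co2"),
               c(pyr = -2, actn = 1, co2 = 2))
  expect_equal(parse_reaction_string("a ->"), c(a = -1))
  expect_equal(parse_reaction_string("-> a"), c(a = 1))
  expect_equal(parse_reaction_string("0.5 x -> y"), c(x = -0.5, y = 1))
  # a species on both sides nets out
  expect_equal(parse_reaction_string("a + b -> a + c"), c(b = -1, c = 1))
  expect_error(parse_reaction_string("a -> b -> c"),
               class = "morp_format_error")
})

test_that("formulas parse to element counts and bad ones error", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("CO2"), c(C = 1, O = 2))
  expect_equal(parse_formula(""), numeric(0))
  expect_equal(parse_formula("X"), c(X = 1))
  expect_error(parse_formula("C6H12-"), class = "morp_validation_error")
})

test_that("model validation catches structural defects", {
  mets <- tibble::tibble(id = c("a", "b"))
  rx <- tibble::tibble(id = c("r1", "bio"),
                       equation = c("a -> b", "b ->"),
                       lb = 0, ub = 10,
                       kind = c("metabolic", "biomass"))
  expect_s3_class(stoichiometric_model(mets, rx, "bio"), "stoich_model")
  # undeclared metabolite
  rx2 <- rx; rx2$equation[1] <- "a -> ghost"
  expect_error(stoichiometric_model(mets, rx2, "bio"),
               class = "morp_format_error")
  # missing biomass
  expect_error(stoichiometric_model(mets, rx, "nope"),
               class = "morp_config_error")
  # biomass id of wrong kind
  expect_error(stoichiometric_model(mets, rx, "r1"),
               class = "morp_config_error")
  # lb > ub
  rx3 <- rx; rx3$lb[1] <- 20
  expect_error(stoichiometric_model(mets, rx3, "bio"),
               class = "morp_validation_error")
})

test_that("stoich_matrix lays out coefficients by metabolite x reaction", {
  ec <- chain_model()
  S <- stoich_matrix(ec)
  expect_equal(S["s", "CAT"], -1)
  expect_equal(S["p", "CAT"], 1 - 0)
  # CAT consumes its enzyme pseudo-metabolite at 1/kcat
  expect_equal(S["prot_E1", "CAT"], -1 / 100)
  # usage reaction draws mw grams of pool per mmol enzyme
  expect_equal(S["prot_pool", "usage_E1"], -0.05)
  expect_equal(S["prot_E1", "usage_E1"], 1)
  expect_equal(S["prot_pool", "pool_exchange"], 1)
})

test_that("enzyme capacity bounds flux at kcat * pool / mw", {
  ec <- chain_model(kcat = 100, mw = 0.05, pool = 0.1)
  sol <- fba(ec, objective("custom_linear", target = "EX_p"))
  expect_equal(sol$objective_value, 200, tolerance = 1e-9)
  expect_equal(unname(sol$enzyme_usage[["usage_E1"]]), 2, tolerance = 1e-8)
  # pool exchange equals sum mw_i * usage_i
  expect_equal(unname(sol$fluxes[["pool_exchange"]]),
               sum(ec$enzymes$mw * sol$enzyme_usage), tolerance = 1e-9)
})

test_that("an empty enzyme table leaves the base optima unchanged", {
  gem <- stoichiometric_model(
    metabolites = tibble::tibble(id = c("s", "p")),
    reactions = tibble::tibble(
      id = c("EX_s", "CAT", "EX_p", "bio"),
      equation = c("s ->", "s -> p", "p ->", "p ->"),
      lb = c(-7, 0, 0, 0), ub = c(0, 1000, 1000, 1000),
      kind = c("exchange", "metabolic", "exchange", "biomass")),
    biomass_id = "bio")
  ec0 <- build_ec_model(gem, tibble::tibble(
    enzyme_id = character(), reaction_id = character(),
    kcat_per_h = numeric(), mw_g_per_mmol = numeric()), pool_capacity = 1)
  sol <- fba(ec0, objective("custom_linear", target = "EX_p"))
  expect_equal(sol$objective_value, 7, tolerance = 1e-9)
})

test_that("reversible catalyzed reactions split into fwd/rev arms", {
  gem <- stoichiometric_model(
    metabolites = tibble::tibble(id = c("a", "b")),
    reactions = tibble::tibble(
      id = c("EX_a", "ISO", "EX_b", "bio"),
      equation = c("a ->", "a -> b", "b ->", "b ->"),
      lb = c(-5, -20, -5, 0), ub = c(5, 30, 5, 10),
      kind = c("exchange", "metabolic", "exchange", "biomass")),
    biomass_id = "bio")
  enz <- tibble::tibble(enzyme_id = "EI", reaction_id = "ISO",
                        kcat_per_h = 50, mw_g_per_mmol = 0.1)
  ec <- build_ec_model(gem, enz, pool_capacity = 1)
  ids <- ec$network$reactions$id
  expect_true(all(c("ISO__fwd", "ISO__rev") %in% ids))
  expect_false("ISO" %in% ids)
  fwd <- ec$network$reactions[ec$network$reactions$id == "ISO__fwd", ]
  rev <- ec$network$reactions[ec$network$reactions$id == "ISO__rev", ]
  expect_equal(c(fwd$lb, fwd$ub), c(0, 30))
  expect_equal(c(rev$lb, rev$ub), c(0, 20))
  # both arms are enzyme-coupled
  expect_equal(fwd$stoichiometry[[1]][["prot_EI"]], -1 / 50)
  expect_equal(rev$stoichiometry[[1]][["prot_EI"]], -1 / 50)
  # de-split reporting sums fwd - rev
  fl <- setNames(rep(0, length(ids)), ids)
  fl["ISO__fwd"] <- 4; fl["ISO__rev"] <- 1
  expect_equal(collapse_fluxes(ec, fl)[["ISO"]], 3)
})

test_that("isozymes create parallel arms by default, one arm under 'fastest'", {
  gem <- stoichiometric_model(
    metabolites = tibble::tibble(id = c("s", "p")),
    reactions = tibble::tibble(
      id = c("EX_s", "CAT", "EX_p", "bio"),
      equation = c("s ->", "s -> p", "p ->", "p ->"),
      lb = c(-1000, 0, 0, 0), ub = c(0, 1000, 1000, 1000),
      kind = c("exchange", "metabolic", "exchange", "biomass")),
    biomass_id = "bio")
  enz <- tibble::tibble(enzyme_id = c("E1", "E2"),
                        reaction_id = "CAT",
                        kcat_per_h = c(100, 400),
                        mw_g_per_mmol = c(0.05, 0.05))
  ec <- build_ec_model(gem, enz, pool_capacity = 0.1)
  arms <- grep("^CAT__iso", ec$network$reactions$id, value = TRUE)
  expect_length(arms, 2)
  # both isozymes can carry flux: cap = (k1 + k2) * pool share
  sol <- fba(ec, objective("custom_linear", target = "EX_p"))
  expect_equal(sol$objective_value, 400 * 0.1 / 0.05, tolerance = 1e-8)
  ec_f <- build_ec_model(gem, enz, pool_capacity = 0.1,
                         isozyme_policy = "fastest")
  expect_false(any(grepl("__iso", ec_f$network$reactions$id)))
  sol_f <- fba(ec_f, objective("custom_linear", target = "EX_p"))
  expect_equal(sol_f$objective_value, 400 * 0.1 / 0.05, tolerance = 1e-8)
})

test_that("build_ec_model validates its enzyme table", {
  gem <- chain_model()$network  # any valid network with CAT present
  gem <- stoichiometric_model(
    metabolites = tibble::tibble(id = c("s", "p")),
    reactions = tibble::tibble(
      id = c("EX_s", "CAT", "EX_p", "bio"),
      equation = c("s ->", "s -> p", "p ->", "p ->"),
      lb = c(-5, 0, 0, 0), ub = c(0, 1, 1, 1),
      kind = c("exchange", "metabolic", "exchange", "biomass")),
    biomass_id = "bio")
  bad_kcat <- tibble::tibble(enzyme_id = "E", reaction_id = "CAT",
                             kcat_per_h = -1, mw_g_per_mmol = 0.1)
  expect_error(build_ec_model(gem, bad_kcat, 1),
               class = "morp_validation_error")
  bad_mw <- tibble::tibble(enzyme_id = "E", reaction_id = "CAT",
                           kcat_per_h = 10, mw_g_per_mmol = 0)
  expect_error(build_ec_model(gem, bad_mw, 1),
               class = "morp_validation_error")
  dup <- tibble::tibble(enzyme_id = c("E", "E"), reaction_id = "CAT",
                        kcat_per_h = 10, mw_g_per_mmol = 0.1)
  expect_error(build_ec_model(gem, dup, 1),
               class = "morp_validation_error")
  ghost <- tibble::tibble(enzyme_id = "E", reaction_id = "GHOST",
                          kcat_per_h = 10, mw_g_per_mmol = 0.1)
  expect_error(build_ec_model(gem, ghost, 1),
               class = "morp_validation_error")
  expect_error(build_ec_model(gem, ghost[0, ], 0),
               class = "morp_validation_error")
})

test_that("mass-balance check flags forced imbalances, skips exchanges", {
  toy <- toy_fixture()
  expect_equal(nrow(check_mass_balance(toy$model, elements = "C")), 0)
  # inject A(C6) -> B(C3)
  gem <- stoichiometric_model(
    metabolites = tibble::tibble(id = c("A", "B"),
                                 formula = c("C6H12O6", "C3H6O3")),
    reactions = tibble::tibble(
      id = c("EX_A", "BAD", "EX_B", "bio"),
      equation = c("A ->", "A -> B", "B ->", "B ->"),
      lb = c(-5, 0, 0, 0), ub = 5,
      kind = c("exchange", "metabolic", "exchange", "biomass")),
    biomass_id = "bio")
  bal <- check_mass_balance(gem)
  expect_equal(nrow(bal[bal$element == "C", ]), 1)
  expect_equal(bal$reaction_id[bal$element == "C"], "BAD")
  expect_equal(bal$residual[bal$element == "C"], -3)
  # exchange reactions are never reported even though one-sided
  expect_false(any(grepl("^EX_", bal$reaction_id)))
  # residuals match a brute-force per-element sum
  S <- stoich_matrix(gem)
  counts <- sapply(gem$metabolites$formula,
                   function(f) parse_formula(f)[["C"]])
  expect_equal(bal$residual[bal$element == "C"],
               unname(counts %*% S[, "BAD"])[1])
})

test_that("formula-less metabolites are skipped with a warning", {
  gem <- stoichiometric_model(
    metabolites = tibble::tibble(id = c("A", "B"),
                                 formula = c("C6H12O6", "")),
    reactions = tibble::tibble(
      id = c("EX_A", "R", "EX_B", "bio"),
      equation = c("A ->", "A -> B", "B ->", "B ->"),
      lb = c(-5, 0, 0, 0), ub = 5,
      kind = c("exchange", "metabolic", "exchange", "biomass")),
    biomass_id = "bio")
  expect_warning(bal <- check_mass_balance(gem), "skipped")
  expect_equal(attr(bal, "skipped"), "R")
  expect_equal(nrow(bal), 0)
})

test_that("set_flux_bounds updates copies and validates", {
  ec <- chain_model()
  ec2 <- set_flux_bounds(ec, "CAT", ub = 5)
  expect_equal(unname(reaction_bounds <- ec2$network$reactions$ub[
    ec2$network$reactions$id == "CAT"]), 5)
  # original untouched
  expect_equal(ec$network$reactions$ub[ec$network$reactions$id == "CAT"],
               1000)
  expect_error(set_flux_bounds(ec, "GHOST", lb = 0),
               class = "morp_validation_error")
  expect_error(set_flux_bounds(ec, "CAT", lb = 10, ub = 5),
               class = "morp_validation_error")
})

test_that("every EC feasible point maps onto a base-model feasible point", {
  # sample the EC polytope, collapse arms, check base mass balance
  gem <- stoichiometric_model(
    metabolites = tibble::tibble(id = c("a", "b")),
    reactions = tibble::tibble(
      id = c("EX_a", "ISO", "EX_b", "bio"),
      equation = c("a ->", "a -> b", "b ->", "b ->"),
      lb = c(-5, -20, -5, 0), ub = c(5, 30, 5, 10),
      kind = c("exchange", "metabolic", "exchange", "biomass")),
    biomass_id = "bio")
  enz <- tibble::tibble(enzyme_id = "EI", reaction_id = "ISO",
                        kcat_per_h = 50, mw_g_per_mmol = 0.1)
  ec <- build_ec_model(gem, enz, pool_capacity = 1)
  fs <- sample_flux_space(ec, n = 50, seed = 4, thinning = 10)
  S0 <- stoich_matrix(gem)
  for (i in seq_len(10)) {
    v <- collapse_fluxes(ec, fs$matrix[i, ])
    expect_lte(max(abs(S0 %*% v[colnames(S0)])), 1e-6)
  }
})
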