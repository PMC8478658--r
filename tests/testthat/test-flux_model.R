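# Constraint-based network module: GPR rules, SBML round trips, FVA versus
# an independent solver, capability probes, perturbation calls and the
# perturbation network.

test_that("GPR rules parse, round-trip and evaluate with min/max semantics", {
  tree <- amlmetab:::parse_gpr("(g1 and g2) or g3")
  expect_equal(tree$op, "or")
  expect_equal(tree$args[[1]]$op, "and")
  expect_equal(amlmetab:::deparse_gpr(tree), "(g1 and g2) or g3")
  expect_equal(evaluate_gpr("g1 and g2", c(g1 = 0.1, g2 = 1)), 0.1)
  expect_equal(evaluate_gpr("g1 or g2", c(g1 = 0.1, g2 = 1)), 1)
  expect_equal(evaluate_gpr("", c(g1 = 0.1)), 1)
  expect_equal(evaluate_gpr("gX and g1", c(g1 = 0.3)), 0.3)  # absent -> 1
  expect_error(amlmetab:::parse_gpr("g1 and (g2"), "parse")
  expect_error(amlmetab:::parse_gpr("g1 or or g2"), "parse")
})

test_that("toy models are feasible, mass balanced, and SBML round-trips", {
  for (variant in c("core", "nad_purine", "idh")) {
    m <- build_toy_metabolic_model(variant)
    imb <- check_mass_balance(m)
    expect_true(all(abs(as.matrix(imb)) < 1e-9), label = variant)
    path <- withr::local_tempfile(fileext = ".xml")
    write_sbml_model(m, path)
    m2 <- read_sbml_model(path)
    expect_equal(m2$reactions$lb, m$reactions$lb)
    expect_equal(m2$reactions$ub, m$reactions$ub)
    expect_equal(m2$reactions$gpr, m$reactions$gpr)
    expect_equal(unname(m2$S), unname(m$S))
    expect_equal(m2$exchanges, m$exchanges)
  }
  expect_error(build_toy_metabolic_model("banana"))
  core <- build_toy_metabolic_model("core")
  expect_gt(metabolite_capability(core, "biomass_c", "produce"), 0)
})

test_that("reader applies documented bound defaults when fbc refs missing", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="mini"><listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies><species id="a_c" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R1" reversible="true" fast="false"><listOfProducts><speciesReference species="a_c" stoichiometry="1" constant="true"/></listOfProducts></reaction>',
    '<reaction id="R2" reversible="false" fast="false"><listOfReactants><speciesReference species="a_c" stoichiometry="1" constant="true"/></listOfReactants></reaction>',
    '</listOfReactions></model></sbml>'), path)
  m <- read_sbml_model(path)
  expect_equal(m$reactions$lb, c(-1000, 0))
  expect_equal(m$reactions$ub, c(1000, 1000))
  expect_error(read_sbml_model(withr::local_tempfile(fileext = ".xml")),
               "malformed")
})

test_that("FVA matches hand-derived linear chain values and blocks orphans", {
  # uptake(<=10) -> A -> B -> export: every reaction interval [0, 10]
  mets <- data.frame(id = c("s_e", "a_c", "b_c", "p_e", "x_c", "y_c"),
                     compartment = c("e", "c", "c", "e", "c", "c"),
                     formula = c("C1", "C1", "C1", "C1", "C1", "C1"))
  rxns <- data.frame(id = c("EX_s", "UP", "AB", "BP", "EX_p", "ORPHAN"),
                     lb = c(-10, 0, 0, 0, 0, 0),
                     ub = c(0, 1000, 1000, 1000, 1000, 1000),
                     gpr = c("", "", "gab", "", "", ""),
                     subsystem = "")
  S <- matrix(0, 6, 6, dimnames = list(mets$id, rxns$id))
  S["s_e", "EX_s"] <- -1
  S["s_e", "UP"] <- -1; S["a_c", "UP"] <- 1
  S["a_c", "AB"] <- -1; S["b_c", "AB"] <- 1
  S["b_c", "BP"] <- -1; S["p_e", "BP"] <- 1
  S["p_e", "EX_p"] <- -1
  # dead-end branch: x_c has no consumer, so steady state blocks ORPHAN
  S["a_c", "ORPHAN"] <- -1; S["x_c", "ORPHAN"] <- 1
  chain <- metabolic_model("chain", mets, rxns, S)
  f <- run_fva(chain)
  expect_equal(f$vmin[f$reaction == "EX_s"], -10, tolerance = 1e-9)
  for (r in c("UP", "AB", "BP", "EX_p")) {
    expect_equal(f$vmin[f$reaction == r], 0, tolerance = 1e-9)
    expect_equal(f$vmax[f$reaction == r], 10, tolerance = 1e-9)
  }
  expect_equal(f$vmax[f$reaction == "ORPHAN"], 0, tolerance = 1e-9)
  # gene knock-down to 0.1 on AB narrows everything downstream to [0, 1]...
  con <- apply_expression_constraints(
    chain, expression_constraint_set(c(gab = 0.1)))
  expect_equal(con$reactions$ub[con$reactions$id == "AB"], 100)
  con$reactions$ub[con$reactions$id == "AB"] <- 1  # direct capacity variant
  f2 <- run_fva(con)
  expect_equal(f2$vmax[f2$reaction == "BP"], 1, tolerance = 1e-9)
  # capability probes
  expect_equal(metabolite_capability(chain, "b_c", "produce"), 10,
               tolerance = 1e-9)
  expect_equal(metabolite_capability(con, "b_c", "produce"), 1,
               tolerance = 1e-9)
  expect_equal(metabolite_capability(chain, "y_c", "produce"), 0,
               tolerance = 1e-9)  # no reaction touches y_c
  expect_error(metabolite_capability(chain, "nope", "produce"), "unknown")
})

test_that("FVA equals the independent boot::simplex oracle on all toys", {
  for (variant in c("core", "nad_purine", "idh")) {
    m <- build_toy_metabolic_model(variant)
    mine <- run_fva(m)
    ref <- oracle_fva(m)
    expect_lt(max(abs(mine$vmin - ref$vmin)), 1e-6)
    expect_lt(max(abs(mine$vmax - ref$vmax)), 1e-6)
  }
})

test_that("expression constraints scale bounds toward zero and are monotone", {
  m <- build_toy_metabolic_model("core")
  i <- match("GLYCL", m$reactions$id)
  m$reactions$lb[i] <- -10; m$reactions$ub[i] <- 10
  con <- apply_expression_constraints(
    m, expression_constraint_set(c(gly1 = 0.5, gly2 = 0.9)))
  expect_equal(con$reactions$lb[i], -5)   # AND -> min(0.5, 0.9)
  expect_equal(con$reactions$ub[i], 5)
  iden <- apply_expression_constraints(
    m, expression_constraint_set(c(gly1 = 1)))
  expect_equal(iden$reactions$lb, m$reactions$lb)
  expect_equal(iden$reactions$ub, m$reactions$ub)
  expect_error(expression_constraint_set(c(g = 0)), "\\(0, 1\\]")
  expect_error(expression_constraint_set(c(g = 0.5), epsilon = 0), "epsilon")
})

test_that("diff_fva calls, subgroup set operation, and network invariants", {
  base <- data.frame(reaction = c("A", "B", "C"), vmin = c(0, 0, -5),
                     vmax = c(10, 10, 5))
  pert <- data.frame(reaction = c("A", "B", "C"), vmin = c(0, 0, -1),
                     vmax = c(1, 10, 1))
  calls <- diff_fva(base, pert, epsilon = 0.01)
  expect_equal(calls$call, c("max_flux", "none", "both"))
  expect_true(all(diff_fva(base, base)$call == "none"))
  other <- diff_fva(base, data.frame(reaction = c("A", "B", "C"),
                                     vmin = c(0, 0, -5),
                                     vmax = c(1, 10, 5)))
  spec_calls <- subgroup_specific_calls(calls, other)
  expect_equal(spec_calls$reaction, "C")
  expect_error(diff_fva(base, pert[1:2, ]), "different reactions")
})

test_that("perturbation network encodes calls, colors, and outdegree sizes", {
  m <- build_toy_metabolic_model("core")
  calls <- data.frame(reaction = c("LDH", "PDH"),
                      call = c("max_flux", "min_flux"))
  g <- build_perturbation_network(calls, m)
  expect_equal(sum(igraph::V(g)$kind == "reaction"), 2)
  expect_equal(igraph::V(g)$size,
               unname(igraph::degree(g, mode = "out")))
  cols <- igraph::V(g)$color[match(c("LDH", "PDH"),
                                   igraph::V(g)$name)]
  expect_equal(cols, c("green", "red"))
  met_cols <- igraph::V(g)$color[igraph::V(g)$kind == "metabolite"]
  expect_true(all(met_cols == "lightblue"))
  # pyr_c feeds both called reactions: outdegree 2
  expect_equal(igraph::V(g)$size[igraph::V(g)$name == "pyr_c"], 2)
  expect_warning(empty <- build_perturbation_network(
    data.frame(reaction = "GLYCL", call = "none"), m), "no perturbation")
  expect_equal(length(igraph::V(empty)), 0)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_perturbation_network(g, path)
  expect_true(file.size(path) > 0)
})

test_that("IDH scenario: no 2-HG without the mutant reaction, LP value with it", {
  m <- build_toy_metabolic_model("idh")
  rep <- idh_validation_scenario(m)
  expect_equal(rep$capability_disabled, 0, tolerance = 1e-9)
  # supply-limited: NADPH uptake 5, akg from glutamine 5, bounds [0, 10]
  expect_equal(rep$capability_enabled, 5, tolerance = 1e-6)
  expect_equal(rep$mutant_fva$vmax, 5, tolerance = 1e-6)
  # enabling a reaction never decreases any production capability
  on <- m; i <- match("IDH1MUT", on$reactions$id); on$reactions$ub[i] <- 10
  for (met in c("lac_e", "biomass_c", "co2_e")) {
    expect_gte(metabolite_capability(on, met, "produce") + 1e-9,
               metabolite_capability(m, met, "produce"))
  }
  expect_error(idh_validation_scenario(build_toy_metabolic_model("core")),
               "hg2_c")
})
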