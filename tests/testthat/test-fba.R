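test_that("FBA matches the closed-form optimum of the chain family", {
  expect_equal(solveFBA(makeChainModel(0.5, 10))$objective, 5, tolerance = 1e-7)
  expect_equal(solveFBA(makeChainModel(0, 10))$objective, 0, tolerance = 1e-9)
  # empty medium: no carbon, no growth
  expect_equal(solveFBA(makeChainModel(0.5, 10), Medium("none"))$objective, 0,
               tolerance = 1e-9)
  # two carbon chains contribute additively
  m2 <- makeChainModel(c(0.5, 0.25), c(10, 4), c("glc", "ac"))
  expect_equal(solveFBA(m2)$objective, 5 + 1, tolerance = 1e-7)
})

test_that("contradictory fixed bounds give status infeasible", {
  m <- makeChainModel(0.5, 10)
  rxn <- reactions(m)
  rxn$lb[rxn$id == "BIO"] <- 50   # unreachable growth forced
  m@reactions <- rxn
  expect_equal(solveFBA(m)$status, "infeasible")
})

test_that("FVA brackets the forced uptake at full growth and relaxes at fraction 0", {
  m <- makeChainModel(0.5, 10)
  at1 <- fluxVariability(m, reactionIds = "EX_glc", objectiveFraction = 1)
  expect_equal(c(at1$min_flux, at1$max_flux), c(-10, -10), tolerance = 1e-6)
  at0 <- fluxVariability(m, reactionIds = "EX_glc", objectiveFraction = 0)
  expect_equal(c(at0$min_flux, at0$max_flux), c(-10, 0), tolerance = 1e-6)
  # dead-end branch is blocked
  md <- randomToyModel(4)   # seed 4 draws the dead-end branch
  if (!"DEAD" %in% reactions(md)$id)
    md <- repertoire:::addReactionsToModel(md, data.frame(
      id = "DEAD", stoichiometry = "prec_c:-1;dead_c:1", lb = 0, ub = 0))
  dd <- fluxVariability(md, reactionIds = "DEAD", objectiveFraction = 0)
  expect_equal(c(dd$min_flux, dd$max_flux), c(0, 0), tolerance = 1e-9)
})

test_that("utilizability follows the sign of the minimal exchange flux", {
  m <- makeChainModel(0.5, 10)
  expect_true(utilizableCarbonSources(m, Medium("min"), "glc_e")[["glc_e"]])
  # no transporter: minimum is zero, not utilizable
  mt <- knockout(m, "T_glc")
  expect_false(utilizableCarbonSources(mt, Medium("min"), "glc_e")[["glc_e"]])
  # candidate with no exchange reaction: false with a warning
  expect_warning(
    u <- utilizableCarbonSources(m, Medium("min"), "mystery_e"),
    "no exchange")
  expect_false(u[["mystery_e"]])
})

test_that("byproduct production follows the sign of the maximal exchange flux", {
  f <- makeFermenterModel()
  med <- glcMedium(10)
  expect_true(producibleByproducts(f, med, "ac_e")[["ac_e"]])
  # chain model has no secretion route for its carbon source:
  # mass balance forbids net export of glucose beyond what is taken up
  m <- makeChainModel(0.5, 10)
  expect_false(producibleByproducts(m, med, "glc_e")[["glc_e"]])
})

test_that("auxotrophy scan flags components whose biosynthesis is knocked out", {
  m <- makeChainModel(0.5, 10)
  med <- glcMedium(10)
  expect_identical(scanAuxotrophies(m, med, "prec_c"), character())
  ko <- knockout(m, "CAT_glc")
  expect_identical(scanAuxotrophies(ko, med, "prec_c"), "prec_c")
  expect_identical(scanAuxotrophies(m, med, character()), character())
})

test_that("futile-cycle detection flags closed loops and clears acyclic chains", {
  expect_setequal(findFutileCycles(loopModel()), c("F1", "F2"))
  expect_length(findFutileCycles(makeChainModel(0.5, 10)), 0)
  # a lone reversible reaction cannot carry net cycle flux
  solo2 <- MetabolicModel("solo2",
    data.frame(id = c("a_c", "b_c", "p_c"), compartment = "c"),
    data.frame(id = c("R", "BIO"), lb = c(-10, 0), ub = 10,
               is_exchange = FALSE, is_biomass = c(FALSE, TRUE)),
    list(R = c(a_c = -1, b_c = 1), BIO = c(b_c = -1, p_c = 1)))
  expect_length(findFutileCycles(solo2), 0)
})

test_that("gap-filling restores knocked-out reactions and matches exhaustive enumeration", {
  med <- glcMedium(10)
  m <- makeChainModel(0.5, 10)
  broken <- knockout(m, "T_glc")
  pool <- data.frame(
    id = c("T_glc", "Z1", "Z2", "Z3"),
    stoichiometry = c("glc_e:-1;glc_c:1", "glc_e:-1;x1_c:1",
                      "x1_c:-1;x2_c:1", "x2_c:-1;x1_c:1"),
    lb = 0, ub = 1000, stringsAsFactors = FALSE)
  gf <- gapFill(broken, pool, med, minGrowth = 0.1)
  expect_identical(gf$added_reaction_ids, "T_glc")
  expect_equal(gf$achieved_growth, 5, tolerance = 1e-6)
  expect_identical(gf$added_reaction_ids,
                   gapFillOracle(broken, pool, med, 0.1))
  # already-growing model needs nothing
  expect_length(gapFill(m, pool, med, 0.1)$added_reaction_ids, 0)
  # pool without the needed reaction is unfillable
  expect_error(gapFill(broken, pool[-1, ], med, 0.1), "unfillable")
})

test_that("gap-filling finds multi-reaction fills verified against enumeration", {
  med <- glcMedium(10)
  m <- makeChainModel(0.5, 10)
  broken <- knockout(knockout(m, "T_glc"), "CAT_glc")
  pool <- data.frame(
    id = c("T_glc", "CAT_glc", "Z1", "Z2", "Z3", "Z4"),
    stoichiometry = c("glc_e:-1;glc_c:1", "glc_c:-1;prec_c:0.5",
                      "glc_e:-1;x1_c:1", "x1_c:-1;x2_c:1",
                      "x2_c:-1;x1_c:1", "x1_c:-1;dead2_c:1"),
    lb = 0, ub = 1000, stringsAsFactors = FALSE)
  gf <- gapFill(broken, pool, med, minGrowth = 0.1)
  expect_identical(gf$added_reaction_ids,
                   gapFillOracle(broken, pool, med, 0.1))
  expect_identical(gf$added_reaction_ids, c("CAT_glc", "T_glc"))
})

test_that("optimal growth is monotone under bound relaxation and reaction addition", {
  for (seed in c(11, 12, 13, 14, 15)) {
    m <- randomToyModel(seed)
    base <- solveFBA(m)$objective
    # relax first exchange uptake bound
    rxn <- reactions(m)
    i <- which(rxn$is_exchange)[1]
    rxn$lb[i] <- rxn$lb[i] * 2
    m2 <- m; m2@reactions <- rxn
    expect_gte(solveFBA(m2)$objective, base - 1e-7)
    # add a fresh parallel catabolic route
    m3 <- repertoire:::addReactionsToModel(m, data.frame(
      id = "EXTRA", stoichiometry = "carb1_c:-1;prec_c:0.9",
      lb = 0, ub = 1000, stringsAsFactors = FALSE))
    expect_gte(solveFBA(m3)$objective, base - 1e-7)
  }
})
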