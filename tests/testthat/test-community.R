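test_that("joining merges the extracellular pool and namespaces internals", {
  a <- makeChainModel(0.5, 10, id = "A")
  b <- makeChainModel(0.5, 10, id = "B")
  cm <- joinModels(a, b)
  expect_s4_class(cm, "CommunityModel")
  expect_setequal(cm@memberBiomass, c("A.BIO", "B.BIO"))
  # one shared glucose pool, one community exchange
  expect_equal(sum(metabolites(cm)$id == "glc_e"), 1)
  expect_equal(sum(reactions(cm)$is_exchange), 1)
  # internal metabolites are disjoint
  expect_true(all(c("A.glc_c", "B.glc_c") %in% metabolites(cm)$id))
  expect_error(joinModels(a, a), "distinct ids")
})

test_that("coupling c = 0 forbids internal flux without growth", {
  a <- makeChainModel(0.5, 10, id = "A")
  b <- makeChainModel(0.5, 10, id = "B")
  cm <- joinModels(a, b, coupling = 0)
  # with zero coupling no internal reaction may carry flux unless biomass
  # does, and biomass needs internal flux: everything is pinned at zero
  res <- communityFBA(cm, glcMedium(10))
  expect_equal(res$j1 + res$j2, 0, tolerance = 1e-7)
})

test_that("two identical members split a shared carbon pool evenly", {
  a <- makeChainModel(0.5, 10, id = "A")
  b <- makeChainModel(0.5, 10, id = "B")
  res <- communityFBA(joinModels(a, b), glcMedium(10))
  expect_equal(res$j1, 2.5, tolerance = 1e-6)
  expect_equal(res$j2, 2.5, tolerance = 1e-6)
  # no-carbon medium
  res0 <- communityFBA(joinModels(a, b), Medium("none"))
  expect_equal(res0$j1 + res0$j2, 0, tolerance = 1e-9)
})

test_that("the stage-2 split preserves the stage-1 optimal sum", {
  sc <- makeInteractionPairs()
  for (s in sc) {
    cm <- joinModels(s$a, s$b)
    m2 <- applyMedium(cm, s$medium)
    bio <- cm@memberBiomass[cm@memberIds]
    s1 <- repertoire:::optimizeModel(m2, NULL,
      stats::setNames(c(1, 1), bio), maximize = TRUE)
    res <- communityFBA(cm, s$medium)
    expect_equal(res$j1 + res$j2, s1$objective, tolerance = 1e-6)
  }
})

test_that("an inert partner leaves growth unchanged", {
  a <- makeChainModel(0.5, 10, id = "A")
  inert <- MetabolicModel("inert",
    data.frame(id = c("x_c", "p_c"), compartment = "c"),
    data.frame(id = "BIO", lb = 0, ub = 0, is_exchange = FALSE,
               is_biomass = TRUE),
    list(BIO = c(x_c = -1, p_c = 1)))
  s <- monocultureGrowth(a, glcMedium(10))
  res <- communityFBA(joinModels(a, inert), glcMedium(10))
  expect_equal(res$j1, s, tolerance = 1e-6)
})

test_that("the classifier implements the j-versus-s definitions totally", {
  expect_equal(classifyInteraction(1, 1, 2, 2), "mutualism")
  expect_equal(classifyInteraction(1, 1, 0.5, 0.5), "competition")
  expect_equal(classifyInteraction(1, 0, 1, 0.5), "commensalism")
  expect_equal(classifyInteraction(1, 1, 0.5, 2), "parasitism")
  expect_equal(classifyInteraction(1, 1, 2, 0.5), "parasitism")
  expect_equal(classifyInteraction(1, 1, 1, 0.5), "amensalism")
  expect_equal(classifyInteraction(1, 1, 1, 1), "neutral")
  expect_error(classifyInteraction(-1, 1, 1, 1), "non-negative")
  # totality over a random grid: exactly one label each
  labs <- c("mutualism", "competition", "parasitism", "commensalism",
            "amensalism", "neutral")
  set.seed(1)
  for (i in 1:200) {
    v <- sample(c(0, 0.5, 1, 1.5), 4, replace = TRUE)
    expect_true(classifyInteraction(v[1], v[2], v[3], v[4]) %in% labs)
  }
})

test_that("the planted four-label suite is classified perfectly and is coupling-insensitive", {
  sc <- makeInteractionPairs()
  for (cc in c(100, 400, 1000)) {
    for (s in sc) {
      s1 <- suppressWarnings(monocultureGrowth(s$a, s$medium, cc))
      s2 <- suppressWarnings(monocultureGrowth(s$b, s$medium, cc))
      res <- suppressWarnings(
        communityFBA(joinModels(s$a, s$b, cc), s$medium))
      lab <- classifyInteraction(s1, s2, max(res$j1, 0), max(res$j2, 0))
      expect_equal(lab, s$expected,
                   label = paste(s$name, "at coupling", cc))
    }
  }
})

test_that("interaction screen reports label fractions and rejects single models", {
  models <- list(makeChainModel(0.5, 10, id = "A"),
                 makeChainModel(0.5, 10, id = "B"),
                 makeChainModel(0.5, 10, id = "C"))
  scr <- interactionScreen(models, glcMedium(10))
  expect_equal(nrow(scr), 3)
  expect_true(all(scr$label == "competition"))
  fr <- attr(scr, "fractions")
  expect_equal(unname(fr[["competition"]]), 1)
  expect_equal(sum(fr), 1)
  expect_error(interactionScreen(models[1], glcMedium(10)), "at least 2")
})

test_that("exchanged metabolites are detected in cross-feeding but not competition", {
  sc <- makeInteractionPairs()
  names(sc) <- vapply(sc, `[[`, "", "name")
  com <- sc$commensalism
  ex <- suppressWarnings(
    exchangedMetabolites(joinModels(com$a, com$b), com$medium))
  expect_true("ac_e" %in% ex$metabolite)
  expect_true(all(ex$flux > 0))
  expect_equal(ex$donor[ex$metabolite == "ac_e"], "G1")
  cmp <- sc$competition
  ex2 <- suppressWarnings(
    exchangedMetabolites(joinModels(cmp$a, cmp$b), cmp$medium))
  expect_equal(nrow(ex2), 0)
})
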