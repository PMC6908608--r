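test_that("trait derivation counts pathway categories and annotations", {
  defs <- makePathwayDefinitions(nPathways = 10, seed = 1)
  m <- makeChainModel(0.5, 10, id = "isoX")
  m@annotations <- list(genome_size_bp = 5e6, rrna_copies = 4)
  calls <- data.frame(
    genome_id = "isoX", pathway_id = defs$pathway_id,
    completeness = 1, key_present = TRUE,
    present = defs$category == "Energy-Metabolism",
    conservative = FALSE)
  tr <- computeTraits(m, calls, defs, growthRate = 0.8)
  expect_equal(tr$catabolic_diversity,
               sum(defs$category == "Energy-Metabolism"))
  expect_equal(tr$antibiotic_pathways, 0)
  expect_equal(tr$eps_pathways, 0)
  expect_equal(tr$genome_size, 5e6)
  m2 <- makeChainModel(0.5, 10, id = "isoY")
  expect_error(computeTraits(m2, calls, defs, 0.8), "genome_size_bp")
  # auxotrophy count feeds from the FBA scan
  ko <- knockout(m, "CAT_glc")
  ko@annotations <- list(genome_size_bp = 5e6, rrna_copies = 4)
  ko@id <- "isoX"
  tr2 <- computeTraits(ko, calls, defs, 0.8,
                       minimalMedium = glcMedium(10),
                       biomassComponents = "prec_c")
  expect_equal(tr2$auxotrophies, 1)
})

test_that("strategy scores follow the quartile criteria and the tie rule", {
  co <- makeUastCohort(noise = 0, seed = 1)
  sc <- scoreStrategies(co)
  truth <- attr(co, "truth")
  expect_true(all(sc$assigned == truth[sc$isolate_id]))
  # archetypes score 1.0 on their own strategy at zero noise
  expect_true(all(sc$c_score[sc$assigned == "C"] == 1))
  expect_true(all(sc$s_score[sc$assigned == "S"] == 1))
  expect_true(all(sc$r_score[sc$assigned == "R"] == 1))
  expect_true(all(sc$c_score >= 0 & sc$c_score <= 1))
  # assigned label always consistent with argmax / tie -> mixed
  for (i in seq_len(nrow(sc))) {
    v <- c(C = sc$c_score[i], S = sc$s_score[i], R = sc$r_score[i])
    top <- names(v)[v >= max(v) - 1e-12]
    expect_equal(sc$assigned[i],
                 if (length(top) > 1) "mixed" else top)
  }
  expect_error(scoreStrategies(co[1:3, ]), ">= 4")
})

test_that("exact score ties are reported as a mixed strategy", {
  co <- makeUastCohort(noise = 0, seed = 2)
  # craft an isolate in the top quartile of every C criterion AND every S
  # criterion except growth handled by the mean rule
  hybrid <- co[1, ]
  hybrid$isolate_id <- "hybrid"
  hybrid$genome_size <- max(co$genome_size) + 1
  hybrid$antibiotic_pathways <- max(co$antibiotic_pathways) + 1
  hybrid$catabolic_diversity <- max(co$catabolic_diversity) + 1
  hybrid$siderophore_pathways <- max(co$siderophore_pathways) + 1
  hybrid$auxotrophies <- max(co$auxotrophies) + 1
  hybrid$eps_pathways <- max(co$eps_pathways) + 1
  hybrid$rrna_copies <- min(co$rrna_copies)
  hybrid$growth_rate <- 0.01
  sc <- scoreStrategies(rbind(co, hybrid))
  h <- sc[sc$isolate_id == "hybrid", ]
  expect_equal(h$c_score, 1)
  expect_equal(h$s_score, 1)
  expect_equal(h$assigned, "mixed")
})

test_that("scoring is invariant under positive rescaling of a trait", {
  co <- makeUastCohort(noise = 0.2, seed = 3)
  sc1 <- scoreStrategies(co)
  co2 <- co
  co2$genome_size <- co2$genome_size * 3.7
  co2$growth_rate <- co2$growth_rate * 0.37   # mean split is scale-free too
  sc2 <- scoreStrategies(co2)
  expect_identical(sc1$assigned, sc2$assigned)
  expect_identical(sc1$c_score, sc2$c_score)
})

test_that("planted archetypes are recovered at the stated noise level", {
  hits <- vapply(1:5, function(s) {
    co <- makeUastCohort(noise = 0.15, seed = s)
    sc <- scoreStrategies(co)
    mean(sc$assigned == attr(co, "truth")[sc$isolate_id])
  }, 0)
  expect_gte(mean(hits), 0.9)
})

test_that("strategy-phenotype statistics behave on separated and degenerate fixtures", {
  co <- makeUastCohort(noise = 0, seed = 4)
  sc <- scoreStrategies(co)
  truth <- attr(co, "truth")
  set.seed(5)
  loads <- stats::setNames(
    ifelse(truth == "R", stats::rnorm(40, 1, 0.2), stats::rnorm(40, 3, 0.2)),
    names(truth))
  res <- strategyPhenotypeTests(sc, loads)
  expect_lt(res$wilcoxon_p, 0.01)
  # identical loads: correlation undefined -> NA
  flat <- stats::setNames(rep(2, 40), names(truth))
  res2 <- strategyPhenotypeTests(sc, flat)
  expect_true(is.na(res2$spearman_rho))
  expect_equal(res2$wilcoxon_p, 1)
})

test_that("a small exact fixture gives the enumerated ruderal-vs-others p-value", {
  sc <- data.frame(isolate_id = paste0("i", 1:8),
                   c_score = c(rep(1, 4), rep(0, 4)),
                   s_score = 0,
                   r_score = c(rep(0, 4), rep(1, 4)),
                   assigned = c(rep("C", 4), rep("R", 4)))
  loads <- stats::setNames(c(5, 6, 7, 8, 1, 2, 3, 4), sc$isolate_id)
  res <- strategyPhenotypeTests(sc, loads)
  # complete separation of 4 vs 4: exact two-sided p = 2 / C(8,4)
  expect_equal(res$wilcoxon_p, 2 / choose(8, 4), tolerance = 1e-12)
})
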