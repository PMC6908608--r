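test_that("reaction calls honour inclusive bitscore and coverage thresholds", {
  hits <- data.frame(
    genome_id = "g1",
    query_id = c("r1", "r2", "r3"),
    bitscore = c(50, 49.9, 200),
    qcovs = c(0.75, 0.9, 0.5))
  rc <- callReactions(hits)
  pres <- stats::setNames(rc$present, rc$reaction_id)
  expect_true(pres[["r1"]])    # both thresholds met exactly
  expect_false(pres[["r2"]])   # bitscore below
  expect_false(pres[["r3"]])   # coverage below
})

test_that("pathway presence follows the strict completeness rules", {
  def <- function(rxns, keys) data.frame(
    pathway_id = "P", name = "p", reaction_ids = I(list(rxns)),
    key_reaction_ids = I(list(keys)), category = "x",
    stringsAsFactors = FALSE)
  pres <- function(ids) data.frame(genome_id = "g", reaction_id = ids,
                                   present = TRUE)
  # 3 of 4 = 0.75 is NOT > 0.75, keys absent -> absent
  r <- callPathway(pres(c("r1", "r2", "r3")), def(paste0("r", 1:4), "r4"), "g")
  expect_equal(r$completeness, 0.75)
  expect_false(r$present)
  # 2 of 3 = 0.667 > 0.66 with key present -> present
  r2 <- callPathway(pres(c("r1", "r2")), def(paste0("r", 1:3), "r1"), "g")
  expect_true(r2$present)
  # 5 of 6 = 0.833 -> present regardless of keys
  r3 <- callPathway(pres(paste0("r", 1:5)), def(paste0("r", 1:6), "r6"), "g")
  expect_true(r3$present)
  # keyMode any vs all
  r4 <- callPathway(pres(c("r1", "r2")), def(paste0("r", 1:3),
                                             c("r1", "r3")), "g")
  expect_false(r4$present)
  r5 <- callPathway(pres(c("r1", "r2")), def(paste0("r", 1:3),
                                             c("r1", "r3")), "g",
                    keyMode = "any")
  expect_true(r5$present)
  expect_error(callPathway(pres("r1"), def(character(), character()), "g"),
               "empty")
})

test_that("planted hit tables are recovered exactly at zero noise", {
  defs <- makePathwayDefinitions(nPathways = 10, seed = 1)
  set.seed(7)
  truth <- matrix(stats::runif(4 * 10) < 0.5, 4, 10,
                  dimnames = list(paste0("g", 1:4), defs$pathway_id))
  hits <- makeHitTables(defs, truth, noise = 0, seed = 2)
  calls <- callPathways(hits, defs)
  got <- metabolicVectors(calls) == 1
  expect_identical(got[rownames(truth), colnames(truth)], truth)
})

test_that("noisy recovery matches an independent brute-force recomputation", {
  defs <- makePathwayDefinitions(nPathways = 8, seed = 3)
  set.seed(8)
  truth <- matrix(stats::runif(3 * 8) < 0.5, 3, 8,
                  dimnames = list(paste0("g", 1:3), defs$pathway_id))
  hits <- makeHitTables(defs, truth, noise = 0.1, seed = 4)
  calls <- callPathways(hits, defs)
  # brute force: per genome/pathway, recount hits passing thresholds
  for (i in seq_len(nrow(calls))) {
    g <- calls$genome_id[i]; pw <- calls$pathway_id[i]
    rxns <- defs$reaction_ids[[match(pw, defs$pathway_id)]]
    keys <- defs$key_reaction_ids[[match(pw, defs$pathway_id)]]
    ok <- vapply(rxns, function(r) any(
      hits$genome_id == g & hits$query_id == r &
        hits$bitscore >= 50 & hits$qcovs >= 0.75), TRUE)
    comp <- mean(ok)
    keyp <- all(vapply(keys, function(r) ok[[r]], TRUE))
    expect_equal(calls$completeness[i], comp)
    expect_equal(calls$present[i], comp > 0.75 || (comp > 0.66 && keyp))
  }
})

test_that("presence is monotone in both thresholds", {
  defs <- makePathwayDefinitions(nPathways = 6, seed = 5)
  set.seed(9)
  truth <- matrix(stats::runif(3 * 6) < 0.5, 3, 6,
                  dimnames = list(paste0("g", 1:3), defs$pathway_id))
  hits <- makeHitTables(defs, truth, noise = 0.15, seed = 6)
  calls <- callPathways(hits, defs)
  # conservative (bitscore 150) implies standard (bitscore 50)
  expect_true(all(!calls$conservative | calls$present))
  # raising coverage never adds presences
  loose <- callReactions(hits, coverageMin = 0.75)
  tight <- callReactions(hits, coverageMin = 0.9)
  merged <- merge(loose, tight, by = c("genome_id", "reaction_id"))
  expect_true(all(!merged$present.y | merged$present.x))
})

test_that("nutrient provisioning aggregates over isolates into a community row", {
  calls <- data.frame(
    genome_id = rep(c("g1", "g2"), each = 2),
    pathway_id = rep(c("P1", "P2"), 2),
    completeness = 1, key_present = TRUE,
    present = c(TRUE, FALSE, FALSE, TRUE),
    conservative = c(TRUE, FALSE, FALSE, FALSE))
  nm <- nutrientProvisionMatrix(calls, list(b12 = "P1", trp = "P2"))
  expect_true(nm["g1", "b12"] && !nm["g1", "trp"])
  expect_true(!nm["g2", "b12"] && nm["g2", "trp"])
  # complementary isolates cover everything as a community
  expect_true(all(nm["community", ]))
  nmc <- nutrientProvisionMatrix(calls, list(b12 = "P1"), conservative = TRUE)
  expect_true(nmc["g1", "b12"] && !nmc["g2", "b12"])
  expect_error(nutrientProvisionMatrix(calls, list(x = "P9")), "unknown")
})

test_that("completion targets list exactly the missing reactions of present pathways", {
  defs <- makePathwayDefinitions(nPathways = 1, rxnsPer = 5, seed = 1)
  rxns <- defs$reaction_ids[[1]]
  rp <- data.frame(genome_id = "g", reaction_id = rxns[1:4], present = TRUE)
  call <- data.frame(genome_id = "g", pathway_id = defs$pathway_id,
                     completeness = 0.8, key_present = TRUE, present = TRUE,
                     conservative = FALSE)
  ct <- pathwayCompletionTargets(call, defs, rp)
  expect_equal(ct$reaction_id, rxns[5])
  # absent pathway: nothing listed
  call$present <- FALSE
  expect_equal(nrow(pathwayCompletionTargets(call, defs, rp)), 0)
  # fully complete pathway: nothing listed
  rp_full <- data.frame(genome_id = "g", reaction_id = rxns, present = TRUE)
  call$present <- TRUE
  expect_equal(nrow(pathwayCompletionTargets(call, defs, rp_full)), 0)
})
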