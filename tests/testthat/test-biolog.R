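plate_row <- function(strain, substrate, rep, od0, od46) {
  data.frame(strain = strain, substrate = substrate, replicate = rep,
             time_min = c(0, 2760), od = c(od0, od46))
}

test_that("fold change follows the background-subtracted formula exactly", {
  plate <- rbind(
    plate_row("s1", "subA", 1, 0.1, 0.5),
    plate_row("s1", "water", 1, 0.1, 0.12))  # water FC = 0.2
  fc <- foldChange(plate)
  expect_equal(fc["s1", "subA"], (0.5 - 0.1) / 0.1 - 0.2, tolerance = 1e-12)
  # a substrate behaving exactly like water cancels to zero
  plate2 <- rbind(plate, plate_row("s1", "subB", 1, 0.1, 0.12))
  expect_equal(foldChange(plate2)["s1", "subB"], 0, tolerance = 1e-12)
  # shrinking OD with flat water: negative fold changes are allowed
  plate3 <- rbind(plate_row("s1", "subC", 1, 0.2, 0.1),
                  plate_row("s1", "water", 1, 0.1, 0.1))
  expect_lt(foldChange(plate3)["s1", "subC"], 0)
  # raw-OD background variant subtracts OD_t46(water) instead
  expect_equal(foldChange(plate, background = "raw_od")["s1", "subA"],
               (0.5 - 0.1) / 0.1 - 0.12, tolerance = 1e-12)
})

test_that("fold change validates its inputs", {
  bad0 <- rbind(plate_row("s1", "subA", 1, 0, 0.5),
                plate_row("s1", "water", 1, 0.1, 0.1))
  expect_error(foldChange(bad0), "zero")
  missing_t <- rbind(
    data.frame(strain = "s1", substrate = "subA", replicate = 1,
               time_min = 0, od = 0.1),
    plate_row("s1", "water", 1, 0.1, 0.1))
  expect_error(foldChange(missing_t), "exactly one OD")
  noctrl <- plate_row("s1", "subA", 1, 0.1, 0.5)
  expect_error(foldChange(noctrl), "control")
})

test_that("replicates are averaged and match a spreadsheet recomputation on a 5x5 fixture", {
  set.seed(21)
  strains <- paste0("s", 1:5); subs <- paste0("sub", 1:5)
  rows <- list()
  expected <- matrix(0, 5, 5, dimnames = list(strains, subs))
  for (st in strains) {
    for (r in 1:3) {
      w46 <- round(stats::runif(1, 0.1, 0.15), 4)
      rows[[length(rows) + 1]] <- plate_row(st, "water", r, 0.1, w46)
      for (su in subs) {
        o46 <- round(stats::runif(1, 0.1, 0.6), 4)
        rows[[length(rows) + 1]] <- plate_row(st, su, r, 0.1, o46)
        expected[st, su] <- expected[st, su] +
          ((o46 - 0.1) / 0.1 - (w46 - 0.1) / 0.1) / 3
      }
    }
  }
  fc <- foldChange(do.call(rbind, rows))
  expect_equal(fc[strains, subs], expected, tolerance = 1e-12)
})

test_that("substrate k-means recovers planted groups and is deterministic", {
  usage <- cbind(matrix(TRUE, 4, 5), matrix(FALSE, 4, 5))
  usage[3:4, ] <- !usage[3:4, ]
  dimnames(usage) <- list(paste0("s", 1:4), paste0("sub", 1:10))
  fc <- foldChange(makePlate(usage, noiseSd = 0, seed = 1))
  km <- substrateKmeans(fc, k = 2, restarts = 50, seed = 3)
  # ARI = 1 on the planted split: clusters coincide with the two groups
  expect_equal(length(unique(km[paste0("sub", 1:5)])), 1)
  expect_equal(length(unique(km[paste0("sub", 6:10)])), 1)
  expect_false(km[["sub1"]] == km[["sub6"]])
  km2 <- substrateKmeans(fc, k = 2, restarts = 50, seed = 3)
  expect_identical(km, km2)
  # k = number of substrates: singletons with zero SSE (distinct profiles)
  fcn <- foldChange(makePlate(usage, noiseSd = 0.2, seed = 8))
  km_all <- substrateKmeans(fcn, k = 10, restarts = 5, seed = 1)
  expect_equal(attr(km_all, "fit")$tot.withinss, 0, tolerance = 1e-9)
  expect_error(substrateKmeans(fc, k = 11), "at least k")
})

test_that("best-of-restarts SSE never increases with more restarts", {
  usage <- matrix(stats::runif(6 * 12) < 0.5, 6, 12,
                  dimnames = list(paste0("s", 1:6), paste0("sub", 1:12)))
  fc <- foldChange(makePlate(usage, noiseSd = 0.5, seed = 5))
  sse <- vapply(c(1, 10, 100), function(r)
    attr(substrateKmeans(fc, k = 4, restarts = r, seed = 9), "fit")$tot.withinss,
    0)
  expect_true(all(diff(sse) <= 1e-9))
})

test_that("strain dendrogram recovers planted strain groups with high support", {
  usage <- rbind(matrix(TRUE, 3, 8), matrix(FALSE, 3, 8))
  usage <- cbind(usage, !usage)
  dimnames(usage) <- list(paste0("s", 1:6), paste0("sub", 1:16))
  fc <- foldChange(makePlate(usage, noiseSd = 0.3, seed = 6))
  dd <- strainDendrogram(fc, nBoot = 100, seed = 7)
  sets <- repertoire:::nodeLeafSets(dd$hclust)
  g1 <- paste(sort(paste0("s", 1:3)), collapse = "\r")
  g2 <- paste(sort(paste0("s", 4:6)), collapse = "\r")
  expect_gte(dd$support[match(g1, sets)], 0.9)
  expect_gte(dd$support[match(g2, sets)], 0.9)
  expect_null(strainDendrogram(fc, nBoot = 0)$support)
})

test_that("model agreement counts matching cells and is symmetric", {
  calls <- matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE,
                    FALSE, TRUE, TRUE, FALSE, FALSE), 2, 5, byrow = TRUE,
                  dimnames = list(c("s1", "s2"), paste0("sub", 1:5)))
  preds <- calls
  preds[1, 1] <- FALSE; preds[2, 3] <- FALSE; preds[2, 5] <- TRUE
  ag <- modelAgreement(calls, preds)
  expect_equal(ag$overall, 7 / 10)
  ag_sym <- modelAgreement(preds, calls)
  expect_equal(ag$overall, ag_sym$overall)
  expect_equal(modelAgreement(calls, calls)$overall, 1)
  nope <- matrix(TRUE, 2, 2, dimnames = list(c("s1", "s2"), c("x", "y")))
  expect_message(expect_error(modelAgreement(calls, nope), "no shared"),
                 "dropping")
})
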