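# Shared fixtures, all built in code.

# remove one reaction from a model (simple knockout)
knockout <- function(model, rid) {
  rxn <- reactions(model)
  keep <- rxn$id[rxn$id != rid]
  st <- model@stoichiometry[keep]
  used <- unique(unlist(lapply(st, names)))
  met <- metabolites(model)
  MetabolicModel(paste0(modelId(model), "_d", rid), met[met$id %in% used, ],
                 rxn[rxn$id != rid, ], st,
                 annotations = modelAnnotations(model))
}

# a 2-reaction futile loop grafted onto nothing else
loopModel <- function() {
  MetabolicModel("loop",
    data.frame(id = c("a_c", "b_c", "p_c"), compartment = "c"),
    data.frame(id = c("F1", "F2", "BIO"), lb = 0, ub = 1000,
               is_exchange = FALSE, is_biomass = c(FALSE, FALSE, TRUE)),
    list(F1 = c(a_c = -1, b_c = 1), F2 = c(b_c = -1, a_c = 1),
         BIO = c(a_c = -1, p_c = 1)))
}

# random viable toy model: 1-3 carbon chains with random yields/uptakes,
# optionally a dead-end branch; closed-form optimum sum(yield * uptake)
randomToyModel <- function(seed) {
  set.seed(seed)
  k <- sample(1:3, 1)
  yields <- round(stats::runif(k, 0.1, 1), 3)
  uptakes <- round(stats::runif(k, 1, 20), 3)
  m <- makeChainModel(yields, uptakes, carbonId = paste0("carb", seq_len(k)),
                      id = paste0("rand", seed))
  if (stats::runif(1) < 0.5) {
    m <- repertoire:::addReactionsToModel(m, data.frame(
      id = "DEAD", stoichiometry = "prec_c:-1;dead_c:1",
      lb = 0, ub = 0, stringsAsFactors = FALSE))
  }
  attr(m, "optimum") <- sum(yields * uptakes)
  m
}

glcMedium <- function(limit = 10) Medium("glc", c(glc_e = limit))

# exhaustive minimal gap-fill oracle (pool <= 12): smallest-cardinality
# subsets achieving growth, ties broken lexicographically
gapFillOracle <- function(model, pool, medium, minGrowth) {
  n <- nrow(pool)
  best <- NULL
  for (size in 0:n) {
    cand <- utils::combn(n, size, simplify = FALSE)
    sets <- list()
    for (ix in cand) {
      m <- repertoire:::addReactionsToModel(applyMedium(model, medium),
                                            pool[ix, , drop = FALSE])
      s <- solveFBA(m)
      if (s$status == "optimal" && s$objective >= minGrowth - 1e-6)
        sets[[length(sets) + 1]] <- sort(pool$id[ix])
    }
    if (length(sets)) {
      keys <- vapply(sets, paste, "", collapse = ",")
      best <- sets[[order(keys)[1]]]
      break
    }
  }
  best
}
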