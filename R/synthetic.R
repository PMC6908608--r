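#' @include AllClasses.R model_io.R community.R
NULL

# compact model assembly for the toy fixtures
# rxns: named list of list(s = named stoichiometry, lb, ub, ex, bio)
assembleModel <- function(id, mets, rxns, ann = list()) {
  met <- data.frame(id = names(mets),
                    name = names(mets),
                    compartment = ifelse(grepl("_e$", names(mets)), "e", "c"),
                    carbon = as.numeric(unname(mets)),
                    stringsAsFactors = FALSE)
  rxn <- do.call(rbind, lapply(names(rxns), function(r) {
    x <- rxns[[r]]
    data.frame(id = r, lb = if (is.null(x$lb)) 0 else x$lb,
               ub = if (is.null(x$ub)) 1000 else x$ub,
               is_exchange = isTRUE(x$ex), is_biomass = isTRUE(x$bio),
               stringsAsFactors = FALSE)
  }))
  st <- lapply(rxns, function(x) x$s)
  m <- MetabolicModel(id, met, rxn, st, annotations = ann)
  validObject(m)
  m
}

exch <- function(met) list(s = stats::setNames(-1, met), lb = 0, ub = 1000,
                           ex = TRUE)

#' Minimal chain model with a closed-form growth optimum
#'
#' A linear toy network: carbon uptake -> transport -> catabolism into a
#' biomass precursor -> biomass. Its FBA optimum is analytically
#' \code{yield * uptake}, which makes the family a convenient oracle for
#' the LP machinery. With several carbon sources the optimum is the sum
#' of the per-carbon contributions.
#'
#' @param yield biomass per unit carbon flux (gDW/mmol); scalar or one per
#'   carbon.
#' @param uptake default exchange uptake bound (mmol/gDW/h); scalar or one
#'   per carbon.
#' @param carbonId carbon source name(s), default "glc".
#' @param id model id.
#' @param carbonAtoms atoms per molecule of each carbon (default 6).
#' @return a \linkS4class{MetabolicModel}; growth on the default bounds is
#'   \code{sum(yield * uptake)}.
#' @examples
#' solveFBA(makeChainModel(0.5, 10))$objective  # 5
#' @export
makeChainModel <- function(yield = 0.5, uptake = 10, carbonId = "glc",
                           id = paste0("chain_", paste(carbonId, collapse = "_")),
                           carbonAtoms = 6) {
  k <- length(carbonId)
  yield <- rep_len(yield, k); uptake <- rep_len(uptake, k)
  carbonAtoms <- rep_len(carbonAtoms, k)
  mets <- c(stats::setNames(carbonAtoms, paste0(carbonId, "_e")),
            stats::setNames(carbonAtoms, paste0(carbonId, "_c")),
            prec_c = if (all(yield > 0)) carbonAtoms[1] / yield[1] else 1)
  rxns <- list()
  for (i in seq_len(k)) {
    ce <- paste0(carbonId[i], "_e"); cc <- paste0(carbonId[i], "_c")
    rxns[[paste0("EX_", carbonId[i])]] <-
      list(s = stats::setNames(-1, ce), lb = -uptake[i], ub = 1000, ex = TRUE)
    rxns[[paste0("T_", carbonId[i])]] <- list(s = stats::setNames(c(-1, 1), c(ce, cc)))
    rxns[[paste0("CAT_", carbonId[i])]] <-
      list(s = stats::setNames(c(-1, yield[i]), c(cc, "prec_c")))
  }
  rxns$BIO <- list(s = c(prec_c = -1), bio = TRUE,
                   ub = if (all(yield > 0)) 1000 else 0)
  assembleModel(id, mets, rxns)
}

#' Fermenting toy model secreting acetate on glucose
#'
#' Glucose can be respired (higher biomass yield) or fermented with
#' obligatory acetate overflow; acetate can be secreted. Used to exercise
#' byproduct-production screens and cross-feeding fixtures.
#'
#' @param id model id.
#' @return a \linkS4class{MetabolicModel}.
#' @export
makeFermenterModel <- function(id = "fermenter") {
  assembleModel(id,
    c(glc_e = 6, glc_c = 6, ac_e = 2, ac_c = 2, prec_c = 12),
    list(EX_glc = list(s = c(glc_e = -1), lb = -10, ub = 1000, ex = TRUE),
         EX_ac = exch("ac_e"),
         T_glc = list(s = c(glc_e = -1, glc_c = 1)),
         RESP = list(s = c(glc_c = -1, prec_c = 0.5)),
         FERM = list(s = c(glc_c = -1, prec_c = 0.3, ac_c = 2)),
         SEC_ac = list(s = c(ac_c = -1, ac_e = 1)),
         BIO = list(s = c(prec_c = -1), bio = TRUE)))
}

# Generalist member: catabolises the listed carbons at equal yield; its
# glucose route obligately co-produces a cofactor and acetate into the pool.
makeGeneralist <- function(id, richCarbons = paste0("c", 2:5),
                           withGlc = TRUE, yield = 0.5,
                           cofactorYield = 0.05, acetateYield = 0.4) {
  mets <- c(prec_c = 6 / yield)
  rxns <- list(BIO = list(s = c(prec_c = -1), bio = TRUE))
  for (x in richCarbons) {
    mets[paste0(x, "_e")] <- 6; mets[paste0(x, "_c")] <- 6
    rxns[[paste0("EX_", x)]] <- exch(paste0(x, "_e"))
    rxns[[paste0("T_", x)]] <- list(
      s = stats::setNames(c(-1, 1), paste0(x, c("_e", "_c"))))
    rxns[[paste0("CAT_", x)]] <- list(
      s = stats::setNames(c(-1, yield), c(paste0(x, "_c"), "prec_c")))
  }
  if (withGlc) {
    mets <- c(mets, glc_e = 6, glc_c = 6, cof_e = NA, ac_e = 2)
    rxns$EX_glc <- exch("glc_e")
    rxns$EX_cof <- exch("cof_e")
    rxns$EX_ac <- exch("ac_e")
    rxns$T_glc <- list(s = c(glc_e = -1, glc_c = 1))
    rxns$CAT_glc <- list(s = c(glc_c = -1, prec_c = yield,
                               cof_e = cofactorYield, ac_e = acetateYield))
  }
  assembleModel(id, mets, rxns)
}

# Exploiter: uses glucose only with a cofactor supplied by a partner, at a
# higher yield, so at the community optimum it drains glucose away from
# the cofactor producer.
makeExploiter <- function(id = "exploiter", richCarbons = paste0("c", 2:5),
                          yield = 0.8, cofPerPrec = 0.01) {
  m <- makeGeneralist(id, richCarbons, withGlc = FALSE)
  pool <- data.frame(
    id = c("EX_glc", "EX_cof", "T_glc", "T_cof", "CAT_glc_cof"),
    stoichiometry = I(list(c(glc_e = -1), c(cof_e = -1),
                           c(glc_e = -1, glc_c = 1), c(cof_e = -1, cof_c = 1),
                           c(glc_c = -1, cof_c = -cofPerPrec,
                             prec_c = yield))),
    lb = 0, ub = 1000, stringsAsFactors = FALSE)
  m <- addReactionsToModel(m, pool)
  rx <- m@reactions
  rx$is_exchange[rx$id %in% c("EX_glc", "EX_cof")] <- TRUE
  m@reactions <- rx
  validObject(m)
  m
}

# Commensal: cannot use glucose, grows on the acetate overflow of a
# generalist (plus the rich carbons).
makeCommensal <- function(id = "commensal", richCarbons = paste0("c", 2:5),
                          yield = 0.5) {
  m <- makeGeneralist(id, richCarbons, withGlc = FALSE)
  pool <- data.frame(
    id = c("EX_ac", "T_ac", "CAT_ac"),
    stoichiometry = I(list(c(ac_e = -1), c(ac_e = -1, ac_c = 1),
                           c(ac_c = -1, prec_c = yield))),
    lb = 0, ub = 1000, stringsAsFactors = FALSE)
  m <- addReactionsToModel(m, pool)
  rx <- m@reactions
  rx$is_exchange[rx$id == "EX_ac"] <- TRUE
  m@reactions <- rx
  validObject(m)
  m
}

# Obligate cross-feeder: grows on glucose but requires a partner vitamin
# in its biomass, while co-producing the vitamin its partner requires.
makeCrossFeeder <- function(id, makes, needs, yield = 0.5) {
  assembleModel(id,
    stats::setNames(c(6, 6, 12, NA, NA, NA),
      c("glc_e", "glc_c", "prec_c", paste0(makes, "_e"), paste0(needs, "_e"),
        paste0(needs, "_c"))),
    stats::setNames(list(
      exch("glc_e"),
      exch(paste0(makes, "_e")),
      exch(paste0(needs, "_e")),
      list(s = c(glc_e = -1, glc_c = 1)),
      list(s = stats::setNames(c(-1, yield, 0.1),
                               c("glc_c", "prec_c", paste0(makes, "_e")))),
      list(s = stats::setNames(c(-1, 1), paste0(needs, c("_e", "_c")))),
      list(s = stats::setNames(c(-1, -0.01), c("prec_c", paste0(needs, "_c"))),
           bio = TRUE)),
      c("EX_glc", paste0("EX_", makes), paste0("EX_", needs),
        "T_glc", "CAT_glc", paste0("T_", needs), "BIO")))
}

#' Planted pairwise-interaction scenario suite
#'
#' Four constructed model pairs with known ecological interactions on a
#' glucose minimal medium: shared-substrate competitors (competition),
#' obligate vitamin cross-feeders (mutualism), a cofactor-dependent
#' glucose exploiter against its cofactor provider (parasitism), and an
#' acetate-overflow consumer against an unaffected producer
#' (commensalism).
#'
#' @return list of scenarios, each with \code{name}, models \code{a},
#'   \code{b}, \code{medium} and the \code{expected} label.
#' @export
makeInteractionPairs <- function() {
  minimal <- Medium("glc_minimal", c(glc_e = 10))
  g1 <- makeGeneralist("G1", richCarbons = character(), withGlc = TRUE)
  g2 <- makeGeneralist("G2", richCarbons = character(), withGlc = TRUE)
  list(
    list(name = "competition", a = g1, b = g2, medium = minimal,
         expected = "competition"),
    list(name = "mutualism",
         a = makeCrossFeeder("XA", makes = "va", needs = "vb"),
         b = makeCrossFeeder("XB", makes = "vb", needs = "va"),
         medium = Medium("glc_rich", c(glc_e = 100)),
         expected = "mutualism"),
    list(name = "parasitism", a = g1, b = makeExploiter("E1",
           richCarbons = character()), medium = minimal,
         expected = "parasitism"),
    list(name = "commensalism", a = g1, b = makeCommensal("F1",
           richCarbons = character()), medium = minimal,
         expected = "commensalism"))
}

#' Planted six-member community with medium-dependent interactions
#'
#' Six members: four generalists, one cofactor-dependent glucose
#' exploiter, one acetate commensal. On the rich medium (four shared,
#' limited carbon sources; no glucose) every pair competes. On the
#' glucose minimal medium the label set is mixed: generalist pairs
#' compete, the exploiter parasitises generalists, the commensal feeds on
#' generalist acetate overflow, and the two specialists are mutually
#' neutral.
#'
#' @return list with \code{models}, \code{rich}, \code{minimal} media and
#'   the expected label per pair and medium
#'   (\code{expected_rich}, \code{expected_minimal}: named by
#'   "memberA|memberB").
#' @export
makeSixMemberCommunity <- function() {
  gens <- lapply(paste0("G", 1:4), makeGeneralist)
  ex1 <- makeExploiter("E1")
  f1 <- makeCommensal("F1")
  models <- c(gens, list(ex1), list(f1))
  ids <- vapply(models, modelId, "")
  rich <- Medium("rich", stats::setNames(rep(5, 4), paste0("c", 2:5, "_e")))
  minimal <- Medium("glc_minimal", c(glc_e = 10))
  pairkey <- function(i, j) paste(ids[i], ids[j], sep = "|")
  er <- em <- character()
  for (i in 1:5) for (j in (i + 1):6) {
    k <- pairkey(i, j)
    er[k] <- "competition"
    gi <- grepl("^G", ids[i]); gj <- grepl("^G", ids[j])
    em[k] <- if (gi && gj) "competition"
      else if ((gi && ids[j] == "E1") || (gj && ids[i] == "E1")) "parasitism"
      else if ((gi && ids[j] == "F1") || (gj && ids[i] == "F1")) "commensalism"
      else "neutral"
  }
  list(models = models, rich = rich, minimal = minimal,
       expected_rich = er, expected_minimal = em)
}

#' Sucrose-invertase co-growth scenario
#'
#' A bearer strain carries an extracellular sucrose invertase
#' (sucrose -> glucose + fructose, a reaction among pool metabolites,
#' coupled to the bearer's growth) plus hexose catabolism; the non-bearer
#' only catabolises the hexoses and owns no sucrose reaction at all. On a
#' sucrose-only medium the bearer grows in monoculture, the non-bearer
#' does not, and both grow in co-culture because hydrolysis happens in
#' the shared pool. The invertase is also provided as an
#' \linkS4class{EnzymeSpecies} for dynamic simulations, where it acts as
#' an independent catalytic species.
#'
#' @param invRate enzyme turnover for the species form (1/h).
#' @return list with \code{bearer}, \code{nonBearer}, \code{enzyme},
#'   \code{medium}.
#' @export
makeInvertaseScenario <- function(invRate = 5) {
  hexoses <- function(id, extra_mets = c(), extra_rxns = list()) {
    mets <- c(glc_e = 6, glc_c = 6, frc_e = 6, frc_c = 6, prec_c = 12,
              extra_mets)
    rxns <- c(list(
      EX_glc = exch("glc_e"), EX_frc = exch("frc_e"),
      T_glc = list(s = c(glc_e = -1, glc_c = 1)),
      T_frc = list(s = c(frc_e = -1, frc_c = 1)),
      CAT_glc = list(s = c(glc_c = -1, prec_c = 0.5)),
      CAT_frc = list(s = c(frc_c = -1, prec_c = 0.5)),
      BIO = list(s = c(prec_c = -1), bio = TRUE)), extra_rxns)
    assembleModel(id, mets, rxns)
  }
  bearer <- hexoses("bearer", extra_mets = c(suc_e = 12),
    extra_rxns = list(
      EX_suc = exch("suc_e"),
      INV = list(s = c(suc_e = -1, glc_e = 1, frc_e = 1))))
  nonBearer <- hexoses("nonbearer")
  list(bearer = bearer, nonBearer = nonBearer,
       enzyme = EnzymeSpecies("invertase",
                              c(suc_e = -1, glc_e = 1, frc_e = 1),
                              rateConstant = invRate, abundance = 1),
       medium = Medium("sucrose", c(suc_e = 5)))
}

#' Random pathway definitions for synthetic hit tables
#'
#' @param nPathways number of pathways.
#' @param rxnsPer reactions per pathway.
#' @param nKey key reactions per pathway.
#' @param categories category labels cycled over pathways.
#' @param seed RNG seed.
#' @return pathway definitions data.frame (as \code{\link{readPathways}}).
#' @export
makePathwayDefinitions <- function(nPathways = 12, rxnsPer = 6, nKey = 1,
                                   categories = c("Energy-Metabolism",
                                                  "Antibiotic-Biosynthesis",
                                                  "Siderophores-Biosynthesis",
                                                  "EPS", "Amino-Acid-Biosynthesis"),
                                   seed = 1) {
  set.seed(seed)
  data.frame(
    pathway_id = sprintf("PWY%03d", seq_len(nPathways)),
    name = sprintf("synthetic pathway %d", seq_len(nPathways)),
    reaction_ids = I(lapply(seq_len(nPathways), function(i)
      sprintf("RXN%03d_%02d", i, seq_len(rxnsPer)))),
    key_reaction_ids = I(lapply(seq_len(nPathways), function(i)
      sprintf("RXN%03d_%02d", i, seq_len(nKey)))),
    category = rep_len(categories, nPathways),
    stringsAsFactors = FALSE)
}

#' Synthetic homology hit table with planted pathway presence
#'
#' For every (genome, pathway) pair planted present, strong hits are
#' emitted for every pathway reaction (half of the genomes with
#' conservative-grade bitscores >= 150, half with standard-grade scores
#' in [60, 140]); planted-absent pathways receive strong hits for only
#' \code{completenessAbsent} of their reactions, below both completeness
#' thresholds. \code{noise} flips individual reaction hits.
#'
#' @param definitions pathway definitions
#'   (\code{\link{makePathwayDefinitions}}).
#' @param presence logical matrix genomes x pathways (planted truth).
#' @param noise per-reaction flip probability (default 0).
#' @param seed RNG seed.
#' @param completenessAbsent completeness of absent pathways (default 0.5).
#' @param conservativeProb probability a present pathway's hits are
#'   conservative-grade (default 0.5).
#' @return hit table data.frame (genome_id, query_id, bitscore, qcovs)
#'   with the planted truth in attribute \code{"truth"}.
#' @export
makeHitTables <- function(definitions, presence, noise = 0, seed = 1,
                          completenessAbsent = 0.5, conservativeProb = 0.5) {
  set.seed(seed)
  rows <- list()
  for (g in rownames(presence)) {
    for (pi in seq_len(nrow(definitions))) {
      pw <- definitions$pathway_id[pi]
      rxns <- definitions$reaction_ids[[pi]]
      planted <- presence[g, pw]
      conservative <- stats::runif(1) < conservativeProb
      nAbs <- floor(completenessAbsent * length(rxns))
      # absent pathways hit only tail reactions, keeping key enzymes (the
      # leading reactions) absent so the relaxed rule cannot fire
      hit <- if (planted) rep(TRUE, length(rxns))
        else seq_along(rxns) > length(rxns) - nAbs
      flip <- stats::runif(length(rxns)) < noise
      hit <- xor(hit, flip)
      if (!any(hit)) next
      bs <- if (conservative) stats::runif(sum(hit), 160, 300)
        else stats::runif(sum(hit), 60, 140)
      rows[[length(rows) + 1]] <- data.frame(
        genome_id = g, query_id = rxns[hit], bitscore = bs,
        qcovs = stats::runif(sum(hit), 0.8, 1), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- presence
  out
}

#' Synthetic BIOLOG plate with planted substrate usage
#'
#' Generates a long-format plate: for used substrates the dye absorbance
#' rises from \code{od0} to \code{od0 * (1 + fcPos)} by 46 h; unused
#' substrates and the water control stay flat (up to replicate noise, the
#' water well is exactly flat so its fold change is zero by construction).
#'
#' @param usage logical matrix strains x substrates (planted truth).
#' @param fcPos fold change of a used substrate (default 3).
#' @param noiseSd replicate noise on the endpoint fold change (default 0).
#' @param seed RNG seed.
#' @param nReplicates replicates per strain (default 3).
#' @param od0 inoculation OD (default 0.1).
#' @return long plate data.frame (strain, substrate, replicate, time_min,
#'   od) with truth in attribute \code{"truth"}.
#' @export
makePlate <- function(usage, fcPos = 3, noiseSd = 0, seed = 1,
                      nReplicates = 3, od0 = 0.1) {
  set.seed(seed)
  times <- c(0, 690, 1380, 2070, 2760)
  rows <- list()
  for (st in rownames(usage)) {
    for (rep_i in seq_len(nReplicates)) {
      for (sub in c(colnames(usage), "water")) {
        fc <- if (sub == "water") 0
          else (if (usage[st, sub]) fcPos else 0) + stats::rnorm(1, 0, noiseSd)
        od46 <- max(od0 * (1 + fc), 0.005)
        od <- od0 + (od46 - od0) * times / max(times)
        rows[[length(rows) + 1]] <- data.frame(
          strain = st, substrate = sub, replicate = rep_i,
          time_min = times, od = od, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- usage
  attr(out, "water_id") <- "water"
  out
}

# coupling-weight lookup calibrated once for the 16S/pathway generator:
# fraction of tree-coupled pathway columns needed to land near a target
# matrix correlation at n = 30 isolates (linear interpolation between
# anchors).
.rho_anchor_target <- c(0, 0.3, 0.6, 0.9, 1)
.rho_anchor_weight <- c(0, 0.13, 0.30, 0.88, 1)

#' Correlated 16S sequences and pathway repertoires
#'
#' Simulates a random phylogeny, evolves 16S-like sequences along it
#' (Jukes-Cantor), and generates binary pathway vectors in which a
#' fraction of pathway columns evolves on the same tree (flip probability
#' growing with branch length) while the rest is independent noise. The
#' coupled fraction is chosen from a calibrated monotone map so that the
#' Spearman correlation between the 16S identity matrix and the
#' metabolic (simple-matching) similarity matrix lands near
#' \code{targetRho}.
#'
#' @param n number of isolates.
#' @param targetRho target matrix correlation in [0, 1].
#' @param seed RNG seed.
#' @param nPathways pathway universe size (default 400, a MetaCyc-scale
#'   repertoire).
#' @param seqLen 16S fragment length (default 800, a near-full-length
#'   fragment).
#' @return list with \code{sequences} (DNAStringSet), \code{vectors}
#'   (binary matrix), \code{tree} (\code{phylo}) and \code{calls}
#'   (long-format presence calls).
#' @export
makeCorrelated16SAndPathways <- function(n, targetRho, seed = 1,
                                         nPathways = 400, seqLen = 800) {
  stopifnot(targetRho >= 0, targetRho <= 1, n >= 3)
  set.seed(seed)
  tree <- ape::rtree(n, tip.label = sprintf("iso%02d", seq_len(n)))
  tree$edge.length <- tree$edge.length *
    (0.15 / max(ape::node.depth.edgelength(tree)))
  dat <- phangorn::simSeq(tree, l = seqLen, type = "DNA", rate = 1)
  chm <- as.character(dat)          # tips x sites character matrix
  chars <- toupper(apply(chm, 1, paste, collapse = ""))
  seqs <- Biostrings::DNAStringSet(chars)
  names(seqs) <- rownames(chm)
  w <- stats::approx(.rho_anchor_target, .rho_anchor_weight,
                     xout = targetRho, rule = 2)$y
  nCoupled <- round(w * nPathways)
  # evolve a binary character down the tree: flip prob 0.5(1 - exp(-2 r l))
  evolveColumn <- function(rate = 3) {
    root <- stats::rbinom(1, 1, 0.5)
    states <- integer(max(tree$edge)); states[ape::Ntip(tree) + 1] <- root
    for (ei in seq_len(nrow(tree$edge))) {
      from <- tree$edge[ei, 1]; to <- tree$edge[ei, 2]
      pflip <- 0.5 * (1 - exp(-2 * rate * tree$edge.length[ei]))
      states[to] <- if (stats::runif(1) < pflip)
        1L - states[from] else states[from]
    }
    states[seq_len(ape::Ntip(tree))]
  }
  V <- matrix(0L, n, nPathways,
              dimnames = list(tree$tip.label, sprintf("PWY%03d", seq_len(nPathways))))
  for (j in seq_len(nPathways)) {
    V[, j] <- if (j <= nCoupled) evolveColumn()
      else stats::rbinom(n, 1, 0.5)
  }
  calls <- data.frame(
    genome_id = rep(rownames(V), ncol(V)),
    pathway_id = rep(colnames(V), each = nrow(V)),
    present = as.logical(V), stringsAsFactors = FALSE)
  list(sequences = seqs, vectors = V, tree = tree, calls = calls)
}

#' Synthetic isolate cohort with planted adaptive strategies
#'
#' Draws trait vectors from three archetype distributions (competitive,
#' stress-tolerant, ruderal); at zero noise every archetype scores
#' perfectly on its own strategy criteria and zero elsewhere.
#'
#' @param nPerStrategy isolates per archetype (default 13/13/14 for a
#'   cohort of 40).
#' @param noise relative noise level (default 0.15).
#' @param seed RNG seed.
#' @return traits data.frame with planted labels in attribute
#'   \code{"truth"}.
#' @export
makeUastCohort <- function(nPerStrategy = c(C = 13, S = 13, R = 14),
                           noise = 0.15, seed = 1) {
  set.seed(seed)
  arch <- list(
    C = list(genome_size = 7e6, antibiotic_pathways = 8,
             catabolic_diversity = 30, siderophore_pathways = 4,
             auxotrophies = 1, growth_rate = 0.7, rrna_copies = 5,
             eps_pathways = 1),
    S = list(genome_size = 4.5e6, antibiotic_pathways = 1,
             catabolic_diversity = 12, siderophore_pathways = 1,
             auxotrophies = 8, growth_rate = 0.25, rrna_copies = 1,
             eps_pathways = 5),
    R = list(genome_size = 3.5e6, antibiotic_pathways = 1,
             catabolic_diversity = 4, siderophore_pathways = 1,
             auxotrophies = 2, growth_rate = 1.3, rrna_copies = 9,
             eps_pathways = 1))
  rows <- list(); truth <- character()
  i <- 0
  for (strat in names(nPerStrategy)) {
    a <- arch[[strat]]
    for (k in seq_len(nPerStrategy[[strat]])) {
      i <- i + 1
      jitter <- function(v, integer = TRUE, lo = 0) {
        x <- v * (1 + stats::rnorm(1, 0, noise))
        x <- max(x, lo)
        if (integer) round(x) else x
      }
      rows[[i]] <- data.frame(
        isolate_id = sprintf("iso%02d", i),
        genome_size = jitter(a$genome_size, integer = FALSE, lo = 1e6),
        antibiotic_pathways = jitter(a$antibiotic_pathways),
        catabolic_diversity = jitter(a$catabolic_diversity),
        siderophore_pathways = jitter(a$siderophore_pathways),
        auxotrophies = jitter(a$auxotrophies),
        growth_rate = jitter(a$growth_rate, integer = FALSE, lo = 0.01),
        rrna_copies = max(jitter(a$rrna_copies), 1),
        eps_pathways = jitter(a$eps_pathways),
        stringsAsFactors = FALSE)
      truth[sprintf("iso%02d", i)] <- strat
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Random binary trait matrix
#'
#' @param n isolates; @param p traits; @param prevalence Bernoulli rate;
#' @param seed RNG seed.
#' @return binary matrix with named rows/columns.
#' @export
makeTraitMatrix <- function(n = 60, p = 20, prevalence = 0.4, seed = 1) {
  set.seed(seed)
  matrix(stats::rbinom(n * p, 1, prevalence), n, p,
         dimnames = list(sprintf("iso%02d", seq_len(n)),
                         sprintf("trait%02d", seq_len(p))))
}

#' Phenotype with planted trait effects
#'
#' phenotype = sum(effect * trait) + N(0, noiseSd); effect sizes are in
#' noise-SD units (Cohen's d against the trait contrast).
#'
#' @param traits binary matrix isolates x traits.
#' @param effectTraits trait ids carrying an effect.
#' @param effectSizes effect sizes (d), recycled over effectTraits.
#' @param noiseSd residual standard deviation (default 1).
#' @param seed RNG seed.
#' @return numeric phenotype vector (named by isolate) with truth in
#'   attribute \code{"truth"}.
#' @export
makePhenotypes <- function(traits, effectTraits, effectSizes = 1.5,
                           noiseSd = 1, seed = 1) {
  set.seed(seed)
  effectSizes <- rep_len(effectSizes, length(effectTraits))
  y <- stats::rnorm(nrow(traits), 0, noiseSd)
  for (i in seq_along(effectTraits))
    y <- y + effectSizes[i] * noiseSd * traits[, effectTraits[i]]
  y <- stats::setNames(y, rownames(traits))
  attr(y, "truth") <- stats::setNames(effectSizes, effectTraits)
  y
}
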