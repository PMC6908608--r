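#' @include AllClasses.R fba.R
NULL

# Build a CommunityModel from 1..2 member models. Used both for joint
# growth (2 members) and for the coupled monoculture reference (1 member),
# so that single and joint growth rates are computed under identical
# constraint structure.
communityOf <- function(members, coupling = 400) {
  ids <- vapply(members, modelId, "")
  if (anyDuplicated(ids))
    stop("member models must have distinct ids (got: ",
         paste(ids, collapse = ", "), ")")
  metL <- list(); rxnL <- list(); stL <- list()
  memberOf <- character(); memberBiomass <- character()
  exch <- list()   # pooled exchanges: metabolite -> c(lb, ub)
  for (m in members) {
    pre <- paste0(m@id, ".")
    met <- m@metabolites
    comp <- stats::setNames(met$compartment, met$id)
    remap <- ifelse(met$compartment == "e", met$id, paste0(pre, met$id))
    names(remap) <- met$id
    met$id <- remap[met$id]
    met$name <- ifelse(met$compartment == "e", met$name, paste(m@id, met$name))
    metL[[m@id]] <- met
    rxn <- m@reactions
    for (i in seq_len(nrow(rxn))) {
      rid <- rxn$id[i]
      s <- m@stoichiometry[[rid]]
      if (rxn$is_exchange[i]) {
        metid <- names(s)[1]
        prev <- exch[[metid]]
        bounds <- c(rxn$lb[i], rxn$ub[i])
        exch[[metid]] <- if (is.null(prev)) bounds else
          c(min(prev[1], bounds[1]), max(prev[2], bounds[2]))
        next
      }
      nid <- paste0(pre, rid)
      names(s) <- remap[names(s)]
      stL[[nid]] <- s
      rxnL[[nid]] <- data.frame(id = nid, lb = rxn$lb[i], ub = rxn$ub[i],
                                is_exchange = FALSE,
                                is_biomass = FALSE, stringsAsFactors = FALSE)
      memberOf[nid] <- m@id
    }
    memberBiomass[m@id] <- paste0(pre, m@biomassId)
  }
  for (metid in names(exch)) {
    eid <- paste0("EX_", metid)
    rxnL[[eid]] <- data.frame(id = eid, lb = exch[[metid]][1],
                              ub = exch[[metid]][2], is_exchange = TRUE,
                              is_biomass = FALSE, stringsAsFactors = FALSE)
    stL[[eid]] <- stats::setNames(-1, metid)
    memberOf[eid] <- "community"
  }
  met <- do.call(rbind, metL)
  met <- met[!duplicated(met$id), , drop = FALSE]
  rxn <- do.call(rbind, rxnL)
  rownames(met) <- rownames(rxn) <- NULL
  # the first member's biomass is flagged for the MetabolicModel contract;
  # community objectives always address biomass reactions explicitly
  rxn$is_biomass <- rxn$id == memberBiomass[[1]]
  new("CommunityModel", id = paste(ids, collapse = "+"),
      metabolites = met, reactions = rxn, stoichiometry = stL[rxn$id],
      biomassId = memberBiomass[[1]], annotations = list(),
      memberIds = ids, memberOf = memberOf,
      memberBiomass = memberBiomass, coupling = coupling)
}

#' Join two metabolic models into a community model
#'
#' Member cytosolic metabolites and internal reactions are namespaced with
#' the member id; extracellular metabolites are merged by id into one
#' common pool with a single community exchange per metabolite (the pool
#' "compartment" shared for metabolite exchange between microbes). Every
#' member internal reaction v is linearly coupled to that member's growth,
#' \eqn{-c \mu_k \le v \le c \mu_k}, which forbids flux configurations
#' that solely benefit the partner while the producer itself does not grow.
#'
#' @param a,b validated \linkS4class{MetabolicModel}s with distinct ids.
#' @param coupling coupling coefficient c (default 400).
#' @return a \linkS4class{CommunityModel}.
#' @export
joinModels <- function(a, b, coupling = 400) {
  cm <- communityOf(list(a, b), coupling)
  validObject(cm)
  cm
}

#' Joint growth of a two-member community
#'
#' Stage 1 maximises the summed biomass flux \eqn{\mu_1 + \mu_2}. Because
#' the optimum is often degenerate in how growth is split between members,
#' stage 2 fixes the optimal sum and maximises \eqn{\min(\mu_1, \mu_2)},
#' which selects a deterministic, maximally even split among the optimal
#' solutions. Returns the stage-2 growth rates.
#'
#' @param community a \linkS4class{CommunityModel}.
#' @param medium the growth \linkS4class{Medium}.
#' @return list with \code{j1}, \code{j2} (1/h, ordered as
#'   \code{community@memberIds}), \code{status} and the stage-2
#'   \code{fluxes}.
#' @export
communityFBA <- function(community, medium) {
  stopifnot(is(community, "CommunityModel"))
  bio <- community@memberBiomass[community@memberIds]
  m2 <- applyMedium(community, medium)
  obj <- stats::setNames(rep(1, length(bio)), bio)
  s1 <- optimizeModel(m2, NULL, obj, maximize = TRUE)
  if (s1$status != "optimal")
    return(list(j1 = 0, j2 = 0, status = s1$status, fluxes = s1$fluxes))
  if (length(bio) == 1)
    return(list(j1 = s1$objective, j2 = NA_real_, status = "optimal",
                fluxes = s1$fluxes))
  # stage 2: fix the sum, maximise the smaller member's growth via an
  # auxiliary variable t with t <= mu_k
  lp <- modelLP(m2)
  n <- length(lp$rxnIds)
  bidx <- match(bio, lp$rxnIds)
  A <- cbind(rbind(lp$S, lp$A), 0)
  rhs <- c(rep(0, nrow(lp$S)), lp$rhs)
  sense <- c(rep("=", nrow(lp$S)), lp$sense)
  for (i in bidx) {
    row <- rep(0, n + 1); row[n + 1] <- 1; row[i] <- -1
    A <- rbind(A, row); rhs <- c(rhs, 0); sense <- c(sense, "<=")
  }
  sumrow <- rep(0, n + 1); sumrow[bidx] <- 1
  A <- rbind(A, sumrow); rhs <- c(rhs, s1$objective); sense <- c(sense, "=")
  obj2 <- c(rep(0, n), 1)
  s2 <- lpSolveDense(obj2, A, rhs, sense, c(lp$lb, 0),
                     c(lp$ub, max(lp$ub)), maximize = TRUE)
  if (s2$status != "optimal")   # numerically degenerate: keep stage 1
    return(list(j1 = s1$fluxes[[bio[1]]], j2 = s1$fluxes[[bio[2]]],
                status = "optimal", fluxes = s1$fluxes))
  fl <- stats::setNames(s2$x[seq_len(n)], lp$rxnIds)
  list(j1 = fl[[bio[1]]], j2 = fl[[bio[2]]], status = "optimal", fluxes = fl)
}

#' Classify a pairwise ecological interaction
#'
#' Compares joint (co-culture) growth rates j1, j2 with single
#' (monoculture) growth rates s1, s2: mutualism j1 > s1 and j2 > s2;
#' competition j1 < s1 and j2 < s2; parasitism one up, one down;
#' commensalism one unchanged, one up; amensalism one unchanged, one down;
#' neutral both unchanged. Equality is tested with a relative tolerance:
#' |j - s| <= max(eps * s, floor).
#'
#' @param s1,s2 monoculture growth rates (1/h, >= 0).
#' @param j1,j2 co-culture growth rates (1/h, >= 0).
#' @param eps relative equality tolerance (default 1e-6).
#' @param floor absolute equality floor (default 1e-9).
#' @return one of "mutualism", "competition", "parasitism", "commensalism",
#'   "amensalism", "neutral".
#' @examples
#' classifyInteraction(1, 1, 2, 2)      # mutualism
#' classifyInteraction(1, 0, 1, 0.5)    # commensalism
#' @export
classifyInteraction <- function(s1, s2, j1, j2, eps = 1e-6, floor = 1e-9) {
  if (any(c(s1, s2, j1, j2) < 0))
    stop("growth rates must be non-negative")
  cmp <- function(j, s) {
    if (abs(j - s) <= max(eps * s, floor)) 0L else if (j > s) 1L else -1L
  }
  d1 <- cmp(j1, s1); d2 <- cmp(j2, s2)
  if (d1 > 0 && d2 > 0) "mutualism"
  else if (d1 < 0 && d2 < 0) "competition"
  else if ((d1 < 0 && d2 > 0) || (d1 > 0 && d2 < 0)) "parasitism"
  else if ((d1 == 0 && d2 > 0) || (d2 == 0 && d1 > 0)) "commensalism"
  else if ((d1 == 0 && d2 < 0) || (d2 == 0 && d1 < 0)) "amensalism"
  else "neutral"
}

#' Monoculture growth rate under community constraint structure
#'
#' Growth of a single model on a medium with the same coupling constraints
#' a community member would experience, so that s and j rates are
#' comparable.
#'
#' @inheritParams solveFBA
#' @param coupling coupling coefficient (default 400).
#' @return growth rate (1/h).
#' @export
monocultureGrowth <- function(model, medium, coupling = 400) {
  cm <- communityOf(list(model), coupling)
  communityFBA(cm, medium)$j1
}

#' Screen all pairs of a model collection for ecological interactions
#'
#' Evaluates every unordered pair of models: monoculture rates s1, s2 and
#' community rates j1, j2 on the same medium and coupling, then the
#' interaction label.
#'
#' @param models list of >= 2 validated \linkS4class{MetabolicModel}s.
#' @param medium growth medium.
#' @param coupling coupling coefficient (default 400).
#' @param eps equality tolerance for the classification.
#' @return data.frame (member_a, member_b, s1, s2, j1, j2, label) with a
#'   \code{"fractions"} attribute: the fraction of pairs per label.
#' @export
interactionScreen <- function(models, medium, coupling = 400, eps = 1e-6) {
  if (length(models) < 2)
    stop("interaction screen needs at least 2 models")
  ids <- vapply(models, modelId, "")
  mono <- vapply(models, monocultureGrowth, 0, medium = medium,
                 coupling = coupling)
  rows <- list()
  for (i in seq_along(models)[-length(models)]) {
    for (j in seq((i + 1), length(models))) {
      cm <- joinModels(models[[i]], models[[j]], coupling)
      jj <- communityFBA(cm, medium)
      lab <- classifyInteraction(mono[i], mono[j], max(jj$j1, 0),
                                 max(jj$j2, 0), eps = eps)
      rows[[length(rows) + 1]] <- data.frame(
        member_a = ids[i], member_b = ids[j],
        s1 = mono[i], s2 = mono[j], j1 = jj$j1, j2 = jj$j2,
        label = lab, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  frac <- table(factor(out$label,
    levels = c("mutualism", "competition", "parasitism", "commensalism",
               "amensalism", "neutral"))) / nrow(out)
  attr(out, "fractions") <- c(frac)
  out
}

#' Metabolites exchanged between community members at the joint optimum
#'
#' Computes each member's net production of every pooled extracellular
#' metabolite from the stage-2 community flux distribution and reports
#' metabolites with member fluxes of opposite sign: one member secretes
#' what the other consumes. The exchanged flux is
#' min(|secretion|, |uptake|).
#'
#' @param community a \linkS4class{CommunityModel}.
#' @param medium the growth medium.
#' @param tol flux tolerance.
#' @return data.frame (metabolite, donor, recipient, flux), possibly empty.
#' @export
exchangedMetabolites <- function(community, medium, tol = 1e-6) {
  res <- communityFBA(community, medium)
  empty <- data.frame(metabolite = character(), donor = character(),
                      recipient = character(), flux = numeric(),
                      stringsAsFactors = FALSE)
  if (res$status != "optimal") return(empty)
  pool <- community@metabolites$id[community@metabolites$compartment == "e"]
  members <- community@memberIds
  net <- matrix(0, length(pool), length(members),
                dimnames = list(pool, members))
  for (rid in community@reactions$id) {
    mem <- community@memberOf[[rid]]
    if (!mem %in% members) next
    s <- community@stoichiometry[[rid]]
    inpool <- intersect(names(s), pool)
    if (length(inpool))
      net[inpool, mem] <- net[inpool, mem] + s[inpool] * res$fluxes[[rid]]
  }
  rows <- list()
  for (m in pool) {
    prod <- which(net[m, ] > tol); cons <- which(net[m, ] < -tol)
    if (length(prod) == 1 && length(cons) == 1)
      rows[[m]] <- data.frame(metabolite = m, donor = members[prod],
                              recipient = members[cons],
                              flux = min(net[m, prod], -net[m, cons]),
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
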