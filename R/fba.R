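#' @include AllClasses.R model_io.R lp.R
NULL

# Assemble the LP skeleton of a (possibly community) model:
# columns = reactions, equality rows = metabolite balances S v = 0,
# plus coupling inequalities |v| <= c * mu_member for community members.
modelLP <- function(model) {
  S <- stoichiometryMatrix(model)
  rxn <- model@reactions
  lp <- list(S = S, lb = rxn$lb, ub = rxn$ub, rxnIds = rxn$id,
             A = NULL, rhs = numeric(), sense = character())
  if (is(model, "CommunityModel") && is.finite(model@coupling)) {
    cpl <- model@coupling
    internal <- rxn$id[model@memberOf[rxn$id] %in% model@memberIds &
                       !(rxn$id %in% model@memberBiomass)]
    if (length(internal)) {
      n <- length(rxn$id)
      idx <- stats::setNames(seq_len(n), rxn$id)
      A <- matrix(0, 2 * length(internal), n)
      rhs <- rep(0, 2 * length(internal))
      sense <- rep(c("<=", ">="), length(internal))
      for (i in seq_along(internal)) {
        r <- internal[i]
        mu <- model@memberBiomass[[model@memberOf[[r]]]]
        A[2 * i - 1, idx[r]] <- 1; A[2 * i - 1, idx[mu]] <- -cpl  # v <= c mu
        A[2 * i,     idx[r]] <- 1; A[2 * i,     idx[mu]] <- cpl   # v >= -c mu
      }
      lp$A <- A; lp$rhs <- rhs; lp$sense <- sense
    }
  }
  lp
}

# Generic optimizer over a model LP. obj: named coefficients over reactions.
# extra: list(A, rhs, sense) appended rows; cols beyond reactions unsupported.
optimizeModel <- function(model, medium = NULL, obj, maximize = TRUE,
                          extra = NULL) {
  if (!is.null(medium)) model <- applyMedium(model, medium)
  lp <- modelLP(model)
  n <- length(lp$rxnIds)
  cvec <- rep(0, n); cvec[match(names(obj), lp$rxnIds)] <- obj
  A <- rbind(lp$S, lp$A)
  rhs <- c(rep(0, nrow(lp$S)), lp$rhs)
  sense <- c(rep("=", nrow(lp$S)), lp$sense)
  if (!is.null(extra)) {
    A <- rbind(A, extra$A); rhs <- c(rhs, extra$rhs)
    sense <- c(sense, extra$sense)
  }
  sol <- lpSolveDense(cvec, A, rhs, sense, lp$lb, lp$ub, maximize = maximize)
  list(status = sol$status, objective = sol$objective,
       fluxes = stats::setNames(sol$x, lp$rxnIds))
}

#' Flux balance analysis
#'
#' Maximises the flux through an objective reaction (by default the biomass
#' reaction, whose flux is the specific growth rate in 1/h) subject to
#' steady-state mass balance S v = 0 and the flux bounds, after applying
#' the medium to the exchange reactions. Deterministic for a fixed solver
#' configuration.
#'
#' @param model a \linkS4class{MetabolicModel} (or
#'   \linkS4class{CommunityModel}, whose coupling constraints are then
#'   honoured).
#' @param medium optional \linkS4class{Medium}; when NULL the model's
#'   current exchange bounds are used as-is.
#' @param objectiveId reaction to optimise, default the biomass reaction.
#' @param maximize maximise (default) or minimise the objective.
#' @return list with \code{status} ("optimal"/"infeasible"/"unbounded"),
#'   \code{objective} and named \code{fluxes}.
#' @examples
#' m <- makeChainModel(yield = 0.5, uptake = 10)
#' solveFBA(m)$objective   # 5 = uptake x yield
#' @export
solveFBA <- function(model, medium = NULL, objectiveId = biomassId(model),
                     maximize = TRUE) {
  stopifnot(objectiveId %in% model@reactions$id)
  optimizeModel(model, medium, stats::setNames(1, objectiveId),
                maximize = maximize)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimises and maximises its flux subject to
#' the FBA constraints and a growth floor
#' \code{biomass >= objectiveFraction * optimum}.
#'
#' @inheritParams solveFBA
#' @param reactionIds reactions to scan, default all.
#' @param objectiveFraction growth floor as a fraction of the FBA optimum
#'   in [0, 1]; 0 removes the growth requirement entirely.
#' @return data.frame with \code{reaction_id}, \code{min_flux},
#'   \code{max_flux}.
#' @export
fluxVariability <- function(model, medium = NULL,
                            reactionIds = reactions(model)$id,
                            objectiveFraction = 1) {
  stopifnot(objectiveFraction >= 0, objectiveFraction <= 1)
  if (!is.null(medium)) { model <- applyMedium(model, medium); medium <- NULL }
  extra <- NULL
  if (objectiveFraction > 0) {
    base <- solveFBA(model)
    if (base$status != "optimal")
      stop("FVA base problem is ", base$status)
    n <- nrow(model@reactions)
    row <- rep(0, n)
    row[match(biomassId(model), model@reactions$id)] <- 1
    extra <- list(A = matrix(row, 1), rhs = objectiveFraction * base$objective,
                  sense = ">=")
  }
  res <- lapply(reactionIds, function(r) {
    lo <- optimizeModel(model, NULL, stats::setNames(1, r), maximize = FALSE,
                        extra = extra)
    hi <- optimizeModel(model, NULL, stats::setNames(1, r), maximize = TRUE,
                        extra = extra)
    data.frame(reaction_id = r, min_flux = lo$objective,
               max_flux = hi$objective, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Carbon-source utilizability screen
#'
#' A candidate carbon source is called utilizable when, with the candidate
#' added to the medium, the minimal achievable flux of its exchange
#' reaction is negative (below \code{-tol}): the network can actually draw
#' the compound in. By default no growth is enforced during the scan
#' ("can the network consume it"); set \code{growthFraction > 0} for the
#' growth-coupled variant.
#'
#' @inheritParams solveFBA
#' @param baseMedium medium the candidates are added to.
#' @param candidates extracellular metabolite ids to test.
#' @param tol flux tolerance, default 1e-6.
#' @param candidateUptake uptake limit granted to each candidate
#'   (mmol/gDW/h).
#' @param growthFraction optional growth floor (fraction of the optimum on
#'   the candidate-supplemented medium).
#' @return named logical vector over candidates.
#' @export
utilizableCarbonSources <- function(model, baseMedium, candidates,
                                    tol = 1e-6, candidateUptake = 10,
                                    growthFraction = 0) {
  ex <- exchangeReactions(model)
  exmet <- vapply(model@stoichiometry[ex], function(s) names(s)[1], "")
  out <- stats::setNames(logical(length(candidates)), candidates)
  for (cand in candidates) {
    i <- match(cand, exmet)
    if (is.na(i)) {
      warning("candidate '", cand, "' has no exchange reaction; not utilizable")
      next
    }
    up <- uptakeLimits(baseMedium)
    if (!cand %in% names(up)) up[cand] <- candidateUptake
    med <- Medium(paste0(baseMedium@name, "+", cand), up)
    m2 <- applyMedium(model, med)
    extra <- NULL
    if (growthFraction > 0) {
      base <- solveFBA(m2)
      if (base$status == "optimal" && base$objective > tol) {
        row <- rep(0, nrow(m2@reactions))
        row[match(biomassId(m2), m2@reactions$id)] <- 1
        extra <- list(A = matrix(row, 1),
                      rhs = growthFraction * base$objective, sense = ">=")
      }
    }
    lo <- optimizeModel(m2, NULL, stats::setNames(1, ex[i]),
                        maximize = FALSE, extra = extra)
    out[cand] <- lo$status == "optimal" && lo$objective < -tol
  }
  out
}

#' Byproduct production screen
#'
#' A byproduct is producible when the maximal achievable flux of its
#' exchange reaction on the given medium is positive (above \code{tol}):
#' the network can secrete it.
#'
#' @inheritParams utilizableCarbonSources
#' @param medium the growth medium.
#' @return named logical vector over candidates.
#' @export
producibleByproducts <- function(model, medium, candidates, tol = 1e-6) {
  ex <- exchangeReactions(model)
  exmet <- vapply(model@stoichiometry[ex], function(s) names(s)[1], "")
  m2 <- applyMedium(model, medium)
  out <- stats::setNames(logical(length(candidates)), candidates)
  for (cand in candidates) {
    i <- match(cand, exmet)
    if (is.na(i)) {
      warning("candidate '", cand, "' has no exchange reaction; not producible")
      next
    }
    hi <- optimizeModel(m2, NULL, stats::setNames(1, ex[i]), maximize = TRUE)
    out[cand] <- hi$status == "optimal" && hi$objective > tol
  }
  out
}

#' Scan for auxotrophies among biomass components
#'
#' For each cytosolic biomass component, a temporary demand reaction
#' consuming the component is added and maximised on the minimal medium.
#' A component whose demand cannot carry flux (max <= tol) cannot be
#' synthesised from the medium: the isolate is auxotrophic for it.
#'
#' @inheritParams solveFBA
#' @param minimalMedium the medium the biosynthesis must run on.
#' @param components cytosolic metabolite ids (typically the biomass
#'   precursors).
#' @param tol flux tolerance.
#' @return character vector: the auxotrophic subset of \code{components}.
#' @export
scanAuxotrophies <- function(model, minimalMedium, components, tol = 1e-6) {
  if (length(components) == 0) return(character())
  m2 <- applyMedium(model, minimalMedium)
  aux <- character()
  for (comp in components) {
    if (!comp %in% m2@metabolites$id)
      stop("biomass component '", comp, "' is not a metabolite of ", m2@id)
    m3 <- addReactionsToModel(m2, data.frame(
      id = ".demand.", stoichiometry = I(list(stats::setNames(-1, comp))),
      lb = 0, ub = 1000, stringsAsFactors = FALSE))
    hi <- optimizeModel(m3, NULL, stats::setNames(1, ".demand."),
                        maximize = TRUE)
    if (!(hi$status == "optimal" && hi$objective > tol))
      aux <- c(aux, comp)
  }
  aux
}

#' Detect futile cycles
#'
#' Closes every exchange reaction (both bounds 0) and runs FVA over the
#' remaining reactions with no growth requirement. Any reaction still able
#' to carry flux belongs to an internal cycle that runs without any input,
#' i.e. a thermodynamically spurious futile cycle. Report-only: bounds are
#' not modified in the returned value.
#'
#' @inheritParams solveFBA
#' @param tol flux tolerance.
#' @return character vector of reaction ids able to carry cycle flux.
#' @export
findFutileCycles <- function(model, tol = 1e-6) {
  rxn <- model@reactions
  ex <- rxn$is_exchange
  rxn$lb[ex] <- 0; rxn$ub[ex] <- 0
  model@reactions <- rxn
  ids <- rxn$id[!ex]
  if (length(ids) == 0) return(character())
  fva <- fluxVariability(model, reactionIds = ids, objectiveFraction = 0)
  fva$reaction_id[fva$max_flux > tol | fva$min_flux < -tol]
}

# Append reactions (data.frame: id, stoichiometry list-or-string, lb, ub)
# to a model; unknown metabolites are created (compartment from "_e" suffix).
addReactionsToModel <- function(model, pool) {
  pool <- as.data.frame(pool)
  if (nrow(pool) == 0) return(model)
  if (is.character(pool$stoichiometry))
    pool$stoichiometry <- parseStoichiometry(pool$stoichiometry, " in pool")
  clash <- intersect(pool$id, model@reactions$id)
  if (length(clash))
    stop("pool reaction ids already in model: ", paste(clash, collapse = ", "))
  met <- model@metabolites
  newmet <- setdiff(unique(unlist(lapply(pool$stoichiometry, names))), met$id)
  if (length(newmet))
    met <- rbind(met, data.frame(id = newmet, name = newmet,
      compartment = ifelse(grepl("_e$", newmet), "e", "c"),
      carbon = NA_integer_, stringsAsFactors = FALSE))
  rxn <- rbind(model@reactions,
               data.frame(id = pool$id, lb = pool$lb, ub = pool$ub,
                          is_exchange = FALSE, is_biomass = FALSE,
                          stringsAsFactors = FALSE))
  st <- c(model@stoichiometry, stats::setNames(pool$stoichiometry, pool$id))
  initialize(model, metabolites = met, reactions = rxn,
             stoichiometry = st[rxn$id])
}

#' Parsimonious gap-filling against a universal reaction pool
#'
#' Finds a small set of pool reactions whose addition lets the model reach
#' at least \code{minGrowth} on the medium. The search is an LP with
#' penalised pool fluxes (minimise the summed absolute pool flux subject
#' to growth >= minGrowth) followed by a greedy pruning pass in
#' lexicographic reaction-id order; pruning guarantees that no reaction of
#' the returned set can be dropped (subset minimality) and makes the
#' result deterministic. No MILP is involved.
#'
#' @inheritParams solveFBA
#' @param universalPool data.frame of candidate reactions with columns
#'   \code{id}, \code{stoichiometry} (list of named vectors or
#'   \code{"met:coef;..."} strings), \code{lb}, \code{ub}; ids must be
#'   disjoint from the model's.
#' @param minGrowth growth threshold to reach (1/h).
#' @param tol flux tolerance.
#' @return list with \code{added_reaction_ids} (lexicographically sorted),
#'   \code{achieved_growth}, and \code{model}, the gap-filled model.
#' @export
gapFill <- function(model, universalPool, medium, minGrowth = 0.01,
                    tol = 1e-6) {
  base <- solveFBA(model, medium)
  if (base$status == "optimal" && base$objective >= minGrowth - tol)
    return(list(added_reaction_ids = character(),
                achieved_growth = base$objective, model = model))
  pool <- as.data.frame(universalPool)
  if (is.character(pool$stoichiometry))
    pool$stoichiometry <- parseStoichiometry(pool$stoichiometry, " in pool")
  pool <- pool[order(pool$id), , drop = FALSE]
  full <- addReactionsToModel(applyMedium(model, medium), pool)
  sol <- solveFBA(full)
  if (!(sol$status == "optimal" && sol$objective >= minGrowth - tol))
    stop("unfillable: no subset of the ", nrow(pool),
         "-reaction pool lets '", model@id, "' reach growth ", minGrowth,
         " on medium '", medium@name, "'")
  # parsimony LP: minimise sum |v_pool| subject to biomass >= minGrowth
  lp <- modelLP(full)
  n <- length(lp$rxnIds); k <- nrow(pool)
  pidx <- match(pool$id, lp$rxnIds)
  bigM <- max(abs(c(lp$lb, lp$ub))) + 1
  A <- cbind(rbind(lp$S, lp$A), matrix(0, nrow(lp$S) + NROW(lp$A), k))
  rhs <- c(rep(0, nrow(lp$S)), lp$rhs)
  sense <- c(rep("=", nrow(lp$S)), lp$sense)
  for (i in seq_len(k)) {        # t_i >= v_i and t_i >= -v_i
    r1 <- rep(0, n + k); r1[pidx[i]] <- 1; r1[n + i] <- -1
    r2 <- rep(0, n + k); r2[pidx[i]] <- -1; r2[n + i] <- -1
    A <- rbind(A, r1, r2); rhs <- c(rhs, 0, 0); sense <- c(sense, "<=", "<=")
  }
  grow <- rep(0, n + k); grow[match(biomassId(full), lp$rxnIds)] <- 1
  A <- rbind(A, grow); rhs <- c(rhs, minGrowth); sense <- c(sense, ">=")
  obj <- c(rep(0, n), rep(1, k))
  ps <- lpSolveDense(obj, A, rhs, sense, c(lp$lb, rep(0, k)),
                     c(lp$ub, rep(bigM, k)), maximize = FALSE)
  cand <- pool$id[ps$status == "optimal" & ps$x[n + seq_len(k)] > tol]
  if (ps$status != "optimal") cand <- pool$id   # fall back to the whole pool
  growthWith <- function(ids) {
    m <- addReactionsToModel(applyMedium(model, medium),
                             pool[pool$id %in% ids, , drop = FALSE])
    s <- solveFBA(m)
    if (s$status == "optimal") s$objective else 0
  }
  if (growthWith(cand) < minGrowth - tol) cand <- pool$id
  keep <- sort(cand)
  for (r in sort(cand)) {        # lexicographic greedy pruning
    trial <- setdiff(keep, r)
    if (growthWith(trial) >= minGrowth - tol) keep <- trial
  }
  filled <- addReactionsToModel(model, pool[pool$id %in% keep, , drop = FALSE])
  final <- solveFBA(filled, medium)
  list(added_reaction_ids = keep, achieved_growth = final$objective,
       model = filled)
}
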