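#' @import methods
NULL

#' MetabolicModel: a stoichiometric network with bounds and one biomass reaction
#'
#' Core container for a (small to mid-size) genome-scale metabolic model.
#' Metabolites live in one of two compartments: \code{"c"} (cytosolic) and
#' \code{"e"} (extracellular); the e-compartment is the pool shared with the
#' environment and, in community models, with other members. Exchange
#' reactions move a single extracellular metabolite across the system
#' boundary; by the usual convention negative exchange flux is uptake and
#' positive flux is secretion. Flux units are mmol/gDW/h and the biomass
#' flux is read as a specific growth rate in 1/h.
#'
#' @slot id model identifier.
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment} ("c" or "e") and \code{carbon} (atoms per molecule,
#'   \code{NA} when untracked; used only for mass-balance audits).
#' @slot reactions data.frame with columns \code{id}, \code{lb}, \code{ub},
#'   \code{is_exchange}, \code{is_biomass}.
#' @slot stoichiometry named list (one entry per reaction id) of named
#'   numeric vectors: metabolite id -> coefficient, negative = consumed.
#' @slot biomassId id of the single biomass reaction.
#' @slot annotations free-form list; recognised entries include
#'   \code{genome_size_bp} and \code{rrna_copies}.
#' @export
setClass("MetabolicModel",
  representation(id = "character", metabolites = "data.frame",
                 reactions = "data.frame", stoichiometry = "list",
                 biomassId = "character", annotations = "list"),
  prototype(annotations = list()))

setValidity("MetabolicModel", function(object) {
  msgs <- character()
  met <- object@metabolites; rxn <- object@reactions
  need_m <- c("id", "name", "compartment", "carbon")
  need_r <- c("id", "lb", "ub", "is_exchange", "is_biomass")
  if (!all(need_m %in% names(met)))
    return(paste("metabolites must have columns", paste(need_m, collapse = ", ")))
  if (!all(need_r %in% names(rxn)))
    return(paste("reactions must have columns", paste(need_r, collapse = ", ")))
  if (anyDuplicated(met$id)) msgs <- c(msgs, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "duplicated reaction ids")
  if (!all(met$compartment %in% c("c", "e")))
    msgs <- c(msgs, sprintf("unknown compartment '%s'",
                            setdiff(met$compartment, c("c", "e"))[1]))
  if (any(rxn$lb > rxn$ub))
    msgs <- c(msgs, sprintf("reaction '%s' has lb > ub",
                            rxn$id[rxn$lb > rxn$ub][1]))
  if (!setequal(names(object@stoichiometry), rxn$id))
    msgs <- c(msgs, "stoichiometry entries must match reaction ids exactly")
  for (rid in names(object@stoichiometry)) {
    s <- object@stoichiometry[[rid]]
    unknown <- setdiff(names(s), met$id)
    if (length(unknown))
      msgs <- c(msgs, sprintf("reaction '%s' references undefined metabolite '%s'",
                              rid, unknown[1]))
    if (length(s) == 0)
      msgs <- c(msgs, sprintf("reaction '%s' has empty stoichiometry", rid))
  }
  nb <- sum(rxn$is_biomass)
  if (nb != 1) msgs <- c(msgs, sprintf("model must have exactly 1 biomass reaction, found %d", nb))
  if (nb == 1 && rxn$id[rxn$is_biomass] != object@biomassId)
    msgs <- c(msgs, "biomassId does not match the reaction flagged is_biomass")
  comp <- stats::setNames(met$compartment, met$id)
  for (rid in rxn$id[rxn$is_exchange]) {
    s <- object@stoichiometry[[rid]]
    if (length(s) != 1 || s[1] != -1)
      msgs <- c(msgs, sprintf("exchange reaction '%s' must have exactly one metabolite with coefficient -1", rid))
    else if (comp[names(s)] != "e")
      msgs <- c(msgs, sprintf("exchange reaction '%s' must act on an extracellular metabolite", rid))
  }
  # every metabolite must appear somewhere (well-formed S)
  used <- unique(unlist(lapply(object@stoichiometry, names)))
  orphan <- setdiff(met$id, used)
  if (length(orphan))
    msgs <- c(msgs, sprintf("metabolite '%s' is not used by any reaction", orphan[1]))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Medium: named uptake limits over the extracellular pool
#'
#' A growth medium is a map from extracellular metabolite id to the maximum
#' uptake rate (mmol/gDW/h, positive). Applying a medium to a model sets
#' the lower bound of the matching exchange reaction to minus the limit and
#' closes uptake through all other exchanges; secretion bounds are never
#' touched.
#'
#' @slot name medium name, e.g. "rich" or "glc_minimal".
#' @slot uptake named numeric vector of positive maximum uptake rates.
#' @export
setClass("Medium",
  representation(name = "character", uptake = "numeric"))

setValidity("Medium", function(object) {
  u <- object@uptake
  if (length(u) && is.null(names(u))) return("uptake limits must be named")
  if (any(u <= 0)) return("all uptake limits must be > 0")
  if (anyDuplicated(names(u))) return("duplicated metabolite ids in medium")
  TRUE
})

#' CommunityModel: two (or one) member models joined over a shared pool
#'
#' Extends \linkS4class{MetabolicModel}. Member cytosolic metabolites and
#' reactions are namespaced \code{"<member>."}; extracellular metabolites
#' are merged by id into one common pool, with a single community-level
#' exchange reaction per pooled metabolite. Every member internal reaction
#' v carries coupling constraints |v| <= c * mu_member, tying member flux
#' to member growth so that a member cannot transform metabolites for a
#' partner's sole benefit without growing itself.
#'
#' @slot memberIds ids of the member models.
#' @slot memberOf named character, reaction id -> member id (community
#'   exchanges map to "community").
#' @slot memberBiomass named character, member id -> its biomass reaction id.
#' @slot coupling the coupling coefficient c (dimensionless, positive).
#' @export
setClass("CommunityModel", contains = "MetabolicModel",
  representation(memberIds = "character", memberOf = "character",
                 memberBiomass = "character", coupling = "numeric"))

setValidity("CommunityModel", function(object) {
  if (length(object@coupling) != 1 || object@coupling < 0)
    return("coupling must be a single non-negative number")
  if (!all(object@memberIds %in% names(object@memberBiomass)))
    return("memberBiomass must cover every member")
  if (!all(object@memberBiomass %in% object@reactions$id))
    return("memberBiomass ids must be reactions of the community")
  TRUE
})

#' EnzymeSpecies: an extracellular enzyme modeled as an independent species
#'
#' Represents a secreted enzyme (e.g. a sucrose invertase) as a standalone
#' catalytic species in a co-culture: it has no biomass, a fixed abundance,
#' and a single conversion among extracellular metabolites, e.g.
#' sucrose -> glucose + fructose. In dynamic co-culture simulation the
#' conversion proceeds at \code{rateConstant * abundance} (mmol/L/h),
#' capped by substrate availability.
#'
#' @slot id enzyme species identifier.
#' @slot stoichiometry named numeric over extracellular metabolite ids
#'   (negative = consumed).
#' @slot rateConstant turnover per unit abundance (1/h).
#' @slot abundance fixed positive amount (arbitrary units).
#' @export
setClass("EnzymeSpecies",
  representation(id = "character", stoichiometry = "numeric",
                 rateConstant = "numeric", abundance = "numeric"))

setValidity("EnzymeSpecies", function(object) {
  if (length(object@stoichiometry) == 0 || is.null(names(object@stoichiometry)))
    return("stoichiometry must be a named numeric vector")
  if (object@rateConstant < 0 || object@abundance <= 0)
    return("rateConstant must be >= 0 and abundance > 0")
  TRUE
})
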