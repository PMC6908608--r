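#' @include AllClasses.R
NULL

#' Accessors for MetabolicModel and Medium objects
#'
#' Slot access goes through these accessors rather than \code{@}.
#' \code{stoichiometryMatrix} assembles the dense S matrix (metabolites x
#' reactions) on demand.
#'
#' @param object a \linkS4class{MetabolicModel} or \linkS4class{Medium}.
#' @return \code{modelId}: character; \code{metabolites}, \code{reactions}:
#'   data.frames; \code{biomassId}: character; \code{stoichiometryMatrix}:
#'   dense numeric matrix; \code{exchangeReactions}: character vector of
#'   exchange reaction ids; \code{uptakeLimits}: named numeric vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setMethod("modelId", "MetabolicModel", function(object) object@id)

#' @rdname accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))
#' @rdname accessors
#' @export
setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)

#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setMethod("reactions", "MetabolicModel", function(object) object@reactions)

#' @rdname accessors
#' @export
setGeneric("biomassId", function(object) standardGeneric("biomassId"))
#' @rdname accessors
#' @export
setMethod("biomassId", "MetabolicModel", function(object) object@biomassId)

#' @rdname accessors
#' @export
setGeneric("modelAnnotations", function(object) standardGeneric("modelAnnotations"))
#' @rdname accessors
#' @export
setMethod("modelAnnotations", "MetabolicModel", function(object) object@annotations)

#' @rdname accessors
#' @export
setGeneric("stoichiometryMatrix", function(object) standardGeneric("stoichiometryMatrix"))
#' @rdname accessors
#' @export
setMethod("stoichiometryMatrix", "MetabolicModel", function(object) {
  met <- object@metabolites$id
  rxn <- object@reactions$id
  S <- matrix(0, length(met), length(rxn), dimnames = list(met, rxn))
  for (rid in rxn) {
    s <- object@stoichiometry[[rid]]
    S[names(s), rid] <- s
  }
  S
})

#' @rdname accessors
#' @export
setGeneric("exchangeReactions", function(object) standardGeneric("exchangeReactions"))
#' @rdname accessors
#' @export
setMethod("exchangeReactions", "MetabolicModel", function(object)
  object@reactions$id[object@reactions$is_exchange])

#' @rdname accessors
#' @export
setGeneric("uptakeLimits", function(object) standardGeneric("uptakeLimits"))
#' @rdname accessors
#' @export
setMethod("uptakeLimits", "Medium", function(object) object@uptake)

#' @export
setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", object@id, "\n")
  cat(" ", nrow(object@metabolites), "metabolites (",
      sum(object@metabolites$compartment == "e"), "extracellular ),",
      nrow(object@reactions), "reactions (",
      sum(object@reactions$is_exchange), "exchanges )\n")
  cat("  biomass:", object@biomassId, "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "Medium", function(object) {
  cat("Medium:", object@name, "with", length(object@uptake), "uptake limits\n")
  if (length(object@uptake)) {
    hd <- utils::head(object@uptake, 5)
    cat(paste0("  ", names(hd), " <= ", hd, collapse = "\n"), "\n")
    if (length(object@uptake) > 5) cat("  ...\n")
  }
  invisible(NULL)
})

#' @export
setMethod("show", "CommunityModel", function(object) {
  cat("CommunityModel of", paste(object@memberIds, collapse = " + "),
      "( coupling c =", object@coupling, ")\n")
  cat(" ", nrow(object@metabolites), "metabolites,",
      nrow(object@reactions), "reactions,",
      sum(object@memberOf == "community"), "pooled exchanges\n")
  invisible(NULL)
})

#' @export
setMethod("show", "EnzymeSpecies", function(object) {
  lhs <- object@stoichiometry[object@stoichiometry < 0]
  rhs <- object@stoichiometry[object@stoichiometry > 0]
  cat("EnzymeSpecies:", object@id, "\n  ",
      paste(-lhs, names(lhs), collapse = " + "), "->",
      paste(rhs, names(rhs), collapse = " + "),
      sprintf("(k = %g /h, abundance = %g)\n", object@rateConstant,
              object@abundance))
  invisible(NULL)
})

#' Construct an EnzymeSpecies
#'
#' @param id identifier.
#' @param stoichiometry named numeric over extracellular metabolites,
#'   negative = consumed.
#' @param rateConstant turnover per unit abundance (1/h).
#' @param abundance fixed amount of enzyme.
#' @return an \linkS4class{EnzymeSpecies}.
#' @export
EnzymeSpecies <- function(id, stoichiometry, rateConstant = 10, abundance = 1) {
  new("EnzymeSpecies", id = id, stoichiometry = stoichiometry,
      rateConstant = rateConstant, abundance = abundance)
}

#' Construct a Medium
#'
#' @param name medium name.
#' @param uptake named numeric vector of positive maximum uptake rates
#'   (mmol/gDW/h) keyed by extracellular metabolite id.
#' @return a \linkS4class{Medium}.
#' @examples
#' Medium("glc_minimal", c(glc_e = 10))
#' @export
Medium <- function(name, uptake = numeric()) {
  new("Medium", name = name, uptake = uptake)
}
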