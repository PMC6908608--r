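#' @include model_io.R
NULL

#' Call reaction presence from homology hit tables
#'
#' A reaction probe is called present in a genome when any hit reaches
#' both the bitscore threshold and the query-coverage threshold, both
#' inclusive (>= 50 bitscore and >= 75\% coverage by default; 150 is the
#' conventional conservative bitscore).
#'
#' @param hits data.frame as returned by \code{\link{readHitTable}}:
#'   \code{genome_id}, \code{query_id}, \code{bitscore}, \code{qcovs}
#'   (fraction).
#' @param bitscoreMin inclusive bitscore threshold (default 50).
#' @param coverageMin inclusive coverage threshold (default 0.75).
#' @return data.frame (genome_id, reaction_id, present) with one row per
#'   observed (genome, query) combination.
#' @export
callReactions <- function(hits, bitscoreMin = 50, coverageMin = 0.75) {
  ok <- hits$bitscore >= bitscoreMin & hits$qcovs >= coverageMin
  key <- paste(hits$genome_id, hits$query_id, sep = "\r")
  present <- tapply(ok, key, any)
  parts <- strsplit(names(present), "\r", fixed = TRUE)
  data.frame(genome_id = vapply(parts, `[`, "", 1),
             reaction_id = vapply(parts, `[`, "", 2),
             present = unname(as.logical(present)),
             stringsAsFactors = FALSE)
}

# presence lookup helper: named logical by reaction for one genome
presenceFor <- function(reactionPresence, genome) {
  sub <- reactionPresence[reactionPresence$genome_id == genome, ]
  stats::setNames(sub$present, sub$reaction_id)
}

#' Call pathway presence from reaction presence
#'
#' A pathway is called present when its completeness (present reactions /
#' total reactions) is strictly above 0.75, or strictly above 0.66 with
#' the key enzymes present. Key presence defaults to requiring all key
#' reactions (\code{keyMode = "all"}); \code{"any"} is the permissive
#' alternative. Completeness thresholds are strict and the hit thresholds
#' inclusive, mirroring the usual operator conventions of
#' homology-based reconstruction.
#'
#' @param reactionPresence data.frame from \code{\link{callReactions}}.
#' @param definition one row of a pathway table
#'   (\code{\link{readPathways}}): \code{pathway_id}, \code{reaction_ids}
#'   (character vector), \code{key_reaction_ids}.
#' @param genome genome id to evaluate.
#' @param keyMode "all" (default) or "any" key enzymes required.
#' @param completenessMin strict completeness threshold (default 0.75).
#' @param relaxedMin strict threshold of the key-enzyme rule (default 0.66).
#' @return list with \code{completeness}, \code{key_present},
#'   \code{present}.
#' @export
callPathway <- function(reactionPresence, definition, genome,
                        keyMode = c("all", "any"),
                        completenessMin = 0.75, relaxedMin = 0.66) {
  keyMode <- match.arg(keyMode)
  rxns <- definition$reaction_ids[[1]]
  keys <- definition$key_reaction_ids[[1]]
  if (length(rxns) == 0) stop("empty pathway definition")
  pres <- presenceFor(reactionPresence, genome)
  have <- function(ids) {
    v <- pres[ids]
    v[is.na(v)] <- FALSE
    v
  }
  completeness <- mean(have(rxns))
  key_present <- if (length(keys) == 0) FALSE
    else if (keyMode == "all") all(have(keys)) else any(have(keys))
  present <- completeness > completenessMin ||
    (completeness > relaxedMin && key_present)
  list(completeness = completeness, key_present = key_present,
       present = present)
}

#' Pathway presence calls for a hit table, standard and conservative
#'
#' Convenience driver combining \code{\link{callReactions}} and
#' \code{\link{callPathway}} over all genomes and pathways, at the
#' standard bitscore threshold and again at the conservative one; a
#' conservative call implies the standard call by construction
#' (presence is monotone in the bitscore threshold).
#'
#' @param hits hit table (\code{\link{readHitTable}}).
#' @param definitions pathway table (\code{\link{readPathways}}).
#' @param bitscoreMin standard bitscore threshold (default 50).
#' @param conservativeBitscore conservative threshold (default 150).
#' @param coverageMin coverage threshold (default 0.75).
#' @param keyMode key-enzyme mode, see \code{\link{callPathway}}.
#' @return data.frame of presence calls: \code{genome_id},
#'   \code{pathway_id}, \code{completeness}, \code{key_present},
#'   \code{present}, \code{conservative}.
#' @export
callPathways <- function(hits, definitions, bitscoreMin = 50,
                         conservativeBitscore = 150, coverageMin = 0.75,
                         keyMode = c("all", "any")) {
  keyMode <- match.arg(keyMode)
  std <- callReactions(hits, bitscoreMin, coverageMin)
  con <- callReactions(hits, conservativeBitscore, coverageMin)
  genomes <- sort(unique(hits$genome_id))
  rows <- list()
  for (g in genomes) {
    for (i in seq_len(nrow(definitions))) {
      d <- definitions[i, , drop = FALSE]
      cs <- callPathway(std, d, g, keyMode)
      cc <- callPathway(con, d, g, keyMode)
      rows[[length(rows) + 1]] <- data.frame(
        genome_id = g, pathway_id = d$pathway_id,
        completeness = cs$completeness, key_present = cs$key_present,
        present = cs$present, conservative = cc$present,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Essential-nutrient provisioning matrix
#'
#' Maps pathway presence calls to per-isolate provisioning of nutrients
#' (e.g. essential amino acids and co-factors of the host): a nutrient is
#' provisionable by an isolate when any of its mapped biosynthesis
#' pathways is present. A "community" row gives the OR over all isolates:
#' what the collection can synthesise as a whole.
#'
#' @param calls presence calls from \code{\link{callPathways}}.
#' @param nutrientMap named list: nutrient -> character vector of pathway
#'   ids able to provide it.
#' @param conservative use the conservative presence layer instead.
#' @return logical matrix (isolates + "community") x nutrients.
#' @export
nutrientProvisionMatrix <- function(calls, nutrientMap,
                                    conservative = FALSE) {
  col <- if (conservative) "conservative" else "present"
  missing_pw <- setdiff(unlist(nutrientMap), unique(calls$pathway_id))
  if (length(missing_pw))
    stop("nutrient map references unknown pathways: ",
         paste(missing_pw, collapse = ", "))
  genomes <- sort(unique(calls$genome_id))
  M <- matrix(FALSE, length(genomes) + 1, length(nutrientMap),
              dimnames = list(c(genomes, "community"), names(nutrientMap)))
  for (g in genomes) {
    sub <- calls[calls$genome_id == g & calls[[col]], "pathway_id"]
    for (nu in names(nutrientMap))
      M[g, nu] <- any(nutrientMap[[nu]] %in% sub)
  }
  M["community", ] <- apply(M[genomes, , drop = FALSE], 2, any)
  M
}

#' Reactions to add for pathways called present but incomplete
#'
#' For every pathway called present, lists its absent reactions per
#' genome. These are natural gap-filling candidates: a pathway confidently
#' present at, say, 80\% completeness most likely possesses its missing
#' step as well.
#'
#' @param calls presence calls from \code{\link{callPathways}}.
#' @param definitions pathway table.
#' @param reactionPresence reaction calls from \code{\link{callReactions}}
#'   at the standard threshold.
#' @return data.frame (genome_id, pathway_id, reaction_id) of reactions to
#'   add; empty when nothing is missing.
#' @export
pathwayCompletionTargets <- function(calls, definitions, reactionPresence) {
  rows <- list()
  idx <- stats::setNames(seq_len(nrow(definitions)), definitions$pathway_id)
  for (i in which(calls$present)) {
    g <- calls$genome_id[i]; pw <- calls$pathway_id[i]
    rxns <- definitions$reaction_ids[[idx[[pw]]]]
    pres <- presenceFor(reactionPresence, g)
    v <- pres[rxns]; v[is.na(v)] <- FALSE
    miss <- rxns[!v]
    if (length(miss))
      rows[[length(rows) + 1]] <- data.frame(
        genome_id = g, pathway_id = pw, reaction_id = miss,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(genome_id = character(), pathway_id = character(),
                      reaction_id = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
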