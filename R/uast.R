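#' @include fba.R pathways.R stats.R
NULL

#' Derive adaptive-strategy traits for one isolate
#'
#' Collects the genomic/metabolic traits the C/S/R scoring uses:
#' genome size and rRNA copy number from the model annotations, pathway
#' category counts (antibiotic biosynthesis, energy metabolism /
#' catabolic diversity, siderophore biosynthesis, exopolysaccharide
#' biosynthesis) from pathway presence calls, auxotrophy count from an
#' FBA biosynthesis scan, and the rich-medium growth rate.
#'
#' @param model the isolate's \linkS4class{MetabolicModel} with
#'   \code{genome_size_bp} and \code{rrna_copies} annotations.
#' @param calls pathway presence calls covering the isolate
#'   (\code{\link{callPathways}}).
#' @param definitions pathway definitions with a \code{category} column.
#' @param growthRate measured or simulated growth rate in rich medium
#'   (1/h).
#' @param minimalMedium medium for the auxotrophy scan.
#' @param biomassComponents cytosolic biomass precursors to scan.
#' @param categories named list mapping trait names to pathway categories;
#'   defaults to the MetaCyc-style category labels.
#' @return one-row data.frame of \code{IsolateTraits}.
#' @export
computeTraits <- function(model, calls, definitions, growthRate,
                          minimalMedium = NULL, biomassComponents = character(),
                          categories = list(
                            antibiotic = "Antibiotic-Biosynthesis",
                            energy = "Energy-Metabolism",
                            siderophore = "Siderophores-Biosynthesis",
                            eps = "EPS")) {
  ann <- model@annotations
  for (f in c("genome_size_bp", "rrna_copies"))
    if (is.null(ann[[f]]))
      stop("isolate '", model@id, "' lacks annotation '", f, "'")
  mine <- calls[calls$genome_id == model@id & calls$present, ]
  cat_of <- stats::setNames(definitions$category, definitions$pathway_id)
  countCat <- function(category)
    sum(cat_of[mine$pathway_id] == category, na.rm = TRUE)
  aux <- if (!is.null(minimalMedium) && length(biomassComponents))
    length(scanAuxotrophies(model, minimalMedium, biomassComponents)) else 0L
  data.frame(
    isolate_id = model@id,
    genome_size = as.numeric(ann$genome_size_bp),
    antibiotic_pathways = countCat(categories$antibiotic),
    catabolic_diversity = countCat(categories$energy),
    siderophore_pathways = countCat(categories$siderophore),
    auxotrophies = aux,
    growth_rate = growthRate,
    rrna_copies = as.numeric(ann$rrna_copies),
    eps_pathways = countCat(categories$eps),
    stringsAsFactors = FALSE)
}

# quartile membership with inclusive boundaries (rank-based)
inUpperQuartile <- function(x) x >= stats::quantile(x, 0.75)
inLowerQuartile <- function(x) x <= stats::quantile(x, 0.25)

#' Score adaptive strategies (competitive / stress-tolerant / ruderal)
#'
#' Universal adaptive strategy theory scoring over a cohort of isolates.
#' Each strategy has a fixed set of criteria; an isolate earns one point
#' per criterion when its trait value falls in the strategy-favourable
#' quartile of the cohort (for growth rate, above/below the cohort mean):
#' \itemize{
#'   \item Competitive (4): upper quartile of genome size, antibiotic
#'     pathways, catabolic diversity, siderophore pathways.
#'   \item Stress-tolerant (4): upper quartile of auxotrophies and EPS
#'     pathways, lower quartile of rRNA copies, growth below the mean.
#'   \item Ruderal (3): growth above the mean, upper quartile of rRNA
#'     copies, lower quartile of catabolic diversity.
#' }
#' Scores are scaled by the number of criteria per strategy (4/4/3) into
#' [0, 1]; the assigned strategy is the argmax, with exact ties (two- or
#' three-way) giving "mixed". Quartile boundaries are inclusive
#' (value <= Q1 counts as lower, >= Q3 as upper), making the scoring
#' invariant under monotone rescaling of any trait.
#'
#' @param cohort data.frame of isolate traits, one row per isolate (see
#'   \code{\link{computeTraits}}); needs >= 4 isolates so quartiles are
#'   defined.
#' @return data.frame (isolate_id, c_score, s_score, r_score, assigned).
#' @export
scoreStrategies <- function(cohort) {
  need <- c("isolate_id", "genome_size", "antibiotic_pathways",
            "catabolic_diversity", "siderophore_pathways", "auxotrophies",
            "growth_rate", "rrna_copies", "eps_pathways")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort misses trait columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(cohort) < 4)
    stop("cohort must have >= 4 isolates for quartile-based scoring")
  gmean <- mean(cohort$growth_rate)
  cpts <- inUpperQuartile(cohort$genome_size) +
    inUpperQuartile(cohort$antibiotic_pathways) +
    inUpperQuartile(cohort$catabolic_diversity) +
    inUpperQuartile(cohort$siderophore_pathways)
  spts <- inUpperQuartile(cohort$auxotrophies) +
    inUpperQuartile(cohort$eps_pathways) +
    inLowerQuartile(cohort$rrna_copies) +
    (cohort$growth_rate < gmean)
  rpts <- (cohort$growth_rate > gmean) +
    inUpperQuartile(cohort$rrna_copies) +
    inLowerQuartile(cohort$catabolic_diversity)
  sc <- cbind(C = cpts / 4, S = spts / 4, R = rpts / 3)
  assigned <- apply(sc, 1, function(v) {
    top <- max(v)
    winners <- names(v)[v >= top - 1e-12]
    if (length(winners) > 1) "mixed" else winners
  })
  data.frame(isolate_id = cohort$isolate_id,
             c_score = sc[, "C"], s_score = sc[, "S"], r_score = sc[, "R"],
             assigned = assigned, stringsAsFactors = FALSE)
}

#' Strategy-versus-colonization statistics
#'
#' Two statistics relating adaptive strategies to a colonization
#' phenotype (bacterial load): a two-sided Wilcoxon rank-sum test of
#' ruderal isolates against all others, and the Spearman correlation of
#' load with the isolate's own top strategy score within the competitive
#' and stress-tolerant subset.
#'
#' @param scores data.frame from \code{\link{scoreStrategies}}.
#' @param loads named numeric vector isolate -> bacterial load.
#' @return list with \code{wilcoxon_p}, \code{spearman_rho},
#'   \code{spearman_p} (\code{NA} when degenerate, e.g. identical loads).
#' @export
strategyPhenotypeTests <- function(scores, loads) {
  loads <- loads[scores$isolate_id]
  if (anyNA(loads)) stop("loads must cover every scored isolate")
  rud <- scores$assigned == "R"
  if (sum(rud) < 2 || sum(!rud) < 2)
    stop("need >= 2 isolates per group (ruderal vs others)")
  w <- wilcoxonRankSum(loads[rud], loads[!rud])
  cs <- scores$assigned %in% c("C", "S")
  topscore <- pmax(scores$c_score, scores$s_score)[cs]
  if (sum(cs) >= 3 && stats::sd(loads[cs]) > 0 && stats::sd(topscore) > 0) {
    ct <- suppressWarnings(
      stats::cor.test(loads[cs], topscore, method = "spearman"))
    rho <- unname(ct$estimate); sp <- ct$p.value
  } else {
    rho <- NA_real_; sp <- NA_real_
  }
  list(wilcoxon_p = w$p, spearman_rho = rho, spearman_p = sp)
}
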