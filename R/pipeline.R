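#' @include fba.R community.R pathways.R diversity.R biolog.R uast.R stats.R
NULL

pipelineDefaults <- function() list(
  bitscore = 50, conservative_bitscore = 150, coverage = 0.75,
  fold_change_cutoff = 1.0, eps = 1e-6, coupling = 400,
  nperm = 999, nboot = 100, nrandom = 100, kmeans_k = 7, seed = 1)

validatePipelineConfig <- function(config) {
  cfg <- utils::modifyList(pipelineDefaults(), config)
  chk <- function(ok, what) if (!ok) stop("invalid config: ", what)
  chk(cfg$bitscore >= 0, "bitscore must be >= 0")
  chk(cfg$conservative_bitscore >= cfg$bitscore,
      "conservative_bitscore must be >= bitscore")
  chk(cfg$coverage >= 0 && cfg$coverage <= 1, "coverage must be in [0,1]")
  chk(cfg$eps > 0 && cfg$eps < 1, "eps must be in (0,1)")
  chk(cfg$coupling >= 0, "coupling must be >= 0")
  chk(cfg$nperm >= 99, "nperm must be >= 99")
  chk(cfg$nrandom >= 19, "nrandom must be >= 19")
  chk(cfg$kmeans_k >= 2, "kmeans_k must be >= 2")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
      "seed must be an integer")
  cfg
}

#' Run the full analysis pipeline
#'
#' Wires the stages end to end on user-supplied (or synthetic) inputs:
#' pathway presence inference from hit tables, model curation by
#' gap-filling where a universal pool is given, FBA growth and
#' utilizability screens, the pairwise interaction screen,
#' metabolic-versus-phylogenetic similarity, BIOLOG fold-change analysis
#' with model agreement, adaptive-strategy scoring, and trait-phenotype
#' association. Stages whose inputs are absent from the config are
#' skipped. Every output, a config snapshot and a log are written into
#' \code{outDir}; reruns with the same config and seed are
#' reproducible.
#'
#' @param config named list or path of a YAML file. Recognised input
#'   entries: \code{models} (directory of tabular models or vector of
#'   paths), \code{medium} (CSV), \code{hits} (TSV), \code{pathways}
#'   (TSV), \code{fasta} (16S), \code{plate} (CSV), \code{traits} (CSV),
#'   \code{phenotype} (CSV with isolate_id + value columns), plus the
#'   thresholds \code{bitscore}, \code{conservative_bitscore},
#'   \code{coverage}, \code{fold_change_cutoff}, \code{eps},
#'   \code{coupling}, \code{nperm}, \code{nboot}, \code{nrandom},
#'   \code{kmeans_k}, \code{seed}.
#' @param outDir output directory, created if needed.
#' @return (invisibly) a list of stage results; files in \code{outDir}.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outDir, "pipeline.log")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                               "\n", file = logf, append = TRUE)
  yaml::write_yaml(cfg, file.path(outDir, "config_snapshot.yaml"))
  res <- list(config = cfg)
  stage <- function(name, expr) {
    logline("stage", name, "start")
    out <- tryCatch(expr, error = function(e) {
      logline("stage", name, "FAILED:", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logline("stage", name, "done")
    out
  }
  models <- NULL
  if (!is.null(cfg$models)) {
    paths <- cfg$models
    if (length(paths) == 1 && dir.exists(paths) &&
        !file.exists(file.path(paths, "reactions.tsv")))
      paths <- list.dirs(paths, recursive = FALSE)
    models <- stage("read_models", lapply(paths, readModel))
  }
  medium <- if (!is.null(cfg$medium)) stage("read_medium",
                                            readMedium(cfg$medium))
  if (!is.null(cfg$hits) && !is.null(cfg$pathways)) {
    hits <- readHitTable(cfg$hits)
    defs <- readPathways(cfg$pathways)
    res$presence <- stage("pathway_inference",
      callPathways(hits, defs, cfg$bitscore, cfg$conservative_bitscore,
                   cfg$coverage))
    utils::write.csv(res$presence,
                     file.path(outDir, "pathway_presence.csv"),
                     row.names = FALSE)
  }
  if (!is.null(models) && !is.null(medium)) {
    res$growth <- stage("fba_growth", data.frame(
      model = vapply(models, modelId, ""),
      growth = vapply(models, function(m)
        solveFBA(m, medium)$objective, 0)))
    utils::write.csv(res$growth, file.path(outDir, "growth.csv"),
                     row.names = FALSE)
    if (length(models) >= 2) {
      res$interactions <- stage("interactions",
        interactionScreen(models, medium, cfg$coupling, cfg$eps))
      utils::write.csv(res$interactions,
                       file.path(outDir, "interactions.csv"),
                       row.names = FALSE)
      jsonlite::write_json(as.list(attr(res$interactions, "fractions")),
                           file.path(outDir, "interaction_fractions.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(cfg$fasta) && !is.null(res$presence)) {
    res$diversity <- stage("diversity", {
      sim16 <- pairwiseIdentity16S(cfg$fasta)
      V <- metabolicVectors(res$presence)
      shared <- intersect(rownames(sim16), rownames(V))
      ms <- metabolicSimilarity(V[shared, , drop = FALSE])
      corr <- correlateMatrices(sim16[shared, shared],
                                ms$similarity[shared, shared],
                                nPerm = cfg$nperm, seed = cfg$seed)
      tree <- clusterWithBootstrap(V[shared, , drop = FALSE],
                                   nBoot = cfg$nboot, seed = cfg$seed)
      writeNewick(tree, file.path(outDir, "metabolic_tree.nwk"))
      jsonlite::write_json(corr, file.path(outDir, "matrix_correlation.json"),
                           auto_unbox = TRUE, digits = NA)
      list(correlation = corr, tree = tree)
    })
  }
  if (!is.null(cfg$plate)) {
    res$biolog <- stage("biolog", {
      plate <- readPlate(cfg$plate)
      prof <- foldChange(plate)
      km <- substrateKmeans(prof, k = min(cfg$kmeans_k, ncol(prof)),
                            seed = cfg$seed)
      utils::write.csv(as.data.frame(prof),
                       file.path(outDir, "fold_changes.csv"))
      list(profile = prof, clusters = km,
           calls = binarizeProfile(prof, cfg$fold_change_cutoff))
    })
  }
  if (!is.null(cfg$traits)) {
    traits <- readTraits(cfg$traits)
    res$strategies <- stage("uast", scoreStrategies(traits))
    utils::write.csv(res$strategies, file.path(outDir, "strategies.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cfg$phenotype) && !is.null(res$presence)) {
    res$association <- stage("association", {
      ph <- utils::read.csv(cfg$phenotype, stringsAsFactors = FALSE)
      V <- metabolicVectors(res$presence)
      shared <- intersect(ph$isolate_id, rownames(V))
      spearmanPerm(V[shared, , drop = FALSE],
                   stats::setNames(ph$value, ph$isolate_id)[shared],
                   nRandom = cfg$nrandom, seed = cfg$seed)
    })
    utils::write.csv(res$association, file.path(outDir, "association.csv"),
                     row.names = FALSE)
  }
  logline("pipeline complete")
  invisible(res)
}
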