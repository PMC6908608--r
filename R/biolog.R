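#' @include diversity.R
NULL

#' BIOLOG fold-change profiles
#'
#' Substrate reduction in a BIOLOG GN2 phenotype plate is summarised as
#' the fold change of the tetrazolium dye absorbance between inoculation
#' and the 46 h endpoint: per replicate,
#' \code{FC_raw(s) = (OD_t46 - OD_t0) / OD_t0}, and the fold change of the
#' water control well is subtracted as background,
#' \code{FC(s) = FC_raw(s) - FC_raw(water)}. Replicates are averaged.
#' Note this subtracts the water fold-change, not the raw water OD; set
#' \code{background = "raw_od"} for the literal OD-subtraction variant.
#'
#' @param plate long-format plate data from \code{\link{readPlate}}:
#'   strain, substrate, replicate, time_min, od.
#' @param t0_min,t46_min the two timepoints used (minutes; default 0 and
#'   2760 = 46 h).
#' @param water_id substrate id of the water control (default from the
#'   plate attribute, else "water").
#' @param background "fold_change" (default) or "raw_od".
#' @return numeric matrix strains x substrates of mean background-corrected
#'   fold changes; the water well itself is excluded.
#' @examples
#' # OD 0.1 -> 0.5 with water fold-change 0.2 gives (0.5-0.1)/0.1 - 0.2 = 3.8
#' @export
foldChange <- function(plate, t0_min = 0, t46_min = 2760,
                       water_id = NULL,
                       background = c("fold_change", "raw_od")) {
  background <- match.arg(background)
  if (is.null(water_id))
    water_id <- if (!is.null(attr(plate, "water_id")))
      attr(plate, "water_id") else "water"
  if (!water_id %in% plate$substrate)
    stop("no '", water_id, "' control well in plate")
  odAt <- function(sub, tm) {
    v <- sub$od[sub$time_min == tm]
    if (length(v) != 1)
      stop("expected exactly one OD at t=", tm, " min for strain '",
           sub$strain[1], "', substrate '", sub$substrate[1],
           "', replicate ", sub$replicate[1], " (found ", length(v), ")")
    v
  }
  strains <- sort(unique(plate$strain))
  substrates <- sort(setdiff(unique(plate$substrate), water_id))
  M <- matrix(NA_real_, length(strains), length(substrates),
              dimnames = list(strains, substrates))
  for (st in strains) {
    ps <- plate[plate$strain == st, ]
    reps <- sort(unique(ps$replicate))
    fcs <- matrix(NA_real_, length(reps), length(substrates))
    for (ri in seq_along(reps)) {
      pr <- ps[ps$replicate == reps[ri], ]
      w <- pr[pr$substrate == water_id, ]
      if (nrow(w) == 0)
        stop("strain '", st, "' replicate ", reps[ri],
             " has no water control well")
      w0 <- odAt(w, t0_min); w46 <- odAt(w, t46_min)
      if (w0 == 0) stop("OD at t0 is zero (water well, strain '", st, "')")
      bg <- if (background == "fold_change") (w46 - w0) / w0 else w46
      for (si in seq_along(substrates)) {
        sub <- pr[pr$substrate == substrates[si], ]
        if (nrow(sub) == 0) next
        o0 <- odAt(sub, t0_min); o46 <- odAt(sub, t46_min)
        if (o0 == 0) stop("OD at t0 is zero (strain '", st,
                          "', substrate '", substrates[si], "')")
        fcs[ri, si] <- (o46 - o0) / o0 - bg
      }
    }
    M[st, ] <- colMeans(fcs, na.rm = TRUE)
  }
  M
}

#' k-means clustering of substrates by fold-change profile
#'
#' Clusters substrates on their across-strain fold-change vectors with
#' k-means, best of \code{restarts} random initialisations by
#' within-cluster sum of squares. Deterministic given the seed.
#'
#' @param profile strains x substrates fold-change matrix from
#'   \code{\link{foldChange}}.
#' @param k number of clusters (default 7, the usual choice for GN2
#'   substrate guilds).
#' @param restarts random initialisations (default 1000).
#' @param seed RNG seed.
#' @return named integer vector substrate -> cluster id, with the
#'   \code{kmeans} fit in attribute \code{"fit"}.
#' @export
substrateKmeans <- function(profile, k = 7, restarts = 1000, seed = 1) {
  X <- t(profile)
  if (nrow(X) < k) stop("need at least k substrates")
  if (nrow(X) == k) {   # singleton clusters, SSE 0 by definition
    fit <- list(cluster = stats::setNames(seq_len(k), rownames(X)),
                centers = X, tot.withinss = 0)
    return(structure(stats::setNames(seq_len(k), rownames(X)), fit = fit))
  }
  set.seed(seed)
  fit <- stats::kmeans(X, centers = k, nstart = restarts, iter.max = 100)
  structure(stats::setNames(fit$cluster, rownames(X)), fit = fit)
}

#' Strain dendrogram from fold-change profiles
#'
#' Ward clustering (\code{ward.D2}) on Euclidean distances between strain
#' fold-change profiles, with bootstrap node support over substrates
#' (default 100 resamples).
#'
#' @inheritParams substrateKmeans
#' @param nBoot bootstrap replicates (0 skips supports).
#' @return list with \code{hclust}, \code{support}, \code{phylo} as in
#'   \code{\link{clusterWithBootstrap}}.
#' @export
strainDendrogram <- function(profile, nBoot = 100, seed = 1) {
  if (nrow(profile) < 3) stop("need at least 3 strains")
  bs <- bootstrapSupport(profile, "ward.D2", nBoot, seed)
  list(hclust = bs$hclust, support = bs$support,
       phylo = ape::as.phylo(bs$hclust))
}

#' Agreement between experimental usage calls and model predictions
#'
#' Overlap between binary substrate-usage calls (e.g. fold change above a
#' threshold) and in-silico utilizability predictions over the shared
#' substrate universe: (TP + TN) / total compared, per strain and overall.
#' Substrates present in only one of the two matrices are dropped with a
#' message. Symmetric in its two arguments.
#'
#' @param calls logical matrix strains x substrates (experimental).
#' @param predictions logical matrix strains x substrates (model).
#' @return list with \code{overall} and named \code{per_strain} overlap
#'   fractions.
#' @export
modelAgreement <- function(calls, predictions) {
  shared_sub <- intersect(colnames(calls), colnames(predictions))
  shared_str <- intersect(rownames(calls), rownames(predictions))
  dropped <- setdiff(union(colnames(calls), colnames(predictions)),
                     shared_sub)
  if (length(dropped))
    message("modelAgreement: dropping unshared substrates: ",
            paste(dropped, collapse = ", "))
  if (length(shared_sub) == 0 || length(shared_str) == 0)
    stop("no shared substrate/strain universe to compare")
  a <- calls[shared_str, shared_sub, drop = FALSE]
  b <- predictions[shared_str, shared_sub, drop = FALSE]
  agree <- a == b
  list(overall = mean(agree),
       per_strain = apply(agree, 1, mean))
}

#' Binarize a fold-change profile
#'
#' @param profile fold-change matrix.
#' @param threshold positive-call cutoff (default 1.0).
#' @return logical matrix of usage calls.
#' @export
binarizeProfile <- function(profile, threshold = 1.0) profile >= threshold
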