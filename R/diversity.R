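#' @include pathways.R
NULL

#' Pairwise 16S percent identity
#'
#' Global (Needleman-Wunsch) pairwise alignment of 16S rRNA sequences with
#' match +1, mismatch -1, gap opening -2 and gap extension -0.5; identity
#' is the number of matching positions divided by the number of alignment
#' columns including gaps (the \code{"columns"} denominator; use
#' \code{"aligned"} to divide by aligned, non-gap positions instead).
#'
#' @param sequences a \code{Biostrings::DNAStringSet}, or the path of a
#'   FASTA file.
#' @param denominator identity denominator convention.
#' @return symmetric similarity matrix in [0, 1] with unit diagonal.
#' @export
pairwiseIdentity16S <- function(sequences,
                                denominator = c("columns", "aligned")) {
  denominator <- match.arg(denominator)
  if (is.character(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  n <- length(sequences)
  if (n < 2) stop("need at least 2 sequences")
  if (any(Biostrings::width(sequences) == 0)) stop("empty sequence")
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  M <- diag(1, n); dimnames(M) <- list(ids, ids)
  pairs <- which(upper.tri(M), arr.ind = TRUE)
  aln <- Biostrings::pairwiseAlignment(sequences[pairs[, 1]],
    sequences[pairs[, 2]], type = "global", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 0.5)
  nmatch <- Biostrings::nmatch(aln)
  den <- if (denominator == "columns")
    Biostrings::nchar(aln) else    # alignment columns including gaps
    Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  M[pairs] <- M[pairs[, c(2, 1)]] <- nmatch / den
  M
}

#' Binary pathway vectors per isolate
#'
#' Turns pathway presence calls into one binary vector per isolate over a
#' fixed, sorted pathway universe, the representation used for metabolic
#' distance computations.
#'
#' @param calls presence calls from \code{\link{callPathways}} (or any
#'   data.frame with genome_id, pathway_id, present).
#' @return binary matrix isolates x pathways (sorted ids both ways).
#' @export
metabolicVectors <- function(calls) {
  genomes <- sort(unique(calls$genome_id))
  pathways <- sort(unique(calls$pathway_id))
  V <- matrix(0L, length(genomes), length(pathways),
              dimnames = list(genomes, pathways))
  V[cbind(match(calls$genome_id, genomes),
          match(calls$pathway_id, pathways))] <- as.integer(calls$present)
  V
}

#' Metabolic similarity and distance between pathway vectors
#'
#' Distance is Euclidean; "metabolic identity" between two isolates is the
#' simple matching coefficient, the fraction of pathways on whose
#' presence/absence the two isolates agree.
#'
#' @param vectors binary matrix isolates x pathways
#'   (\code{\link{metabolicVectors}}).
#' @return list with \code{similarity} (symmetric matrix, unit diagonal)
#'   and \code{distance} (a \code{dist} of Euclidean distances).
#' @export
metabolicSimilarity <- function(vectors) {
  n <- nrow(vectors); p <- ncol(vectors)
  S <- diag(1, n); dimnames(S) <- list(rownames(vectors), rownames(vectors))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      S[i, j] <- S[j, i] <- mean(vectors[i, ] == vectors[j, ])
    }
  }
  list(similarity = S, distance = stats::dist(vectors))
}

#' Correlate two similarity matrices (Mantel-style)
#'
#' Spearman rank correlation between the upper triangles of two
#' similarity matrices over the same ids, with a permutation p-value
#' obtained by simultaneously permuting rows and columns of the second
#' matrix (Mantel scheme; pairwise entries are not exchangeable, whole-id
#' permutation preserves the dependence structure). The p-value uses the
#' add-one convention (1 + exceedances) / (nPerm + 1).
#'
#' @param a,b symmetric similarity (or distance) matrices with identical
#'   ids.
#' @param nPerm number of permutations (>= 99).
#' @param seed RNG seed.
#' @param alternative "two.sided" (default) or "greater" (positive
#'   association only).
#' @return list with \code{rho} and \code{p}.
#' @export
correlateMatrices <- function(a, b, nPerm = 999, seed = 1,
                              alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (nPerm < 99) stop("nPerm must be >= 99")
  if (!identical(dim(a), dim(b)))
    stop("matrices must have identical dimensions")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("matrices must be over the same ids in the same order")
  ut <- upper.tri(a)
  obs <- stats::cor(a[ut], b[ut], method = "spearman")
  n <- nrow(a)
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(i) {
    p <- sample.int(n)
    stats::cor(a[ut], b[p, p][ut], method = "spearman")
  }, 0)
  p <- if (alternative == "two.sided")
    (1 + sum(abs(null) >= abs(obs))) / (nPerm + 1)
  else (1 + sum(null >= obs)) / (nPerm + 1)
  list(rho = obs, p = p)
}

# Leaf sets of every internal node of an hclust, as sorted label strings.
nodeLeafSets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    leaves <- c()
    for (k in kids)
      leaves <- c(leaves, if (k < 0) hc$labels[-k] else sets[[k]])
    sets[[i]] <- sort(leaves)
  }
  vapply(sets, paste, "", collapse = "\r")
}

# Column-bootstrap support for a hierarchical clustering of the rows of x.
bootstrapSupport <- function(x, linkage, nBoot, seed,
                             distfun = function(m) stats::dist(m)) {
  hc <- stats::hclust(distfun(x), method = linkage)
  if (nBoot <= 0) return(list(hclust = hc, support = NULL))
  ref <- nodeLeafSets(hc)
  hits <- stats::setNames(rep(0, length(ref)), ref)
  set.seed(seed)
  for (b in seq_len(nBoot)) {
    cols <- sample.int(ncol(x), replace = TRUE)
    hb <- tryCatch(stats::hclust(distfun(x[, cols, drop = FALSE]),
                                 method = linkage),
                   error = function(e) NULL)
    if (is.null(hb)) next
    found <- nodeLeafSets(hb)
    hit <- ref %in% found
    hits[hit] <- hits[hit] + 1
  }
  list(hclust = hc, support = unname(hits / nBoot))
}

#' Hierarchical clustering of pathway vectors with bootstrap support
#'
#' Average-linkage (UPGMA) clustering on Euclidean distances between
#' binary pathway vectors. Node support is the plain bootstrap proportion:
#' the fraction of column resamples (pathways drawn with replacement) in
#' which the node's exact leaf set recurs.
#'
#' @param vectors binary matrix isolates x pathways.
#' @param nBoot bootstrap replicates (default 1000; 0 skips supports).
#' @param linkage an \code{hclust} method, default "average".
#' @param seed RNG seed.
#' @return list with \code{hclust}, \code{support} (per internal node in
#'   merge order, NULL when nBoot = 0) and \code{phylo}, an
#'   \code{ape::phylo} tree whose node labels carry the supports.
#' @export
clusterWithBootstrap <- function(vectors, nBoot = 1000, linkage = "average",
                                 seed = 1) {
  if (nrow(vectors) < 3) stop("need at least 3 isolates to cluster")
  bs <- bootstrapSupport(vectors, linkage, nBoot, seed)
  phy <- ape::as.phylo(bs$hclust)
  if (!is.null(bs$support)) {
    # hclust merge order -> phylo internal node order
    phy$node.label <- rep(NA_character_, phy$Nnode)
    ref <- nodeLeafSets(bs$hclust)
    for (nd in seq_len(phy$Nnode)) {
      tips <- ape::extract.clade(phy, nd + ape::Ntip(phy))$tip.label
      key <- paste(sort(tips), collapse = "\r")
      hit <- match(key, ref)
      if (!is.na(hit))
        phy$node.label[nd] <- format(round(bs$support[hit], 3))
    }
  }
  list(hclust = bs$hclust, support = bs$support, phylo = phy)
}

#' Write a dendrogram as newick
#'
#' @param tree result of \code{\link{clusterWithBootstrap}} (or an
#'   \code{ape::phylo}).
#' @param path output file.
#' @export
writeNewick <- function(tree, path) {
  phy <- if (inherits(tree, "phylo")) tree else tree$phylo
  ape::write.tree(phy, file = path)
  invisible(path)
}
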