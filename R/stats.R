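#' @include model_io.R
NULL

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Classic step-up procedure: with ordered p-values p_(1) <= ... <= p_(m),
#' q_(i) = min_{j >= i} p_(j) * m / j, returned in the original order.
#'
#' @param pvals numeric p-values in [0, 1].
#' @return q-values of the same length and order.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
benjaminiHochberg <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  m <- length(pvals)
  if (m == 0) return(numeric())
  o <- order(pvals)
  q <- (m / seq_len(m)) * pvals[o]
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Wilcoxon rank-sum test (exact or normal approximation)
#'
#' Two-sided rank-sum test. For combined sample sizes up to
#' \code{exactLimit} the null distribution is enumerated exactly over all
#' C(n, n_x) group assignments of the (mid-)ranks, counting arrangements
#' whose rank sum deviates from its expectation at least as much as
#' observed; beyond that a normal approximation with tie correction is
#' used.
#'
#' @param x,y numeric samples (both nonempty).
#' @param mode "auto" (default; exact when n_x + n_y <= exactLimit),
#'   "exact", or "normal".
#' @param exactLimit size cutoff for enumeration (default 20).
#' @return list with \code{statistic} (rank sum of x, W form:
#'   sum of x ranks minus its minimum) and two-sided \code{p}.
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p  # exactly 0.1
#' @export
wilcoxonRankSum <- function(x, y, mode = c("auto", "exact", "normal"),
                            exactLimit = 20) {
  mode <- match.arg(mode)
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both groups must be nonempty")
  n <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  EW <- nx * (n + 1) / 2
  if (mode == "auto") mode <- if (n <= exactLimit) "exact" else "normal"
  if (mode == "exact") {
    combs <- utils::combn(n, nx)
    sums <- colSums(matrix(r[combs], nrow = nx))
    p <- mean(abs(sums - EW) >= abs(W - EW) - 1e-12)
  } else {
    ties <- table(r)
    sdW <- sqrt(nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
    if (sdW == 0) { p <- 1.0 } else {
      z <- (W - EW - 0.5 * sign(W - EW)) / sdW   # continuity correction
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(statistic = W - nx * (nx + 1) / 2, p = min(p, 1))
}

#' Spearman trait-phenotype association with a permutation null
#'
#' For every binary metabolic trait, computes the Spearman correlation
#' with a numeric phenotype and an empirical p-value against a null of
#' randomly generated features: by default \code{nRandom} prevalence-
#' preserving permutations of the trait column
#' (\code{null = "permute"}); \code{null = "bernoulli"} draws random
#' features with matched prevalence instead. The permutation p uses the
#' add-one convention p = (1 + #\{|rho_null| >= |rho|\}) / (nRandom + 1),
#' so p is never zero; q-values are Benjamini-Hochberg over traits.
#' Constant trait columns carry no information and are dropped with a
#' message.
#'
#' @param traits binary matrix isolates x traits (0/1).
#' @param phenotype numeric vector aligned with the rows of traits.
#' @param nRandom number of random features per trait (default 100; for
#'   finer p-value granularity use 999 or more).
#' @param seed RNG seed.
#' @param null "permute" (default) or "bernoulli".
#' @return data.frame (trait_id, rho, p_perm, q), ordered as the input
#'   columns.
#' @export
spearmanPerm <- function(traits, phenotype, nRandom = 100, seed = 1,
                         null = c("permute", "bernoulli")) {
  null <- match.arg(null)
  traits <- as.matrix(traits)
  if (!all(traits %in% c(0, 1)))
    stop("traits must be binary 0/1")
  if (nrow(traits) != length(phenotype))
    stop("traits and phenotype must cover the same isolates")
  if (stats::sd(phenotype) == 0) stop("phenotype is constant")
  keep <- apply(traits, 2, function(v) stats::sd(v) > 0)
  if (any(!keep))
    message("spearmanPerm: dropping constant traits: ",
            paste(colnames(traits)[!keep], collapse = ", "))
  traits <- traits[, keep, drop = FALSE]
  n <- nrow(traits)
  set.seed(seed)
  rows <- lapply(colnames(traits), function(tid) {
    tr <- traits[, tid]
    rho <- stats::cor(tr, phenotype, method = "spearman")
    nullr <- vapply(seq_len(nRandom), function(i) {
      f <- if (null == "permute") sample(tr) else
        stats::rbinom(n, 1, mean(tr))
      if (stats::sd(f) == 0) 0 else
        stats::cor(f, phenotype, method = "spearman")
    }, 0)
    p <- (1 + sum(abs(nullr) >= abs(rho) - 1e-12)) / (nRandom + 1)
    data.frame(trait_id = tid, rho = rho, p_perm = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- benjaminiHochberg(out$p_perm)
  rownames(out) <- NULL
  out
}
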