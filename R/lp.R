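#' Solve a dense linear program with bounded variables
#'
#' Minimises (or maximises) \code{obj \%*\% x} subject to general linear
#' constraints \code{A x (=, <=, >=) rhs} and box constraints
#' \code{lb <= x <= ub}, using a two-phase primal simplex with the
#' upper-bounding technique. Dantzig pricing with a Bland's-rule fallback
#' guarantees termination on degenerate problems.
#'
#' This is the numerical workhorse behind all flux-balance computations in
#' the package. Problem sizes are small (tens to a few hundred variables),
#' so a dense implementation with fresh basis factorisations each iteration
#' is both fast enough and numerically transparent.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense constraint matrix (m x n).
#' @param rhs numeric right-hand sides (length m).
#' @param sense character vector of "=", "<=" or ">=" per row.
#' @param lb,ub variable bounds; each variable needs at least one finite
#'   bound. Use \code{Inf}/\code{-Inf} for one-sided boxes.
#' @param maximize logical; maximise instead of minimise.
#' @param tol feasibility/optimality tolerance.
#' @return list with \code{status} ("optimal", "infeasible", "unbounded",
#'   "iteration_limit"), \code{objective}, and the primal solution \code{x}.
#' @keywords internal
lpSolveDense <- function(obj, A, rhs, sense, lb, ub, maximize = FALSE,
                         tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n0 <- ncol(A)
  stopifnot(length(obj) == n0, length(rhs) == m, length(sense) == m,
            length(lb) == n0, length(ub) == n0, all(lb <= ub + tol))
  cvec <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # slack columns for inequalities
  nslack <- sum(sense != "=")
  if (nslack > 0) {
    Sl <- matrix(0, m, nslack)
    j <- 0
    for (i in seq_len(m)) {
      if (sense[i] == "=") next
      j <- j + 1
      Sl[i, j] <- if (sense[i] == "<=") 1 else -1
    }
    A <- cbind(A, Sl)
    cvec <- c(cvec, rep(0, nslack))
    lb <- c(lb, rep(0, nslack))
    ub <- c(ub, rep(Inf, nslack))
  }
  n <- ncol(A)

  # initial nonbasic placement at a finite bound
  x <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  resid <- rhs - as.numeric(A %*% x)

  # artificial columns carrying the initial residual
  Art <- matrix(0, m, m)
  sgn <- ifelse(resid >= 0, 1, -1)
  for (i in seq_len(m)) Art[i, i] <- sgn[i]
  A <- cbind(A, Art)
  lb <- c(lb, rep(0, m)); ub <- c(ub, rep(Inf, m))
  x <- c(x, abs(resid))
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, n + m)   # meaningful for nonbasic vars only

  runPhase <- function(cost, basis, x, at_upper, lbv, ubv) {
    nn <- length(cost)
    maxit <- 200L + 40L * (nn + m)
    bland_after <- 20L + 10L * (nn + m)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > maxit) return(list(status = "iteration_limit", basis = basis,
                                    x = x, at_upper = at_upper))
      nb <- setdiff(seq_len(nn), basis)
      B <- A[, basis, drop = FALSE]
      xN <- x[nb]
      xB <- tryCatch(solve(B, rhs - A[, nb, drop = FALSE] %*% xN),
                     error = function(e) NULL)
      if (is.null(xB)) return(list(status = "singular", basis = basis,
                                   x = x, at_upper = at_upper))
      x[basis] <- as.numeric(xB)
      y <- solve(t(B), cost[basis])
      r <- cost[nb] - as.numeric(crossprod(A[, nb, drop = FALSE], y))
      cand_up <- !at_upper[nb] & r < -tol & is.finite(lbv[nb])
      cand_dn <- at_upper[nb] & r > tol
      # nonbasic free vars (neither bound finite) can move either way
      free <- !is.finite(lbv[nb]) & !is.finite(ubv[nb])
      cand_up <- cand_up | (free & r < -tol)
      cand <- which(cand_up | cand_dn)
      if (length(cand) == 0)
        return(list(status = "optimal", basis = basis, x = x,
                    at_upper = at_upper))
      if (iter > bland_after) {
        pick <- cand[which.min(nb[cand])]
      } else {
        pick <- cand[which.max(abs(r[cand]))]
      }
      j <- nb[pick]
      sigma <- if (at_upper[j]) -1 else 1     # direction of change of x_j
      d <- as.numeric(solve(B, A[, j]))       # xB changes by -sigma*d*t
      # ratio test
      t_best <- ubv[j] - lbv[j]
      if (!is.finite(t_best)) t_best <- Inf
      leave <- 0L
      leave_to_upper <- FALSE
      for (i in seq_len(m)) {
        di <- sigma * d[i]
        bi <- basis[i]
        if (di > tol) {
          lim <- (x[bi] - lbv[bi]) / di
          if (!is.na(lim) && is.finite(lim)) {
            if (lim < (if (is.finite(t_best)) t_best - tol * max(1, abs(t_best)) else Inf)) {
              t_best <- max(lim, 0); leave <- i; leave_to_upper <- FALSE
            } else if (lim <= t_best + tol && leave > 0L &&
                       iter > bland_after && bi < basis[leave]) {
              leave <- i; leave_to_upper <- FALSE   # Bland tie-break
            }
          }
        } else if (di < -tol) {
          lim <- (ubv[bi] - x[bi]) / (-di)
          if (!is.na(lim) && is.finite(lim)) {
            if (lim < (if (is.finite(t_best)) t_best - tol * max(1, abs(t_best)) else Inf)) {
              t_best <- max(lim, 0); leave <- i; leave_to_upper <- TRUE
            } else if (lim <= t_best + tol && leave > 0L &&
                       iter > bland_after && bi < basis[leave]) {
              leave <- i; leave_to_upper <- TRUE
            }
          }
        }
      }
      if (!is.finite(t_best))
        return(list(status = "unbounded", basis = basis, x = x,
                    at_upper = at_upper))
      if (leave == 0L) {
        # bound flip of the entering variable
        x[j] <- x[j] + sigma * t_best
        at_upper[j] <- !at_upper[j]
      } else {
        bl <- basis[leave]
        x[j] <- x[j] + sigma * t_best
        x[basis] <- x[basis] - sigma * d * t_best
        x[bl] <- if (leave_to_upper) ubv[bl] else lbv[bl]
        at_upper[bl] <- leave_to_upper
        basis[leave] <- j
        at_upper[j] <- FALSE
      }
    }
  }

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(1, m))
  p1 <- runPhase(c1, basis, x, at_upper, lb, ub)
  if (!p1$status %in% c("optimal"))
    return(list(status = if (p1$status == "unbounded") "infeasible" else p1$status,
                objective = NA_real_, x = rep(NA_real_, n0)))
  art_sum <- sum(p1$x[n + seq_len(m)])
  if (art_sum > 1e-6)
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n0)))
  # pin artificials at zero for phase 2
  lb[n + seq_len(m)] <- 0; ub[n + seq_len(m)] <- 0
  x <- p1$x; x[n + seq_len(m)] <- pmin(x[n + seq_len(m)], 0) * 0
  c2 <- c(cvec, rep(0, m))
  p2 <- runPhase(c2, p1$basis, x, p1$at_upper, lb, ub)
  if (p2$status == "unbounded")
    return(list(status = "unbounded", objective = NA_real_,
                x = rep(NA_real_, n0)))
  if (p2$status != "optimal")
    return(list(status = p2$status, objective = NA_real_,
                x = rep(NA_real_, n0)))
  xs <- p2$x[seq_len(n0)]
  objv <- sum(as.numeric(obj) * xs)
  list(status = "optimal", objective = objv, x = xs)
}
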