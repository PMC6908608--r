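#' @include AllClasses.R fba.R
NULL

#' Dynamic FBA co-culture simulation (well-mixed)
#'
#' Simulates growth of one or more metabolic models sharing a well-mixed
#' pool of extracellular metabolites, with optional extracellular enzyme
#' species (e.g. a secreted sucrose invertase represented as an
#' independent catalytic species). Explicit-Euler loop: at each step every
#' member's uptake bound for pool metabolite m is
#' \code{min(vmax, conc_m / (biomass_total * dt))} (a hard kinetic cap
#' combined with availability rationing, so the pool can never be
#' overdrawn), each member's FBA is solved, biomass is updated as
#' \code{X += mu X dt}, and pools are updated from the realised exchange
#' fluxes and the enzyme conversions (rate \code{rateConstant * abundance},
#' capped by substrate availability). Residual negative concentrations
#' from floating-point arithmetic are clamped to zero and counted.
#'
#' Units: biomass gDW/L, concentrations mM, fluxes mmol/gDW/h, time h.
#' The simulation is fully deterministic.
#'
#' @param members list of \linkS4class{MetabolicModel}s.
#' @param enzymes list of \linkS4class{EnzymeSpecies} (default none).
#' @param initBiomass named numeric, initial biomass per member id (gDW/L).
#' @param initConc named numeric, initial pool concentrations (mM);
#'   metabolites absent from the vector start at 0.
#' @param dt Euler step (h), default 0.05.
#' @param tEnd simulation horizon (h).
#' @param vmax hard uptake cap (mmol/gDW/h), default 10.
#' @return object of class \code{"CocultureTrajectory"}: list with
#'   \code{times}, \code{biomass} (matrix time x member), \code{conc}
#'   (matrix time x metabolite), and a \code{clamps} counter of negative
#'   concentration clamping events.
#' @examples
#' m <- makeChainModel(yield = 0.5, uptake = 10)
#' tr <- monoculture(m, init = 0.01, mediumConc = c(glc_e = 5), tEnd = 10)
#' tail(tr$conc[, "glc_e"], 1)   # glucose nearly depleted
#' @export
simulateCoculture <- function(members, enzymes = list(), initBiomass,
                              initConc, dt = 0.05, tEnd = 12, vmax = 10) {
  stopifnot(dt > 0, tEnd > 0, all(initBiomass >= 0), all(initConc >= 0))
  ids <- vapply(members, modelId, "")
  names(members) <- ids
  if (!all(ids %in% names(initBiomass)))
    stop("initBiomass must name every member")
  # pooled metabolite universe: everything extracellular anywhere
  pool <- unique(c(names(initConc),
    unlist(lapply(members, function(m)
      m@metabolites$id[m@metabolites$compartment == "e"])),
    unlist(lapply(enzymes, function(e) names(e@stoichiometry)))))
  conc <- stats::setNames(rep(0, length(pool)), pool)
  conc[names(initConc)] <- initConc
  X <- stats::setNames(initBiomass[ids], ids)
  # per-member exchange reaction -> metabolite map
  exmap <- lapply(members, function(m) {
    ex <- exchangeReactions(m)
    stats::setNames(vapply(m@stoichiometry[ex], function(s) names(s)[1], ""),
                    ex)
  })
  steps <- ceiling(tEnd / dt)
  times <- seq(0, by = dt, length.out = steps + 1)
  bioM <- matrix(0, steps + 1, length(ids), dimnames = list(NULL, ids))
  concM <- matrix(0, steps + 1, length(pool), dimnames = list(NULL, pool))
  bioM[1, ] <- X; concM[1, ] <- conc
  clamps <- 0L
  for (st in seq_len(steps)) {
    Xtot <- sum(X)
    dconc <- stats::setNames(rep(0, length(pool)), pool)
    for (k in ids) {
      if (X[[k]] <= 0) next
      m <- members[[k]]
      mets <- exmap[[k]]
      avail <- stats::setNames(conc[unname(mets)] / max(Xtot * dt, 1e-12),
                               unname(mets))
      lims <- pmin(avail, vmax)
      lims <- lims[lims > 1e-12]
      med <- Medium("dfba", lims)
      sol <- tryCatch(solveFBA(m, med), error = function(e) NULL)
      mu <- if (!is.null(sol) && sol$status == "optimal")
        max(sol$objective, 0) else 0
      if (!is.null(sol) && sol$status == "optimal") {
        v <- sol$fluxes[names(mets)]
        dconc[mets] <- dconc[mets] + v * X[[k]] * dt
      }
      X[[k]] <- X[[k]] + mu * X[[k]] * dt
    }
    for (e in enzymes) {
      s <- e@stoichiometry
      rate <- e@rateConstant * e@abundance          # mmol/L/h
      subs <- names(s)[s < 0]
      cap <- min(vapply(subs, function(mm)
        (conc[[mm]] + dconc[[mm]]) / (dt * (-s[[mm]])), 0))
      act <- max(min(rate, cap), 0)
      dconc[names(s)] <- dconc[names(s)] + s * act * dt
    }
    conc <- conc + dconc
    neg <- conc < 0
    if (any(neg & conc < -1e-9)) clamps <- clamps + sum(neg & conc < -1e-9)
    conc[neg] <- 0
    bioM[st + 1, ] <- X
    concM[st + 1, ] <- conc
  }
  structure(list(times = times, biomass = bioM, conc = concM,
                 clamps = clamps, steps = steps),
            class = "CocultureTrajectory")
}

#' @rdname simulateCoculture
#' @param member a single \linkS4class{MetabolicModel}.
#' @param init initial biomass (gDW/L).
#' @param mediumConc named initial pool concentrations (mM).
#' @export
monoculture <- function(member, init, mediumConc, dt = 0.05, tEnd = 12,
                        vmax = 10) {
  simulateCoculture(list(member),
                    initBiomass = stats::setNames(init, modelId(member)),
                    initConc = mediumConc, dt = dt, tEnd = tEnd, vmax = vmax)
}

#' @export
print.CocultureTrajectory <- function(x, ...) {
  cat("CocultureTrajectory:", ncol(x$biomass), "member(s),",
      length(x$times), "timepoints over", max(x$times), "h\n")
  fin <- x$biomass[nrow(x$biomass), ]
  cat("  final biomass:", paste(colnames(x$biomass), "=",
                                signif(fin, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Carbon mass-balance audit of a trajectory
#'
#' On fixtures whose metabolites carry carbon atom counts, the total
#' carbon in pools plus carbon fixed in biomass must be conserved over a
#' run. Biomass carbon per unit growth is derived from the biomass
#' reaction: carbon of consumed precursors minus carbon of co-produced
#' byproducts.
#'
#' @param traj a \code{CocultureTrajectory}.
#' @param members the member models of the run.
#' @return list with \code{initial}, \code{final} (total C-mmol/L) and
#'   \code{relative_drift}.
#' @export
carbonBalance <- function(traj, members) {
  ids <- vapply(members, modelId, "")
  names(members) <- ids
  carbonOfPool <- function(concRow) {
    tot <- 0
    for (m in members) {
      met <- m@metabolites
      tracked <- met$id[met$compartment == "e" & !is.na(met$carbon)]
      tracked <- intersect(tracked, names(concRow))
      if (length(tracked))
        tot <- tot + sum(concRow[tracked] *
                           met$carbon[match(tracked, met$id)])
      concRow <- concRow[setdiff(names(concRow), tracked)]
    }
    tot
  }
  biomassCarbon <- vapply(members, function(m) {
    s <- m@stoichiometry[[m@biomassId]]
    carb <- stats::setNames(m@metabolites$carbon, m@metabolites$id)
    k <- carb[names(s)]
    if (anyNA(k)) return(NA_real_)
    -sum(s * k)       # net carbon drawn from precursors per unit growth
  }, 0)
  if (anyNA(biomassCarbon))
    stop("carbon audit needs carbon counts for all biomass precursors")
  first <- 1; last <- nrow(traj$conc)
  total <- function(i) carbonOfPool(traj$conc[i, ]) +
    sum(traj$biomass[i, ids] * biomassCarbon[ids])
  ini <- total(first); fin <- total(last)
  list(initial = ini, final = fin,
       relative_drift = abs(fin - ini) / max(ini, 1e-12))
}
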