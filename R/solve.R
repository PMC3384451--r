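# Flux balance solves, with and without the molecular-crowding constraint.

#' Solver configuration
#'
#' @param vProt crowding budget: the volume fraction of macromolecules
#'   devoted to metabolic enzymes, in (0, 1]. Fitted values for real
#'   organisms cluster around 0.15-0.2; the default is 0.2.
#' @param feasibilityTolerance componentwise tolerance on steady-state and
#'   bound residuals.
#' @param objectiveTolerance tolerance used when comparing objective values.
#' @param tieBreak \code{"min_crowding_usage"} (default) performs a second
#'   optimization at the fixed optimal objective that minimizes total
#'   crowding usage, making the reported flux vector reproducible;
#'   \code{"none"} returns the first optimal vertex found (itself
#'   deterministic, via Bland's rule, but dependent on problem layout).
#' @param bigBound sentinel flux (mmol/gDW/h) standing in for "unconstrained";
#'   infinite bounds are clamped to it.
#' @return a validated config list of class \code{"solverConfig"}.
#' @export
solverConfig <- function(vProt = 0.2, feasibilityTolerance = 1e-9,
                         objectiveTolerance = 1e-6,
                         tieBreak = c("min_crowding_usage", "none"),
                         bigBound = 1000) {
  tieBreak <- match.arg(tieBreak)
  if (!.isNumber(vProt) || vProt <= 0 || vProt > 1) {
    .stopf("vProt must be in (0, 1]")
  }
  if (!.isNumber(feasibilityTolerance) || feasibilityTolerance <= 0 ||
      !.isNumber(objectiveTolerance) || objectiveTolerance <= 0) {
    .stopf("tolerances must be > 0")
  }
  if (!.isNumber(bigBound) || bigBound <= 0) .stopf("bigBound must be > 0")
  structure(list(vProt = vProt,
                 feasibilityTolerance = feasibilityTolerance,
                 objectiveTolerance = objectiveTolerance,
                 tieBreak = tieBreak, bigBound = bigBound),
            class = "solverConfig")
}

# Build and solve the LP for a model, optionally with a crowding budget.
#
# Each reaction is represented by nonnegative variables so that the crowding
# cost applies to |f|:
#   lb >= 0 : f = lb + x,      x in [0, ub - lb]   (|f| = lb + x)
#   ub <= 0 : f = ub - x,      x in [0, ub - lb]   (|f| = -ub + x)
#   else    : f = xf - xr,     xf in [0, ub], xr in [0, -lb]
# A signed crowding sum would let reverse flux subsidize forward crowding,
# so both directions of a reversible reaction pay the same coefficient.
.solveModelLP <- function(model, coefs, config,
                          fixObjective = NULL, minimizeCrowding = FALSE) {
  rxn <- model@reactions
  n <- nrow(rxn)
  big <- config$bigBound
  lb <- pmax(rxn$lower_bound, -big)
  ub <- pmin(rxn$upper_bound, big)
  S <- as.matrix(model@stoichiometry)
  m <- nrow(S)

  # variable layout
  vRxn <- integer(0); vDir <- numeric(0); vBase <- numeric(0); vCap <- numeric(0)
  for (i in seq_len(n)) {
    if (lb[i] >= 0) {
      vRxn <- c(vRxn, i); vDir <- c(vDir, 1); vBase <- c(vBase, lb[i])
      vCap <- c(vCap, ub[i] - lb[i])
    } else if (ub[i] <= 0) {
      vRxn <- c(vRxn, i); vDir <- c(vDir, -1); vBase <- c(vBase, ub[i])
      vCap <- c(vCap, ub[i] - lb[i])
    } else {
      vRxn <- c(vRxn, i, i); vDir <- c(vDir, 1, -1); vBase <- c(vBase, 0, 0)
      vCap <- c(vCap, ub[i], -lb[i])
    }
  }
  nv <- length(vRxn)
  f0 <- numeric(n)
  for (k in seq_len(nv)) if (vBase[k] != 0) f0[vRxn[k]] <- vBase[k]

  Avar <- S[, vRxn, drop = FALSE] * rep(vDir, each = m)
  bMet <- -drop(S %*% f0)

  capRows <- which(vCap < big * 2 + 1) # all caps are finite by construction
  nCap <- length(capRows)

  hasCrowd <- !is.null(coefs)
  cVar <- if (hasCrowd) unname(coefs[rxn$id][vRxn]) else numeric(nv)
  crowdConst <- if (hasCrowd) sum(abs(f0) * unname(coefs[rxn$id])) else 0

  hasFix <- !is.null(fixObjective)
  objIdx <- which(vRxn == match(model@objectiveReaction, rxn$id))
  objRowVec <- numeric(nv)
  objRowVec[objIdx] <- vDir[objIdx]
  objConst <- f0[match(model@objectiveReaction, rxn$id)]

  nRows <- m + nCap + as.integer(hasCrowd) + as.integer(hasFix)
  nSlack <- nCap + as.integer(hasCrowd)
  A <- matrix(0, nRows, nv + nSlack)
  b <- numeric(nRows)
  A[seq_len(m), seq_len(nv)] <- Avar
  b[seq_len(m)] <- bMet
  r <- m
  s <- nv
  for (k in capRows) {
    r <- r + 1; s <- s + 1
    A[r, k] <- 1; A[r, s] <- 1
    b[r] <- vCap[k]
  }
  if (hasCrowd) {
    r <- r + 1; s <- s + 1
    A[r, seq_len(nv)] <- cVar
    A[r, s] <- 1
    b[r] <- config$vProt - crowdConst
    if (b[r] < 0) {
      return(list(status = "infeasible")) # forced fluxes already exceed budget
    }
  }
  if (hasFix) {
    # pin the objective flux at its optimum (equality row); the optimal
    # vertex from the first stage satisfies it to rounding error
    r <- r + 1
    A[r, seq_len(nv)] <- objRowVec
    b[r] <- fixObjective - objConst
  }

  obj <- numeric(nv + nSlack)
  if (minimizeCrowding) {
    obj[seq_len(nv)] <- -cVar
  } else {
    obj[seq_len(nv)] <- objRowVec
  }

  res <- .simplex(obj, A, b, tol = config$feasibilityTolerance * 1)
  if (res$status != "optimal") return(list(status = res$status))
  x <- res$x[seq_len(nv)]
  f <- f0
  for (k in seq_len(nv)) f[vRxn[k]] <- f[vRxn[k]] + vDir[k] * x[k]
  list(status = "optimal", fluxes = stats::setNames(f, rxn$id),
       objective = f[match(model@objectiveReaction, rxn$id)])
}

#' Solve the plain flux balance problem
#'
#' Maximizes the objective flux subject to steady state (\eqn{S f = 0}) and
#' the per-reaction flux bounds. Reversible reactions may carry negative
#' flux.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param config a [solverConfig()].
#' @return a \linkS4class{FluxSolution}; \code{crowdingUsage} is \code{NA}.
#' @export
solveFBA <- function(model, config = solverConfig()) {
  res <- .solveModelLP(model, coefs = NULL, config = config)
  if (res$status != "optimal") {
    return(methods::new("FluxSolution", fluxes = numeric(0),
                        growthRate = NA_real_, crowdingUsage = NA_real_,
                        status = res$status))
  }
  .checkSteadyState(model, res$fluxes, config)
  methods::new("FluxSolution", fluxes = res$fluxes,
               growthRate = res$objective, crowdingUsage = NA_real_,
               status = "optimal")
}

#' Solve the flux balance problem with molecular crowding
#'
#' Adds the crowding constraint \eqn{\sum_i c_i |f_i| \le V_{prot}} to the
#' flux balance problem: the total enzyme volume fraction sustaining the flux
#' distribution may not exceed the budget \code{vProt}. Absolute fluxes enter
#' the sum via a directional split of every reversible reaction (both
#' directions pay the same coefficient). When
#' \code{config$tieBreak == "min_crowding_usage"}, a second optimization at
#' the fixed optimal objective minimizes total crowding usage, so repeated
#' solves return identical flux vectors even on degenerate problems.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param crowding a \linkS4class{CrowdingAssignment} covering every model
#'   reaction (see [sampleCrowding()]).
#' @param config a [solverConfig()]; \code{config$vProt} is the budget.
#' @return a \linkS4class{FluxSolution} with \code{crowdingUsage} filled in.
#' @export
solveFBAwMC <- function(model, crowding, config = solverConfig()) {
  coefs <- crowding@coefficients
  missing <- setdiff(model@reactions$id, names(coefs))
  if (length(missing)) {
    .stopf("crowding assignment lacks reaction(s): %s",
           paste(missing, collapse = ", "))
  }
  res <- .solveModelLP(model, coefs = coefs, config = config)
  if (res$status != "optimal") {
    return(methods::new("FluxSolution", fluxes = numeric(0),
                        growthRate = NA_real_, crowdingUsage = NA_real_,
                        status = res$status))
  }
  mu <- res$objective
  if (config$tieBreak == "min_crowding_usage") {
    res2 <- .solveModelLP(model, coefs = coefs, config = config,
                          fixObjective = mu, minimizeCrowding = TRUE)
    if (res2$status == "optimal") res <- res2
  }
  .checkSteadyState(model, res$fluxes, config)
  usage <- sum(coefs[model@reactions$id] * abs(res$fluxes))
  methods::new("FluxSolution", fluxes = res$fluxes, growthRate = mu,
               crowdingUsage = usage, status = "optimal")
}

.checkSteadyState <- function(model, f, config) {
  resid <- max(abs(drop(model@stoichiometry %*% f)))
  tol <- config$feasibilityTolerance * max(1, max(abs(f)))
  if (resid > tol * 10) {
    warning(sprintf("steady-state residual %.3g exceeds tolerance", resid),
            call. = FALSE)
  }
  invisible(resid)
}

#' Growth yield of a solution
#'
#' Growth yield is the growth rate divided by the glucose uptake rate,
#' expressed in g dry weight per g glucose: \eqn{Y = \mu / (G \cdot 0.18016)}
#' with \eqn{G} the glucose uptake in mmol/gDW/h and 0.18016 g/mmol the molar
#' mass of glucose. Zero uptake with zero growth yields 0 by convention;
#' zero uptake with positive growth is a mass-balance violation and raises an
#' error.
#'
#' @param solution an optimal \linkS4class{FluxSolution}.
#' @param model the model it was solved on.
#' @param glucoseExchange id of the glucose exchange reaction; by default the
#'   first reaction id matching \code{^(R_)?EX_glc}.
#' @param glucoseMolarMass g/mmol; default 0.18016.
#' @return yield in g dry weight per g glucose (for ATP-drain objectives the
#'   same formula applies with the drain flux in place of \eqn{\mu}).
#' @export
computeYield <- function(solution, model, glucoseExchange = NULL,
                         glucoseMolarMass = 0.18016) {
  if (solution@status != "optimal") .stopf("solution is not optimal")
  glucoseExchange <- glucoseExchange %||% .findGlucoseExchange(model)
  f <- solution@fluxes[glucoseExchange]
  if (is.na(f)) .stopf("glucose exchange '%s' not in solution", glucoseExchange)
  uptake <- max(0, -f) # uptake = negative exchange flux
  mu <- solution@growthRate
  tol <- 1e-9 * max(1, abs(mu))
  if (uptake <= tol) {
    if (mu <= 1e-6) return(0)
    .stopf("positive growth (%.4g) with zero glucose uptake: mass imbalance", mu)
  }
  mu / (uptake * glucoseMolarMass)
}

.findGlucoseExchange <- function(model) {
  hit <- grep("^(R_)?EX_glc", model@reactions$id, value = TRUE)
  if (!length(hit)) .stopf("no glucose exchange reaction found (pattern ^EX_glc)")
  hit[1]
}

#' Serialize a flux solution
#'
#' \code{writeFluxTable} writes a two-column (reaction id, flux) TSV;
#' \code{solutionSummary} returns a list (objective flux, yield, crowding
#' usage, status) ready for JSON serialization.
#'
#' @param solution a \linkS4class{FluxSolution}.
#' @param path output path.
#' @return \code{path} invisibly / a named list.
#' @export
writeFluxTable <- function(solution, path) {
  utils::write.table(
    data.frame(id = names(solution@fluxes), flux = unname(solution@fluxes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFluxTable
#' @param model the model the solution belongs to (for the yield).
#' @inheritParams computeYield
#' @export
solutionSummary <- function(solution, model, glucoseExchange = NULL) {
  list(status = solution@status,
       growth_rate = solution@growthRate,
       yield = if (solution@status == "optimal") {
         computeYield(solution, model, glucoseExchange)
       } else NA_real_,
       crowding_usage = solution@crowdingUsage)
}
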