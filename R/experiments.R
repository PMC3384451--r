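# Ensemble experiments: growth curves, switch statistics, yield ensembles,
# knockouts, overexpression mimicry, V_prot fitting, mode counting.

# Exchange id patterns for the reporter/excretion machinery. The lumped
# five-reaction model pools lactate and ethanol into EX_waste.
.exchangePatterns <- list(
  oxygen = "^(R_)?EX_o2",
  acetate = "^(R_)?EX_ac($|[_(])",
  lactate = "^(R_)?EX_lac|^(R_)?EX_waste",
  ethanol = "^(R_)?EX_etoh",
  formate = "^(R_)?EX_for($|[_(])"
)

.findExchange <- function(model, what) {
  hit <- grep(.exchangePatterns[[what]], model@reactions$id, value = TRUE)
  if (length(hit)) hit[1] else NA_character_
}

#' Scan growth over a grid of glucose uptake bounds
#'
#' Runs one crowding-constrained solve per grid point with the glucose
#' exchange lower bound set to minus the grid value, recording growth, yield
#' and the fluxes of reporter exchanges (oxygen uptake and
#' formate/acetate/lactate/ethanol excretion, when present in the model).
#' Infeasible points are recorded with zero growth and flagged in
#' \code{status}.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param crowding a \linkS4class{CrowdingAssignment}.
#' @param config a [solverConfig()].
#' @param glucoseGrid ascending nonempty vector of glucose uptake bounds
#'   (mmol/gDW/h, magnitudes).
#' @param glucoseExchange glucose exchange id (default autodetected).
#' @param reporters named character vector of reporter reaction ids; default:
#'   all of oxygen/acetate/lactate/ethanol/formate exchanges present.
#' @return data.frame of class \code{"growthCurve"}: one row per grid point
#'   with columns \code{glucose_bound}, \code{growth_rate}, \code{yield},
#'   \code{status} and one column per reporter.
#' @export
growthCurve <- function(model, crowding, config = solverConfig(), glucoseGrid,
                        glucoseExchange = NULL, reporters = NULL) {
  if (!length(glucoseGrid)) .stopf("empty glucose grid")
  if (is.unsorted(glucoseGrid)) .stopf("glucose grid must be ascending")
  if (any(glucoseGrid < 0)) .stopf("glucose bounds are uptake magnitudes, >= 0")
  glucoseExchange <- glucoseExchange %||% .findGlucoseExchange(model)
  if (is.null(reporters)) {
    reporters <- vapply(names(.exchangePatterns), .findExchange,
                        character(1), model = model)
    reporters <- reporters[!is.na(reporters)]
  }
  rows <- lapply(glucoseGrid, function(g) {
    mg <- setReactionBounds(model, glucoseExchange, lower = -g)
    sol <- solveFBAwMC(mg, crowding, config)
    ok <- sol@status == "optimal"
    rep_flux <- if (ok) sol@fluxes[reporters] else rep(0, length(reporters))
    out <- data.frame(glucose_bound = g,
                      growth_rate = if (ok) sol@growthRate else 0,
                      yield = if (ok) computeYield(sol, mg, glucoseExchange) else 0,
                      status = sol@status)
    for (j in seq_along(reporters)) out[[names(reporters)[j]]] <- unname(rep_flux[j])
    out
  })
  curve <- do.call(rbind, rows)
  attr(curve, "crowding_seed") <- crowding@seed
  attr(curve, "reporters") <- reporters
  class(curve) <- c("growthCurve", "data.frame")
  curve
}

#' Flux decrease through a reporter pathway during the metabolic switch
#'
#' Quantifies how strongly a high-yield pathway is shut down at high growth:
#' the decrease of the reporter flux at the maximal-growth point of a glucose
#' scan, relative to the maximal reporter flux anywhere on the scan. 0 means
#' overflow-like behavior (the high-yield pathway stays fully active); 1
#' means a complete metabolic switch. Reporter fluxes are compared by
#' magnitude, so uptake reporters (oxygen) and excretion reporters (formate)
#' are treated alike.
#'
#' @param curve a [growthCurve()] result.
#' @param reporter column name in \code{curve} (e.g. \code{"oxygen"}) or a
#'   reaction id recorded as a reporter.
#' @return list with \code{flux_decrease} (fraction in [0, 1]),
#'   \code{reporter}, \code{max_reporter_flux},
#'   \code{reporter_flux_at_max_growth}, and \code{flagged} (TRUE when the
#'   reporter never carried flux, in which case \code{flux_decrease} is 0).
#' @export
fluxDecreaseStatistic <- function(curve, reporter) {
  if (!reporter %in% names(curve)) {
    reporters <- attr(curve, "reporters")
    hit <- names(reporters)[reporters == reporter]
    if (!length(hit)) .stopf("reporter '%s' not recorded in curve", reporter)
    reporter <- hit[1]
  }
  v <- abs(curve[[reporter]])
  vmax <- max(v)
  # evaluation point: the maximal-growth point; under monotone growth this is
  # the terminal, crowding-limited regime of the scan
  iEval <- which(curve$growth_rate >= max(curve$growth_rate) - 1e-12)
  atMax <- v[iEval[length(iEval)]]
  if (vmax <= 0) {
    return(list(flux_decrease = 0, reporter = reporter, max_reporter_flux = 0,
                reporter_flux_at_max_growth = 0, flagged = TRUE))
  }
  list(flux_decrease = (vmax - atMax) / vmax, reporter = reporter,
       max_reporter_flux = vmax, reporter_flux_at_max_growth = atMax,
       flagged = FALSE)
}

#' Classify a growth yield as low-yield metabolism
#'
#' @param yield growth yield in g dry weight per g glucose.
#' @return \code{TRUE} iff \code{yield < 0.3} strictly.
#' @export
classifyLowYield <- function(yield) {
  if (any(yield < 0)) .stopf("yield must be >= 0")
  yield < 0.3
}

#' Classify the excretion profile of a solution
#'
#' @param solution an optimal \linkS4class{FluxSolution}.
#' @param model the model it was solved on (for exchange autodetection).
#' @param tol flux threshold below which an efflux counts as absent.
#' @param acetate,lactate,ethanol exchange reaction ids (default autodetected;
#'   absent exchanges count as zero efflux).
#' @return one of \code{"acetate_only"} (acetate efflux without lactate or
#'   ethanol), \code{"lactate_or_ethanol"}, \code{"mixed"}, \code{"none"}.
#' @export
excretionProfile <- function(solution, model, tol = 1e-6, acetate = NULL,
                             lactate = NULL, ethanol = NULL) {
  eff <- function(id, what) {
    id <- id %||% .findExchange(model, what)
    if (is.na(id) || !(id %in% names(solution@fluxes))) return(0)
    max(0, solution@fluxes[[id]])
  }
  ac <- eff(acetate, "acetate")
  lac <- eff(lactate, "lactate")
  eth <- eff(ethanol, "ethanol")
  ferm <- max(lac, eth)
  if (ac > tol && ferm <= tol) "acetate_only"
  else if (ac <= tol && ferm > tol) "lactate_or_ethanol"
  else if (ac > tol && ferm > tol) "mixed"
  else "none"
}

#' Block an exchange efflux
#'
#' Returns a copy of the model with the efflux (upper) bound of the given
#' exchange reaction set to zero, leaving everything else untouched; uptake
#' through that exchange, if allowed by the lower bound, stays allowed.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param id exchange reaction id.
#' @return the modified copy.
#' @export
knockoutExchange <- function(model, id) {
  i <- match(id, model@reactions$id)
  if (is.na(i)) .stopf("unknown reaction id: %s", id)
  setReactionBounds(model, id, upper = 0)
}

#' Add an overexpressed reaction with an enforced minimal flux
#'
#' Appends a reaction to the model and sets its lower bound to
#' \code{minFlux}, mimicking enzyme overexpression by forcing flux through
#' the added activity. Metabolites referenced by the reaction that are not in
#' the model are added.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param reaction list with elements \code{id}, \code{stoichiometry} (named
#'   numeric, negative = consumed), optional \code{upper_bound} (default
#'   1000) and \code{enzymatic} (default TRUE). See [noxReaction()] /
#'   [aoxReaction()].
#' @param minFlux enforced lower flux bound, >= 0. A \code{minFlux} that the
#'   network cannot sustain makes downstream solves report infeasibility.
#' @return the extended model copy.
#' @export
addOverexpression <- function(model, reaction, minFlux = 0) {
  if (minFlux < 0) .stopf("minFlux must be >= 0")
  if (reaction$id %in% model@reactions$id) {
    .stopf("reaction '%s' already in model", reaction$id)
  }
  st <- reaction$stoichiometry
  newMets <- setdiff(names(st), model@metabolites$id)
  mets <- rbind(model@metabolites,
                if (length(newMets)) data.frame(id = newMets, name = newMets,
                                                compartment = "c"))
  S <- as.matrix(model@stoichiometry)
  if (length(newMets)) {
    S <- rbind(S, matrix(0, length(newMets), ncol(S),
                         dimnames = list(newMets, colnames(S))))
  }
  S <- cbind(S, stats::setNames(numeric(nrow(S)), NULL))
  colnames(S)[ncol(S)] <- reaction$id
  S[names(st), ncol(S)] <- st
  rxns <- rbind(model@reactions,
                data.frame(id = reaction$id, lower_bound = minFlux,
                           upper_bound = reaction$upper_bound %||% 1000,
                           enzymatic = reaction$enzymatic %||% TRUE,
                           exchange = FALSE))
  MetabolicModel(metabolites = mets, reactions = rxns, stoichiometry = S,
                 objective = model@objectiveReaction, name = model@modelName)
}

#' NADH-oxidase and alternative-oxidase reaction specifications
#'
#' Water-forming NADH oxidase (NOX) oxidizes cytosolic NADH with oxygen
#' without conserving energy: NADH + 1/2 O2 -> NAD+. The alternative oxidase
#' (AOX) bypasses proton-pumping respiration; at the resolution of a lumped
#' redox pool its net effect is the same non-phosphorylating NADH sink
#' (the two differ only in subcellular localization, which lumped models do
#' not represent).
#'
#' @param nadh,o2 metabolite ids of the reduced cofactor pool and oxygen.
#' @return a reaction spec list for [addOverexpression()].
#' @export
noxReaction <- function(nadh = "nadh", o2 = "o2") {
  list(id = "NOX", stoichiometry = stats::setNames(c(-1, -0.5), c(nadh, o2)),
       enzymatic = TRUE)
}

#' @rdname noxReaction
#' @export
aoxReaction <- function(nadh = "nadh", o2 = "o2") {
  list(id = "AOX", stoichiometry = stats::setNames(c(-1, -0.5), c(nadh, o2)),
       enzymatic = TRUE)
}

#' Run an ensemble of FBAwMC solves over random crowding draws
#'
#' For each of \code{n} seeds derived from \code{masterSeed}, draws a
#' crowding assignment, solves the model at unconstrained glucose influx
#' (glucose uptake bound set to \code{config$bigBound}, so that crowding, not
#' glucose, binds), and records growth, glucose uptake, yield, the low-yield
#' flag and the excretion class. When \code{glucoseGrid} is given, a full
#' glucose scan is additionally run per sample and the flux-decrease switch
#' statistic of \code{reporter} recorded. Fully reproducible from
#' \code{masterSeed}.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param dist a \linkS4class{CrowdingDistribution}.
#' @param config a [solverConfig()].
#' @param n number of crowding draws.
#' @param masterSeed integer master seed.
#' @param glucoseExchange glucose exchange id (default autodetected).
#' @param glucoseGrid optional ascending grid for per-sample switch curves.
#' @param reporter reporter name for the switch statistic (default
#'   \code{"oxygen"}).
#' @param glucoseBound glucose uptake bound (magnitude) for the per-sample
#'   solves; the default \code{config$bigBound} realizes unconstrained
#'   glucose influx. A finite value emulates a glucose-limited medium, in
#'   which optima may mix two elementary modes.
#' @return an \linkS4class{EnsembleResult}.
#' @export
runEnsemble <- function(model, dist, config = solverConfig(), n = 1000,
                        masterSeed = 1, glucoseExchange = NULL,
                        glucoseGrid = NULL, reporter = "oxygen",
                        glucoseBound = config$bigBound) {
  if (!.isCount(n)) .stopf("n must be a positive count")
  glucoseExchange <- glucoseExchange %||% .findGlucoseExchange(model)
  seeds <- .spawnSeeds(masterSeed, n)
  mUnc <- setReactionBounds(model, glucoseExchange, lower = -glucoseBound)
  rows <- lapply(seeds, function(sd) {
    cr <- sampleCrowding(model, dist, sd)
    sol <- solveFBAwMC(mUnc, cr, config)
    ok <- sol@status == "optimal"
    yld <- if (ok) computeYield(sol, mUnc, glucoseExchange) else NA_real_
    fd <- NA_real_
    if (ok && !is.null(glucoseGrid)) {
      curve <- growthCurve(model, cr, config, glucoseGrid, glucoseExchange)
      fd <- fluxDecreaseStatistic(curve, reporter)$flux_decrease
    }
    data.frame(seed = sd,
               growth_rate = if (ok) sol@growthRate else NA_real_,
               glucose_uptake = if (ok) max(0, -sol@fluxes[[glucoseExchange]]) else NA_real_,
               yield = yld,
               low_yield = if (ok) classifyLowYield(yld) else NA,
               excretion_class = if (ok) excretionProfile(sol, mUnc) else NA_character_,
               flux_decrease = fd,
               status = sol@status)
  })
  methods::new("EnsembleResult", samples = do.call(rbind, rows),
               vProt = config$vProt, modelName = model@modelName,
               masterSeed = as.integer(masterSeed))
}

#' Fit the crowding budget to observed growth data
#'
#' Grid search for the crowding budget \eqn{V_{prot}}: for every grid value
#' an ensemble of \code{n} random crowding draws is run (at unconstrained
#' glucose influx), the fitted maximal growth rate and maximal glucose uptake
#' are taken as ensemble means, and the returned value minimizes
#' \deqn{((\mu_{fit}-\mu_{obs})/\mu_{obs})^2 + ((G_{fit}-G_{obs})/G_{obs})^2.}
#' Ties resolve to the smallest grid value. The same \code{masterSeed} is
#' reused at every grid value (common random numbers), so with a degenerate
#' one-point distribution the fit is exact.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param dist a \linkS4class{CrowdingDistribution}.
#' @param observed list with \code{muMaxObs} (1/h) and \code{gupMaxObs}
#'   (mmol/gDW/h), both > 0; see [generateObservedGrowth()].
#' @param grid ascending vector of candidate budgets in (0, 1].
#' @param n ensemble size per grid value.
#' @param masterSeed integer master seed.
#' @param config base [solverConfig()]; its \code{vProt} is overridden by
#'   each grid value.
#' @param glucoseBound glucose uptake bound for the ensembles (see
#'   [runEnsemble()]); keep it identical to the bound the observations were
#'   generated/measured under.
#' @return list with \code{vProt} (the fitted value) and \code{fitTable}
#'   (per-grid-value criterion and ensemble aggregates).
#' @export
fitVprot <- function(model, dist, observed, grid, n = 100, masterSeed = 1,
                     config = solverConfig(), glucoseBound = config$bigBound) {
  if (any(grid <= 0) || any(grid > 1)) .stopf("grid values must be in (0, 1]")
  if (!.isNumber(observed$muMaxObs) || observed$muMaxObs <= 0 ||
      !.isNumber(observed$gupMaxObs) || observed$gupMaxObs <= 0) {
    .stopf("observed muMaxObs and gupMaxObs must be > 0")
  }
  grid <- sort(grid)
  rows <- lapply(grid, function(vp) {
    cfg <- config
    cfg$vProt <- vp
    ens <- runEnsemble(model, dist, cfg, n = n, masterSeed = masterSeed,
                       glucoseBound = glucoseBound)
    s <- ens@samples[ens@samples$status == "optimal", ]
    muFit <- mean(s$growth_rate)
    gupFit <- mean(s$glucose_uptake)
    crit <- ((muFit - observed$muMaxObs) / observed$muMaxObs)^2 +
      ((gupFit - observed$gupMaxObs) / observed$gupMaxObs)^2
    data.frame(v_prot = vp, mu_max_fit = muFit, gup_max_fit = gupFit,
               criterion = crit, n_optimal = nrow(s))
  })
  tab <- do.call(rbind, rows)
  feas <- tab[is.finite(tab$criterion) & tab$n_optimal > 0, ]
  if (!nrow(feas)) .stopf("all grid values infeasible")
  best <- feas$v_prot[which.min(feas$criterion)] # which.min: first = smallest v_prot
  list(vProt = best, fitTable = tab)
}

#' Count metabolic modes in an ensemble yield distribution
#'
#' Clusters the ensemble's optimal yields by single linkage with a relative
#' gap criterion (a new cluster starts where the gap between consecutive
#' sorted yields exceeds \code{relTol} times the larger yield) and discards
#' clusters holding less than \code{minFreq} of the samples. Under a single
#' binding crowding constraint each optimum lies on one elementary flux
#' mode, so the count estimates the number of elementary modes the network
#' realizes over the crowding ensemble.
#'
#' @param x an \linkS4class{EnsembleResult} or a numeric vector of yields.
#' @param relTol relative gap opening a new cluster (default 0.01).
#' @param minFreq minimal cluster frequency to count (default 0.01).
#' @return integer mode count.
#' @export
countMetabolicModes <- function(x, relTol = 0.01, minFreq = 0.01) {
  y <- if (methods::is(x, "EnsembleResult")) {
    x@samples$yield[x@samples$status == "optimal"]
  } else as.numeric(x)
  y <- y[!is.na(y)]
  if (!length(y)) .stopf("no yields to cluster")
  y <- sort(y)
  gaps <- diff(y)
  scale <- pmax(abs(y[-1]), .Machine$double.eps)
  newCluster <- c(TRUE, gaps / scale > relTol)
  cl <- cumsum(newCluster)
  sizes <- tabulate(cl)
  sum(sizes / length(y) >= minFreq)
}
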