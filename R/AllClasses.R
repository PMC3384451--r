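#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' MetabolicModel: a stoichiometric metabolic network
#'
#' Container for a constraint-based metabolic model: a sparse stoichiometric
#' matrix \eqn{S} (metabolites in rows, reactions in columns), per-reaction
#' flux bounds in mmol/gDW/h, an objective reaction whose flux is maximized,
#' and per-reaction annotations (\code{enzymatic}, \code{exchange}).
#'
#' Sign conventions follow the BiGG/COBRA standard: an exchange reaction
#' touches exactly one metabolite with coefficient \eqn{-1}, so negative
#' exchange flux is uptake and positive flux is excretion. Reversibility is
#' encoded purely through the bounds: \code{lower_bound < 0} means the
#' reaction may run backwards.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}; ids are nonempty and unique.
#' @slot reactions data.frame with columns \code{id}, \code{lower_bound},
#'   \code{upper_bound}, \code{enzymatic}, \code{exchange}.
#' @slot stoichiometry \linkS4class{dgCMatrix}, metabolites x reactions,
#'   with dimnames matching the id columns.
#' @slot objectiveReaction id of the reaction whose flux is maximized
#'   (biomass for genome-scale models, an ATP drain for lumped toy models).
#' @slot modelName free-text label.
#'
#' @seealso [MetabolicModel()] for the user-facing constructor,
#'   [readModel()] and [buildSimplifiedNetwork()].
#' @name MetabolicModel-class
#' @rdname MetabolicModel-class
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  slots = c(
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "dgCMatrix",
    objectiveReaction = "character",
    modelName = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character(0)
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  need_met <- c("id", "name", "compartment")
  need_rxn <- c("id", "lower_bound", "upper_bound", "enzymatic", "exchange")
  if (!all(need_met %in% names(met))) {
    return(paste("metabolites must have columns", paste(need_met, collapse = ", ")))
  }
  if (!all(need_rxn %in% names(rxn))) {
    return(paste("reactions must have columns", paste(need_rxn, collapse = ", ")))
  }
  if (any(!nzchar(met$id))) msg <- c(msg, "empty metabolite id")
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicated metabolite ids")
  if (any(!nzchar(rxn$id))) msg <- c(msg, "empty reaction id")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicated reaction ids")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn)) {
    return("stoichiometry dimensions do not match metabolite/reaction tables")
  }
  if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id)) {
    msg <- c(msg, "stoichiometry dimnames must equal metabolite/reaction ids")
  }
  if (any(!is.finite(S@x))) msg <- c(msg, "non-finite stoichiometric coefficient")
  bad_bounds <- which(rxn$lower_bound > rxn$upper_bound)
  if (length(bad_bounds)) {
    msg <- c(msg, paste0("lower_bound > upper_bound for reaction(s): ",
                         paste(rxn$id[bad_bounds], collapse = ", ")))
  }
  nnz <- diff(S@p)
  if (any(nnz == 0)) {
    msg <- c(msg, paste0("reaction(s) with empty stoichiometry: ",
                         paste(rxn$id[nnz == 0], collapse = ", ")))
  }
  bad_ex <- which(rxn$exchange & nnz != 1)
  if (length(bad_ex)) {
    msg <- c(msg, paste0("exchange reaction(s) must touch exactly one metabolite: ",
                         paste(rxn$id[bad_ex], collapse = ", ")))
  }
  if (length(object@objectiveReaction) != 1 ||
      !(object@objectiveReaction %in% rxn$id)) {
    msg <- c(msg, "objectiveReaction must name exactly one existing reaction")
  }
  if (length(msg)) msg else TRUE
})

#' CrowdingDistribution: pooled crowding-coefficient values
#'
#' Holds the pool of crowding coefficients \eqn{c = (M/V)\, v / b} derived
#' from an enzyme turnover/mass table, together with the cell density
#' \eqn{M/V} (gDW/l) and specific protein volume (ml/g) used to build it.
#' Per-reaction assignments are drawn from this pool with
#' [sampleCrowding()].
#'
#' @slot coefficients numeric vector of crowding coefficients (gDW h/mmol).
#' @slot cellDensity cell dry mass per volume, gDW/l.
#' @slot specificVolume specific protein volume, ml/g.
#' @name CrowdingDistribution-class
#' @rdname CrowdingDistribution-class
#' @exportClass CrowdingDistribution
setClass("CrowdingDistribution",
  slots = c(coefficients = "numeric", cellDensity = "numeric",
            specificVolume = "numeric")
)

setValidity("CrowdingDistribution", function(object) {
  if (length(object@coefficients) == 0) return("empty coefficient pool")
  if (any(!is.finite(object@coefficients)) || any(object@coefficients < 0)) {
    return("coefficients must be finite and >= 0")
  }
  if (object@cellDensity <= 0 || object@specificVolume <= 0) {
    return("cellDensity and specificVolume must be > 0")
  }
  TRUE
})

#' CrowdingAssignment: per-reaction crowding coefficients
#'
#' One random draw of crowding coefficients for a specific model: every
#' enzymatic reaction carries a coefficient sampled from a
#' \linkS4class{CrowdingDistribution}; non-enzymatic reactions (exchanges,
#' demand/drain pseudo-reactions) carry exactly 0.
#'
#' @slot coefficients named numeric vector, one entry per model reaction
#'   (gDW h/mmol).
#' @slot seed integer seed the draw was made with.
#' @name CrowdingAssignment-class
#' @rdname CrowdingAssignment-class
#' @exportClass CrowdingAssignment
setClass("CrowdingAssignment",
  slots = c(coefficients = "numeric", seed = "integer")
)

setValidity("CrowdingAssignment", function(object) {
  cf <- object@coefficients
  if (is.null(names(cf)) || any(!nzchar(names(cf)))) {
    return("coefficients must be named by reaction id")
  }
  if (any(!is.finite(cf)) || any(cf < 0)) return("coefficients must be finite and >= 0")
  TRUE
})

#' FluxSolution: result of one flux balance solve
#'
#' @slot fluxes named numeric vector of optimal fluxes (mmol/gDW/h); empty
#'   when the problem is infeasible.
#' @slot growthRate optimized objective flux (1/h for biomass objectives,
#'   mmol ATP/gDW/h for ATP-drain objectives).
#' @slot crowdingUsage \eqn{\sum_i c_i |f_i|} at the optimum (dimensionless);
#'   \code{NA} when no crowding constraint was active.
#' @slot status one of \code{"optimal"}, \code{"infeasible"}, \code{"unbounded"}.
#' @name FluxSolution-class
#' @rdname FluxSolution-class
#' @exportClass FluxSolution
setClass("FluxSolution",
  slots = c(fluxes = "numeric", growthRate = "numeric",
            crowdingUsage = "numeric", status = "character")
)

setValidity("FluxSolution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded")) {
    return("status must be optimal, infeasible or unbounded")
  }
  if (object@status == "optimal" && length(object@fluxes) == 0) {
    return("optimal solution must carry fluxes")
  }
  TRUE
})

#' EnsembleResult: ensemble of FBAwMC solves over random crowding draws
#'
#' @slot samples data.frame, one row per crowding draw, with columns
#'   \code{seed}, \code{growth_rate}, \code{glucose_uptake}, \code{yield},
#'   \code{low_yield}, \code{excretion_class}, \code{status} and, when a
#'   glucose scan was requested, \code{flux_decrease}.
#' @slot vProt crowding budget used.
#' @slot modelName model the ensemble was run on.
#' @slot masterSeed seed the per-sample seeds were derived from.
#' @name EnsembleResult-class
#' @rdname EnsembleResult-class
#' @exportClass EnsembleResult
setClass("EnsembleResult",
  slots = c(samples = "data.frame", vProt = "numeric",
            modelName = "character", masterSeed = "integer")
)

setValidity("EnsembleResult", function(object) {
  need <- c("seed", "growth_rate", "glucose_uptake", "yield", "low_yield",
            "excretion_class", "status")
  if (!all(need %in% names(object@samples))) {
    return(paste("samples must have columns", paste(need, collapse = ", ")))
  }
  ok <- is.na(object@samples$yield) | object@samples$yield >= 0
  if (!all(ok)) return("negative yield in samples")
  flag <- object@samples$low_yield
  yld <- object@samples$yield
  consistent <- is.na(yld) | flag == (yld < 0.3)
  if (!all(consistent)) return("low_yield flags inconsistent with the 0.3 g/g rule")
  TRUE
})
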