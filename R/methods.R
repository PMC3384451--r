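# Accessor and show methods.

#' @rdname accessors
setMethod("reactionIds", "MetabolicModel", function(x) x@reactions$id)

#' @rdname accessors
setMethod("metaboliteIds", "MetabolicModel", function(x) x@metabolites$id)

#' @rdname accessors
setMethod("stoichiometry", "MetabolicModel", function(x) x@stoichiometry)

#' @rdname accessors
setMethod("reactionBounds", "MetabolicModel", function(x) {
  data.frame(id = x@reactions$id,
             lower_bound = x@reactions$lower_bound,
             upper_bound = x@reactions$upper_bound)
})

#' @rdname accessors
setMethod("objectiveReaction", "MetabolicModel", function(x) x@objectiveReaction)

#' @rdname accessors
setMethod("modelName", "MetabolicModel", function(x) x@modelName)

#' @rdname accessors
setMethod("crowdingCoefficients", "CrowdingDistribution", function(x) x@coefficients)

#' @rdname accessors
setMethod("crowdingCoefficients", "CrowdingAssignment", function(x) x@coefficients)

#' @rdname accessors
setMethod("fluxes", "FluxSolution", function(x) x@fluxes)

#' @rdname accessors
setMethod("growthRate", "FluxSolution", function(x) x@growthRate)

#' @rdname accessors
setMethod("crowdingUsage", "FluxSolution", function(x) x@crowdingUsage)

#' @rdname accessors
setMethod("solverStatus", "FluxSolution", function(x) x@status)

#' @rdname accessors
setMethod("ensembleSamples", "EnsembleResult", function(x) x@samples)

setMethod("show", "MetabolicModel", function(object) {
  rxn <- object@reactions
  cat("MetabolicModel:", object@modelName, "\n")
  cat(" ", nrow(object@metabolites), "metabolites x", nrow(rxn), "reactions",
      sprintf("(%d exchange, %d enzymatic)\n", sum(rxn$exchange), sum(rxn$enzymatic)))
  cat("  objective:", object@objectiveReaction, "\n")
})

setMethod("show", "CrowdingDistribution", function(object) {
  cf <- object@coefficients
  cat("CrowdingDistribution:", length(cf), "coefficients (gDW h/mmol)\n")
  cat(sprintf("  range %.3g - %.3g, median %.3g\n",
              min(cf), max(cf), stats::median(cf)))
  cat(sprintf("  cell density %.3g gDW/l, specific volume %.3g ml/g\n",
              object@cellDensity, object@specificVolume))
})

setMethod("show", "CrowdingAssignment", function(object) {
  cf <- object@coefficients
  cat("CrowdingAssignment:", length(cf), "reactions,",
      sum(cf > 0), "with nonzero coefficient (seed", paste0(object@seed, ")"), "\n")
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution:", object@status, "\n")
  if (object@status == "optimal") {
    cat(sprintf("  objective flux %.6g", object@growthRate))
    if (!is.na(object@crowdingUsage)) {
      cat(sprintf(", crowding usage %.6g", object@crowdingUsage))
    }
    cat("\n ", sum(abs(object@fluxes) > 1e-9), "of", length(object@fluxes),
        "fluxes active\n")
  }
})

setMethod("show", "EnsembleResult", function(object) {
  s <- object@samples
  cat("EnsembleResult:", nrow(s), "crowding draws on", object@modelName,
      sprintf("(V_prot %.3g, master seed %d)\n", object@vProt, object@masterSeed))
  ok <- s$status == "optimal"
  if (any(ok)) {
    cat(sprintf("  yield range %.3g - %.3g g/g, %.1f%% low-yield (< 0.3 g/g)\n",
                min(s$yield[ok]), max(s$yield[ok]), 100 * mean(s$low_yield[ok])))
  }
})
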