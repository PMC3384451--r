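#' Accessors for crowdFBA classes
#'
#' Small accessor generics: \code{reactionIds}, \code{metaboliteIds},
#' \code{stoichiometry}, \code{reactionBounds}, \code{objectiveReaction},
#' \code{modelName}, \code{crowdingCoefficients}, \code{fluxes},
#' \code{growthRate}, \code{crowdingUsage}, \code{solverStatus},
#' \code{ensembleSamples}.
#'
#' @param x an object of the documented class.
#' @return The slot content; see the class documentation for units.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname accessors
#' @export
setGeneric("reactionBounds", function(x) standardGeneric("reactionBounds"))

#' @rdname accessors
#' @export
setGeneric("objectiveReaction", function(x) standardGeneric("objectiveReaction"))

#' @rdname accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname accessors
#' @export
setGeneric("crowdingCoefficients", function(x) standardGeneric("crowdingCoefficients"))

#' @rdname accessors
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname accessors
#' @export
setGeneric("growthRate", function(x) standardGeneric("growthRate"))

#' @rdname accessors
#' @export
setGeneric("crowdingUsage", function(x) standardGeneric("crowdingUsage"))

#' @rdname accessors
#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))

#' @rdname accessors
#' @export
setGeneric("ensembleSamples", function(x) standardGeneric("ensembleSamples"))
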