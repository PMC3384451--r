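# Crowding coefficients: enzyme turnover/mass tables -> coefficient
# distributions -> per-reaction random assignments.

#' Read an enzyme turnover/mass table
#'
#' Delimited text with header \code{enzyme_id}, \code{kcat_per_s},
#' \code{mass_da}, \code{wild_type} and optionally \code{substrate},
#' emulating a curated extract from enzyme databases (turnover numbers in
#' 1/s, molar masses in g/mol).
#'
#' @param path file path (tab-separated).
#' @return data.frame of raw records with columns \code{enzyme_id},
#'   \code{kcat}, \code{mass}, \code{wild_type}, \code{substrate}.
#' @export
readKcatTable <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("enzyme_id", "kcat_per_s", "mass_da", "wild_type")
  miss <- setdiff(need, names(tab))
  if (length(miss)) .stopf("kcat table lacks column(s): %s",
                           paste(miss, collapse = ", "))
  data.frame(enzyme_id = tab$enzyme_id,
             kcat = as.numeric(tab$kcat_per_s),
             mass = as.numeric(tab$mass_da),
             wild_type = as.logical(tab$wild_type),
             substrate = if ("substrate" %in% names(tab)) tab$substrate else NA_character_)
}

#' Filter raw turnover records to one per enzyme
#'
#' Applies the curation rule for turnover-number extracts: per enzyme,
#' restrict to wild-type measurements whenever any exist, keep the single
#' record with the highest turnover number, and drop enzymes whose retained
#' turnover number is below 0.01/s (extremely slow turnover numbers typically
#' belong to non-metabolic activities or atypical substrates). The boundary
#' value 0.01/s itself is retained. Idempotent.
#'
#' @param records data.frame with columns \code{enzyme_id}, \code{kcat} (1/s),
#'   \code{mass} (g/mol), \code{wild_type} (logical), optionally
#'   \code{substrate}.
#' @param minKcat retention threshold (1/s); records strictly below are dropped.
#' @param provenance free-text provenance note attached to the result.
#' @return filtered data.frame, one row per retained enzyme, with attribute
#'   \code{provenance}.
#' @export
buildKcatTable <- function(records, minKcat = 0.01, provenance = "unspecified") {
  if (is.null(records) || nrow(records) == 0) .stopf("empty turnover record set")
  if (any(records$kcat <= 0) || any(records$mass <= 0)) {
    .stopf("kcat and mass must be > 0")
  }
  if (anyNA(records$kcat) || anyNA(records$mass)) .stopf("NA in kcat/mass")
  picks <- lapply(split(records, records$enzyme_id), function(d) {
    if (any(d$wild_type)) d <- d[d$wild_type, , drop = FALSE]
    d[order(-d$kcat, d$enzyme_id)[1], , drop = FALSE]
  })
  out <- do.call(rbind, picks)
  out <- out[out$kcat >= minKcat, , drop = FALSE]
  out <- out[order(out$enzyme_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- provenance
  out
}

#' Crowding coefficient of an enzyme
#'
#' The crowding coefficient is the fraction of cytosolic volume that must be
#' filled with enzyme to sustain unit flux: \eqn{c = (M/V)\, v / b}, where
#' \eqn{M/V} is the cell dry-mass density, \eqn{v} the molar volume of the
#' enzyme and \eqn{b} the flux sustained per mole of enzyme. \eqn{v} is
#' estimated from the molar mass via the specific protein volume
#' (\code{specificVolume * mass}, converted to l/mmol) and \eqn{b} from the
#' turnover number (\code{kcat * 3600} substrate mmol per enzyme mmol per
#' hour, i.e. the enzyme is assumed substrate-saturated, \eqn{b = V_{max}}).
#'
#' @param mass molar mass, g/mol. Vectorized.
#' @param kcat turnover number, 1/s. Vectorized.
#' @param cellDensity cell dry mass per cell volume \eqn{M/V}, gDW/l.
#' @param specificVolume specific protein volume, ml/g.
#' @return crowding coefficient(s) in gDW h/mmol; linear in \code{mass} and
#'   \code{cellDensity}, inversely proportional to \code{kcat}.
#' @examples
#' crowdingCoefficient(mass = 1e5, kcat = 10)
#' @export
crowdingCoefficient <- function(mass, kcat, cellDensity = 340,
                                specificVolume = 0.73) {
  if (any(!is.finite(mass)) || any(mass <= 0)) .stopf("mass must be > 0")
  if (any(!is.finite(kcat)) || any(kcat <= 0)) .stopf("kcat must be > 0")
  if (!.isNumber(cellDensity) || cellDensity <= 0) .stopf("cellDensity must be > 0")
  if (!.isNumber(specificVolume) || specificVolume <= 0) .stopf("specificVolume must be > 0")
  v <- specificVolume * mass * 1e-6  # ml/mol -> l/mmol
  b <- kcat * 3600                   # 1/s -> mmol substrate / mmol enzyme / h
  cellDensity * v / b
}

#' Build a crowding-coefficient distribution from a filtered turnover table
#'
#' @param table filtered table from [buildKcatTable()] (or any data.frame
#'   with \code{kcat} and \code{mass} columns, one row per enzyme).
#' @inheritParams crowdingCoefficient
#' @return a \linkS4class{CrowdingDistribution} with one coefficient per
#'   retained enzyme.
#' @export
buildCrowdingDistribution <- function(table, cellDensity = 340,
                                      specificVolume = 0.73) {
  if (is.null(table) || nrow(table) == 0) .stopf("empty turnover table")
  cf <- crowdingCoefficient(table$mass, table$kcat, cellDensity, specificVolume)
  methods::new("CrowdingDistribution", coefficients = unname(cf),
               cellDensity = cellDensity, specificVolume = specificVolume)
}

#' Draw a random per-reaction crowding assignment
#'
#' Each enzymatic reaction of the model receives an independent uniform draw
#' (with replacement) from the distribution's coefficient pool; non-enzymatic
#' reactions (exchanges, drains) receive exactly 0. Enzymes are deliberately
#' not identity-mapped to reactions: the coefficient pool is treated as a
#' range of physiologically plausible values whose assignment to reactions is
#' unknown, and the ensemble over draws characterizes the network rather than
#' one parameterization. A reversible reaction carries a single coefficient,
#' applied to both directions (one enzyme catalyses both).
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param dist a \linkS4class{CrowdingDistribution}.
#' @param seed integer; identical \code{(model, dist, seed)} give identical
#'   assignments.
#' @return a \linkS4class{CrowdingAssignment} covering every model reaction.
#' @export
sampleCrowding <- function(model, dist, seed) {
  enz <- model@reactions$enzymatic
  pool <- dist@coefficients
  draw <- .withSeed(seed, sample.int(length(pool), sum(enz), replace = TRUE))
  cf <- stats::setNames(numeric(nrow(model@reactions)), model@reactions$id)
  cf[enz] <- pool[draw]
  methods::new("CrowdingAssignment", coefficients = cf, seed = as.integer(seed))
}

#' Serialize / read a coefficient pool as single-column text
#'
#' @param dist a \linkS4class{CrowdingDistribution}.
#' @param path file path.
#' @return \code{writeCrowdingDistribution}: \code{path} invisibly;
#'   \code{readCrowdingDistribution}: a \linkS4class{CrowdingDistribution}.
#' @export
writeCrowdingDistribution <- function(dist, path) {
  writeLines(c(sprintf("# cell_density %.15g", dist@cellDensity),
               sprintf("# specific_volume %.15g", dist@specificVolume),
               format(dist@coefficients, digits = 15, trim = TRUE)), path)
  invisible(path)
}

#' @rdname writeCrowdingDistribution
#' @inheritParams buildCrowdingDistribution
#' @export
readCrowdingDistribution <- function(path, cellDensity = NULL,
                                     specificVolume = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getPar <- function(key, fallback) {
    hit <- grep(paste0("^# *", key), hdr, value = TRUE)
    if (length(hit)) as.numeric(sub(paste0("^# *", key, " +"), "", hit[1])) else fallback
  }
  methods::new("CrowdingDistribution",
               coefficients = as.numeric(lines[!grepl("^#", lines) & nzchar(lines)]),
               cellDensity = cellDensity %||% getPar("cell_density", 340),
               specificVolume = specificVolume %||% getPar("specific_volume", 0.73))
}
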