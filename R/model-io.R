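# Model construction and I/O: reaction-table dialect, SBML, media.

#' Construct a MetabolicModel
#'
#' User-facing constructor performing coercion and validation. Most users
#' will instead use [readModel()], [buildSimplifiedNetwork()] or
#' [generateToyNetwork()].
#'
#' @param metabolites data.frame with columns \code{id} and optionally
#'   \code{name}, \code{compartment}.
#' @param reactions data.frame with columns \code{id}, \code{lower_bound},
#'   \code{upper_bound}, \code{enzymatic}, \code{exchange}.
#' @param stoichiometry matrix (dense or sparse), metabolites x reactions.
#' @param objective id of the reaction whose flux is maximized.
#' @param name model label.
#' @return A validated \linkS4class{MetabolicModel}.
#' @export
MetabolicModel <- function(metabolites, reactions, stoichiometry, objective,
                           name = "model") {
  metabolites <- as.data.frame(metabolites)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  reactions <- as.data.frame(reactions)
  S <- methods::as(methods::as(Matrix::Matrix(stoichiometry, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  dimnames(S) <- list(metabolites$id, reactions$id)
  methods::new("MetabolicModel",
               metabolites = metabolites, reactions = reactions,
               stoichiometry = S, objectiveReaction = objective,
               modelName = name)
}

# --- reaction-equation dialect ------------------------------------------------

# "1 glc -> 2 pyr + 2 atp" ; empty side allowed for exchanges ("glc ->").
.parseEquation <- function(eq, id = "?") {
  eq <- gsub("→", "->", eq, fixed = TRUE)
  if (!grepl("->", eq, fixed = TRUE)) {
    .stopf("reaction '%s': equation '%s' has no '->' arrow", id, eq)
  }
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2) .stopf("reaction '%s': more than one arrow", id)
  left <- if (length(sides) >= 1) sides[1] else ""
  right <- if (length(sides) == 2) sides[2] else ""
  coef <- c(.parseSide(left, -1, id), .parseSide(right, +1, id))
  if (!length(coef)) .stopf("reaction '%s': empty stoichiometry", id)
  out <- tapply(coef, names(coef), sum)
  out <- out[abs(out) > 0]
  if (!length(out)) .stopf("reaction '%s': all coefficients cancel", id)
  stats::setNames(as.numeric(out), names(out))
}

.parseSide <- function(side, sgn, id) {
  side <- trimws(side)
  if (!nzchar(side)) return(numeric(0))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (term in terms) {
    if (!nzchar(term)) .stopf("reaction '%s': empty term in equation", id)
    mm <- regmatches(term, regexec("^([0-9]*\\.?[0-9]+)\\s+(\\S+)$", term))[[1]]
    if (length(mm)) {
      cf <- as.numeric(mm[2])
      met <- mm[3]
    } else {
      cf <- 1
      met <- term
    }
    out <- c(out, stats::setNames(sgn * cf, met))
  }
  out
}

.formatEquation <- function(coef) {
  fmtTerm <- function(cf, met) {
    if (isTRUE(all.equal(cf, 1))) met else paste(format(cf, digits = 15), met)
  }
  lhs <- names(coef)[coef < 0]
  rhs <- names(coef)[coef > 0]
  left <- paste(mapply(fmtTerm, -coef[coef < 0], lhs), collapse = " + ")
  right <- paste(mapply(fmtTerm, coef[coef > 0], rhs), collapse = " + ")
  paste(left, "->", right)
}

# Build a model from a parsed reaction table (id, equation, lb, ub,
# enzymatic, exchange).
.modelFromTable <- function(tab, name, objective = NULL) {
  need <- c("id", "equation", "lb", "ub", "enzymatic", "exchange")
  miss <- setdiff(need, names(tab))
  if (length(miss)) .stopf("reaction table lacks column(s): %s",
                           paste(miss, collapse = ", "))
  coefs <- lapply(seq_len(nrow(tab)),
                  function(i) .parseEquation(tab$equation[i], tab$id[i]))
  mets <- unique(unlist(lapply(coefs, names)))
  S <- matrix(0, length(mets), nrow(tab), dimnames = list(mets, tab$id))
  for (i in seq_along(coefs)) S[names(coefs[[i]]), i] <- coefs[[i]]
  exch <- as.logical(tab$exchange) | grepl("^EX_", tab$id)
  nTouched <- colSums(S != 0)
  exch <- exch | nTouched == 1
  if (is.null(objective)) {
    objective <- if ("objective" %in% names(tab) && any(as.logical(tab$objective))) {
      tab$id[which(as.logical(tab$objective))[1]]
    } else {
      tab$id[nrow(tab)]
    }
  }
  MetabolicModel(
    metabolites = data.frame(id = mets, name = mets, compartment = "c"),
    reactions = data.frame(id = tab$id,
                           lower_bound = as.numeric(tab$lb),
                           upper_bound = as.numeric(tab$ub),
                           enzymatic = as.logical(tab$enzymatic),
                           exchange = exch),
    stoichiometry = S, objective = objective, name = name)
}

#' Read a metabolic model from file
#'
#' Two dialects are supported. \code{"reaction-table"} is a dependency-free
#' tab-separated format with columns \code{id}, \code{equation} (e.g.
#' \code{"1 glc -> 2 pyr + 2 atp"}; an empty right- or left-hand side marks a
#' boundary exchange), \code{lb}, \code{ub}, \code{enzymatic},
#' \code{exchange}, and optionally \code{objective} (flag column; otherwise
#' the last reaction is the objective). \code{"sbml"} reads SBML Level 2
#' (kinetic-law \code{LOWER_BOUND}/\code{UPPER_BOUND} parameters) and
#' Level 3 with the \code{fbc} flux-bounds/objective extension.
#'
#' Reversibility is encoded purely through bounds (\code{lower_bound < 0});
#' reactions touching a single metabolite or with ids prefixed \code{EX_}
#' are flagged as exchanges.
#'
#' @param path file path.
#' @param format \code{"reaction-table"} or \code{"sbml"}.
#' @param objective optional reaction id overriding the objective declared in
#'   (or defaulted from) the file.
#' @param name model label; defaults to the file name.
#' @return A validated \linkS4class{MetabolicModel}.
#' @export
readModel <- function(path, format = c("reaction-table", "sbml"),
                      objective = NULL, name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("model file not found: %s", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (format == "reaction-table") {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             comment.char = "#", check.names = TRUE)
    .modelFromTable(tab, name = name, objective = objective)
  } else {
    .readSBML(path, name = name, objective = objective)
  }
}

#' Write a model in the reaction-table dialect
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeReactionTable <- function(model, path) {
  S <- as.matrix(model@stoichiometry)
  eqs <- vapply(seq_len(ncol(S)), function(i) {
    cf <- S[, i]
    .formatEquation(cf[cf != 0])
  }, character(1))
  tab <- data.frame(id = model@reactions$id,
                    equation = eqs,
                    lb = model@reactions$lower_bound,
                    ub = model@reactions$upper_bound,
                    enzymatic = model@reactions$enzymatic,
                    exchange = model@reactions$exchange,
                    objective = model@reactions$id == model@objectiveReaction)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- SBML ---------------------------------------------------------------------

.xfind <- function(node, tag) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", tag))
}

.readSBML <- function(path, name, objective = NULL, bigBound = 1000) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) .stopf("SBML parse failure in '%s': %s",
                                             path, conditionMessage(e)))
  spNodes <- .xfind(doc, "species")
  if (!length(spNodes)) .stopf("SBML file '%s' declares no species", path)
  spId <- xml2::xml_attr(spNodes, "id")
  boundary <- xml2::xml_attr(spNodes, "boundaryCondition") %in% c("true", "1")
  mets <- data.frame(id = spId,
                     name = ifelse(is.na(xml2::xml_attr(spNodes, "name")),
                                   spId, xml2::xml_attr(spNodes, "name")),
                     compartment = xml2::xml_attr(spNodes, "compartment"))
  mets <- mets[!boundary, , drop = FALSE]
  # global parameters (SBML L3/fbc keeps bounds here)
  parNodes <- xml2::xml_find_all(doc,
    "./*[local-name()='model']/*[local-name()='listOfParameters']/*[local-name()='parameter']")
  globalPar <- stats::setNames(as.numeric(xml2::xml_attr(parNodes, "value")),
                               xml2::xml_attr(parNodes, "id"))
  rxNodes <- .xfind(doc, "reaction")
  if (!length(rxNodes)) .stopf("SBML file '%s' declares no reactions", path)
  ids <- xml2::xml_attr(rxNodes, "id")
  n <- length(ids)
  lb <- numeric(n); ub <- numeric(n)
  stoich <- vector("list", n)
  for (i in seq_len(n)) {
    node <- rxNodes[[i]]
    refs <- function(tag) {
      sr <- xml2::xml_find_all(node, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(st, xml2::xml_attr(sr, "species"))
    }
    prod <- refs("listOfProducts")
    reac <- refs("listOfReactants")
    cf <- c(-reac, prod)
    cf <- tapply(cf, names(cf), sum)
    cf <- stats::setNames(as.numeric(cf), names(cf))
    bad <- setdiff(names(cf), spId)
    if (length(bad)) {
      .stopf("reaction '%s' references undeclared species: %s",
             ids[i], paste(bad, collapse = ", "))
    }
    stoich[[i]] <- cf[abs(cf) > 0]
    # bounds: fbc attributes referencing global parameters, else kinetic-law
    # local parameters, else the `reversible` attribute
    attrs <- xml2::xml_attrs(node)
    lbRef <- attrs[grepl("lowerFluxBound$", names(attrs))]
    ubRef <- attrs[grepl("upperFluxBound$", names(attrs))]
    loc <- xml2::xml_find_all(node,
      ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")
    locPar <- stats::setNames(as.numeric(xml2::xml_attr(loc, "value")),
                              xml2::xml_attr(loc, "id"))
    rev <- xml2::xml_attr(node, "reversible")
    if (length(lbRef) && lbRef %in% names(globalPar)) {
      lb[i] <- globalPar[[lbRef]]
    } else if ("LOWER_BOUND" %in% names(locPar)) {
      lb[i] <- locPar[["LOWER_BOUND"]]
    } else {
      lb[i] <- if (isTRUE(rev == "false")) 0 else -bigBound
    }
    if (length(ubRef) && ubRef %in% names(globalPar)) {
      ub[i] <- globalPar[[ubRef]]
    } else if ("UPPER_BOUND" %in% names(locPar)) {
      ub[i] <- locPar[["UPPER_BOUND"]]
    } else {
      ub[i] <- bigBound
    }
  }
  # drop boundary species from stoichiometries (they are outside the balance)
  stoich <- lapply(stoich, function(cf) cf[names(cf) %in% mets$id])
  empty <- !vapply(stoich, length, 1L)
  if (any(empty)) {
    # pure boundary<->boundary reactions carry no constraint; drop them
    ids <- ids[!empty]; lb <- lb[!empty]; ub <- ub[!empty]
    stoich <- stoich[!empty]
    n <- length(ids)
  }
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, ids))
  for (i in seq_len(n)) S[names(stoich[[i]]), i] <- stoich[[i]]
  exch <- grepl("^(R_)?EX_", ids) | colSums(S != 0) == 1
  if (is.null(objective)) {
    fo <- .xfind(doc, "fluxObjective")
    if (length(fo)) {
      attrs <- xml2::xml_attrs(fo[[1]])
      objective <- unname(attrs[grepl("reaction$", names(attrs))][1])
    } else {
      hit <- grep("biomass", ids, ignore.case = TRUE)
      if (!length(hit)) .stopf("no objective declared in '%s'; pass `objective`", path)
      objective <- ids[hit[1]]
    }
  }
  MetabolicModel(metabolites = mets,
                 reactions = data.frame(id = ids, lower_bound = lb,
                                        upper_bound = ub,
                                        enzymatic = !exch, exchange = exch),
                 stoichiometry = S, objective = objective, name = name)
}

# --- bound edits --------------------------------------------------------------

#' Set flux bounds on a reaction
#'
#' Returns a modified copy; the input model is never mutated.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param id reaction id.
#' @param lower,upper new bounds (mmol/gDW/h); \code{NULL} leaves a bound
#'   unchanged.
#' @return the modified model.
#' @export
setReactionBounds <- function(model, id, lower = NULL, upper = NULL) {
  i <- match(id, model@reactions$id)
  if (is.na(i)) .stopf("unknown reaction id: %s", id)
  if (!is.null(lower)) model@reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model@reactions$upper_bound[i] <- upper
  methods::validObject(model)
  model
}

#' Flag reactions as enzymatic or not
#'
#' Crowding coefficients are only sampled for enzymatic reactions; spontaneous
#' reactions, exchanges and pseudo-reactions (biomass, ATP drain) should carry
#' \code{enzymatic = FALSE} so that [sampleCrowding()] assigns them cost 0.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param ids reaction ids to re-flag.
#' @param value logical flag.
#' @return the modified model.
#' @export
setEnzymatic <- function(model, ids, value) {
  i <- match(ids, model@reactions$id)
  if (anyNA(i)) .stopf("unknown reaction id(s): %s",
                       paste(ids[is.na(i)], collapse = ", "))
  model@reactions$enzymatic[i] <- value
  model
}

# --- built-in simplified network ---------------------------------------------

#' The five-reaction fermentation/respiration network
#'
#' A lumped model of the choice between fermentation and respiration in a
#' facultative anaerobe. Five internal reactions -- glycolysis, acetate
#' excretion, lactate/ethanol excretion, the TCA cycle, and oxidative
#' phosphorylation -- are coupled through pyruvate, NADH and ATP. Growth is
#' proxied by an ATP-drain objective (\code{DM_atp}) because the lumped model
#' has no biomass composition.
#'
#' Default stoichiometry (configurable through \code{coef}):
#' \itemize{
#'   \item \code{R_glycolysis}: 1 glc -> 2 pyr + 2 atp + 2 nadh
#'   \item \code{R_acetate}: 1 pyr -> 1 ac + 1 co2 + 1 atp + 1 nadh
#'     (the pyruvate-dehydrogenase NADH is folded in)
#'   \item \code{R_lactate}: 1 pyr + 1 nadh -> 1 waste (lactate/ethanol lumped)
#'   \item \code{R_tca}: 1 pyr -> 3 co2 + 5 nadh + 1 atp
#'     (FADH2 lumped as NADH, GTP as ATP)
#'   \item \code{R_oxphos}: 1 nadh + 0.5 o2 -> 2 atp (P/O ratio 2)
#' }
#' plus exchanges for glucose, oxygen, acetate, waste and CO2. Every
#' steady-state route is redox-closed (net NADH 0) and carbon-balanced. The
#' network has exactly three ATP-yielding elementary flux modes -- lactate
#' fermentation (2 ATP/glc), acetate + oxidative phosphorylation (12 ATP/glc)
#' and TCA + oxidative phosphorylation (28 ATP/glc) -- so the yield ordering
#' lactate < acetate+oxphos < TCA+oxphos holds by construction.
#'
#' @param glucoseUptake maximal glucose uptake magnitude (mmol/gDW/h) put on
#'   the glucose exchange lower bound.
#' @param coef named list overriding individual stoichiometric coefficients:
#'   \code{glycNADH}, \code{glycATP} (per glucose), \code{acNADH},
#'   \code{acATP} (per pyruvate), \code{lacNADH} (consumed per pyruvate),
#'   \code{tcaNADH}, \code{tcaATP} (per pyruvate), \code{poRatio} (ATP per
#'   NADH oxidized).
#' @return A validated \linkS4class{MetabolicModel}.
#' @export
buildSimplifiedNetwork <- function(glucoseUptake = 10, coef = list()) {
  cf <- utils::modifyList(list(glycNADH = 2, glycATP = 2, acNADH = 1,
                               acATP = 1, lacNADH = 1, tcaNADH = 5,
                               tcaATP = 1, poRatio = 2), coef)
  eq <- function(fmt, ...) sprintf(fmt, ...)
  tab <- data.frame(
    id = c("R_glycolysis", "R_acetate", "R_lactate", "R_tca", "R_oxphos",
           "EX_glc", "EX_o2", "EX_ac", "EX_waste", "EX_co2", "DM_atp"),
    equation = c(
      eq("1 glc -> 2 pyr + %g atp + %g nadh", cf$glycATP, cf$glycNADH),
      eq("1 pyr -> 1 ac + 1 co2 + %g atp + %g nadh", cf$acATP, cf$acNADH),
      eq("1 pyr + %g nadh -> 1 waste", cf$lacNADH),
      eq("1 pyr -> 3 co2 + %g nadh + %g atp", cf$tcaNADH, cf$tcaATP),
      eq("1 nadh + 0.5 o2 -> %g atp", cf$poRatio),
      "glc ->", "o2 ->", "ac ->", "waste ->", "co2 ->", "atp ->"),
    lb = c(0, 0, 0, 0, 0, -glucoseUptake, -1000, 0, 0, 0, 0),
    ub = c(1000, 1000, 1000, 1000, 1000, 0, 0, 1000, 1000, 1000, 1000),
    enzymatic = c(rep(TRUE, 5), rep(FALSE, 6)),
    exchange = c(rep(FALSE, 5), rep(TRUE, 6)))
  .modelFromTable(tab, name = "simplified_network", objective = "DM_atp")
}

# --- media --------------------------------------------------------------------

#' Read a medium description
#'
#' Tab-separated file with columns \code{type}, \code{id}, \code{value}.
#' \code{type} is one of \code{uptake} (maximal uptake magnitude for an
#' exchange reaction, mmol/gDW/h), \code{biomass} (biomass content of an
#' amino acid, mmol/gDW, keyed by its exchange reaction id) or
#' \code{growth} (the observed maximal growth rate, 1/h; \code{id} ignored).
#'
#' @param path file path.
#' @return a medium list with elements \code{uptakeBounds},
#'   \code{biomassComposition}, \code{observedMaxGrowth}.
#' @export
readMedium <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("type", "id", "value")
  if (!all(need %in% names(tab))) {
    .stopf("medium file must have columns %s", paste(need, collapse = ", "))
  }
  up <- tab[tab$type == "uptake", ]
  bm <- tab[tab$type == "biomass", ]
  gr <- tab[tab$type == "growth", ]
  list(uptakeBounds = stats::setNames(up$value, up$id),
       biomassComposition = stats::setNames(bm$value, bm$id),
       observedMaxGrowth = if (nrow(gr)) gr$value[1] else NA_real_)
}

#' Apply a growth medium to a model
#'
#' Sets exchange uptake bounds from a medium description. Uptake magnitudes
#' are applied to the exchange \emph{lower} bound as their negation (uptake =
#' negative exchange flux). For amino acids the maximal uptake rate is the
#' biomass content of that amino acid multiplied by twice the observed
#' maximal growth rate, so that amino-acid supply never limits growth below
#' twice the observed rate.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium a list as returned by [readMedium()]: \code{uptakeBounds}
#'   (named, mmol/gDW/h, >= 0), \code{biomassComposition} (named by amino-acid
#'   exchange id, mmol/gDW, >= 0), \code{observedMaxGrowth} (1/h).
#' @return a modified copy of the model; stoichiometry and internal-reaction
#'   bounds are untouched.
#' @export
applyMedium <- function(model, medium) {
  up <- medium$uptakeBounds %||% numeric(0)
  bm <- medium$biomassComposition %||% numeric(0)
  mu <- medium$observedMaxGrowth
  if (any(up < 0) || any(bm < 0)) .stopf("uptake bounds and biomass coefficients must be >= 0")
  if (length(bm) && (!.isNumber(mu) || mu < 0)) {
    .stopf("observedMaxGrowth must be a single number >= 0 when amino acids are given")
  }
  aaUptake <- if (length(bm)) bm * 2 * mu else numeric(0)
  all <- c(up, aaUptake)
  missing <- setdiff(names(all), model@reactions$id)
  if (length(missing)) {
    .stopf("medium references unknown exchange reaction(s): %s",
           paste(missing, collapse = ", "))
  }
  notExch <- names(all)[!model@reactions$exchange[match(names(all), model@reactions$id)]]
  if (length(notExch)) {
    .stopf("medium references non-exchange reaction(s): %s",
           paste(notExch, collapse = ", "))
  }
  i <- match(names(all), model@reactions$id)
  model@reactions$lower_bound[i] <- -unname(all)
  methods::validObject(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
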