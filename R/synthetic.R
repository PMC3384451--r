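# Synthetic inputs: turnover/mass tables with multi-decade spread, branched
# toy networks with cofactor coupling, and noiseless observed-growth data
# for budget-recovery tests.

#' Generate a synthetic enzyme turnover/mass table
#'
#' Emulates a curated database extract: turnover numbers and molar masses
#' are drawn log-uniformly over multi-decade ranges (real extracts show
#' broad histograms spanning orders of magnitude without an obvious
#' parametric family; log-uniform is the least-informative match). A
#' fraction of enzymes additionally receives a non-wild-type record
#' (exercising the wild-type-preference filter) and a fraction receives a
#' sub-threshold turnover number below 0.01/s (exercising the retention
#' filter).
#'
#' @param nEnzymes number of distinct enzymes.
#' @param log10KcatRange range of log10 turnover numbers (1/s); default
#'   \code{c(-2, 4)}.
#' @param log10MassRange range of log10 molar masses (g/mol); default
#'   \code{c(4, 6)}, i.e. 10 kDa - 1 MDa.
#' @param mutantFraction fraction of enzymes with an extra mutant record.
#' @param subThresholdFraction fraction of enzymes whose wild-type turnover
#'   number falls below the 0.01/s retention threshold.
#' @param seed integer; the generator is a pure function of its arguments.
#' @return data.frame of raw records (columns \code{enzyme_id}, \code{kcat},
#'   \code{mass}, \code{wild_type}, \code{substrate}) for [buildKcatTable()].
#' @export
generateKcatTable <- function(nEnzymes, log10KcatRange = c(-2, 4),
                              log10MassRange = c(4, 6), mutantFraction = 0.1,
                              subThresholdFraction = 0.1, seed = 1) {
  if (!.isCount(nEnzymes)) .stopf("nEnzymes must be a positive count")
  if (diff(log10KcatRange) < 0 || diff(log10MassRange) < 0) {
    .stopf("ranges must be ordered")
  }
  if (mutantFraction < 0 || mutantFraction > 1 ||
      subThresholdFraction < 0 || subThresholdFraction > 1) {
    .stopf("fractions must be in [0, 1]")
  }
  .withSeed(seed, {
    ids <- sprintf("enz%04d", seq_len(nEnzymes))
    kcat <- 10^stats::runif(nEnzymes, log10KcatRange[1], log10KcatRange[2])
    mass <- 10^stats::runif(nEnzymes, log10MassRange[1], log10MassRange[2])
    nSub <- floor(subThresholdFraction * nEnzymes)
    if (nSub > 0) {
      sub <- sample.int(nEnzymes, nSub)
      # strictly below the 0.01/s retention threshold
      kcat[sub] <- 10^stats::runif(nSub, -4, log10(0.01) - 1e-9)
    }
    rec <- data.frame(enzyme_id = ids, kcat = kcat, mass = mass,
                      wild_type = TRUE, substrate = "native")
    nMut <- floor(mutantFraction * nEnzymes)
    if (nMut > 0) {
      mut <- sample.int(nEnzymes, nMut)
      rec <- rbind(rec, data.frame(
        enzyme_id = ids[mut],
        kcat = 10^stats::runif(nMut, log10KcatRange[1], log10KcatRange[2]),
        mass = mass[mut], wild_type = FALSE, substrate = "engineered"))
    }
    rec[order(rec$enzyme_id, !rec$wild_type), ]
  })
}

#' Write a raw turnover record table in the readable dialect
#'
#' @param records data.frame from [generateKcatTable()].
#' @param path output path (tab-separated, header \code{enzyme_id},
#'   \code{kcat_per_s}, \code{mass_da}, \code{wild_type}, \code{substrate}).
#' @return \code{path}, invisibly.
#' @export
writeKcatTable <- function(records, path) {
  utils::write.table(
    data.frame(enzyme_id = records$enzyme_id, kcat_per_s = records$kcat,
               mass_da = records$mass, wild_type = records$wild_type,
               substrate = records$substrate),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a branched toy metabolic network
#'
#' A glycolysis-like backbone (1 glucose -> 2 pyruvate, plus 2 NADH when
#' cofactor coupling is on) feeds \code{nBranches} alternative ATP-producing
#' branches, each excreting its own waste product. With cofactor coupling,
#' every branch consumes one NADH per pyruvate, so each backbone+branch
#' combination is redox-closed and forms one elementary flux mode; branch
#' \eqn{i} yields exactly \code{atpYields[i]} ATP per glucose. The objective
#' is an ATP drain.
#'
#' @param nBranches number of branches, >= 2.
#' @param atpYields ATP per glucose of each branch; all > 0, not all equal.
#' @param cofactorCoupling couple branches through the NADH pool.
#' @param glucoseUptake maximal glucose uptake magnitude (mmol/gDW/h).
#' @param seed integer; permutes the branch order (the generator is a pure
#'   function of its arguments).
#' @return a validated \linkS4class{MetabolicModel}.
#' @export
generateToyNetwork <- function(nBranches = 2, atpYields = c(2, 28),
                               cofactorCoupling = TRUE, glucoseUptake = 10,
                               seed = 1) {
  if (!.isCount(nBranches) || nBranches < 2) .stopf("nBranches must be >= 2")
  if (length(atpYields) != nBranches) .stopf("need one ATP yield per branch")
  if (any(atpYields <= 0)) .stopf("atpYields must be > 0")
  if (length(unique(atpYields)) == 1) .stopf("atpYields must not all be equal")
  ord <- .withSeed(seed, sample.int(nBranches))
  atpYields <- atpYields[ord]
  branchIds <- sprintf("R_branch%d", seq_len(nBranches))
  backbone <- if (cofactorCoupling) "1 glc -> 2 pyr + 2 nadh" else "1 glc -> 2 pyr"
  branchEq <- vapply(seq_len(nBranches), function(i) {
    lhs <- if (cofactorCoupling) "1 pyr + 1 nadh" else "1 pyr"
    sprintf("%s -> 1 waste%d + %.10g atp", lhs, i, atpYields[i] / 2)
  }, character(1))
  tab <- data.frame(
    id = c("R_backbone", branchIds, "EX_glc",
           sprintf("EX_waste%d", seq_len(nBranches)), "DM_atp"),
    equation = c(backbone, branchEq, "glc ->",
                 sprintf("waste%d ->", seq_len(nBranches)), "atp ->"),
    lb = c(rep(0, nBranches + 1), -glucoseUptake, rep(0, nBranches + 1)),
    ub = c(rep(1000, nBranches + 1), 0, rep(1000, nBranches + 1)),
    enzymatic = c(rep(TRUE, nBranches + 1), rep(FALSE, nBranches + 2)),
    exchange = c(rep(FALSE, nBranches + 1), rep(TRUE, nBranches + 2)))
  .modelFromTable(tab, name = sprintf("toy_network_%db", nBranches),
                  objective = "DM_atp")
}

#' Generate synthetic observed growth data at a known crowding budget
#'
#' Runs an ensemble at \code{trueVprot} and returns the ensemble-mean maximal
#' growth rate and glucose uptake as synthetic "observations", enabling
#' round-trip recovery tests for [fitVprot()]. With a degenerate one-point
#' crowding distribution the observations are noiseless deterministic
#' functions of \code{trueVprot}.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param dist a \linkS4class{CrowdingDistribution}.
#' @param config base [solverConfig()]; \code{vProt} overridden by
#'   \code{trueVprot}.
#' @param trueVprot the generating crowding budget, in (0, 1].
#' @param n ensemble size.
#' @param seed master seed.
#' @param glucoseBound glucose uptake bound for the ensemble (see
#'   [runEnsemble()]).
#' @return list with \code{muMaxObs} (1/h) and \code{gupMaxObs} (mmol/gDW/h).
#' @export
generateObservedGrowth <- function(model, dist, config = solverConfig(),
                                   trueVprot = 0.15, n = 100, seed = 1,
                                   glucoseBound = config$bigBound) {
  if (trueVprot <= 0 || trueVprot > 1) .stopf("trueVprot must be in (0, 1]")
  cfg <- config
  cfg$vProt <- trueVprot
  ens <- runEnsemble(model, dist, cfg, n = n, masterSeed = seed,
                     glucoseBound = glucoseBound)
  s <- ens@samples[ens@samples$status == "optimal", ]
  if (!nrow(s)) .stopf("no feasible ensemble samples at trueVprot = %g", trueVprot)
  list(muMaxObs = mean(s$growth_rate), gupMaxObs = mean(s$glucose_uptake))
}
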