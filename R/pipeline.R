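# Pipeline orchestration and tabular/JSON report emission.

#' Equal-width histogram table
#'
#' @param values nonempty numeric vector.
#' @param nBins number of equal-width bins over \code{[min, max]}.
#' @return data.frame with columns \code{bin_left}, \code{bin_right},
#'   \code{count}; counts sum to \code{length(values)}.
#' @export
emitHistogram <- function(values, nBins = 30) {
  values <- values[!is.na(values)]
  if (!length(values)) .stopf("no values to bin")
  if (!.isCount(nBins)) .stopf("nBins must be a positive count")
  lo <- min(values); hi <- max(values)
  if (hi == lo) {
    return(data.frame(bin_left = lo, bin_right = hi, count = length(values)))
  }
  edges <- seq(lo, hi, length.out = nBins + 1)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1],
             count = tabulate(idx, nbins = nBins))
}

#' Run a configured pipeline stage
#'
#' Orchestrates model loading, crowding-distribution construction, the
#' requested experiment, and report emission. The configuration is a list
#' (or a path to a JSON/YAML file) with fields:
#' \describe{
#'   \item{experiment}{one of \code{"ensemble"}, \code{"modes"},
#'     \code{"growth-curve"}, \code{"fit-vprot"}, \code{"synth"}.}
#'   \item{model}{\code{"simplified"} for the built-in five-reaction network,
#'     or a file path; \code{model_format} selects the dialect
#'     (\code{"reaction-table"} default, or \code{"sbml"}).}
#'   \item{kcat_table}{path to a turnover/mass table, or NULL to use
#'     \code{synthetic_kcat} (a list of [generateKcatTable()] arguments;
#'     defaults used when absent).}
#'   \item{v_prot / fit}{exactly one: a fixed crowding budget, or a list
#'     with \code{grid}, \code{mu_max_obs}, \code{gup_max_obs}.}
#'   \item{n_samples, master_seed}{ensemble size and master seed.}
#'   \item{glucose_grid}{uptake-bound grid for growth curves / switch
#'     statistics (optional).}
#'   \item{knockouts}{exchange reaction ids to block (optional).}
#'   \item{overexpression}{list of \code{list(type = "nox"|"aox",
#'     min_flux = ...)} entries (optional).}
#'   \item{output_dir}{directory for the emitted tables and manifest.}
#' }
#' Outputs are deterministic: identical configurations produce byte-identical
#' tables. Progress is logged to standard error unless \code{quiet}.
#'
#' @param config list or path to a JSON/YAML config file.
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- .readConfig(config)
  cfg <- utils::modifyList(
    list(experiment = "ensemble", model = "simplified",
         model_format = "reaction-table", kcat_table = NULL,
         synthetic_kcat = list(), v_prot = NULL, fit = NULL,
         n_samples = 100, master_seed = 1, glucose_grid = NULL,
         knockouts = NULL, overexpression = NULL, n_bins = 30,
         cell_density = 340, specific_volume = 0.73,
         mode_rel_tol = 0.01, mode_min_freq = 0.01,
         output_dir = "crowdfba_out"),
    config)
  if (is.null(cfg$v_prot) == is.null(cfg$fit) && cfg$experiment != "synth") {
    .stopf("exactly one of v_prot / fit must be set")
  }
  if (!.isCount(cfg$n_samples)) .stopf("n_samples must be >= 1")
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(x) file.path(cfg$output_dir, x)
  writeTsv <- function(d, name) {
    utils::write.table(d, outfile(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    name
  }
  manifest <- list(package = "crowdFBA",
                   version = as.character(utils::packageVersion("crowdFBA")),
                   config = cfg, outputs = character(0))

  if (cfg$experiment == "synth") {
    say("generating synthetic inputs")
    rec <- do.call(generateKcatTable,
                   utils::modifyList(list(nEnzymes = 200, seed = cfg$master_seed),
                                     cfg$synthetic_kcat))
    writeKcatTable(rec, outfile("kcat_table.tsv"))
    writeReactionTable(buildSimplifiedNetwork(), outfile("model.tsv"))
    manifest$outputs <- c("kcat_table.tsv", "model.tsv")
    jsonlite::write_json(manifest, outfile("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(manifest))
  }

  model <- if (identical(cfg$model, "simplified")) buildSimplifiedNetwork()
           else readModel(cfg$model, cfg$model_format)
  for (ko in cfg$knockouts) {
    say("knocking out %s", ko)
    model <- knockoutExchange(model, ko)
  }
  for (ox in cfg$overexpression) {
    spec <- switch(ox$type, nox = noxReaction(), aox = aoxReaction(),
                   .stopf("unknown overexpression type '%s'", ox$type))
    say("adding %s with enforced flux >= %g", spec$id, ox$min_flux %||% 0)
    model <- addOverexpression(model, spec, ox$min_flux %||% 0)
  }
  records <- if (!is.null(cfg$kcat_table)) readKcatTable(cfg$kcat_table)
             else do.call(generateKcatTable,
                          utils::modifyList(list(nEnzymes = 200,
                                                 seed = cfg$master_seed),
                                            cfg$synthetic_kcat))
  dist <- buildCrowdingDistribution(buildKcatTable(records),
                                    cellDensity = cfg$cell_density,
                                    specificVolume = cfg$specific_volume)
  baseCfg <- solverConfig(vProt = cfg$v_prot %||% 0.2)

  if (cfg$experiment %in% c("ensemble", "modes")) {
    say("running ensemble: n = %d, V_prot = %g", cfg$n_samples, baseCfg$vProt)
    ens <- runEnsemble(model, dist, baseCfg, n = cfg$n_samples,
                       masterSeed = cfg$master_seed,
                       glucoseGrid = cfg$glucose_grid)
    manifest$outputs <- c(manifest$outputs,
                          writeTsv(ens@samples, "ensemble.tsv"))
    ok <- ens@samples$status == "optimal"
    if (any(ok)) {
      manifest$outputs <- c(manifest$outputs,
        writeTsv(emitHistogram(ens@samples$yield[ok], cfg$n_bins),
                 "yield_histogram.tsv"))
    }
    manifest$mode_count <- countMetabolicModes(ens, cfg$mode_rel_tol,
                                               cfg$mode_min_freq)
    manifest$low_yield_fraction <- mean(ens@samples$low_yield[ok])
    say("mode count: %d", manifest$mode_count)
  } else if (cfg$experiment == "growth-curve") {
    if (is.null(cfg$glucose_grid)) .stopf("growth-curve needs glucose_grid")
    say("glucose scan over %d points", length(cfg$glucose_grid))
    cr <- sampleCrowding(model, dist, cfg$master_seed)
    curve <- growthCurve(model, cr, baseCfg, cfg$glucose_grid)
    manifest$outputs <- c(manifest$outputs,
                          writeTsv(as.data.frame(curve), "growth_curve.tsv"))
    reps <- attr(curve, "reporters")
    stats <- do.call(rbind, lapply(names(reps), function(rp) {
      st <- fluxDecreaseStatistic(curve, rp)
      data.frame(reporter = rp, reaction = unname(reps[rp]),
                 flux_decrease = st$flux_decrease,
                 max_reporter_flux = st$max_reporter_flux,
                 flagged = st$flagged)
    }))
    manifest$outputs <- c(manifest$outputs,
                          writeTsv(stats, "switch_statistics.tsv"))
  } else if (cfg$experiment == "fit-vprot") {
    say("fitting V_prot over %d grid values", length(cfg$fit$grid))
    fit <- fitVprot(model, dist,
                    observed = list(muMaxObs = cfg$fit$mu_max_obs,
                                    gupMaxObs = cfg$fit$gup_max_obs),
                    grid = cfg$fit$grid, n = cfg$n_samples,
                    masterSeed = cfg$master_seed, config = baseCfg)
    manifest$outputs <- c(manifest$outputs,
                          writeTsv(fit$fitTable, "vprot_fit.tsv"))
    manifest$fitted_v_prot <- fit$vProt
    say("fitted V_prot: %g", fit$vProt)
  } else {
    .stopf("unknown experiment '%s'", cfg$experiment)
  }
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.readConfig <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
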