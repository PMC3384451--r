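# Fixtures built in code.

# Linear chain A_ext -> A -> B -> B_ext with uptake bound `uptake` and the
# terminal drain as objective.
chain_model <- function(uptake = 1) {
  tab <- data.frame(
    id = c("EX_A", "R_uptake", "R_convert", "DM_B"),
    equation = c("A_ext ->", "A_ext -> A", "A -> B", "B ->"),
    lb = c(-uptake, 0, 0, 0),
    ub = c(0, 1000, 1000, 1000),
    enzymatic = c(FALSE, TRUE, TRUE, FALSE),
    exchange = c(TRUE, FALSE, FALSE, TRUE))
  crowdFBA:::.modelFromTable(tab, name = "chain", objective = "DM_B")
}

# Uniform crowding assignment: coefficient `value` on enzymatic reactions.
uniform_assignment <- function(model, value = 1, seed = 0L) {
  cf <- stats::setNames(numeric(length(reactionIds(model))), reactionIds(model))
  cf[model@reactions$enzymatic] <- value
  methods::new("CrowdingAssignment", coefficients = cf, seed = as.integer(seed))
}

degenerate_distribution <- function(value = 0.01) {
  methods::new("CrowdingDistribution", coefficients = value,
               cellDensity = 340, specificVolume = 0.73)
}

broad_distribution <- function(seed = 42, n = 200) {
  tab <- buildKcatTable(generateKcatTable(n, seed = seed))
  buildCrowdingDistribution(tab)
}

# Coefficient pool for oracle-equivalence checks: kept in a range
# (~7e-3 .. 7 gDW h/mmol) where the crowding constraint is the single
# binding constraint at the optimum (fluxes stay far below the caps),
# the premise of the mode-ratio identity.
oracle_distribution <- function(seed = 5, n = 100) {
  tab <- buildKcatTable(generateKcatTable(
    n, log10KcatRange = c(-2, 0), log10MassRange = c(5, 6),
    mutantFraction = 0, subThresholdFraction = 0, seed = seed))
  buildCrowdingDistribution(tab)
}

internal_ids <- function(model) {
  ids <- reactionIds(model)
  ids[!grepl("^(R_)?EX_|^DM_", ids)]
}
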