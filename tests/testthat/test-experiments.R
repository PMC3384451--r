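# Growth curves, switch statistics, ensembles, knockouts, overexpression,
# budget fitting and mode counting.

test_that("growth curves: no carbon means no growth, and growth is monotone", {
  m <- buildSimplifiedNetwork()
  a <- sampleCrowding(m, oracle_distribution(), 21)
  c0 <- growthCurve(m, a, solverConfig(vProt = 0.2), glucoseGrid = 0)
  expect_equal(nrow(c0), 1)
  expect_equal(c0$growth_rate, 0, tolerance = 1e-9)
  grid <- c(0, 0.01, 0.05, 0.1, 0.5, 1, 5, 20)
  curve <- growthCurve(m, a, solverConfig(vProt = 0.2), grid)
  expect_equal(curve$glucose_bound, grid)
  expect_true(all(diff(curve$growth_rate) >= -1e-9))
  expect_true(all(curve$status == "optimal"))
  expect_true(all(c("oxygen", "acetate", "lactate") %in% names(curve)))
  expect_error(growthCurve(m, a, solverConfig(), numeric(0)), "empty")
  expect_error(growthCurve(m, a, solverConfig(), c(1, 0.5)), "ascending")
})

test_that("growth saturates exactly where the winning mode exhausts the budget", {
  m <- buildSimplifiedNetwork()
  a <- uniform_assignment(m, value = 1)
  vProt <- 0.3
  # uniform costs: TCA+oxphos wins both per glucose (28 ATP, cost 15) and per
  # cost, so mu(G) = min(28 G, 28 vProt / 15) -- saturation at G* = vProt/15
  gStar <- vProt / 15
  grid <- sort(c(gStar / 4, gStar / 2, gStar, 2 * gStar, 10 * gStar))
  curve <- growthCurve(m, a, solverConfig(vProt = vProt), grid)
  expect_equal(curve$growth_rate, pmin(28 * grid, 28 * vProt / 15),
               tolerance = 1e-8)
})

test_that("the flux-decrease statistic matches its definition", {
  curve <- data.frame(glucose_bound = 1:3, growth_rate = c(0.1, 0.5, 1),
                      status = "optimal", oxygen = c(-5, -10, -8))
  attr(curve, "reporters") <- c(oxygen = "EX_o2")
  st <- fluxDecreaseStatistic(curve, "oxygen")
  expect_equal(st$flux_decrease, (10 - 8) / 10) # hand-derived 0.2
  expect_false(st$flagged)
  # monotone reporter: maximum sits at the evaluation point
  curve$oxygen <- c(-2, -5, -9)
  expect_equal(fluxDecreaseStatistic(curve, "oxygen")$flux_decrease, 0)
  # complete shutdown
  curve$oxygen <- c(-9, -4, 0)
  expect_equal(fluxDecreaseStatistic(curve, "oxygen")$flux_decrease, 1)
  # reporter never active: zero with a flag
  curve$oxygen <- c(0, 0, 0)
  st0 <- fluxDecreaseStatistic(curve, "oxygen")
  expect_equal(st0$flux_decrease, 0)
  expect_true(st0$flagged)
})

test_that("the low-yield threshold is strict at 0.3 g/g", {
  expect_true(classifyLowYield(0.29))
  expect_false(classifyLowYield(0.30))
  expect_false(classifyLowYield(0.5))
  expect_error(classifyLowYield(-0.1), ">= 0")
})

test_that("excretion profiles classify by acetate vs fermentative efflux", {
  m <- buildSimplifiedNetwork()
  mk <- function(ac, waste) {
    methods::new("FluxSolution",
                 fluxes = c(EX_ac = ac, EX_waste = waste, EX_glc = -1),
                 growthRate = 1, crowdingUsage = 0.1, status = "optimal")
  }
  expect_identical(excretionProfile(mk(2, 0), m), "acetate_only")
  expect_identical(excretionProfile(mk(0, 1.5), m), "lactate_or_ethanol")
  expect_identical(excretionProfile(mk(1, 1), m), "mixed")
  expect_identical(excretionProfile(mk(0, 0), m), "none")
})

test_that("ensembles are reproducible and collapse under a degenerate pool", {
  m <- buildSimplifiedNetwork()
  d <- broad_distribution()
  e1 <- runEnsemble(m, d, solverConfig(vProt = 0.2), n = 12, masterSeed = 5)
  e2 <- runEnsemble(m, d, solverConfig(vProt = 0.2), n = 12, masterSeed = 5)
  expect_identical(ensembleSamples(e1), ensembleSamples(e2))
  dd <- degenerate_distribution(0.05)
  e3 <- runEnsemble(m, dd, solverConfig(vProt = 0.2), n = 6, masterSeed = 5)
  expect_equal(length(unique(ensembleSamples(e3)$yield)), 1)
})

test_that("every ensemble optimum realizes one elementary mode's yield", {
  m <- buildSimplifiedNetwork()
  modeYields <- oracle_mode_yields(m) / 0.18016 # ATP/glc -> the g/g-scaled axis
  d <- oracle_distribution()
  ens <- runEnsemble(m, d, solverConfig(vProt = 0.2), n = 60, masterSeed = 31)
  ylds <- ensembleSamples(ens)$yield
  expect_lte(length(unique(round(ylds, 6))), length(modeYields))
  for (y in unique(ylds)) {
    expect_true(any(abs(modeYields - y) / y < 1e-6))
  }
})

test_that("ensemble yields never exceed the stoichiometric yield optimum", {
  m <- buildSimplifiedNetwork()
  yMax <- computeYield(solveFBA(buildSimplifiedNetwork(glucoseUptake = 1)),
                       m, "EX_glc") # crowding can only reduce yield-optimality
  d <- broad_distribution()
  ens <- runEnsemble(m, d, solverConfig(vProt = 0.2), n = 40, masterSeed = 13)
  expect_true(all(ensembleSamples(ens)$yield <= yMax * (1 + 1e-9)))
})

test_that("exchange knockouts block efflux without touching anything else", {
  m <- buildSimplifiedNetwork()
  ko <- knockoutExchange(m, "EX_ac")
  expect_equal(reactionBounds(ko)$upper_bound[reactionIds(ko) == "EX_ac"], 0)
  # input untouched, all else identical
  expect_equal(reactionBounds(m)$upper_bound[reactionIds(m) == "EX_ac"], 1000)
  expect_identical(stoichiometry(ko), stoichiometry(m))
  expect_identical(knockoutExchange(ko, "EX_ac"), ko) # idempotent
  expect_error(knockoutExchange(m, "EX_nope"), "unknown reaction")
  # acetate flux is zero in every optimum of the reduced network
  d <- broad_distribution()
  mUnc <- setReactionBounds(ko, "EX_glc", lower = -1000)
  for (s in 1:10) {
    sol <- solveFBAwMC(mUnc, sampleCrowding(ko, d, s), solverConfig(vProt = 0.2))
    expect_equal(unname(fluxes(sol)[["EX_ac"]]), 0, tolerance = 1e-9)
  }
  # oracle: the winner is always lactate or TCA+oxphos, never the acetate mode
  expect_equal(unname(oracle_mode_yields(ko)), c(2, 28))
})

test_that("overexpression appends a forced-flux reaction", {
  m <- buildSimplifiedNetwork()
  # inactive addition leaves the optimum unchanged
  m0 <- addOverexpression(m, noxReaction(), minFlux = 0)
  expect_equal(growthRate(solveFBA(setReactionBounds(m0, "EX_glc", lower = -1))),
               growthRate(solveFBA(setReactionBounds(m, "EX_glc", lower = -1))),
               tolerance = 1e-9)
  # the enforced bound is respected
  m1 <- addOverexpression(m, noxReaction(), minFlux = 0.5)
  sol <- solveFBA(setReactionBounds(m1, "EX_glc", lower = -1))
  expect_gte(unname(fluxes(sol)[["NOX"]]), 0.5 - 1e-9)
  # input model untouched
  expect_false("NOX" %in% reactionIds(m))
})

test_that("forced NADH oxidation weakly suppresses the fermentative branch", {
  m <- buildSimplifiedNetwork()
  d <- oracle_distribution()
  cfg <- solverConfig(vProt = 0.2)
  mox <- addOverexpression(m, noxReaction(), minFlux = 0.05)
  for (s in 1:12) {
    a <- sampleCrowding(m, d, s)
    cfA <- crowdingCoefficients(a)
    # matched assignment on the extended model: NOX itself is cost-free so the
    # comparison isolates the redox effect of the forced sink
    cfB <- c(cfA, NOX = 0)
    aB <- methods::new("CrowdingAssignment", coefficients = cfB, seed = a@seed)
    base <- solveFBAwMC(setReactionBounds(m, "EX_glc", lower = -1000), a, cfg)
    forced <- solveFBAwMC(setReactionBounds(mox, "EX_glc", lower = -1000), aB, cfg)
    if (solverStatus(forced) != "optimal") next
    expect_lte(fluxes(forced)[["R_lactate"]],
               fluxes(base)[["R_lactate"]] + 1e-6)
  }
})

test_that("budget fitting recovers a known value and honors the argmin contract", {
  m <- buildSimplifiedNetwork()
  dd <- degenerate_distribution(0.01)
  grid <- seq(0.05, 0.3, by = 0.01)
  obs <- generateObservedGrowth(m, dd, trueVprot = 0.15, n = 5, seed = 3)
  fit <- fitVprot(m, dd, obs, grid = grid, n = 5, masterSeed = 3)
  expect_equal(fit$vProt, 0.15, tolerance = 1e-12)
  iBest <- which(fit$fitTable$v_prot == fit$vProt)
  expect_true(all(fit$fitTable$criterion >= fit$fitTable$criterion[iBest] - 1e-12))
  expect_error(fitVprot(m, dd, obs, grid = c(0, 0.5), n = 2), "\\(0, 1\\]")
  expect_error(fitVprot(m, dd, list(muMaxObs = -1, gupMaxObs = 1), grid = 0.1, n = 2),
               "> 0")
})

test_that("mode counting separates well-spaced clusters and drops rare ones", {
  expect_equal(countMetabolicModes(rep(0.25, 50)), 1)
  expect_equal(countMetabolicModes(c(rep(0.1, 50), rep(0.5, 50)),
                                   relTol = 0.01, minFreq = 0.01), 2)
  # a 0.5% stray cluster falls under the default 1% frequency floor
  expect_equal(countMetabolicModes(c(rep(0.1, 199), 0.5), relTol = 0.01,
                                   minFreq = 0.01), 1)
  # LP-noise-scale jitter does not split a cluster
  set.seed(1)
  jitter <- c(stats::rnorm(100, 0.1, 1e-6), stats::rnorm(100, 0.5, 1e-6))
  expect_equal(countMetabolicModes(jitter), 2)
})

test_that("mode counts agree with the oracle's winning-mode census", {
  m <- buildSimplifiedNetwork()
  modes <- oracle_modes(m)
  d <- oracle_distribution()
  cfg <- solverConfig(vProt = 0.2)
  ens <- runEnsemble(m, d, cfg, n = 150, masterSeed = 77)
  # oracle: which mode wins for each of the same draws?
  winners <- vapply(ensembleSamples(ens)$seed, function(s) {
    a <- sampleCrowding(m, d, s)
    coefs <- crowdingCoefficients(a)
    ratios <- vapply(modes, function(mm) {
      mm$objective / sum(coefs[mm$support] * mm$flux)
    }, numeric(1))
    which.max(ratios)
  }, integer(1))
  expect_equal(countMetabolicModes(ens),
               length(unique(winners[table(winners)[as.character(winners)] >=
                                       0.01 * length(winners)])))
})
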