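# LP core, plain flux balance, the crowding-constrained solve and yields.

test_that("the simplex core agrees with an independent LP implementation", {
  skip_if_not_installed("boot")
  # random bounded standard-form LPs: max c'x s.t. Ax = b, x >= 0, built
  # feasible by construction
  set.seed(17)
  for (k in 1:25) {
    m <- sample(2:4, 1); n <- m + sample(2:4, 1)
    A <- matrix(stats::runif(m * n, -1, 1), m, n)
    A <- cbind(A, diag(m)) # slack block guarantees full row rank
    x0 <- stats::runif(n + m, 0, 2)
    b <- drop(A %*% x0)
    # cap total mass so the maximum is finite
    A <- rbind(cbind(A, 0), c(rep(1, n + m), 1))
    b <- c(b, sum(x0) + 5)
    obj <- c(stats::runif(n + m, -1, 1), 0)
    mine <- crowdFBA:::.simplex(obj, A, b)
    ref <- boot::simplex(a = obj, A3 = A, b3 = b, maxi = TRUE)
    expect_equal(mine$status, "optimal")
    expect_equal(ref$solved, 1)
    expect_equal(mine$value, unname(ref$value), tolerance = 1e-7)
  }
})

test_that("flux conservation on a linear chain", {
  m <- chain_model(uptake = 1)
  sol <- solveFBA(m)
  expect_identical(solverStatus(sol), "optimal")
  expect_equal(growthRate(sol), 1, tolerance = 1e-9)
  expect_equal(unname(fluxes(sol)["R_convert"]), 1, tolerance = 1e-9)
  # clamped objective
  m0 <- setReactionBounds(m, "DM_B", lower = 0, upper = 0)
  expect_equal(growthRate(solveFBA(m0)), 0, tolerance = 1e-12)
})

test_that("infeasible problems are reported as such", {
  m <- chain_model(uptake = 1)
  # force more flux through the chain than the uptake allows
  bad <- setReactionBounds(m, "R_convert", lower = 5)
  sol <- solveFBA(bad)
  expect_identical(solverStatus(sol), "infeasible")
  expect_length(fluxes(sol), 0)
})

test_that("unconstrained FBA on the five-reaction network hits the best mode yield", {
  m <- buildSimplifiedNetwork(glucoseUptake = 1)
  best <- max(oracle_mode_yields(m)) # 28 ATP per glucose, enumerated independently
  sol <- solveFBA(m)
  expect_equal(growthRate(sol), best, tolerance = 1e-9)
})

test_that("zero crowding cost reduces FBAwMC to FBA exactly", {
  m <- buildSimplifiedNetwork(glucoseUptake = 1)
  a0 <- uniform_assignment(m, value = 0)
  fba <- solveFBA(m)
  wmc <- solveFBAwMC(m, a0, solverConfig(vProt = 0.2))
  expect_equal(growthRate(wmc), growthRate(fba), tolerance = 1e-12)
  expect_equal(crowdingUsage(wmc), 0)
})

test_that("a loose budget reproduces the unconstrained optimum", {
  m <- buildSimplifiedNetwork(glucoseUptake = 1)
  a <- uniform_assignment(m, value = 1e-4)
  fba <- solveFBA(m)
  usage <- sum(crowdingCoefficients(a) * abs(fluxes(fba)))
  cfg <- solverConfig(vProt = min(1, usage * 10))
  wmc <- solveFBAwMC(m, a, cfg)
  expect_equal(growthRate(wmc), growthRate(fba), tolerance = 1e-6)
})

test_that("the crowding constraint is homogeneous in (c, vProt)", {
  m <- setReactionBounds(buildSimplifiedNetwork(), "EX_glc", lower = -1000)
  a1 <- uniform_assignment(m, value = 1)
  a3 <- uniform_assignment(m, value = 3)
  cfg1 <- solverConfig(vProt = 0.25)
  cfg3 <- solverConfig(vProt = 0.75)
  expect_equal(growthRate(solveFBAwMC(m, a1, cfg1)),
               growthRate(solveFBAwMC(m, a3, cfg3)), tolerance = 1e-9)
})

test_that("uniform unit costs select the best ATP-per-cost mode", {
  m <- setReactionBounds(buildSimplifiedNetwork(), "EX_glc", lower = -1000)
  a <- uniform_assignment(m, value = 1)
  sol <- solveFBAwMC(m, a, solverConfig(vProt = 1))
  # hand-derived mode ratios: lactate 2/3, acetate+oxphos 12/7, TCA+oxphos 28/15
  expect_equal(growthRate(sol), 28 / 15, tolerance = 1e-9)
  expect_lte(crowdingUsage(sol), 1 + 1e-6)
  f <- fluxes(sol)
  expect_gt(f[["R_tca"]], 0)
  expect_equal(unname(f[c("R_acetate", "R_lactate")]), c(0, 0), tolerance = 1e-9)
})

test_that("the FBAwMC optimum equals the oracle mode ratio across random draws", {
  m <- buildSimplifiedNetwork()
  mUnc <- setReactionBounds(m, "EX_glc", lower = -1000)
  modes <- oracle_modes(m)
  d <- oracle_distribution()
  cfg <- solverConfig(vProt = 0.2)
  for (s in 1:60) {
    a <- sampleCrowding(m, d, s)
    lp <- growthRate(solveFBAwMC(mUnc, a, cfg))
    or <- oracle_optimum(m, a, 0.2, modes)
    expect_equal(lp, or, tolerance = 1e-6)
  }
})

test_that("growth is monotone in the budget and the glucose bound", {
  m <- buildSimplifiedNetwork()
  a <- sampleCrowding(m, oracle_distribution(), 4)
  mus <- vapply(seq(0.05, 0.95, by = 0.1), function(vp) {
    growthRate(solveFBAwMC(setReactionBounds(m, "EX_glc", lower = -1000), a,
                           solverConfig(vProt = vp)))
  }, numeric(1))
  expect_true(all(diff(mus) >= -1e-9))
  mus2 <- vapply(c(0, 0.5, 1, 2, 5, 10, 50), function(g) {
    growthRate(solveFBAwMC(setReactionBounds(m, "EX_glc", lower = -g), a,
                           solverConfig(vProt = 0.2)))
  }, numeric(1))
  expect_true(all(diff(mus2) >= -1e-9))
})

test_that("the tie-break makes repeated solves return identical flux vectors", {
  m <- setReactionBounds(buildSimplifiedNetwork(), "EX_glc", lower = -1000)
  d <- oracle_distribution()
  for (s in c(3, 8)) {
    a <- sampleCrowding(m, d, s)
    s1 <- solveFBAwMC(m, a, solverConfig(vProt = 0.2))
    s2 <- solveFBAwMC(m, a, solverConfig(vProt = 0.2))
    expect_identical(fluxes(s1), fluxes(s2))
  }
})

test_that("optimal solutions satisfy steady state and the crowding budget", {
  m <- setReactionBounds(buildSimplifiedNetwork(), "EX_glc", lower = -1000)
  d <- broad_distribution()
  cfg <- solverConfig(vProt = 0.2)
  for (s in 1:20) {
    a <- sampleCrowding(m, d, s)
    sol <- solveFBAwMC(m, a, cfg)
    expect_identical(solverStatus(sol), "optimal")
    f <- fluxes(sol)
    resid <- max(abs(drop(stoichiometry(m) %*% f)))
    expect_lt(resid, 1e-6 * max(1, max(abs(f))))
    expect_lte(crowdingUsage(sol), cfg$vProt + 1e-6)
    bounds <- reactionBounds(m)
    expect_true(all(f >= bounds$lower_bound - 1e-6))
    expect_true(all(f <= bounds$upper_bound + 1e-6))
  }
})

test_that("missing crowding coefficients are a contract error", {
  m <- buildSimplifiedNetwork()
  short <- methods::new("CrowdingAssignment",
                        coefficients = c(R_glycolysis = 1), seed = 1L)
  expect_error(solveFBAwMC(m, short, solverConfig()), "lacks reaction")
})

test_that("yields follow the growth-per-glucose definition", {
  # mu = 0.2 /h at 5 mmol/gDW/h uptake: 0.2 / (5 * 0.18016) = 0.2220248 g/g
  sol <- methods::new("FluxSolution",
                      fluxes = c(EX_glc = -5, Biomass = 0.2),
                      growthRate = 0.2, crowdingUsage = NA_real_,
                      status = "optimal")
  m <- buildSimplifiedNetwork() # only used for the exchange lookup
  expect_equal(computeYield(sol, m, glucoseExchange = "EX_glc"),
               0.2 / (5 * 0.18016), tolerance = 1e-12)
  # doubling both leaves the yield unchanged
  sol2 <- methods::new("FluxSolution",
                       fluxes = c(EX_glc = -10, Biomass = 0.4),
                       growthRate = 0.4, crowdingUsage = NA_real_,
                       status = "optimal")
  expect_equal(computeYield(sol2, m, "EX_glc"), computeYield(sol, m, "EX_glc"))
  # zero uptake with zero growth is yield zero by convention
  sol0 <- methods::new("FluxSolution", fluxes = c(EX_glc = 0),
                       growthRate = 0, crowdingUsage = NA_real_,
                       status = "optimal")
  expect_equal(computeYield(sol0, m, "EX_glc"), 0)
  # positive growth without uptake is a mass imbalance
  solBad <- methods::new("FluxSolution", fluxes = c(EX_glc = 0),
                         growthRate = 1, crowdingUsage = NA_real_,
                         status = "optimal")
  expect_error(computeYield(solBad, m, "EX_glc"), "mass imbalance")
})

test_that("solver configs validate their domains", {
  expect_error(solverConfig(vProt = 0), "vProt")
  expect_error(solverConfig(vProt = 1.2), "vProt")
  expect_error(solverConfig(feasibilityTolerance = -1), "tolerances")
  expect_silent(solverConfig(vProt = 1))
})

test_that("solutions serialize to flux tables and JSON-ready summaries", {
  m <- buildSimplifiedNetwork(glucoseUptake = 1)
  sol <- solveFBA(m)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeFluxTable(sol, tmp)
  back <- utils::read.delim(tmp)
  expect_equal(nrow(back), length(fluxes(sol)))
  sm <- solutionSummary(sol, m)
  expect_identical(sm$status, "optimal")
  expect_equal(sm$growth_rate, 28)
  expect_equal(sm$yield, 28 / (1 * 0.18016), tolerance = 1e-9)
})
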