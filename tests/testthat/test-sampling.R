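# Metropolis acceptance, annealing and replica-exchange drivers, observers
# and the exact dynamic-programming oracle.

test_that("Metropolis acceptance follows min(1, exp(-dE/T))", {
  set.seed(22)
  expect_true(all(metropolisAccept(rep(0, 1000), 0.5)))     # dE = 0
  expect_true(all(metropolisAccept(rep(-5, 1000), 0.01)))   # downhill
  acc <- metropolisAccept(rep(1, 1e6), 1)
  expect_equal(mean(acc), exp(-1), tolerance = 0.01)
  err <- tryCatch(metropolisAccept(1, 0), condition = function(c) c)
  expect_s3_class(err, "threadmc_config_error")
})

test_that("replica-exchange swap probability uses the two-temperature criterion", {
  expect_equal(exchangeProbability(-3, -3, 0.1, 0.2), 1)    # equal energies
  expect_equal(exchangeProbability(-1, -5, 0.1, 0.2), 1)    # hot holds lower E
  expect_equal(exchangeProbability(-5, -1, 0.1, 0.2),
               exp((1 / 0.1 - 1 / 0.2) * (-4)))
})

test_that("sampler configuration is validated", {
  expect_equal(length(defaultTemperatures()), 10L)
  expect_error(SamplerConfig(temperatures = c(1, 0.5)), "increasing")
  expect_error(SamplerConfig(temperatures = c(-1, 2)), "positive")
  expect_error(SamplerConfig(temperatures = 1), "at least 2")
  expect_silent(SamplerConfig(temperatures = 1, mode = "annealing"))
  expect_error(SamplerConfig(mode = "tempering"), "mode")
})

flatProblem <- function(n = 24) {
  ThreadingProblem(ChainData(sequence = strrep("A", n)),
                   ChainData(sequence = strrep("A", n)))
}

test_that("a flat landscape accepts every feasible proposal", {
  n <- 24
  ff <- ForceField(list(matrixScoreTerm(matrix(0, n, n))), 1)
  cfg <- SamplerConfig(mode = "annealing", innerSteps = 500L, cycles = 10L,
                       seed = 4, sampleEvery = 0L)
  r <- runAnnealing(flatProblem(n), ff, cfg)
  st <- r@moverStats
  expect_equal(sum(st$accepted), sum(st$attempted) - sum(st$infeasible))
  expect_equal(r@bestRecord@totalEnergy, 0)
})

test_that("samplers are deterministic under a fixed seed", {
  fx <- toyThreadingFixture(30)
  ff <- defaultThreadingForceField()
  cfg <- SamplerConfig(innerSteps = 300L, cycles = 8L, seed = 99)
  r1 <- runREMC(fx$problem, ff, cfg)
  r2 <- runREMC(fx$problem, ff, cfg)
  expect_equal(r1@bestRecord@totalEnergy, r2@bestRecord@totalEnergy)
  expect_identical(alignmentBlocks(r1@bestRecord@alignment),
                   alignmentBlocks(r2@bestRecord@alignment))
  expect_equal(vapply(r1@records, function(x) x@totalEnergy, numeric(1)),
               vapply(r2@records, function(x) x@totalEnergy, numeric(1)))
  expect_identical(r1@samples, r2@samples)

  cfgA <- SamplerConfig(mode = "annealing", innerSteps = 300L, cycles = 8L,
                        seed = 31)
  a1 <- runAnnealing(fx$problem, ff, cfgA)
  a2 <- runAnnealing(fx$problem, ff, cfgA)
  expect_equal(a1@bestRecord@totalEnergy, a2@bestRecord@totalEnergy)
})

test_that("annealing improves on the initial random alignment", {
  fx <- toyThreadingFixture(30)
  ff <- ForceField(list(substitutionScoreTerm()), 1)
  cfg <- SamplerConfig(mode = "annealing", innerSteps = 500L, cycles = 10L,
                       seed = 8)
  set.seed(8)
  init <- randomAlignment(nResidues(fx$problem@query),
                          nResidues(fx$problem@template))
  e0 <- totalEnergy(ff, init, fx$problem)$total
  r <- runAnnealing(fx$problem, ff, cfg)
  expect_lte(r@bestRecord@totalEnergy, e0)
  # elitism: the reported best is the minimum over all kept records
  expect_equal(r@bestRecord@totalEnergy,
               min(vapply(r@records, function(x) x@totalEnergy, numeric(1))))
})

test_that("records carry a consistent per-term breakdown", {
  fx <- toyThreadingFixture(30)
  ff <- defaultThreadingForceField()
  r <- runREMC(fx$problem, ff,
               SamplerConfig(innerSteps = 400L, cycles = 10L, seed = 5))
  best <- r@bestRecord
  expect_gt(length(best@perTermEnergies), 0)
  expect_equal(best@totalEnergy, sum(ff@weights * best@perTermEnergies),
               tolerance = 1e-9)
  # and the breakdown matches an independent full evaluation
  expect_equal(best@totalEnergy,
               totalEnergy(ff, best@alignment, fx$problem)$total,
               tolerance = 1e-9)
})

test_that("suboptimal collection deduplicates, ranks and truncates", {
  mk <- function(qs, e) {
    new("AlignmentRecord",
        alignment = BlockAlignment(qs, qs, 4, queryLength = 20,
                                   templateLength = 20),
        totalEnergy = e, perTermEnergies = numeric(),
        replicaTemperature = 1, cycle = 1L)
  }
  # duplicates (same canonical form) collapse to the first
  recs <- list(mk(1, -5), mk(1, -5), mk(3, -7), mk(5, -7), mk(7, -1))
  out <- collectSuboptimal(recs, 10)
  expect_length(out, 4L)
  expect_equal(vapply(out, function(x) x@totalEnergy, numeric(1)),
               c(-7, -7, -5, -1))   # equal energies, distinct forms retained
  expect_length(collectSuboptimal(recs, 2), 2L)
  expect_equal(collectSuboptimal(recs, 2)[[1]]@totalEnergy, -7)
})

test_that("the Gotoh oracle solves trivial cases exactly", {
  # identity scoring of identical sequences: perfect diagonal
  S <- diag(6)
  r <- nwAffineOracle(S, 2, 0.5)
  expect_equal(r$score, 6)
  expect_equal(unname(alignmentBlocks(r$alignment)),
               matrix(c(1L, 1L, 6L), 1))

  # 1x1 matrix: the single cell is the score
  expect_equal(nwAffineOracle(matrix(3.5, 1, 1), 1, 1)$score, 3.5)
})

test_that("the Gotoh oracle matches brute-force enumeration on tiny instances", {
  set.seed(23)
  for (i in 1:6) {
    S <- matrix(rnorm(25, mean = 0.3), 5, 5)
    dp <- nwAffineOracle(S, 1.5, 0.4)
    bf <- oracleEnumerateAlignment(S, 1.5, 0.4)
    expect_equal(dp$score, bf, tolerance = 1e-9)
    # the traceback alignment attains the reported score
    a <- dp$alignment
    p <- residuePairs(a)
    gapE <- termEnergy(affineGapTerm(1.5, 0.4), a,
                       flatProblem(5))
    expect_equal(sum(S[p]) - gapE, dp$score, tolerance = 1e-9)
  }
})

test_that("REMC attains the DP optimum on small decomposable instances", {
  set.seed(24)
  insts <- lapply(1:5, function(i) matrix(rnorm(144), 12, 12))
  cons1 <- SamplingConstraints(1, 1)
  dummy <- flatProblem(12)
  wins <- 0
  for (i in seq_along(insts)) {
    S <- insts[[i]]
    dp <- nwAffineOracle(S, 5, 0.5)
    ff <- ForceField(list(matrixScoreTerm(-S), affineGapTerm()), c(1, 1))
    cfg <- SamplerConfig(innerSteps = 500L, cycles = 20L, seed = 100L + i,
                         sampleEvery = 0L, maxRecords = 20L)
    r <- runREMC(dummy, ff, cfg, constraints = cons1)
    # the DP optimum is a lower bound on every MC-visited energy ...
    expect_gte(r@bestRecord@totalEnergy, -dp$score - 1e-9)
    wins <- wins + (abs(r@bestRecord@totalEnergy + dp$score) < 1e-6)
  }
  # ... and is attained on these small instances
  expect_gte(wins, 4)
})

test_that("energy histograms cover every replica on a common grid", {
  fx <- toyThreadingFixture(30)
  r <- runREMC(fx$problem, defaultThreadingForceField(),
               SamplerConfig(innerSteps = 500L, cycles = 10L, seed = 12))
  h <- energyHistograms(r, 25)
  expect_setequal(unique(h$temperature), defaultTemperatures())
  expect_true(all(tapply(h$count, h$temperature, sum) > 0))
  expect_equal(nrow(h), 25 * 10)
})
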