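# Metropolis acceptance, simulated annealing, replica-exchange Monte Carlo
# and the observers collecting best/suboptimal alignments and per-replica
# energy histograms.

#' Metropolis acceptance test
#'
#' Accepts with probability `min(1, exp(-deltaEnergy / temperature))`;
#' energies and temperatures are dimensionless. Vectorized over
#' `deltaEnergy`.
#'
#' @param deltaEnergy numeric vector of proposed energy changes.
#' @param temperature positive temperature.
#' @return logical vector of accept decisions.
#' @examples
#' set.seed(1)
#' mean(metropolisAccept(rep(1, 1e5), 1))  # ~ exp(-1)
#' @export
metropolisAccept <- function(deltaEnergy, temperature) {
  if (temperature <= 0) configError("temperature must be positive")
  deltaEnergy <= 0 | runif(length(deltaEnergy)) < exp(-deltaEnergy / temperature)
}

#' Replica-exchange swap acceptance probability
#'
#' The two-temperature criterion
#' `min(1, exp((1/T_i - 1/T_j) (E_i - E_j)))` used when adjacent replicas
#' attempt to exchange states; at `T_i = T_j` it is always 1.
#'
#' @param energyI,energyJ current energies of the two replicas.
#' @param tempI,tempJ their temperatures.
#' @return the swap acceptance probability.
#' @export
exchangeProbability <- function(energyI, energyJ, tempI, tempJ) {
  pmin(1, exp((1 / tempI - 1 / tempJ) * (energyI - energyJ)))
}

# resolve NA defaults in a config against a concrete problem size
resolveConfig <- function(config, queryLength) {
  if (is.na(config@innerSteps))
    config@innerSteps <- as.integer(200L * queryLength)
  if (is.na(config@sampleEvery))
    config@sampleEvery <- max(1L, config@innerSteps %/% 100L)
  config
}

# turn the compiled engine's record list into ranked AlignmentRecord
# objects; the per-term breakdown (with the sampler's TM evaluation, so it
# sums to the sampled total) is computed for the top `breakdownTop` only
buildRecords <- function(raw, forceField, problem, qlen, tlen,
                         breakdownTop = 25L) {
  if (length(raw) == 0) return(list())
  energies <- vapply(raw, `[[`, numeric(1), "energy")
  ord <- order(energies)
  raw <- raw[ord]
  lapply(seq_along(raw), function(i) {
    r <- raw[[i]]
    aln <- newBlockAlignment(r$blocks, qlen, tlen)
    per <- numeric()
    tot <- r$energy
    if (i <= breakdownTop) {
      br <- totalEnergy(forceField, aln, problem, tmThorough = FALSE)
      per <- br$terms
      tot <- br$total
    }
    new("AlignmentRecord", alignment = aln, totalEnergy = tot,
        perTermEnergies = per, replicaTemperature = r$temperature,
        cycle = as.integer(r$cycle))
  })
}

samplingResultFrom <- function(res, forceField, problem, qlen, tlen, temps,
                               mode) {
  recs <- buildRecords(res$records, forceField, problem, qlen, tlen)
  ms <- res$moverStats
  moverStats <- data.frame(mover = MOVER_NAMES,
                           attempted = ms$attempted,
                           accepted = ms$accepted,
                           infeasible = ms$infeasible)
  if (!is.null(res$exchangeAttempted)) {
    exch <- data.frame(lowerReplica = seq_along(res$exchangeAttempted),
                       attempted = res$exchangeAttempted,
                       accepted = res$exchangeAccepted)
  } else {
    exch <- data.frame(lowerReplica = integer(), attempted = integer(),
                       accepted = integer())
  }
  samples <- if (is.list(res$samples)) res$samples else list(res$samples)
  names(samples) <- paste0("T", seq_along(samples))
  new("SamplingResult", records = recs, bestRecord = recs[[1]],
      samples = samples, temperatures = temps, moverStats = moverStats,
      exchangeStats = exch, cyclesRun = as.integer(res$cyclesRun),
      mode = mode)
}

#' Run a replica-exchange Monte Carlo alignment search
#'
#' One replica per ladder temperature, each started from an independent
#' random alignment. Every cycle each replica makes `innerSteps` mover
#' proposals under Metropolis acceptance at its own temperature, then
#' adjacent replicas attempt state swaps (alternating even/odd pairings)
#' with acceptance `min(1, exp((1/T_i - 1/T_j)(E_i - E_j)))`. Observers
#' keep the best and distinct suboptimal alignments plus thinned
#' per-replica energy samples for overlap diagnostics.
#'
#' @param problem a [ThreadingProblem-class].
#' @param forceField a [ForceField-class].
#' @param config a [SamplerConfig-class] with mode `"replica_exchange"`.
#' @param moverSet a [MoverSet-class] (default [defaultMoverSet()]).
#' @param constraints a [SamplingConstraints-class].
#' @return a [SamplingResult-class].
#' @export
runREMC <- function(problem, forceField, config = SamplerConfig(),
                    moverSet = defaultMoverSet(),
                    constraints = SamplingConstraints()) {
  if (config@mode != "replica_exchange")
    configError("config mode must be 'replica_exchange' for runREMC")
  qlen <- nResidues(problem@query)
  tlen <- nResidues(problem@template)
  config <- resolveConfig(config, qlen)
  ctx <- compileForceField(forceField, problem)
  minB <- effectiveMinBlocks(qlen, tlen, constraints)
  set.seed(config@seed)
  init <- lapply(config@temperatures, function(t)
    randomAlignment(qlen, tlen, constraints)@blocks)
  res <- cpp_run_remc(init, ctx, config@temperatures, config@innerSteps,
                      config@cycles, constraints@minBlockLength, minB,
                      moverSet@weights, config@sampleEvery,
                      config@maxRecords, config@stopAfterStable)
  samplingResultFrom(res, forceField, problem, qlen, tlen,
                     config@temperatures, "replica_exchange")
}

#' Run a simulated-annealing alignment search
#'
#' A single chain visits the configured temperatures from the hottest down
#' with an equal number of proposals per stage
#' (`innerSteps * cycles / length(temperatures)` in total split evenly).
#'
#' @inheritParams runREMC
#' @param config a [SamplerConfig-class] with mode `"annealing"`.
#' @return a [SamplingResult-class].
#' @export
runAnnealing <- function(problem, forceField,
                         config = SamplerConfig(mode = "annealing"),
                         moverSet = defaultMoverSet(),
                         constraints = SamplingConstraints()) {
  if (config@mode != "annealing")
    configError("config mode must be 'annealing' for runAnnealing")
  qlen <- nResidues(problem@query)
  tlen <- nResidues(problem@template)
  config <- resolveConfig(config, qlen)
  ctx <- compileForceField(forceField, problem)
  minB <- effectiveMinBlocks(qlen, tlen, constraints)
  temps <- sort(config@temperatures, decreasing = TRUE)
  stepsPerStage <- max(1L, as.integer(ceiling(
    config@innerSteps * config@cycles / length(temps))))
  set.seed(config@seed)
  init <- randomAlignment(qlen, tlen, constraints)@blocks
  res <- cpp_run_sa(init, ctx, temps, stepsPerStage,
                    constraints@minBlockLength, minB, defaultOrSet(moverSet),
                    config@sampleEvery, config@maxRecords)
  samplingResultFrom(res, forceField, problem, qlen, tlen, temps, "annealing")
}

defaultOrSet <- function(moverSet) moverSet@weights

#' Ranked distinct suboptimal alignments
#'
#' Deduplicates records by canonical alignment, sorts ascending by energy
#' and returns up to `maxCount`; the first entry is the global best
#' observed.
#'
#' @param records list of [AlignmentRecord-class] (or a
#'   [SamplingResult-class], whose records are used).
#' @param maxCount maximum number of records returned.
#' @return list of [AlignmentRecord-class].
#' @export
collectSuboptimal <- function(records, maxCount = 10L) {
  if (is(records, "SamplingResult")) records <- records@records
  if (length(records) == 0) return(list())
  keys <- vapply(records, function(r) {
    b <- canonicalize(r@alignment)@blocks
    paste(t(b), collapse = ",")
  }, character(1))
  keep <- !duplicated(keys)
  records <- records[keep]
  energies <- vapply(records, function(r) r@totalEnergy, numeric(1))
  records <- records[order(energies)]
  records[seq_len(min(maxCount, length(records)))]
}

setMethod("show", "AlignmentRecord", function(object) {
  cat(sprintf("AlignmentRecord: energy %.4f, %d block(s), T = %g, cycle %d\n",
              object@totalEnergy, numBlocks(object@alignment),
              object@replicaTemperature, object@cycle))
  if (length(object@perTermEnergies) > 0) {
    for (nm in names(object@perTermEnergies))
      cat(sprintf("  %-22s %.4f\n", nm, object@perTermEnergies[nm]))
  }
})

setMethod("show", "SamplingResult", function(object) {
  cat(sprintf("SamplingResult (%s): %d distinct record(s), %d cycle(s)\n",
              object@mode, length(object@records), object@cyclesRun))
  cat(sprintf("  best energy: %.6f\n", object@bestRecord@totalEnergy))
  acc <- sum(object@moverStats$accepted)
  att <- sum(object@moverStats$attempted)
  if (att > 0) cat(sprintf("  overall acceptance: %.1f%%\n", 100 * acc / att))
})

#' Per-replica energy histograms
#'
#' Bins the thinned per-replica energy samples of a replica-exchange run on
#' a common grid -- the overlap diagnostic for the temperature ladder
#' (significant overlap between neighbouring replicas indicates the ladder
#' supports a random walk in temperature space).
#'
#' @param result a [SamplingResult-class] from [runREMC()].
#' @param bins number of bins over the pooled energy range.
#' @return data.frame with columns temperature, binCenter, count.
#' @export
energyHistograms <- function(result, bins = 30L) {
  allE <- unlist(result@samples)
  if (length(allE) == 0) return(data.frame(temperature = numeric(),
                                           binCenter = numeric(),
                                           count = integer()))
  rng <- range(allE)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  out <- lapply(seq_along(result@samples), function(r) {
    h <- hist(result@samples[[r]], breaks = edges, plot = FALSE)
    data.frame(temperature = result@temperatures[r], binCenter = centers,
               count = h$counts)
  })
  do.call(rbind, out)
}

# ------------------------------------------------------------ the DP oracle

#' Needleman-Wunsch/Gotoh affine-gap alignment (exact oracle)
#'
#' Exact global alignment maximizing the summed score matrix entries minus
#' affine gap costs `open + (g - 1) * extend` per internal gap run, with
#' free terminal gaps by default (matching [affineGapTerm()] semantics).
#' Used as the exact optimum against which the stochastic search is
#' checked on force fields that are fully per-position decomposable.
#'
#' @param scoreMatrix query x template matrix of per-pair scores (larger
#'   is better; the negated output of [precomputeMatrix()]).
#' @param gapOpen,gapExtend affine gap parameters (costs, >= 0).
#' @param terminalFree charge nothing for terminal gaps (default TRUE).
#' @return list with `score` (the optimum) and `alignment` (a
#'   [BlockAlignment-class] attaining it).
#' @export
nwAffineOracle <- function(scoreMatrix, gapOpen, gapExtend,
                           terminalFree = TRUE) {
  S <- as.matrix(scoreMatrix)
  n <- nrow(S)
  m <- ncol(S)
  NEG <- -1e18
  eps <- 1e-9
  # Three-state Gotoh over 1-based residue indices; matrices are (n+1) x
  # (m+1) with row/col 1 the empty prefix. M[i,j]: residue i-1 aligned to
  # j-1; X: query residue skipped (gap in template row); Y: template
  # residue skipped.
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (!terminalFree) {
    X[2:(n + 1), 1] <- -gapOpen - (0:(n - 1)) * gapExtend
    Y[1, 2:(m + 1)] <- -gapOpen - (0:(m - 1)) * gapExtend
  }
  # with free terminal gaps an aligned region may start at any cell
  startBonus <- if (terminalFree) 0 else NEG
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- S[i - 1, j - 1] +
        max(startBonus, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - gapOpen, X[i - 1, j] - gapExtend)
      Y[i, j] <- max(M[i, j - 1] - gapOpen, Y[i, j - 1] - gapExtend)
    }
  }
  if (terminalFree) {
    sub <- M[2:(n + 1), 2:(m + 1), drop = FALSE]
    score <- max(sub)
    best <- which(sub == score, arr.ind = TRUE)[1, ]
    i <- as.integer(best[1] + 1L)
    j <- as.integer(best[2] + 1L)
    state <- "M"
  } else {
    cands <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
    state <- c("M", "X", "Y")[which.max(cands)]
    score <- max(cands)
    i <- n + 1L
    j <- m + 1L
  }
  pairs <- matrix(integer(), 0, 2)
  while (!(i == 1 && j == 1)) {
    if (state == "M") {
      pairs <- rbind(c(i - 1L, j - 1L), pairs)
      need <- M[i, j] - S[i - 1, j - 1]
      i <- i - 1L
      j <- j - 1L
      if (terminalFree && abs(need) < eps) break       # free-start cell
      if (i == 1 && j == 1) break
      if (abs(need - M[i, j]) < eps) state <- "M"
      else if (abs(need - X[i, j]) < eps) state <- "X"
      else state <- "Y"
    } else if (state == "X") {
      need <- X[i, j]
      i <- i - 1L
      state <- if (abs(need - (M[i, j] - gapOpen)) < eps) "M" else "X"
      if (i == 1) break
    } else {
      need <- Y[i, j]
      j <- j - 1L
      state <- if (abs(need - (M[i, j] - gapOpen)) < eps) "M" else "Y"
      if (j == 1) break
    }
  }
  list(score = score, alignment = pairsToAlignment(pairs, n, m))
}

# convert a strictly increasing pair list into canonical blocks
pairsToAlignment <- function(pairs, queryLength, templateLength) {
  if (nrow(pairs) == 0)
    return(BlockAlignment(queryLength = queryLength,
                          templateLength = templateLength))
  dq <- diff(pairs[, 1])
  dt <- diff(pairs[, 2])
  newBlock <- c(TRUE, !(dq == 1 & dt == 1))
  starts <- which(newBlock)
  ends <- c(starts[-1] - 1L, nrow(pairs))
  canonicalize(BlockAlignment(pairs[starts, 1], pairs[starts, 2],
                              ends - starts + 1L, queryLength, templateLength))
}
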