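# Independent oracles used to cross-check the compiled implementations.
# Everything here is deliberately plain R, written from the definitions.

# Kabsch superposition in R via svd(); returns distances of all pairs under
# the superposition fitted on `subset`
oracleSuperposeDists <- function(Q, T, pairs, subset) {
  qs <- Q[pairs[subset, 1], , drop = FALSE]
  ts <- T[pairs[subset, 2], , drop = FALSE]
  qc <- colMeans(qs)
  tc <- colMeans(ts)
  H <- t(sweep(qs, 2, qc)) %*% sweep(ts, 2, tc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  qAll <- sweep(Q[pairs[, 1], , drop = FALSE], 2, qc) %*% R
  tAll <- sweep(T[pairs[, 2], , drop = FALSE], 2, tc)
  sqrt(rowSums((qAll - tAll)^2))
}

# exhaustive-restart TM-score: every contiguous fragment window (all
# starts, all lengths >= 3), each refined by iterative inlier reselection
oracleTMScore <- function(Q, T, pairs, Lnorm) {
  m <- nrow(pairs)
  if (m < 3) return(0)
  d0 <- if (Lnorm <= 15) 0.5 else max(0.5, 1.24 * (Lnorm - 15)^(1 / 3) - 1.8)
  scoreOf <- function(d) sum(1 / (1 + (d / d0)^2)) / Lnorm
  refine <- function(subset) {
    best <- 0
    for (it in 1:30) {
      d <- oracleSuperposeDists(Q, T, pairs, subset)
      best <- max(best, scoreOf(d))
      dc <- max(d0, 3.5)
      repeat {
        nw <- which(d <= dc)
        if (length(nw) >= 3) break
        dc <- dc + 0.5
      }
      if (identical(nw, subset)) break
      subset <- nw
    }
    best
  }
  seeds <- list(seq_len(m))
  for (L in 3:(m - 1)) {
    for (s in 1:(m - L + 1))
      seeds[[length(seeds) + 1]] <- s:(s + L - 1)
  }
  max(vapply(seeds, refine, numeric(1)))
}

# DALI elastic similarity by definition: 0.2 per aligned pair plus the
# single-counted envelope term over unordered pairs of aligned columns
oracleDali <- function(Q, T, pairs) {
  m <- nrow(pairs)
  sim <- 0.2 * m
  if (m < 2) return(sim)
  for (a in 1:(m - 1)) {
    for (b in (a + 1):m) {
      dQ <- sqrt(sum((Q[pairs[a, 1], ] - Q[pairs[b, 1], ])^2))
      dT <- sqrt(sum((T[pairs[a, 2], ] - T[pairs[b, 2], ])^2))
      ds <- (dQ + dT) / 2
      if (ds > 0)
        sim <- sim + (0.2 - abs(dQ - dT) / ds) * exp(-(ds / 20)^2)
    }
  }
  sim
}

# brute-force global affine-gap alignment by enumeration of all monotone
# pair sets (free terminal gaps); feasible only for tiny matrices
oracleEnumerateAlignment <- function(S, gapOpen, gapExtend) {
  n <- nrow(S)
  m <- ncol(S)
  gapCost <- function(g) if (g > 0) gapOpen + (g - 1) * gapExtend else 0
  best <- -Inf
  recurse <- function(i, j, score, lastI, lastJ) {
    # every state is a potential end (terminal gaps free)
    best <<- max(best, score)
    if (i > n || j > m) return()
    for (ii in i:n) {
      for (jj in j:m) {
        g <- if (lastI == 0) 0 else gapCost(ii - lastI - 1) + gapCost(jj - lastJ - 1)
        recurse(ii + 1, jj + 1, score + S[ii, jj] - g, ii, jj)
      }
    }
  }
  recurse(1, 1, 0, 0, 0)
  best
}

# enumerate every feasible destination of a block-shift for block `b`,
# holding the other blocks fixed (used as the chi-squared reference)
oracleShiftDestinations <- function(alignment, b) {
  blk <- alignmentBlocks(alignment)
  out <- NULL
  for (qs in 1:(queryLength(alignment) - blk[b, 3] + 1)) {
    for (ts in 1:(templateLength(alignment) - blk[b, 3] + 1)) {
      if (qs == blk[b, 1] && ts == blk[b, 2]) next
      cand <- blk
      cand[b, 1] <- qs
      cand[b, 2] <- ts
      ok <- tryCatch({
        a <- ThreadMC:::newBlockAlignment(cand, queryLength(alignment),
                                          templateLength(alignment))
        validateAlignment(a, SamplingConstraints(min(blk[, 3]), nrow(blk)))$ok
      }, error = function(e) FALSE)
      if (ok) out <- rbind(out, c(qs, ts))
    }
  }
  out
}

# small complete threading problem shared across tests
toyThreadingFixture <- function(n = 40, seed = 7, noise = 0.2,
                                deletions = list()) {
  makeThreadingFixture(n, coordinateNoiseSD = noise, deletions = deletions,
                       seed = seed)
}
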