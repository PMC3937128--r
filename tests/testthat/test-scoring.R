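# Scoring terms, the force field and incremental (changed-column) energy
# evaluation, cross-checked against independent plain-R oracles.

seqProblem <- function(qseq, tseq) {
  ThreadingProblem(ChainData(sequence = qseq), ChainData(sequence = tseq))
}

test_that("substitution energy is the negated matrix sum over pairs", {
  term <- substitutionScoreTerm("BLOSUM62")
  prob <- seqProblem("WWWW", "WWWW")
  a <- BlockAlignment(1, 1, 4, queryLength = 4, templateLength = 4)
  b62 <- loadSubstitutionMatrix("BLOSUM62")
  expect_equal(termEnergy(term, a, prob), -4 * b62["W", "W"])

  empty <- BlockAlignment(queryLength = 4, templateLength = 4)
  expect_equal(termEnergy(term, empty, prob), 0)

  # canonicalization invariance: same pairs, same score
  split <- BlockAlignment(c(1, 3), c(1, 3), c(2, 2),
                          queryLength = 4, templateLength = 4)
  expect_equal(termEnergy(term, split, prob), termEnergy(term, a, prob))
})

test_that("unknown residues score through the wildcard row", {
  term <- substitutionScoreTerm("BLOSUM62")
  prob <- seqProblem("WBWW", "WWWW")  # B is not in the 20-letter alphabet
  a <- BlockAlignment(1, 1, 4, queryLength = 4, templateLength = 4)
  b62 <- loadSubstitutionMatrix("BLOSUM62")
  # B actually exists in BLOSUM62; use a letter that does not
  prob2 <- seqProblem("WUWW", "WWWW")
  expect_warning(e <- termEnergy(term, a, prob2), "wildcard")
  expect_equal(e, -(3 * b62["W", "W"] + b62["X", "W"]))
})

test_that("profile cross-score matches hand arithmetic and is symmetric", {
  oneHot <- function(k) {
    f <- matrix(0, 1, 20)
    f[1, k] <- 1
    f
  }
  # hand-set single-column profiles
  qf <- oneHot(1)                       # all mass on A
  ql <- matrix(seq(0.1, 2.0, by = 0.1), 1, 20)
  tf <- oneHot(3)                       # all mass on D
  tl <- matrix(seq(-1.0, 0.9, by = 0.1), 1, 20)
  qp <- Profile(freqs = qf, logOdds = ql)
  tp <- Profile(freqs = tf, logOdds = tl)
  prob <- ThreadingProblem(ChainData(sequence = "A", profile = qp),
                           ChainData(sequence = "D", profile = tp))
  a <- BlockAlignment(1, 1, 1, queryLength = 1, templateLength = 1)
  # cross score = t_logodds[A] + q_logodds[D] = -1.0 + 0.3, negated
  expect_equal(termEnergy(profileScoreTerm(), a, prob), -(-1.0 + 0.3))

  # identical one-hot profiles with zero log-odds score 0
  zp <- Profile(freqs = oneHot(1), logOdds = matrix(0, 1, 20))
  prob0 <- ThreadingProblem(ChainData(sequence = "A", profile = zp),
                            ChainData(sequence = "A", profile = zp))
  expect_equal(termEnergy(profileScoreTerm(), a, prob0), 0)

  # symmetry under query/template exchange
  probSwap <- ThreadingProblem(ChainData(sequence = "D", profile = tp),
                               ChainData(sequence = "A", profile = qp))
  expect_equal(termEnergy(profileScoreTerm(), a, prob),
               termEnergy(profileScoreTerm(), a, probSwap))
})

ssProblem <- function(qss, tss, n) {
  qp <- Profile(freqs = matrix(1 / 20, n, 20), ss3 = qss)
  tp <- Profile(freqs = matrix(1 / 20, n, 20), ss3 = tss)
  ThreadingProblem(ChainData(sequence = strrep("A", n), profile = qp),
                   ChainData(sequence = strrep("A", n), profile = tp))
}

test_that("secondary-structure energy follows the assigned probability", {
  n <- 6
  a <- BlockAlignment(1, 1, n, queryLength = n, templateLength = n)
  oneHotH <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  expect_equal(termEnergy(secondaryScoreTerm(), a,
                          ssProblem(oneHotH, oneHotH, n)), -n)
  uniform <- matrix(1 / 3, n, 3)
  expect_equal(termEnergy(secondaryScoreTerm(), a,
                          ssProblem(uniform, oneHotH, n)), -n / 3)

  # two term instances with different labels coexist in one force field
  ff <- ForceField(list(secondaryScoreTerm("ss_a"), secondaryScoreTerm("ss_b")),
                   c(1, 2))
  e <- totalEnergy(ff, a, ssProblem(uniform, oneHotH, n))
  expect_named(e$terms, c("ss_a", "ss_b"))
  expect_equal(e$total, -n / 3 * 3)
})

test_that("burial agreement and hydropathy mismatch kernels", {
  n <- 5
  mk <- function(qb, tb) {
    qp <- Profile(freqs = matrix(1 / 20, n, 20), burial = qb)
    tp <- Profile(freqs = matrix(1 / 20, n, 20), burial = tb)
    ThreadingProblem(ChainData(sequence = strrep("L", n), profile = qp),
                     ChainData(sequence = strrep("L", n), profile = tp))
  }
  a <- BlockAlignment(1, 1, n, queryLength = n, templateLength = n)
  same <- rep(0.4, n)
  expect_equal(termEnergy(envScoreTerm(), a, mk(same, same)), -n)
  expect_equal(termEnergy(asaScoreTerm(), a, mk(same, same)), -n)
  expect_equal(termEnergy(envScoreTerm(), a, mk(rep(0, n), rep(1, n))), 0)

  # gravy: identical sequences incur no penalty; A vs I penalty is |1.8-4.5|/9
  probAA <- seqProblem(strrep("A", n), strrep("A", n))
  expect_equal(termEnergy(gravyScoreTerm(), a, probAA), 0)
  probAI <- seqProblem(strrep("A", n), strrep("I", n))
  expect_equal(termEnergy(gravyScoreTerm(), a, probAI), n * (4.5 - 1.8) / 9)
})

test_that("affine gap penalties follow open + (g-1) * extend per run", {
  prob <- seqProblem(strrep("A", 20), strrep("A", 20))
  gap <- affineGapTerm(open = 10, extend = 1)
  self <- tileSelfAlignment(20, 4)
  expect_equal(termEnergy(gap, self, prob), 0)

  # one internal query gap of 3 (template contiguous)
  g3 <- BlockAlignment(c(1, 8), c(1, 5), c(4, 6),
                       queryLength = 20, templateLength = 20)
  expect_equal(termEnergy(gap, g3, prob), 12)

  # terminal gaps charged only when terminalFree = FALSE
  charged <- affineGapTerm(open = 10, extend = 1, terminalFree = FALSE)
  # g3 leaves query 14..20 (7), template 11..20 (10) unaligned at the end
  expect_equal(termEnergy(charged, g3, prob), 12 + (10 + 6) + (10 + 9))

  # splitting a block (abutting) adds no gap penalty
  expect_equal(termEnergy(gap, tileSelfAlignment(20, 5), prob),
               termEnergy(gap, tileSelfAlignment(20, 10), prob))
})

contactProblem <- function() {
  # toy 6-residue template with contacts (1,5) and (2,6) [1-based]
  cm <- ContactMap(rbind(c(1, 5), c(2, 6)), nres = 6)
  ThreadingProblem(ChainData(sequence = "LVLVLV"),
                   ChainData(sequence = "AAAAAA"), contactMap = cm)
}

test_that("structural gap penalty counts lost contacts", {
  prob <- contactProblem()
  term <- structuralGapPenaltyTerm(penalty = 1)
  full <- BlockAlignment(1, 1, 6, queryLength = 6, templateLength = 6)
  expect_equal(termEnergy(term, full, prob), 0)

  # template residues 5-6 unaligned: both contacts lose an endpoint
  part <- BlockAlignment(1, 1, 4, queryLength = 6, templateLength = 6)
  expect_equal(termEnergy(term, part, prob), 2)

  # monotone: unaligning more template residues never lowers the penalty
  set.seed(14)
  tmpl <- makeHelixTrace(30, seed = 2)
  probH <- ThreadingProblem(ChainData(sequence = strrep("A", 30)),
                            ChainData(trace = tmpl))
  for (i in 1:20) {
    a <- randomAlignment(30, 30)
    e1 <- termEnergy(term, a, probH)
    p <- proposeMove(a, "annihilate", SamplingConstraints(4, 1))
    if (!p@feasible) next
    expect_gte(termEnergy(term, p@newAlignment, probH), e1)
  }
})

test_that("Go-like energy rewards recovered template contacts", {
  tmpl <- makeHelixTrace(24, seed = 3)
  cm <- buildContactMap(tmpl)
  prob <- ThreadingProblem(ChainData(trace = tmpl), ChainData(trace = tmpl),
                           contactMap = cm)
  a <- tileSelfAlignment(24, 4)
  term <- goLikeScoreTerm(cutoff = 8)
  expect_equal(termEnergy(term, a, prob), -nContacts(cm))

  # equals an independent loop over all contacts for partial alignments
  set.seed(15)
  for (i in 1:10) {
    r <- randomAlignment(24, 24)
    tm <- ThreadMC:::templateMap(r)
    manual <- 0
    for (k in seq_len(nContacts(cm))) {
      qi <- tm[contactPairs(cm)[k, 1]]
      qj <- tm[contactPairs(cm)[k, 2]]
      if (qi > 0 && qj > 0 &&
          sqrt(sum((caCoords(tmpl)[qi, ] - caCoords(tmpl)[qj, ])^2)) <= 8)
        manual <- manual - 1
    }
    expect_equal(termEnergy(term, r, prob), manual)
  }

  # no contacts, no energy
  prob0 <- ThreadingProblem(ChainData(trace = tmpl), ChainData(trace = tmpl),
                            contactMap = ContactMap(matrix(0, 0, 2), 24))
  expect_equal(termEnergy(term, a, prob0), 0)
})

test_that("two-body contact energy maps template contacts through the alignment", {
  mj <- loadMJTable()
  expect_equal(dim(mj), c(20L, 20L))
  expect_true(isSymmetric(mj))
  # spot values from the published table
  expect_equal(mj["C", "C"], -5.44)
  expect_equal(mj["K", "K"], -0.12)
  expect_equal(mj["L", "V"], mj["V", "L"])

  prob <- contactProblem()   # query LVLVLV; contacts (1,5), (2,6)
  term <- twoBodyContactTerm()
  full <- BlockAlignment(1, 1, 6, queryLength = 6, templateLength = 6)
  # contact (1,5) -> (L,L); contact (2,6) -> (V,V)
  expect_equal(termEnergy(term, full, prob), mj["L", "L"] + mj["V", "V"])

  # single mapped contact: alignment covering template 1..4 keeps neither
  part <- BlockAlignment(1, 2, 5, queryLength = 6, templateLength = 6)
  # template 2..6 aligned to query 1..5: contact (2,6) -> (L, L); (1,5) lost
  expect_equal(termEnergy(term, part, prob), mj["L", "L"])
})

test_that("TM-score behaves as a length-normalized similarity", {
  tr <- makeHelixTrace(30, seed = 4)
  prob <- ThreadingProblem(tr, tr)
  idt <- tileSelfAlignment(30, 5)
  expect_equal(tmScore(tr, tr, idt), 1.0)

  # decoy pairings score strictly less than the identity
  set.seed(16)
  for (i in 1:5) {
    d <- randomAlignment(30, 30)
    if (nrow(residuePairs(d)) < 3) next
    expect_lt(tmScore(tr, tr, d), 1.0)
  }

  # fewer than 3 aligned pairs is undefined, scored 0 with a warning
  tiny <- BlockAlignment(1, 1, 2, queryLength = 30, templateLength = 30)
  expect_warning(z <- tmScore(tr, tr, tiny, thorough = FALSE), "fewer than 3")
  expect_equal(z, 0)
})

test_that("TM-score matches a multi-start superposition oracle on toys", {
  set.seed(17)
  for (rep in 1:4) {
    tr <- makeHelixTrace(25, seed = rep)
    hom <- makeHomolog(tr, coordinateNoiseSD = 0.8, seed = rep + 10)
    a <- randomAlignment(25, 25)
    p <- residuePairs(a)
    if (nrow(p) < 3) next
    mine <- tmScore(hom$trace, tr, a, normLength = 25)
    ref <- oracleTMScore(caCoords(hom$trace), caCoords(tr), p, 25)
    expect_equal(mine, ref, tolerance = 1e-3)
    expect_gt(mine, 0)
    expect_lte(mine, 1)
  }
})

test_that("RMSD is superposition-invariant with a closed-form toy", {
  tr <- makeHelixTrace(12, seed = 5)
  idt <- tileSelfAlignment(12, 4)
  expect_equal(rmsdScore(tr, tr, idt), 0, tolerance = 1e-9)

  # translation and rotation are removed exactly
  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- StructureTrace(caCoords(tr) %*% rot + 7, chainSequence(tr))
  expect_equal(rmsdScore(tr, moved, idt), 0, tolerance = 1e-9)

  # equilateral triangle scaled radially: optimal fit leaves |c-1|*r per vertex
  r <- 2
  ang <- c(0, 2 * pi / 3, 4 * pi / 3)
  P <- cbind(r * cos(ang), r * sin(ang), 0)
  cc <- 1.5
  Q <- cbind(cc * r * cos(ang), cc * r * sin(ang), 0)
  a3 <- BlockAlignment(1, 1, 3, queryLength = 3, templateLength = 3)
  tP <- StructureTrace(P, "AAA")
  tQ <- StructureTrace(Q, "AAA")
  expect_equal(rmsdScore(tP, tQ, a3), (cc - 1) * r, tolerance = 1e-9)
})

test_that("DALI similarity equals the brute-force double loop", {
  tr <- makeHelixTrace(10, seed = 6)
  hom <- makeHomolog(tr, coordinateNoiseSD = 0.6, seed = 7)
  idt <- tileSelfAlignment(10, 5)
  expect_equal(daliScore(hom$trace, tr, idt),
               oracleDali(caCoords(hom$trace), caCoords(tr),
                          residuePairs(idt)))

  # single aligned pair: diagonal contribution only
  a1 <- BlockAlignment(1, 1, 1, queryLength = 10, templateLength = 10)
  c1 <- SamplingConstraints(1, 1)
  expect_equal(daliScore(tr, tr, a1), 0.2)

  # self-alignment maximizes the elastic similarity over random decoys
  set.seed(18)
  selfSim <- daliScore(tr, tr, idt)
  for (i in 1:5) {
    d <- randomAlignment(10, 10, c1)
    expect_lte(daliScore(tr, tr, d), selfSim + 1e-9)
  }
})

test_that("precomputed matrices reproduce direct term evaluation", {
  fx <- toyThreadingFixture(30)
  prob <- fx$problem
  terms <- list(substitutionScoreTerm(), profileScoreTerm(),
                secondaryScoreTerm(), envScoreTerm(), gravyScoreTerm())
  set.seed(19)
  for (term in terms) {
    m <- precomputeMatrix(term, prob)
    expect_equal(dim(m), c(nResidues(prob@query), nResidues(prob@template)))
    for (i in 1:5) {
      a <- randomAlignment(nResidues(prob@query), nResidues(prob@template))
      expect_equal(termEnergy(term, a, prob), sum(m[residuePairs(a)]),
                   tolerance = 1e-12)
    }
  }
  expect_error(precomputeMatrix(affineGapTerm(), prob), "BigMatrix")
})

test_that("force-field totals are weighted sums with a consistent breakdown", {
  fx <- toyThreadingFixture(36)
  prob <- fx$problem
  a <- fx$truth
  ff <- defaultThreadingForceField()
  expect_equal(unname(ff@weights), c(0.1, 0.25, 0.5, 1.0, 0.4, 0.15))
  e <- totalEnergy(ff, a, prob)
  expect_equal(e$total, sum(ff@weights * e$terms), tolerance = 1e-9)
  # hand-summed default weighting
  hand <- 0.1 * termEnergy(envScoreTerm(), a, prob) +
    0.25 * termEnergy(secondaryScoreTerm(), a, prob) +
    0.5 * termEnergy(profileScoreTerm(), a, prob) +
    1.0 * termEnergy(goLikeScoreTerm(), a, prob) +
    0.4 * termEnergy(twoBodyContactTerm(), a, prob) +
    0.15 * termEnergy(structuralGapPenaltyTerm(), a, prob)
  expect_equal(e$total, hand, tolerance = 1e-9)

  zero <- ForceField(ff@terms, rep(0, length(ff@terms)))
  expect_equal(totalEnergy(zero, a, prob)$total, 0)

  single <- ForceField(list(profileScoreTerm()), 1)
  expect_equal(totalEnergy(single, a, prob)$total,
               termEnergy(profileScoreTerm(), a, prob))
})

test_that("missing inputs are configuration errors naming the term", {
  bare <- ThreadingProblem(ChainData(sequence = "AAAAAAAA"),
                           ChainData(sequence = "AAAAAAAA"))
  ff <- ForceField(list(profileScoreTerm()), 1)
  err <- tryCatch(checkInputs(ff, bare), condition = function(c) c)
  expect_s3_class(err, "threadmc_config_error")
  expect_match(conditionMessage(err), "profile")
})

test_that("incremental delta energy equals the full difference", {
  fx <- toyThreadingFixture(32)
  prob <- fx$problem
  ff <- defaultThreadingForceField()
  cons <- SamplingConstraints()
  set.seed(20)
  a <- randomAlignment(nResidues(prob@query), nResidues(prob@template), cons)
  ms <- defaultMoverSet()
  checked <- 0
  for (i in 1:120) {
    p <- selectAndPropose(ms, a, cons)
    if (!p@feasible) next
    d <- deltaEnergy(ff, a, p, prob)
    full <- totalEnergy(ff, p@newAlignment, prob, tmThorough = FALSE)$total -
      totalEnergy(ff, a, prob, tmThorough = FALSE)$total
    expect_equal(d, full, tolerance = 1e-9)
    a <- p@newAlignment
    checked <- checked + 1
  }
  expect_gt(checked, 60)

  # pure split: empty changed-column set, zero delta
  b8 <- BlockAlignment(1, 1, 8, queryLength = nResidues(prob@query),
                       templateLength = nResidues(prob@template))
  sp <- proposeMove(b8, "split", SamplingConstraints(4, 1))
  expect_true(sp@feasible)
  expect_equal(deltaEnergy(ff, b8, sp, prob), 0)
})
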