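# The seven alignment movers: feasibility geometry, proposal
# distributions, conservation properties and closure under the validity
# rules.

test_that("the mover set registers seven movers with the default ratio", {
  ms <- defaultMoverSet()
  expect_length(ms@moverNames, 7L)
  expect_setequal(ms@moverNames, c("shift", "shrink_expand", "part_jump",
                                   "split", "merge", "annihilate", "create"))
  w <- setNames(ms@weights, ms@moverNames)
  expect_equal(unname(w[c("shift", "shrink_expand", "part_jump", "split",
                          "merge", "annihilate")]),
               c(100, 100, 100, 10, 10, 1))
  expect_equal(unname(w["create"]), 1)  # creation kept symmetric with annihilation
})

test_that("geometrically impossible moves are infeasible, not errors", {
  cons <- SamplingConstraints()
  full <- tileSelfAlignment(16, 4)  # 4 abutting blocks, no free space
  set.seed(1)
  expect_false(proposeMove(full, "shift", cons)@feasible)
  expect_false(proposeMove(full, "create", cons)@feasible)
  expect_false(proposeMove(full, "merge", cons)@feasible)       # at min count
  expect_false(proposeMove(full, "annihilate", cons)@feasible)  # at min count

  # a single block has no neighbour to jump to and no partner to merge
  one <- BlockAlignment(3, 3, 8, queryLength = 20, templateLength = 20)
  c1 <- SamplingConstraints(4, 1)
  expect_false(proposeMove(one, "part_jump", c1)@feasible)
  expect_false(proposeMove(one, "merge", c1)@feasible)

  # split needs at least twice the minimum block length
  b7 <- BlockAlignment(1, 1, 7, queryLength = 30, templateLength = 30)
  expect_false(proposeMove(b7, "split", c1)@feasible)

  # donors at the minimum length cannot give residues away
  donors <- BlockAlignment(c(1, 6), c(1, 6), c(4, 4),
                           queryLength = 10, templateLength = 10)
  expect_false(proposeMove(donors, "part_jump", SamplingConstraints(4, 2))@feasible)

  # a block at minimum length boxed in by abutting neighbours cannot resize
  expect_false(proposeMove(tileSelfAlignment(12, 4),
                           "shrink_expand", SamplingConstraints(4, 3))@feasible)
})

test_that("a length-8 block splits only at its midpoint", {
  c1 <- SamplingConstraints(4, 1)
  b8 <- BlockAlignment(1, 1, 8, queryLength = 30, templateLength = 30)
  set.seed(2)
  for (i in 1:10) {
    p <- proposeMove(b8, "split", c1)
    expect_true(p@feasible)
    expect_equal(unname(alignmentBlocks(p@newAlignment)[, "length"]), c(4L, 4L))
    # abutting split leaves the pair set (and thus any energy) unchanged
    expect_length(p@changedQueryColumns, 0L)
    expect_identical(residuePairs(p@newAlignment), residuePairs(b8))
  }
})

test_that("shift destinations are uniform over the enumerated feasible set", {
  cons <- SamplingConstraints(4, 3)
  a <- BlockAlignment(c(2, 10, 18), c(2, 10, 18), c(4, 4, 4),
                      queryLength = 24, templateLength = 24)
  feas <- oracleShiftDestinations(a, 2)          # brute-force enumeration
  key <- paste(feas[, 1], feas[, 2])
  base <- alignmentBlocks(a)
  set.seed(31)
  seen <- character(100000)
  n <- 0
  for (i in 1:100000) {
    p <- proposeMove(a, "shift", cons)
    if (!p@feasible) next
    b <- alignmentBlocks(p@newAlignment)
    moved <- which(b[, 1] != base[, 1] | b[, 2] != base[, 2])
    if (length(moved) != 1 || moved != 2) next   # only draws moving block 2
    n <- n + 1
    seen[n] <- paste(b[2, 1], b[2, 2])
  }
  seen <- seen[seq_len(n)]
  expect_gt(n, 10000)
  expect_true(all(seen %in% key))
  counts <- table(factor(seen, levels = key))
  chi <- suppressWarnings(chisq.test(counts, p = rep(1 / length(key),
                                                     length(key))))
  expect_gt(chi$p.value, 1e-4)
})

test_that("shrink/expand lengths follow the truncated 1/2^N distribution", {
  set.seed(5)
  draws <- sampleShrinkLength(1e5, 12)
  expect_true(all(draws >= 1 & draws <= 12))
  # frequencies halve per increment
  expect_equal(mean(draws == 2) / mean(draws == 1), 0.5, tolerance = 0.05)
  expect_equal(mean(draws == 3) / mean(draws == 2), 0.5, tolerance = 0.10)
  pExp <- 2^-(1:12) / sum(2^-(1:12))
  obs <- tabulate(draws, 12)
  chi <- suppressWarnings(chisq.test(obs, p = pExp))
  expect_gt(chi$p.value, 1e-4)
  # truncation respects the feasible bound
  expect_true(all(sampleShrinkLength(1000, 3) <= 3))
})

test_that("merge then split at the seam restores the block list", {
  c1 <- SamplingConstraints(4, 1)
  a <- BlockAlignment(c(1, 5), c(1, 5), c(4, 4),
                      queryLength = 8, templateLength = 8)
  set.seed(3)
  m <- proposeMove(a, "merge", c1)
  expect_true(m@feasible)
  expect_equal(numBlocks(m@newAlignment), 1L)
  expect_length(m@changedQueryColumns, 0L)
  s <- proposeMove(m@newAlignment, "split", c1)
  expect_true(s@feasible)
  expect_identical(alignmentBlocks(s@newAlignment), alignmentBlocks(a))
})

test_that("two blocks separated by a gap cannot merge", {
  c1 <- SamplingConstraints(4, 1)
  gapped <- BlockAlignment(c(1, 6), c(1, 8), c(4, 4),
                           queryLength = 12, templateLength = 12)
  set.seed(4)
  expect_false(proposeMove(gapped, "merge", c1)@feasible)
})

test_that("part-jump conserves the aligned-pair count", {
  cons <- SamplingConstraints(4, 2)
  a <- BlockAlignment(c(1, 12), c(1, 14), c(8, 6),
                      queryLength = 30, templateLength = 30)
  set.seed(6)
  for (i in 1:50) {
    p <- proposeMove(a, "part_jump", cons)
    expect_true(p@feasible)
    expect_equal(nrow(residuePairs(p@newAlignment)), nrow(residuePairs(a)))
    expect_equal(numBlocks(canonicalize(p@newAlignment)), 2L)
  }
})

test_that("annihilate removes one block and its pairs", {
  cons <- SamplingConstraints(4, 4)
  a <- tileSelfAlignment(25, 5)    # 5 blocks of 5
  set.seed(7)
  p <- proposeMove(a, "annihilate", cons)
  expect_true(p@feasible)
  expect_equal(numBlocks(p@newAlignment), 4L)
  expect_equal(nrow(residuePairs(p@newAlignment)), 20L)
  expect_length(p@changedQueryColumns, 5L)
  expect_true(validateAlignment(p@newAlignment, cons)$ok)
})

test_that("create places blocks of exactly the minimum length", {
  cons <- SamplingConstraints(4, 4)
  a <- BlockAlignment(c(1, 30, 40, 50), c(1, 30, 40, 50), rep(4L, 4),
                      queryLength = 60, templateLength = 60)
  set.seed(8)
  for (i in 1:50) {
    p <- proposeMove(a, "create", cons)
    expect_true(p@feasible)
    b <- alignmentBlocks(p@newAlignment)
    expect_equal(numBlocks(p@newAlignment), 5L)
    created <- setdiff(paste(b[, 1], b[, 2]),
                       paste(alignmentBlocks(a)[, 1], alignmentBlocks(a)[, 2]))
    expect_length(created, 1L)
    expect_true(all(b[, 3] >= 4))
    expect_equal(sum(b[, 3]), 20L)
  }
})

test_that("changed query columns equal the map symmetric difference", {
  cons <- SamplingConstraints()
  set.seed(9)
  a <- randomAlignment(50, 60, cons)
  ms <- defaultMoverSet()
  for (i in 1:500) {
    p <- selectAndPropose(ms, a, cons)
    if (!p@feasible) next
    old <- ThreadMC:::queryMap(a)
    new <- ThreadMC:::queryMap(p@newAlignment)
    expect_identical(p@changedQueryColumns, which(old != new))
    a <- p@newAlignment
  }
})

test_that("every mover proposal from a valid state passes validation", {
  cons <- SamplingConstraints()
  ms <- defaultMoverSet()
  # R-level walk through the full S4 surface
  set.seed(10)
  for (start in 1:4) {
    a <- randomAlignment(45, 55, cons)
    for (i in 1:500) {
      p <- selectAndPropose(ms, a, cons)
      if (!p@feasible) next
      expect_true(validateAlignment(p@newAlignment, cons)$ok)
      a <- p@newAlignment
    }
  }
  # compiled-path storm: 1e5 accepted states checked against the
  # independent validity rules inside the engine (flat landscape)
  ctx <- list(qlen = 45L, tlen = 55L, big = NULL, gap = NULL, contacts = NULL,
              sgp = NULL, golike = NULL, twobody = NULL, tm = NULL,
              rmsd = NULL, dali = NULL, qcoords = NULL, tcoords = NULL)
  set.seed(12)
  init <- randomAlignment(45, 55, cons)
  chk <- ThreadMC:::cpp_delta_check(alignmentBlocks(init), ctx, 1.0, 100000L,
                                    4L, 4L, defaultMoverSet()@weights)
  expect_equal(chk$invalid, 0)
  expect_gt(chk$accepted, 50000)
})

test_that("mover selection follows the proposal weights", {
  onlyFirst <- MoverSet(c(shift = 1))
  set.seed(13)
  expect_true(all(selectMover(onlyFirst, 1000) == "shift"))
  expect_error(MoverSet(c(bogus = 1)), "class|valid names")
  expect_error(MoverSet(c(shift = 0)), "positive weight")
})
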