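# Block-list representation: validity, canonical form, conversions and
# alignment-overlap metrics.

test_that("self-alignment tilings encode the same alignment", {
  a25 <- tileSelfAlignment(100, 4)
  a4 <- tileSelfAlignment(100, 25)
  expect_equal(numBlocks(a25), 25L)
  expect_equal(numBlocks(a4), 4L)
  c25 <- canonicalize(a25)
  c4 <- canonicalize(a4)
  expect_equal(numBlocks(c25), 1L)
  expect_equal(unname(alignmentBlocks(c25)), matrix(c(1L, 1L, 100L), 1))
  expect_true(alignmentIdentical(a25, a4))
  # residue pairs are the identity in both encodings
  p <- residuePairs(a25)
  expect_equal(nrow(p), 100L)
  expect_equal(p[, 1], p[, 2])
  expect_identical(residuePairs(a25), residuePairs(a4))
})

test_that("tiling handles remainders and refuses impossible inputs", {
  a <- tileSelfAlignment(102, 4)   # last block absorbs the remainder
  expect_equal(numBlocks(a), 25L)
  expect_equal(unname(alignmentBlocks(a)[25, "length"]), 6L)
  expect_error(tileSelfAlignment(3, 4), "at least")
})

test_that("validation reports rule violations without raising", {
  cons <- SamplingConstraints()
  empty <- BlockAlignment(queryLength = 100, templateLength = 100)
  v <- validateAlignment(empty, cons)
  expect_false(v$ok)
  expect_match(v$violations, "too few blocks", all = FALSE)

  expect_true(validateAlignment(tileSelfAlignment(100, 4), cons)$ok)

  # overlapping template ranges are structurally invalid at construction
  expect_error(BlockAlignment(c(1, 10), c(1, 3), c(4, 4),
                              queryLength = 20, templateLength = 20),
               "non-overlapping")

  # short blocks pass construction but fail the constraint check
  short <- BlockAlignment(c(1, 5, 9, 13), c(1, 5, 9, 13), rep(2L, 4),
                          queryLength = 20, templateLength = 20)
  v <- validateAlignment(short, cons)
  expect_false(v$ok)
  expect_match(v$violations, "minBlockLength", all = FALSE)
})

test_that("minimum block count relaxes for chains too short to host it", {
  # 10 residues cannot host 4 blocks of 4: the feasible maximum is 2
  a <- BlockAlignment(c(1, 6), c(1, 6), c(4, 4),
                      queryLength = 10, templateLength = 10)
  expect_true(validateAlignment(a, SamplingConstraints())$ok)
  expect_warning(randomAlignment(10, 10), "relaxing")
})

test_that("canonicalize is idempotent and preserves the pair set", {
  set.seed(11)
  cons <- SamplingConstraints()
  for (rep in 1:25) {
    a <- randomAlignment(40, 50, cons)
    for (k in 1:20) {
      p <- selectAndPropose(defaultMoverSet(), a, cons)
      if (p@feasible) a <- p@newAlignment
    }
    ca <- canonicalize(a)
    expect_identical(residuePairs(ca), residuePairs(a))
    expect_identical(alignmentBlocks(canonicalize(ca)), alignmentBlocks(ca))
    expect_lte(numBlocks(ca), numBlocks(a))
    # strict monotonicity in both coordinates
    p <- residuePairs(a)
    if (nrow(p) > 1) {
      expect_true(all(diff(p[, 1]) > 0))
      expect_true(all(diff(p[, 2]) > 0))
    }
  }
})

test_that("residuePairs expands blocks directly", {
  a <- BlockAlignment(1, 6, 4, queryLength = 10, templateLength = 12)
  expect_equal(unname(residuePairs(a)), cbind(1:4, 6:9))
})

test_that("alignment overlap metrics behave as defined", {
  ref <- tileSelfAlignment(60, 4)
  expect_equal(al0p(ref, ref), 1.0)
  expect_equal(al4p(ref, ref), 1.0)

  shift <- function(d) BlockAlignment(1, 1 + d, 50, queryLength = 60,
                                      templateLength = 60)
  expect_equal(al0p(shift(2), ref), 0.0)
  expect_equal(al4p(shift(2), ref), 50 / 60)  # 50 of 60 reference pairs hit
  expect_equal(al4p(shift(5), ref), 0.0)

  # fully shifted candidate over the reference's aligned span
  refShort <- BlockAlignment(1, 1, 50, queryLength = 60, templateLength = 60)
  expect_equal(al0p(shift(2), refShort), 0.0)
  expect_equal(al4p(shift(2), refShort), 1.0)
  expect_equal(al4p(shift(5), refShort), 0.0)

  # a null candidate scores 0
  empty <- BlockAlignment(queryLength = 60, templateLength = 60)
  expect_equal(al0p(empty, ref), 0.0)

  expect_error(al0p(ref, tileSelfAlignment(50, 5)), "same chain lengths")

  # al0p <= al4p over random alignment pairs
  set.seed(21)
  for (i in 1:20) {
    a <- randomAlignment(30, 30)
    b <- randomAlignment(30, 30)
    expect_lte(al0p(a, b), al4p(a, b))
  }
})

test_that("gapped strings reproduce gap runs and residues", {
  qseq <- strrep("Q", 10)
  tseq <- strrep("T", 12)
  a <- BlockAlignment(c(1, 8), c(1, 10), c(4, 3), queryLength = 10,
                      templateLength = 12)
  rows <- alignmentStrings(a, qseq, tseq)
  expect_equal(nchar(rows[1]), nchar(rows[2]))
  # query gap of 3 and template gap of 5 between the blocks
  expect_match(rows[2], "-{3}")
  expect_match(rows[1], "-{5}")
  # degapped rows give back the sequences
  expect_equal(gsub("-", "", rows[1]), qseq)
  expect_equal(gsub("-", "", rows[2]), tseq)
})
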