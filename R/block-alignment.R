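# Block-list alignment representation: validity rules, canonical form,
# residue-pair and gapped-string conversions, and alignment-quality metrics.

#' @rdname BlockAlignment-class
#' @export
setMethod("alignmentBlocks", "BlockAlignment", function(x) x@blocks)

#' @rdname BlockAlignment-class
#' @export
setMethod("queryLength", "BlockAlignment", function(x) x@queryLength)

#' @rdname BlockAlignment-class
#' @export
setMethod("templateLength", "BlockAlignment", function(x) x@templateLength)

#' @rdname BlockAlignment-class
#' @export
setMethod("numBlocks", "BlockAlignment", function(x) nrow(x@blocks))

#' @rdname SamplingConstraints-class
#' @export
setMethod("minBlockLength", "SamplingConstraints", function(x) x@minBlockLength)

#' @rdname SamplingConstraints-class
#' @export
setMethod("minNumberOfBlocks", "SamplingConstraints", function(x) x@minNumberOfBlocks)

setMethod("show", "SamplingConstraints", function(object) {
  cat("SamplingConstraints: minBlockLength =", object@minBlockLength,
      ", minNumberOfBlocks =", object@minNumberOfBlocks, "\n")
})

setMethod("show", "BlockAlignment", function(object) {
  cat(sprintf("BlockAlignment: %d block(s), %d aligned pair(s), query %d aa, template %d aa\n",
              numBlocks(object), sum(object@blocks[, 3]),
              object@queryLength, object@templateLength))
  if (numBlocks(object) > 0 && numBlocks(object) <= 12) {
    b <- object@blocks
    for (i in seq_len(nrow(b)))
      cat(sprintf("  [%d] query %d-%d <-> template %d-%d (len %d)\n", i,
                  b[i, 1], b[i, 1] + b[i, 3] - 1L,
                  b[i, 2], b[i, 2] + b[i, 3] - 1L, b[i, 3]))
  }
})

# the effective minimum block count: for short chains the constraint is
# relaxed to the largest feasible value (it is only a technical trick that
# keeps all movers executable)
effectiveMinBlocks <- function(queryLength, templateLength, constraints) {
  feasible <- min(queryLength, templateLength) %/% constraints@minBlockLength
  min(constraints@minNumberOfBlocks, max(1L, feasible))
}

#' Validate an alignment against the sampling constraints
#'
#' Checks the block-alignment invariants: every block at least
#' `minBlockLength` residues long, at least `minNumberOfBlocks` blocks
#' (relaxed, with a message in the report, when the chains are too short to
#' admit that many), blocks ordered and non-overlapping in both sequences,
#' and all indices in range. Violations are reported, not raised.
#'
#' @param alignment a [BlockAlignment-class].
#' @param constraints a [SamplingConstraints-class].
#' @return list with `ok` (logical) and `violations` (character vector).
#' @examples
#' a <- tileSelfAlignment(100, 4)
#' validateAlignment(a, SamplingConstraints())$ok   # TRUE
#' @export
validateAlignment <- function(alignment, constraints = SamplingConstraints()) {
  b <- alignment@blocks
  v <- character()
  minB <- effectiveMinBlocks(alignment@queryLength, alignment@templateLength,
                             constraints)
  if (nrow(b) < minB) {
    msg <- sprintf("too few blocks: %d < %d", nrow(b), minB)
    if (minB < constraints@minNumberOfBlocks)
      msg <- paste0(msg, " (minimum relaxed for short chains)")
    v <- c(v, msg)
  }
  if (nrow(b) > 0) {
    if (any(b[, 3] < constraints@minBlockLength))
      v <- c(v, sprintf("block shorter than minBlockLength (%d)",
                        constraints@minBlockLength))
    if (any(b[, 1] < 1) || any(b[, 2] < 1))
      v <- c(v, "block start below 1")
    if (any(b[, 1] + b[, 3] - 1 > alignment@queryLength))
      v <- c(v, "block exceeds query length")
    if (any(b[, 2] + b[, 3] - 1 > alignment@templateLength))
      v <- c(v, "block exceeds template length")
    if (nrow(b) > 1) {
      dq <- b[-1, 1] - (b[-nrow(b), 1] + b[-nrow(b), 3])
      dt <- b[-1, 2] - (b[-nrow(b), 2] + b[-nrow(b), 3])
      if (any(dq < 0)) v <- c(v, "blocks overlap or are out of order on the query")
      if (any(dt < 0)) v <- c(v, "blocks overlap or are out of order on the template")
    }
  }
  list(ok = length(v) == 0L, violations = v)
}

#' @rdname canonicalize
#' @export
setMethod("canonicalize", "BlockAlignment", function(x) {
  b <- x@blocks
  if (nrow(b) < 2) return(x)
  keep <- matrix(0L, nrow(b), 3)
  n <- 0L
  for (i in seq_len(nrow(b))) {
    if (n > 0L && keep[n, 1] + keep[n, 3] == b[i, 1] &&
        keep[n, 2] + keep[n, 3] == b[i, 2]) {
      keep[n, 3] <- keep[n, 3] + b[i, 3]
    } else {
      n <- n + 1L
      keep[n, ] <- b[i, ]
    }
  }
  newBlockAlignment(keep[seq_len(n), , drop = FALSE],
                    x@queryLength, x@templateLength)
})

#' @rdname residuePairs
#' @export
setMethod("residuePairs", "BlockAlignment", function(x) {
  b <- x@blocks
  if (nrow(b) == 0)
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("query", "template"))))
  off <- sequence(as.vector(b[, 3])) - 1L
  q <- rep(as.vector(b[, 1]), b[, 3]) + off
  t <- rep(as.vector(b[, 2]), b[, 3]) + off
  cbind(query = q, template = t)
})

# query -> template partner map (0 = unaligned), used for overlap metrics
# and changed-column bookkeeping
queryMap <- function(alignment) {
  m <- integer(alignment@queryLength)
  p <- residuePairs(alignment)
  m[p[, 1]] <- p[, 2]
  m
}

#' Test equality of two alignments
#'
#' Alignment identity is defined on canonical forms; this is the relation
#' used to deduplicate suboptimal alignments.
#'
#' @param a,b [BlockAlignment-class] objects.
#' @return TRUE iff the canonical forms are identical.
#' @export
alignmentIdentical <- function(a, b) {
  identical(unname(canonicalize(a)@blocks), unname(canonicalize(b)@blocks)) &&
    a@queryLength == b@queryLength && a@templateLength == b@templateLength
}

#' Tile the identity self-alignment with diagonal blocks
#'
#' Builds the perfect alignment of a chain with itself as abutting diagonal
#' blocks of the requested length -- e.g. a 100-residue self-alignment as
#' 25 blocks of 4 residues, or 4 blocks of 25. All such tilings
#' canonicalize to the same single-block alignment and have the same score
#' under any force field.
#'
#' @param sequenceLength chain length in residues.
#' @param blockLength residues per tile; if it does not divide
#'   `sequenceLength`, the last block absorbs the remainder.
#' @return a [BlockAlignment-class].
#' @examples
#' numBlocks(tileSelfAlignment(100, 4))   # 25
#' numBlocks(tileSelfAlignment(100, 25))  # 4
#' @export
tileSelfAlignment <- function(sequenceLength, blockLength) {
  sequenceLength <- as.integer(sequenceLength)
  blockLength <- as.integer(blockLength)
  if (sequenceLength < blockLength)
    stop("sequenceLength must be at least blockLength")
  n <- sequenceLength %/% blockLength
  starts <- (seq_len(n) - 1L) * blockLength + 1L
  lens <- rep(blockLength, n)
  lens[n] <- sequenceLength - starts[n] + 1L  # absorb any remainder
  BlockAlignment(starts, starts, lens, sequenceLength, sequenceLength)
}

# shared engine for the AL_0P / AL_4P alignment-overlap metrics
alignmentOverlap <- function(alignment, reference, tolerance) {
  if (alignment@queryLength != reference@queryLength ||
      alignment@templateLength != reference@templateLength)
    stop("alignment and reference must be over the same chain lengths")
  ref <- residuePairs(reference)
  if (nrow(ref) == 0) {
    warning("reference alignment has no aligned pairs")
    return(NA_real_)
  }
  m <- queryMap(alignment)
  partner <- m[ref[, 1]]
  mean(partner > 0 & abs(partner - ref[, 2]) <= tolerance)
}

#' Fraction of reference positions aligned exactly (AL_0P)
#'
#' The percent of correctly aligned positions: the fraction of the
#' reference's aligned residue pairs reproduced exactly by `alignment`.
#' The denominator is the reference's aligned-pair count; a null (empty)
#' candidate alignment scores 0.
#'
#' @param alignment candidate [BlockAlignment-class].
#' @param reference reference [BlockAlignment-class] over the same chains.
#' @return fraction in \[0, 1\].
#' @export
al0p <- function(alignment, reference) alignmentOverlap(alignment, reference, 0L)

#' Fraction of reference positions aligned within four residues (AL_4P)
#'
#' The fraction of reference pairs (i, j) for which `alignment` maps query
#' residue i to some template residue j' with |j' - j| <= 4.
#'
#' @inheritParams al0p
#' @return fraction in \[0, 1\].
#' @export
al4p <- function(alignment, reference) alignmentOverlap(alignment, reference, 4L)

#' Gapped two-row representation of an alignment
#'
#' Expands a block alignment into the familiar two-row gapped-string form,
#' '-' marking gaps. Between blocks, unaligned query residues are emitted
#' before unaligned template residues; unaligned terminal residues are
#' included.
#'
#' @param alignment a [BlockAlignment-class].
#' @param querySeq,templateSeq one-letter sequences of the two chains.
#' @return character vector of length 2 (query row, template row).
#' @export
alignmentStrings <- function(alignment, querySeq, templateSeq) {
  qs <- strsplit(querySeq, "")[[1]]
  ts <- strsplit(templateSeq, "")[[1]]
  if (length(qs) != alignment@queryLength || length(ts) != alignment@templateLength)
    inputError("sequence lengths do not match the alignment")
  b <- canonicalize(alignment)@blocks
  qrow <- character()
  trow <- character()
  qi <- 1L
  ti <- 1L
  emitGap <- function(qto, tto) {
    if (qi <= qto) {
      qrow <<- c(qrow, qs[qi:qto])
      trow <<- c(trow, rep("-", qto - qi + 1L))
      qi <<- qto + 1L
    }
    if (ti <= tto) {
      qrow <<- c(qrow, rep("-", tto - ti + 1L))
      trow <<- c(trow, ts[ti:tto])
      ti <<- tto + 1L
    }
  }
  for (i in seq_len(nrow(b))) {
    emitGap(b[i, 1] - 1L, b[i, 2] - 1L)
    idx <- seq_len(b[i, 3]) - 1L
    qrow <- c(qrow, qs[b[i, 1] + idx])
    trow <- c(trow, ts[b[i, 2] + idx])
    qi <- b[i, 1] + b[i, 3]
    ti <- b[i, 2] + b[i, 3]
  }
  emitGap(length(qs), length(ts))
  c(paste(qrow, collapse = ""), paste(trow, collapse = ""))
}
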