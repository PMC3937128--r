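# The seven stochastic alignment-modification operators and the weighted
# mover-selection machinery. The actual proposal geometry lives in compiled
# code (shared with the samplers); these wrappers add the changed-column
# bookkeeping and the S4 proposal type.

MOVER_NAMES <- c("shift", "shrink_expand", "part_jump", "split",
                 "merge", "annihilate", "create")

#' Default mover proposal weights
#'
#' Shift, shrink/expand and part-jump run in ratio 100 : 100 : 100 to
#' split and merge at 10 : 10 and annihilate at 1; block creation, kept
#' symmetric with annihilation, also gets weight 1.
#'
#' @return A [MoverSet-class] with the default weights.
#' @export
defaultMoverSet <- function() {
  MoverSet(weights = c(shift = 100, shrink_expand = 100, part_jump = 100,
                       split = 10, merge = 10, annihilate = 1, create = 1))
}

#' Construct a MoverSet
#' @param weights named nonnegative numeric vector; names must be among
#'   `"shift"`, `"shrink_expand"`, `"part_jump"`, `"split"`, `"merge"`,
#'   `"annihilate"`, `"create"`. Movers omitted from the vector get
#'   weight 0.
#' @return A [MoverSet-class].
#' @export
MoverSet <- function(weights) {
  w <- setNames(numeric(length(MOVER_NAMES)), MOVER_NAMES)
  if (is.null(names(weights)) || !all(names(weights) %in% MOVER_NAMES))
    configError("mover weights must be named; valid names: ",
                paste(MOVER_NAMES, collapse = ", "))
  w[names(weights)] <- weights
  new("MoverSet", moverNames = MOVER_NAMES, weights = unname(w))
}

setMethod("show", "MoverSet", function(object) {
  cat("MoverSet:\n")
  for (i in seq_along(object@moverNames))
    cat(sprintf("  %-14s weight %g\n", object@moverNames[i], object@weights[i]))
})

#' @rdname proposeMove
#' @export
setMethod("show", "MoveProposal", function(object) {
  if (object@feasible) {
    cat(sprintf("MoveProposal by '%s': %d changed query column(s)\n",
                object@moverName, length(object@changedQueryColumns)))
  } else {
    cat(sprintf("MoveProposal by '%s': infeasible\n", object@moverName))
  }
})

#' Propose a single alignment modification
#'
#' Applies one of the seven movers to an alignment:
#' \describe{
#'   \item{shift}{moves one block horizontally and/or vertically on the
#'     alignment matrix, uniformly over the space its neighbours allow.}
#'   \item{shrink_expand}{moves one block end in or out by N residues,
#'     N drawn from a truncated 1/2^N distribution; a block never shrinks
#'     below the minimum block length.}
#'   \item{part_jump}{detaches a terminal segment of one block and appends
#'     it to the adjacent block on that block's diagonal; the segment
#'     length is uniform among those leaving the donor at least the minimum
#'     block length.}
#'   \item{split}{cuts a block into two abutting parts (both at least the
#'     minimum block length); the residue pairs -- and hence the energy --
#'     are unchanged.}
#'   \item{merge}{fuses two neighbouring blocks that abut with zero gap on
#'     both sequences, provided the block count stays at or above the
#'     minimum.}
#'   \item{annihilate}{removes one block, provided the block count stays at
#'     or above the minimum.}
#'   \item{create}{places a new block of exactly the minimum block length
#'     uniformly over all positions that preserve ordering and
#'     non-overlap.}
#' }
#' A move that is geometrically impossible returns an infeasible proposal,
#' never an error. Randomness comes from R's RNG (`set.seed()` for
#' reproducibility).
#'
#' @param alignment a [BlockAlignment-class].
#' @param mover one of the mover names (see [defaultMoverSet()]).
#' @param constraints a [SamplingConstraints-class].
#' @return a [MoveProposal-class].
#' @examples
#' set.seed(7)
#' a <- tileSelfAlignment(60, 4)
#' proposeMove(a, "annihilate")
#' @export
proposeMove <- function(alignment, mover, constraints = SamplingConstraints()) {
  id <- match(mover, MOVER_NAMES)
  if (is.na(id)) configError("unknown mover '", mover, "'")
  minB <- effectiveMinBlocks(alignment@queryLength, alignment@templateLength,
                             constraints)
  res <- cpp_propose(alignment@blocks, alignment@queryLength,
                     alignment@templateLength, constraints@minBlockLength,
                     minB, id)
  if (!res$feasible) {
    return(new("MoveProposal", newAlignment = alignment,
               changedQueryColumns = integer(), moverName = mover,
               feasible = FALSE))
  }
  newAln <- newBlockAlignment(res$blocks, alignment@queryLength,
                              alignment@templateLength)
  changed <- which(queryMap(newAln) != queryMap(alignment))
  new("MoveProposal", newAlignment = newAln,
      changedQueryColumns = as.integer(changed), moverName = mover,
      feasible = TRUE)
}

#' Select a mover by weight and let it propose
#'
#' Chooses a mover with probability proportional to its weight in the
#' mover set, then returns its proposal (possibly infeasible) tagged with
#' the mover's name.
#'
#' @param moverSet a [MoverSet-class].
#' @param alignment a [BlockAlignment-class].
#' @param constraints a [SamplingConstraints-class].
#' @return a [MoveProposal-class].
#' @export
selectAndPropose <- function(moverSet, alignment,
                             constraints = SamplingConstraints()) {
  mover <- selectMover(moverSet, 1L)
  proposeMove(alignment, mover, constraints)
}

#' Draw mover names according to the proposal weights
#'
#' @param moverSet a [MoverSet-class].
#' @param n number of draws.
#' @return character vector of mover names.
#' @export
selectMover <- function(moverSet, n = 1L) {
  moverSet@moverNames[sample.int(length(moverSet@moverNames), n,
                                 replace = TRUE, prob = moverSet@weights)]
}

#' Sample shrink/expand lengths from the truncated 1/2^N distribution
#'
#' The length N of a shrink or expansion is drawn with probability
#' proportional to 2^-N, truncated to the geometrically feasible range.
#' This is the same routine the movers use internally; exposed so the
#' distribution can be inspected.
#'
#' @param n number of draws.
#' @param maxN truncation bound (largest feasible length).
#' @return integer vector of draws in 1..maxN.
#' @export
sampleShrinkLength <- function(n, maxN) {
  cpp_shrink_lengths(as.integer(n), as.integer(maxN))
}

#' Build a random valid alignment
#'
#' Starts from an empty alignment and applies block-creation moves until
#' the minimum block count is reached -- the initialization used for every
#' sampler replica.
#'
#' @param queryLength,templateLength chain lengths.
#' @param constraints a [SamplingConstraints-class]; for chains too short
#'   to host the minimum number of blocks, the count constraint is relaxed
#'   to the largest feasible value with a warning.
#' @return a valid [BlockAlignment-class].
#' @export
randomAlignment <- function(queryLength, templateLength,
                            constraints = SamplingConstraints()) {
  queryLength <- as.integer(queryLength)
  templateLength <- as.integer(templateLength)
  minB <- effectiveMinBlocks(queryLength, templateLength, constraints)
  if (minB < constraints@minNumberOfBlocks)
    warning("chains too short for ", constraints@minNumberOfBlocks,
            " blocks; relaxing the minimum block count to ", minB)
  # uniform placement can corner itself (no room left for the remaining
  # blocks); restart from empty when that happens
  for (attempt in 1:50) {
    aln <- BlockAlignment(queryLength = queryLength,
                          templateLength = templateLength)
    ok <- TRUE
    for (i in seq_len(minB)) {
      res <- cpp_propose(aln@blocks, queryLength, templateLength,
                         constraints@minBlockLength, minB, 7L)
      if (!res$feasible) {
        ok <- FALSE
        break
      }
      aln <- newBlockAlignment(res$blocks, queryLength, templateLength)
    }
    if (ok) return(aln)
  }
  # tight geometries (chains barely hosting minB blocks) defeat sequential
  # placement; draw a random valid layout directly on each axis instead
  lay <- function(n) {
    slack <- n - minB * constraints@minBlockLength
    cuts <- sort(sample.int(slack + 1L, minB, replace = TRUE)) - 1L
    (seq_len(minB) - 1L) * constraints@minBlockLength + cuts + 1L
  }
  BlockAlignment(lay(queryLength), lay(templateLength),
                 rep(constraints@minBlockLength, minB),
                 queryLength, templateLength)
}
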