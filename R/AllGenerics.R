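#' @rdname BlockAlignment-class
#' @param x,object an object.
#' @export
setGeneric("alignmentBlocks", function(x) standardGeneric("alignmentBlocks"))

#' @rdname BlockAlignment-class
#' @export
setGeneric("queryLength", function(x) standardGeneric("queryLength"))

#' @rdname BlockAlignment-class
#' @export
setGeneric("templateLength", function(x) standardGeneric("templateLength"))

#' @rdname BlockAlignment-class
#' @export
setGeneric("numBlocks", function(x) standardGeneric("numBlocks"))

#' Merge abutting blocks into the canonical minimal representation
#'
#' Because neighbouring blocks need not be separated by a gap, many block
#' lists encode the same alignment. `canonicalize` merges every pair of
#' consecutive blocks that abut with zero gap on both sequences, yielding
#' the unique minimal-block-count representation. The residue-pair set is
#' unchanged; two alignments are equal iff their canonical forms are equal.
#'
#' @param x a [BlockAlignment-class].
#' @return a [BlockAlignment-class] in canonical form.
#' @examples
#' a <- tileSelfAlignment(100, 4)    # 25 blocks of 4
#' numBlocks(canonicalize(a))        # 1
#' @export
setGeneric("canonicalize", function(x) standardGeneric("canonicalize"))

#' Expand an alignment into residue pairs
#'
#' @param x a [BlockAlignment-class].
#' @return integer m x 2 matrix of (query, template) residue pairs, strictly
#'   increasing in both columns.
#' @export
setGeneric("residuePairs", function(x) standardGeneric("residuePairs"))

#' @rdname StructureTrace-class
#' @param x an object.
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' @rdname StructureTrace-class
#' @export
setGeneric("chainSequence", function(x) standardGeneric("chainSequence"))

#' @rdname StructureTrace-class
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname ContactMap-class
#' @param x an object.
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname ContactMap-class
#' @export
setGeneric("nContacts", function(x) standardGeneric("nContacts"))

#' @rdname SamplingConstraints-class
#' @param x an object.
#' @export
setGeneric("minBlockLength", function(x) standardGeneric("minBlockLength"))

#' @rdname SamplingConstraints-class
#' @export
setGeneric("minNumberOfBlocks", function(x) standardGeneric("minNumberOfBlocks"))

#' Unweighted energy of one scoring term
#'
#' Evaluates a single term on an alignment. Similarity-type terms return
#' negated values (the sampler minimizes); penalty terms return positive
#' values.
#'
#' @param term a [ScoringTerm-class].
#' @param alignment a [BlockAlignment-class].
#' @param problem a [ThreadingProblem-class] with the term's inputs.
#' @return a single numeric energy.
#' @export
setGeneric("termEnergy",
           function(term, alignment, problem) standardGeneric("termEnergy"))

#' Precompute a per-position energy matrix for a BigMatrix term
#'
#' For terms whose column contributions depend only on the (query position,
#' template position) pair, the whole term can be pre-calculated once into
#' a query-length x template-length matrix; thereafter evaluating the term
#' on any alignment is a sum of lookups. The (negated) matrix is also the
#' score matrix fed to the dynamic-programming oracle.
#'
#' @param term a BigMatrix-capable [ScoringTerm-class].
#' @param problem a [ThreadingProblem-class].
#' @return numeric queryLength x templateLength matrix; entry (i, k) is the
#'   term's energy contribution for aligning query residue i to template
#'   residue k.
#' @export
setGeneric("bigMatrix", function(term, problem) standardGeneric("bigMatrix"))

#' Inputs a term requires from the problem
#'
#' @param term a [ScoringTerm-class].
#' @return character vector of required input names (subset of
#'   "query.sequence", "query.trace", "query.profile", "query.ss3",
#'   "query.burial", "template.sequence", "template.trace",
#'   "template.profile", "template.ss3", "template.burial", "contactMap").
#' @export
setGeneric("requiredInputs", function(term) standardGeneric("requiredInputs"))

#' Total force-field energy of an alignment
#'
#' @param forceField a [ForceField-class].
#' @param alignment a [BlockAlignment-class].
#' @param problem a [ThreadingProblem-class].
#' @param ... further arguments for methods.
#' @return list with elements `total` (weighted sum) and `terms` (named
#'   vector of unweighted per-term energies).
#' @export
setGeneric("totalEnergy",
           function(forceField, alignment, problem, ...) standardGeneric("totalEnergy"))

#' Energy difference of a proposed move, evaluated incrementally
#'
#' Column-decomposable (by-atom) terms are re-evaluated only at the query
#' columns the move affected; the remaining terms are recomputed in full.
#' Equals `totalEnergy(new) - totalEnergy(old)` to within 1e-9.
#'
#' @param forceField a [ForceField-class].
#' @param alignment the current [BlockAlignment-class].
#' @param proposal a [MoveProposal-class].
#' @param problem a [ThreadingProblem-class].
#' @param ... further arguments for methods.
#' @return a single numeric energy difference.
#' @export
setGeneric("deltaEnergy",
           function(forceField, alignment, proposal, problem, ...)
             standardGeneric("deltaEnergy"))
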