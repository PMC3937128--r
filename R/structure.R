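# Structure containers and the structure-based similarity scores.

#' @rdname StructureTrace-class
#' @export
setMethod("caCoords", "StructureTrace", function(x) x@coords)

#' @rdname StructureTrace-class
#' @export
setMethod("chainSequence", "StructureTrace", function(x) x@sequence)

#' @rdname StructureTrace-class
#' @export
setMethod("nResidues", "StructureTrace", function(x) nrow(x@coords))

#' @rdname ChainData-class
#' @export
setMethod("chainSequence", "ChainData", function(x) x@sequence)

#' @rdname ChainData-class
#' @export
setMethod("nResidues", "ChainData", function(x) nchar(x@sequence))

setMethod("show", "StructureTrace", function(object) {
  cat(sprintf("StructureTrace: %d residues, sequence %s%s\n",
              nResidues(object),
              substr(object@sequence, 1, 30),
              if (nResidues(object) > 30) "..." else ""))
})

setMethod("show", "ThreadingProblem", function(object) {
  cat("ThreadingProblem\n")
  for (side in c("query", "template")) {
    cd <- slot(object, side)
    cat(sprintf("  %-8s %d aa%s%s\n", side, nResidues(cd),
                if (!is.null(cd@trace)) ", structure" else "",
                if (!is.null(cd@profile)) ", profile" else ""))
  }
  if (!is.null(object@contactMap))
    cat(sprintf("  contact map: %d contacts (cutoff %.1f A)\n",
                nContacts(object@contactMap), object@contactMap@cutoff))
})

#' @rdname ContactMap-class
#' @export
setMethod("contactPairs", "ContactMap", function(x) x@pairs)

#' @rdname ContactMap-class
#' @export
setMethod("nContacts", "ContactMap", function(x) nrow(x@pairs))

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %d contacts over %d residues (cutoff %.1f A, |i-j| >= 3)\n",
              nContacts(object), object@nres, object@cutoff))
})

#' Construct a ContactMap from explicit pairs
#' @param pairs m x 2 matrix of residue index pairs (any order; stored i < j).
#' @param nres chain length.
#' @param cutoff the cutoff used to derive the pairs (bookkeeping only).
#' @return A [ContactMap-class].
#' @export
ContactMap <- function(pairs, nres, cutoff = NA_real_) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) > 0) {
    pairs <- t(apply(pairs, 1, sort))
    pairs <- unique(pairs[pairs[, 2] - pairs[, 1] >= 3, , drop = FALSE])
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  storage.mode(pairs) <- "integer"
  colnames(pairs) <- c("i", "j")
  new("ContactMap", pairs = pairs, cutoff = as.numeric(cutoff),
      nres = as.integer(nres))
}

#' Build a contact map from a C-alpha trace
#'
#' Residues i, j with |i - j| >= 3 are in contact when their C-alpha atoms
#' lie within the cutoff (default 8 Angstrom).
#'
#' @param trace a [StructureTrace-class].
#' @param cutoff contact distance in Angstrom.
#' @return A [ContactMap-class].
#' @export
buildContactMap <- function(trace, cutoff = 8.0) {
  xyz <- trace@coords
  d <- as.matrix(dist(xyz))
  n <- nrow(xyz)
  sep <- abs(row(d) - col(d))
  hit <- which(d <= cutoff & sep >= 3 & upper.tri(d), arr.ind = TRUE)
  ContactMap(hit[, c(1, 2), drop = FALSE], n, cutoff)
}

# residue pairs of an alignment restricted to chains with traces
alignedCoordPairs <- function(alignment) {
  p <- residuePairs(alignment)
  storage.mode(p) <- "integer"
  p
}

#' TM-score of an alignment between two structures
#'
#' Length-normalized structure-similarity score in (0, 1\]: the maximum
#' over rigid superpositions of `mean(1 / (1 + (d_i/d0)^2))` with
#' `d0 = 1.24 (Lnorm - 15)^(1/3) - 1.8` (floored at 0.5), found by
#' iterative Kabsch superposition on shrinking inlier sets. By default the
#' normalization length is the query length (threading semantics) and a
#' multi-seed fragment-window search is used; the sampler's energy uses
#' the faster single-seed refinement.
#'
#' @param query,template [StructureTrace-class] objects.
#' @param alignment a [BlockAlignment-class] between them.
#' @param normLength normalization length (default: query length).
#' @param thorough use the multi-seed search (default TRUE).
#' @return TM-score; 0 (with a warning) when fewer than 3 pairs are aligned.
#' @export
tmScore <- function(query, template, alignment,
                    normLength = nResidues(query), thorough = TRUE) {
  p <- alignedCoordPairs(alignment)
  if (nrow(p) < 3) {
    warning("TM-score undefined for fewer than 3 aligned pairs; returning 0")
    return(0)
  }
  cpp_tm_score(query@coords, template@coords, p, as.integer(normLength),
               isTRUE(thorough))
}

#' Coordinate RMSD of the aligned pairs after optimal superposition
#'
#' @inheritParams tmScore
#' @return RMSD in Angstrom (0 for an empty alignment, with a warning).
#' @export
rmsdScore <- function(query, template, alignment) {
  p <- alignedCoordPairs(alignment)
  if (nrow(p) == 0) {
    warning("RMSD undefined for an empty alignment; returning 0")
    return(0)
  }
  cpp_rmsd(query@coords, template@coords, p)
}

#' Holm-Sander elastic (DALI) similarity of the aligned pairs
#'
#' For every unordered pair of aligned columns with intramolecular
#' distances dQ and dT and d* = (dQ + dT)/2, contributes
#' `(0.2 - |dQ - dT| / d*) exp(-(d*/20)^2)`; each aligned column adds the
#' diagonal term 0.2.
#'
#' @inheritParams tmScore
#' @return similarity (larger is more similar).
#' @export
daliScore <- function(query, template, alignment) {
  p <- alignedCoordPairs(alignment)
  if (nrow(p) == 0) return(0)
  cpp_dali(query@coords, template@coords, p)
}
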