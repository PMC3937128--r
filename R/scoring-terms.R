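# Concrete scoring terms. Every term answers termEnergy(); BigMatrix terms
# additionally answer bigMatrix(), the per-position precomputation the
# sampler and the DP oracle consume. The R methods here are deliberately
# straightforward (independent of the compiled sampling path) so the two
# routes can be cross-checked.

# ----------------------------------------------------------- substitution

#' Load a substitution matrix
#'
#' `loadSubstitutionMatrix("BLOSUM62")` (or BLOSUM45/50/80/100, PAM30/40/
#' 70/120/250) returns the packaged standard matrix; a file path is parsed
#' as an NCBI-format ASCII matrix.
#'
#' @param name matrix name or path to an NCBI-format file.
#' @return integer/numeric square matrix with residue dimnames.
#' @export
loadSubstitutionMatrix <- function(name = "BLOSUM62") {
  packaged <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
                "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (name %in% packaged) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    return(get(name, envir = e))
  }
  if (!file.exists(name)) inputError("substitution matrix not found: ", name)
  readNCBIMatrix(name)
}

# NCBI ASCII substitution-matrix format: '#' comments, a header row of
# residue letters, then one labelled row per residue
readNCBIMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  m <- matrix(NA_real_, length(rows), length(header),
              dimnames = list(vapply(rows, `[`, character(1), 1), header))
  for (i in seq_along(rows)) m[i, ] <- as.numeric(rows[[i]][-1])
  m
}

#' Substitution-matrix scoring term
#'
#' Energy of an alignment under a residue substitution matrix such as
#' BLOSUM62: the negated sum of matrix entries over aligned pairs. Unknown
#' residues score through the matrix's wildcard ('X') row with a warning
#' at matrix-construction time.
#'
#' @param matrixName packaged matrix name or NCBI-format file path.
#' @return a BigMatrix [ScoringTerm-class].
#' @export
substitutionScoreTerm <- function(matrixName = "BLOSUM62") {
  new("SubstitutionScore", name = paste0("substitution_", matrixName),
      matrixName = matrixName, matrix = loadSubstitutionMatrix(matrixName))
}

setMethod("requiredInputs", "SubstitutionScore",
          function(term) c("query.sequence", "template.sequence"))

# map residue letters to rows of a substitution matrix, wildcarding
# letters the matrix does not know
matrixResidueIndex <- function(letters, m) {
  idx <- match(letters, rownames(m))
  if (anyNA(idx)) {
    if (!"X" %in% rownames(m))
      inputError("matrix has no wildcard row for unknown residue(s): ",
                 paste(unique(letters[is.na(idx)]), collapse = ", "))
    warning("unknown residue(s) scored via the wildcard row: ",
            paste(unique(letters[is.na(idx)]), collapse = ", "))
    idx[is.na(idx)] <- match("X", rownames(m))
  }
  idx
}

setMethod("bigMatrix", "SubstitutionScore", function(term, problem) {
  qi <- matrixResidueIndex(strsplit(problem@query@sequence, "")[[1]], term@matrix)
  ti <- matrixResidueIndex(strsplit(problem@template@sequence, "")[[1]], term@matrix)
  -term@matrix[qi, ti, drop = FALSE]
})

# ----------------------------------------------------------- profile score

#' Profile-profile scoring term (PICASSO-style cross score)
#'
#' Per aligned column, the symmetric cross score
#' `sum_a qfreq(a) tlogodds(a) + sum_a tfreq(a) qlogodds(a)`, negated and
#' summed over columns.
#'
#' @return a BigMatrix [ScoringTerm-class].
#' @export
profileScoreTerm <- function() new("ProfileScore", name = "profile")

setMethod("requiredInputs", "ProfileScore",
          function(term) c("query.profile", "template.profile"))

setMethod("bigMatrix", "ProfileScore", function(term, problem) {
  qp <- problem@query@profile
  tp <- problem@template@profile
  -(qp@freqs %*% t(tp@logOdds) + qp@logOdds %*% t(tp@freqs))
})

# ------------------------------------------------------ secondary structure

#' Probabilistic secondary-structure scoring term
#'
#' Per aligned column, the negated probability the query's 3-state
#' prediction assigns to the template's secondary-structure state (one-hot
#' when derived from the template structure; a probability row otherwise).
#' Several instances with different predictions may coexist in one force
#' field.
#'
#' @param name term label, so multiple instances remain distinguishable.
#' @return a BigMatrix [ScoringTerm-class].
#' @export
secondaryScoreTerm <- function(name = "secondary") new("SecondaryScore", name = name)

setMethod("requiredInputs", "SecondaryScore",
          function(term) c("query.ss3", "template.ss3"))

setMethod("bigMatrix", "SecondaryScore", function(term, problem) {
  -(problem@query@profile@ss3 %*% t(problem@template@profile@ss3))
})

# ----------------------------------------------------- environment / burial

# env and asa share the agreement kernel 1 - |q - t| on [0,1] burials but
# read different input channels (generic environment class vs solvent
# accessibility), mirroring their distinct places in the term taxonomy
burialAgreementMatrix <- function(qBurial, tBurial) {
  -(1 - abs(outer(qBurial, tBurial, "-")))
}

#' Environment (burial-class) scoring term
#'
#' Per aligned column, the negated agreement `1 - |q - t|` between the
#' query's predicted burial and the template's structure-derived burial,
#' both in \[0, 1\].
#'
#' @return a BigMatrix [ScoringTerm-class].
#' @export
envScoreTerm <- function() new("EnvScore", name = "env")

setMethod("requiredInputs", "EnvScore",
          function(term) c("query.burial", "template.burial"))

setMethod("bigMatrix", "EnvScore", function(term, problem) {
  burialAgreementMatrix(problem@query@profile@burial,
                        problem@template@profile@burial)
})

#' Solvent-accessibility scoring term
#'
#' Same agreement kernel as [envScoreTerm()] on the solvent-accessibility
#' channel.
#'
#' @return a BigMatrix [ScoringTerm-class].
#' @export
asaScoreTerm <- function() new("AsaScore", name = "asa")

setMethod("requiredInputs", "AsaScore",
          function(term) c("query.burial", "template.burial"))

setMethod("bigMatrix", "AsaScore", function(term, problem) {
  burialAgreementMatrix(problem@query@profile@burial,
                        problem@template@profile@burial)
})

#' Hydropathy-agreement (GRAVY) scoring term
#'
#' Per aligned column, the hydropathy mismatch `|h(q) - h(t)|` on the
#' Kyte-Doolittle scale normalized to \[0, 1\]; identical residues incur no
#' penalty. A pure penalty term (positive under the package's energy sign
#' convention), at most 1 per column.
#'
#' @return a BigMatrix [ScoringTerm-class].
#' @export
gravyScoreTerm <- function() new("GravyScore", name = "gravy")

setMethod("requiredInputs", "GravyScore",
          function(term) c("query.sequence", "template.sequence"))

normalizedHydropathy <- function(letters) {
  h <- (KYTE_DOOLITTLE[letters] + 4.5) / 9
  h[is.na(h)] <- 0.5 # unknown residues sit mid-scale
  unname(h)
}

setMethod("bigMatrix", "GravyScore", function(term, problem) {
  qh <- normalizedHydropathy(strsplit(problem@query@sequence, "")[[1]])
  th <- normalizedHydropathy(strsplit(problem@template@sequence, "")[[1]])
  abs(outer(qh, th, "-"))
})

# generic BigMatrix evaluation: precompute once, sum the aligned lookups
setMethod("termEnergy", signature(term = "BigMatrixTerm"),
          function(term, alignment, problem) {
  m <- bigMatrix(term, problem)
  p <- residuePairs(alignment)
  if (nrow(p) == 0) return(0)
  sum(m[p])
})

# --------------------------------------------------------------- affine gap

#' Affine gap penalty term
#'
#' Every run of g >= 1 unaligned residues between consecutive blocks
#' (query runs and template runs counted separately) costs
#' `open + (g - 1) * extend`; terminal gaps are free by default.
#'
#' @param open gap-opening penalty (default 5).
#' @param extend gap-extension penalty (default 0.5).
#' @param terminalFree charge nothing for terminal gaps (default TRUE).
#' @return a [ScoringTerm-class].
#' @export
affineGapTerm <- function(open = 5.0, extend = 0.5, terminalFree = TRUE) {
  new("AffineGapTerm", name = "affine_gap", open = open, extend = extend,
      terminalFree = terminalFree)
}

setMethod("requiredInputs", "AffineGapTerm", function(term) character())

setMethod("termEnergy", signature(term = "AffineGapTerm"),
          function(term, alignment, problem) {
  b <- canonicalize(alignment)@blocks
  if (nrow(b) == 0) return(0)
  runCost <- function(g) sum(ifelse(g > 0, term@open + (g - 1) * term@extend, 0))
  e <- 0
  if (nrow(b) > 1) {
    e <- e + runCost(b[-1, 1] - (b[-nrow(b), 1] + b[-nrow(b), 3]))
    e <- e + runCost(b[-1, 2] - (b[-nrow(b), 2] + b[-nrow(b), 3]))
  }
  if (!term@terminalFree) {
    e <- e + runCost(c(b[1, 1] - 1, b[1, 2] - 1,
                       alignment@queryLength - (b[nrow(b), 1] + b[nrow(b), 3] - 1),
                       alignment@templateLength - (b[nrow(b), 2] + b[nrow(b), 3] - 1)))
  }
  e
})

# ------------------------------------------------------------ contact terms

# template residue -> aligned query partner (0 = unaligned)
templateMap <- function(alignment) {
  m <- integer(alignment@templateLength)
  p <- residuePairs(alignment)
  m[p[, 2]] <- p[, 1]
  m
}

#' Structural gap penalty
#'
#' A gap introduced into the template structure is charged by the number
#' of lost contacts: `penalty` per template contact with at least one
#' endpoint in an unaligned template region.
#'
#' @param penalty cost per lost contact (default 1).
#' @return a ContactBased [ScoringTerm-class].
#' @export
structuralGapPenaltyTerm <- function(penalty = 1.0) {
  new("StructuralGapPenalty", name = "structural_gap", penalty = penalty)
}

setMethod("requiredInputs", "StructuralGapPenalty", function(term) "contactMap")

setMethod("termEnergy", signature(term = "StructuralGapPenalty"),
          function(term, alignment, problem) {
  ct <- problem@contactMap@pairs
  if (nrow(ct) == 0) return(0)
  tm <- templateMap(alignment)
  term@penalty * sum(tm[ct[, 1]] == 0 | tm[ct[, 2]] == 0)
})

#' Go-like contact-recovery score
#'
#' For every template contact (i, j) whose endpoints are both aligned to
#' query residues (i', j'), rewards -1 when the query C-alpha distance
#' |r_i' - r_j'| is within the contact cutoff. Requires the query
#' structure (benchmarking and structure-alignment use).
#'
#' @param cutoff query-side contact cutoff in Angstrom (default 8).
#' @return a ContactBased [ScoringTerm-class].
#' @export
goLikeScoreTerm <- function(cutoff = 8.0) {
  new("GoLikeScore", name = "go_like", cutoff = cutoff)
}

setMethod("requiredInputs", "GoLikeScore",
          function(term) c("contactMap", "query.trace"))

setMethod("termEnergy", signature(term = "GoLikeScore"),
          function(term, alignment, problem) {
  ct <- problem@contactMap@pairs
  if (nrow(ct) == 0) return(0)
  tm <- templateMap(alignment)
  qi <- tm[ct[, 1]]
  qj <- tm[ct[, 2]]
  both <- qi > 0 & qj > 0
  if (!any(both)) return(0)
  xyz <- problem@query@trace@coords
  d <- sqrt(rowSums((xyz[qi[both], , drop = FALSE] -
                     xyz[qj[both], , drop = FALSE])^2))
  -sum(d <= term@cutoff)
})

#' Load the packaged Miyazawa-Jernigan contact-energy table
#'
#' The 1996 residue-residue contact energies e_ij (RT units), shipped as a
#' documented TSV; returned as a symmetric 20 x 20 matrix with one-letter
#' dimnames in the package's canonical residue order.
#'
#' @param path alternative table in the same upper-triangle TSV layout.
#' @return symmetric numeric 20 x 20 matrix.
#' @export
loadMJTable <- function(path = system.file("extdata", "mj1996_eij.tsv",
                                           package = "ThreadMC")) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  parts <- strsplit(lines, "\t")
  res <- vapply(parts, `[`, character(1), 1)
  m <- matrix(NA_real_, 20, 20, dimnames = list(res, res))
  for (i in seq_along(parts)) {
    vals <- as.numeric(parts[[i]][-1])
    m[i, i:(i + length(vals) - 1)] <- vals
    m[i:(i + length(vals) - 1), i] <- vals
  }
  m[AA_STANDARD, AA_STANDARD]
}

#' Two-body contact potential term
#'
#' Transforms the template contact map onto the query through the current
#' alignment: every template contact with both endpoints aligned
#' contributes the pair potential of the two query residues. The packaged
#' potential is the Miyazawa-Jernigan contact-energy table.
#'
#' @param table symmetric 20 x 20 pair-potential matrix with one-letter
#'   dimnames; default the packaged MJ table.
#' @return a ContactBased [ScoringTerm-class].
#' @export
twoBodyContactTerm <- function(table = loadMJTable()) {
  new("TwoBodyContact", name = "two_body_contact", table = table)
}

setMethod("requiredInputs", "TwoBodyContact",
          function(term) c("contactMap", "query.sequence"))

setMethod("termEnergy", signature(term = "TwoBodyContact"),
          function(term, alignment, problem) {
  ct <- problem@contactMap@pairs
  if (nrow(ct) == 0) return(0)
  tm <- templateMap(alignment)
  qi <- tm[ct[, 1]]
  qj <- tm[ct[, 2]]
  both <- qi > 0 & qj > 0
  if (!any(both)) return(0)
  qs <- strsplit(problem@query@sequence, "")[[1]]
  a1 <- match(qs[qi[both]], rownames(term@table))
  a2 <- match(qs[qj[both]], colnames(term@table))
  known <- !is.na(a1) & !is.na(a2)
  sum(term@table[cbind(a1[known], a2[known])])
})

# ---------------------------------------------------------- structure terms

#' TM-score energy term (negated TM-score)
#'
#' @param thorough use the multi-seed superposition search in scoring-mode
#'   evaluations (the sampler always uses the fast single-seed refinement).
#' @return a StructureBased [ScoringTerm-class].
#' @export
tmScoreTerm <- function(thorough = TRUE) {
  new("TMScoreTerm", name = "tm_score", thorough = thorough)
}

setMethod("requiredInputs", "TMScoreTerm",
          function(term) c("query.trace", "template.trace"))

setMethod("termEnergy", signature(term = "TMScoreTerm"),
          function(term, alignment, problem) {
  p <- residuePairs(alignment)
  if (nrow(p) < 3) return(0)
  -cpp_tm_score(problem@query@trace@coords, problem@template@trace@coords,
                p, nResidues(problem@query), term@thorough)
})

#' RMSD energy term
#' @return a StructureBased [ScoringTerm-class].
#' @export
rmsdTerm <- function() new("RMSDTerm", name = "rmsd")

setMethod("requiredInputs", "RMSDTerm",
          function(term) c("query.trace", "template.trace"))

setMethod("termEnergy", signature(term = "RMSDTerm"),
          function(term, alignment, problem) {
  rmsdScore(problem@query@trace, problem@template@trace, alignment)
})

#' DALI energy term (negated elastic similarity)
#' @return a StructureBased [ScoringTerm-class].
#' @export
daliTerm <- function() new("DaliTerm", name = "dali")

setMethod("requiredInputs", "DaliTerm",
          function(term) c("query.trace", "template.trace"))

setMethod("termEnergy", signature(term = "DaliTerm"),
          function(term, alignment, problem) {
  -daliScore(problem@query@trace, problem@template@trace, alignment)
})

setMethod("show", "ScoringTerm", function(object) {
  caps <- c(if (is(object, "BigMatrixTerm")) "big-matrix"
            else if (is(object, "ByAtomTerm")) "by-atom",
            if (is(object, "StructureBasedTerm")) "structure-based",
            if (is(object, "ContactBasedTerm")) "contact-based")
  if (length(caps) == 0) caps <- "whole-alignment"
  cat(sprintf("ScoringTerm '%s' (%s)\n", object@name, paste(caps, collapse = ", ")))
})

# ------------------------------------------------------- user score matrix

#' User-supplied per-position score-matrix term
#'
#' Wraps an arbitrary precomputed query x template energy matrix as a
#' BigMatrix term -- the route for externally computed per-position scores
#' and for experiments on synthetic score landscapes. Entries are energies
#' (lower is better); negate a similarity matrix before wrapping it.
#'
#' @param matrix numeric queryLength x templateLength energy matrix.
#' @param name term label.
#' @return a BigMatrix [ScoringTerm-class].
#' @export
matrixScoreTerm <- function(matrix, name = "matrix_score") {
  new("MatrixScore", name = name, matrix = as.matrix(matrix))
}

setMethod("requiredInputs", "MatrixScore", function(term) character())

setMethod("bigMatrix", "MatrixScore", function(term, problem) {
  if (nrow(term@matrix) != nResidues(problem@query) ||
      ncol(term@matrix) != nResidues(problem@template))
    configError("matrix term '", term@name, "' has dimensions ",
                nrow(term@matrix), "x", ncol(term@matrix),
                " but the problem is ", nResidues(problem@query), "x",
                nResidues(problem@template))
  term@matrix
})
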