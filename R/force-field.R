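# Force-field composition: input checking, the compiled-sampler context,
# total and incremental energy evaluation.

setMethod("show", "ForceField", function(object) {
  cat("ForceField with", length(object@terms), "term(s):\n")
  for (i in seq_along(object@terms))
    cat(sprintf("  %-22s weight %g\n", object@terms[[i]]@name, object@weights[i]))
})

#' The default threading force field
#'
#' The weighted combination used for sequence-to-structure threading:
#' environment 0.1, secondary structure 0.25, profile 0.5, Go-like contact
#' recovery 1.0, Miyazawa-Jernigan two-body contacts 0.4 and structural
#' gap penalty 0.15.
#'
#' @param goLike include the Go-like term (needs the query structure;
#'   benchmarking use). Default TRUE.
#' @return a [ForceField-class].
#' @export
defaultThreadingForceField <- function(goLike = TRUE) {
  terms <- list(envScoreTerm(), secondaryScoreTerm(), profileScoreTerm())
  weights <- c(0.1, 0.25, 0.5)
  if (goLike) {
    terms <- c(terms, goLikeScoreTerm())
    weights <- c(weights, 1.0)
  }
  terms <- c(terms, twoBodyContactTerm(), structuralGapPenaltyTerm())
  weights <- c(weights, 0.4, 0.15)
  ForceField(terms, weights)
}

#' The structure-alignment force field
#'
#' Negative TM-score as the (single-term) energy function, the setting in
#' which threading doubles as a structure-alignment method.
#'
#' @return a [ForceField-class].
#' @export
structureAlignmentForceField <- function() {
  ForceField(list(tmScoreTerm()), 1.0)
}

# does the problem provide one named input channel?
hasInput <- function(problem, what) {
  switch(what,
    "query.sequence" = nchar(problem@query@sequence) > 0,
    "template.sequence" = nchar(problem@template@sequence) > 0,
    "query.trace" = !is.null(problem@query@trace),
    "template.trace" = !is.null(problem@template@trace),
    "query.profile" = !is.null(problem@query@profile),
    "template.profile" = !is.null(problem@template@profile),
    "query.ss3" = !is.null(problem@query@profile) &&
      nrow(problem@query@profile@ss3) > 0,
    "template.ss3" = !is.null(problem@template@profile) &&
      nrow(problem@template@profile@ss3) > 0,
    "query.burial" = !is.null(problem@query@profile) &&
      length(problem@query@profile@burial) > 0,
    "template.burial" = !is.null(problem@template@profile) &&
      length(problem@template@profile@burial) > 0,
    "contactMap" = !is.null(problem@contactMap),
    FALSE)
}

#' Check that a problem provides every enabled term's inputs
#'
#' @param forceField a [ForceField-class].
#' @param problem a [ThreadingProblem-class].
#' @return invisibly TRUE; a configuration error naming the term and the
#'   missing input otherwise.
#' @export
checkInputs <- function(forceField, problem) {
  for (term in forceField@terms) {
    for (need in requiredInputs(term)) {
      if (!hasInput(problem, need))
        configError("term '", term@name, "' requires input '", need,
                    "' which the problem does not provide")
    }
  }
  invisible(TRUE)
}

# Compile a force field + problem into the flat context the compiled
# sampler consumes: all BigMatrix terms pre-summed into one weighted
# matrix, gap/contact/structure terms as parameter records. The sampler
# supports at most one instance each of the gap, Go-like, two-body,
# structural-gap, TM, RMSD and DALI terms (multiple BigMatrix instances
# are unrestricted).
compileForceField <- function(forceField, problem) {
  checkInputs(forceField, problem)
  qlen <- nResidues(problem@query)
  tlen <- nResidues(problem@template)
  ctx <- list(qlen = qlen, tlen = tlen, big = NULL, gap = NULL,
              contacts = NULL, sgp = NULL, golike = NULL, twobody = NULL,
              tm = NULL, rmsd = NULL, dali = NULL,
              qcoords = NULL, tcoords = NULL)
  big <- NULL
  sgpCoef <- 0
  haveSgp <- FALSE
  for (i in seq_along(forceField@terms)) {
    term <- forceField@terms[[i]]
    w <- forceField@weights[i]
    if (is(term, "BigMatrixTerm")) {
      m <- w * bigMatrix(term, problem)
      big <- if (is.null(big)) m else big + m
    } else if (is(term, "AffineGapTerm")) {
      if (!is.null(ctx$gap)) configError("only one affine-gap term is supported")
      ctx$gap <- list(open = w * term@open, extend = w * term@extend,
                      terminalFree = term@terminalFree)
    } else if (is(term, "StructuralGapPenalty")) {
      sgpCoef <- sgpCoef + w * term@penalty
      haveSgp <- TRUE
    } else if (is(term, "GoLikeScore")) {
      if (!is.null(ctx$golike)) configError("only one Go-like term is supported")
      ctx$golike <- list(w = w, cutoff = term@cutoff)
    } else if (is(term, "TwoBodyContact")) {
      if (!is.null(ctx$twobody)) configError("only one two-body contact term is supported")
      tab <- term@table[AA_STANDARD, AA_STANDARD]
      qseq <- match(strsplit(problem@query@sequence, "")[[1]], AA_STANDARD)
      qseq[is.na(qseq)] <- 0L
      ctx$twobody <- list(w = w, table = tab, qseq = as.integer(qseq))
    } else if (is(term, "TMScoreTerm")) {
      if (!is.null(ctx$tm)) configError("only one TM-score term is supported")
      ctx$tm <- list(w = w, Lnorm = qlen)
    } else if (is(term, "RMSDTerm")) {
      if (!is.null(ctx$rmsd)) configError("only one RMSD term is supported")
      ctx$rmsd <- list(w = w)
    } else if (is(term, "DaliTerm")) {
      if (!is.null(ctx$dali)) configError("only one DALI term is supported")
      ctx$dali <- list(w = w)
    } else {
      configError("term '", term@name, "' is not supported by the sampler")
    }
  }
  if (haveSgp) ctx$sgp <- list(coef = sgpCoef)
  ctx["big"] <- list(big)  # keep the element even when NULL
  needContacts <- haveSgp || !is.null(ctx$golike) || !is.null(ctx$twobody)
  if (needContacts) ctx$contacts <- problem@contactMap@pairs
  needQx <- !is.null(ctx$golike) || !is.null(ctx$tm) || !is.null(ctx$rmsd) ||
    !is.null(ctx$dali)
  if (needQx) ctx$qcoords <- problem@query@trace@coords
  if (!is.null(ctx$tm) || !is.null(ctx$rmsd) || !is.null(ctx$dali))
    ctx$tcoords <- problem@template@trace@coords
  ctx
}

#' @describeIn totalEnergy Weighted total with a per-term breakdown. With
#'   `tmThorough = FALSE`, TM-score terms are evaluated with the sampler's
#'   fast superposition refinement so a sampling run's energies can be
#'   reproduced exactly.
#' @param tmThorough logical; use the multi-seed TM-score search.
#' @export
setMethod("totalEnergy",
          signature(forceField = "ForceField", alignment = "BlockAlignment",
                    problem = "ThreadingProblem"),
          function(forceField, alignment, problem, tmThorough = TRUE) {
  checkInputs(forceField, problem)
  vals <- vapply(forceField@terms, function(term) {
    if (is(term, "TMScoreTerm") && !tmThorough) {
      p <- residuePairs(alignment)
      if (nrow(p) < 3) return(0)
      return(-cpp_tm_score(problem@query@trace@coords,
                           problem@template@trace@coords, p,
                           nResidues(problem@query), FALSE))
    }
    termEnergy(term, alignment, problem)
  }, numeric(1))
  names(vals) <- vapply(forceField@terms, function(t) t@name, character(1))
  list(total = sum(forceField@weights * vals), terms = vals)
})

#' @describeIn deltaEnergy Incremental evaluation: BigMatrix terms are
#'   re-scored only at the proposal's changed query columns; all other
#'   terms are recomputed in full on both alignments.
#' @export
setMethod("deltaEnergy",
          signature(forceField = "ForceField", alignment = "BlockAlignment",
                    proposal = "MoveProposal", problem = "ThreadingProblem"),
          function(forceField, alignment, proposal, problem,
                   tmThorough = FALSE) {
  if (!proposal@feasible) return(0)
  oldMap <- queryMap(alignment)
  newMap <- queryMap(proposal@newAlignment)
  changed <- proposal@changedQueryColumns
  delta <- 0
  for (i in seq_along(forceField@terms)) {
    term <- forceField@terms[[i]]
    w <- forceField@weights[i]
    if (is(term, "BigMatrixTerm")) {
      if (length(changed) == 0) next
      m <- bigMatrix(term, problem)
      oldPart <- oldMap[changed]
      newPart <- newMap[changed]
      d <- 0
      gain <- newPart > 0
      loss <- oldPart > 0
      if (any(gain)) d <- d + sum(m[cbind(changed[gain], newPart[gain])])
      if (any(loss)) d <- d - sum(m[cbind(changed[loss], oldPart[loss])])
      delta <- delta + w * d
    } else {
      eNew <- if (is(term, "TMScoreTerm") && !tmThorough)
        termEnergy(tmScoreTerm(thorough = FALSE), proposal@newAlignment, problem)
      else termEnergy(term, proposal@newAlignment, problem)
      eOld <- if (is(term, "TMScoreTerm") && !tmThorough)
        termEnergy(tmScoreTerm(thorough = FALSE), alignment, problem)
      else termEnergy(term, alignment, problem)
      delta <- delta + w * (eNew - eOld)
    }
  }
  delta
})

#' Precompute the per-position matrix of one BigMatrix term
#'
#' Thin exported wrapper around the [bigMatrix()] generic with input
#' checking; see that generic for semantics.
#'
#' @param term a BigMatrix-capable [ScoringTerm-class].
#' @param problem a [ThreadingProblem-class].
#' @return numeric queryLength x templateLength matrix.
#' @export
precomputeMatrix <- function(term, problem) {
  if (!is(term, "BigMatrixTerm"))
    configError("term '", term@name, "' is not BigMatrix-capable")
  for (need in requiredInputs(term)) {
    if (!hasInput(problem, need))
      configError("term '", term@name, "' requires input '", need, "'")
  }
  bigMatrix(term, problem)
}
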