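# Deterministic synthetic-data generators: every input format the engine
# reads can be fabricated with a seed, so the whole package is testable
# without downloading anything.

# re-express an alignment with enough (abutting) blocks to satisfy the
# minimum block count; the residue-pair set is unchanged
splitToMinBlocks <- function(alignment, constraints = SamplingConstraints()) {
  minB <- effectiveMinBlocks(alignment@queryLength, alignment@templateLength,
                             constraints)
  b <- alignment@blocks
  while (nrow(b) < minB) {
    i <- which.max(b[, 3])
    if (b[i, 3] < 2L * constraints@minBlockLength) break
    left <- b[i, 3] %/% 2L
    top <- b[seq_len(i - 1), , drop = FALSE]
    bottom <- b[-seq_len(i), , drop = FALSE]
    mid <- rbind(c(b[i, 1], b[i, 2], left),
                 c(b[i, 1] + left, b[i, 2] + left, b[i, 3] - left))
    b <- rbind(top, mid, bottom)
  }
  newBlockAlignment(b, alignment@queryLength, alignment@templateLength)
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate an ideal alpha-helix C-alpha trace
#'
#' Standard helix geometry -- 1.5 Angstrom rise and 100 degrees of turn
#' per residue at 2.3 Angstrom radius, giving the canonical ~3.8 Angstrom
#' consecutive C-alpha distance -- with a random but seed-fixed sequence.
#'
#' @param nResidues chain length.
#' @param seed RNG seed for the sequence.
#' @return a [StructureTrace-class].
#' @export
makeHelixTrace <- function(nResidues, seed = 1L) {
  i <- seq_len(nResidues) - 1
  theta <- i * 100 * pi / 180
  coords <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  seqLetters <- withSeed(seed, sample(AA_STANDARD, nResidues, replace = TRUE))
  StructureTrace(coords, paste(seqLetters, collapse = ""))
}

#' Generate a homolog with a known ground-truth alignment
#'
#' Perturbs a trace into a synthetic homolog: Gaussian coordinate noise,
#' optional residue substitutions, and deletions that remove template
#' segments (specified as a list of `c(start, length)` in template
#' coordinates). The preserved segments become the blocks of the returned
#' ground-truth alignment (homolog = query, input trace = template), so
#' alignment-recovery and AL_0P/AL_4P experiments have an exact reference.
#'
#' @param trace template [StructureTrace-class].
#' @param coordinateNoiseSD Gaussian noise per coordinate, Angstrom.
#' @param deletions list of `c(start, length)` template segments to delete;
#'   every preserved segment must stay at least `minBlockLength` long.
#' @param mutationRate fraction of residues substituted at random.
#' @param seed RNG seed.
#' @param minBlockLength used only to check the deletion spec.
#' @return list with `trace` (the homolog) and `truth` (the ground-truth
#'   [BlockAlignment-class], query = homolog, template = input trace).
#' @export
makeHomolog <- function(trace, coordinateNoiseSD = 0, deletions = list(),
                        mutationRate = 0, seed = 1L, minBlockLength = 4L) {
  n <- nResidues(trace)
  keep <- rep(TRUE, n)
  for (d in deletions) {
    if (length(d) != 2 || d[1] < 1 || d[1] + d[2] - 1 > n)
      inputError("bad deletion spec: start ", d[1], " length ", d[2])
    keep[d[1]:(d[1] + d[2] - 1)] <- FALSE
  }
  kept <- which(keep)
  if (length(kept) == 0) inputError("deletions remove the whole chain")
  # preserved template segments -> ground-truth blocks
  brk <- c(TRUE, diff(kept) != 1)
  starts <- kept[brk]
  lens <- as.integer(diff(c(which(brk), length(kept) + 1L)))
  if (any(lens < minBlockLength))
    inputError("a preserved segment is shorter than ", minBlockLength,
               " residues; place deletions further apart")
  qStarts <- cumsum(c(1L, lens[-length(lens)]))
  truth <- BlockAlignment(qStarts, starts, lens, length(kept), n)
  truth <- splitToMinBlocks(truth, SamplingConstraints(minBlockLength, 4L))
  withSeed(seed, {
    coords <- trace@coords[kept, , drop = FALSE] +
      matrix(stats::rnorm(3 * length(kept), sd = coordinateNoiseSD),
             ncol = 3)
    letters1 <- strsplit(trace@sequence, "")[[1]][kept]
    if (mutationRate > 0) {
      mut <- runif(length(letters1)) < mutationRate
      letters1[mut] <- sample(AA_STANDARD, sum(mut), replace = TRUE)
    }
    list(trace = StructureTrace(coords, paste(letters1, collapse = "")),
         truth = truth)
  })
}

#' Generate a synthetic sequence profile
#'
#' Concentrates probability mass `sharpness` on the true residue at each
#' position and spreads the rest uniformly; log-odds are against the
#' uniform background. `sharpness = 1` gives a one-hot profile.
#'
#' @param sequence one-letter sequence.
#' @param sharpness mass on the true residue, in \[0, 1\].
#' @param seed RNG seed (jitters the off-residue mass slightly so
#'   synthetic profiles are not exactly exchangeable between positions).
#' @return a [Profile-class].
#' @export
makeProfile <- function(sequence, sharpness = 0.9, seed = 1L) {
  letters1 <- strsplit(sequence, "")[[1]]
  n <- length(letters1)
  withSeed(seed, {
    freqs <- matrix(runif(n * 20, 0.8, 1.2), n, 20)
    freqs <- freqs / rowSums(freqs) * (1 - sharpness)
    idx <- match(letters1, AA_STANDARD)
    idx[is.na(idx)] <- 1L
    freqs[cbind(seq_len(n), idx)] <- freqs[cbind(seq_len(n), idx)] + sharpness
    freqs <- freqs / rowSums(freqs)
    Profile(freqs = freqs, logOdds = log2(pmax(freqs, 1e-4) / 0.05))
  })
}

#' Derive 3-state secondary-structure probabilities from a trace
#'
#' Geometric assignment from C-alpha distances: a residue whose i to i+4
#' distance is below 6.5 Angstrom is called helix, above 10 Angstrom
#' strand, else coil; chain ends inherit their nearest assignable
#' neighbour. The called state gets probability `confidence`, the rest is
#' split evenly.
#'
#' @param trace a [StructureTrace-class].
#' @param confidence probability on the called state (default 0.9).
#' @return n x 3 matrix with columns H, E, C.
#' @export
makeSS2 <- function(trace, confidence = 0.9) {
  xyz <- trace@coords
  n <- nrow(xyz)
  state <- rep(NA_character_, n)
  if (n > 4) {
    for (i in seq_len(n - 4)) {
      d <- sqrt(sum((xyz[i, ] - xyz[i + 4, ])^2))
      state[i] <- if (d < 6.5) "H" else if (d > 10) "E" else "C"
    }
    for (i in which(is.na(state))) state[i] <- state[max(which(!is.na(state)))]
  } else {
    state[] <- "C"
  }
  ss <- matrix((1 - confidence) / 2, n, 3, dimnames = list(NULL, c("H", "E", "C")))
  ss[cbind(seq_len(n), match(state, c("H", "E", "C")))] <- confidence
  ss
}

#' Derive a relative burial vector from a trace
#'
#' Neighbour-count burial: the number of C-alpha atoms within 10 Angstrom,
#' rescaled to \[0, 1\] over the chain. A cheap structure-derived stand-in
#' for relative solvent accessibility predictions.
#'
#' @param trace a [StructureTrace-class].
#' @param radius neighbour radius in Angstrom.
#' @return numeric vector in \[0, 1\].
#' @export
makeBurial <- function(trace, radius = 10) {
  d <- as.matrix(dist(trace@coords))
  counts <- rowSums(d <= radius) - 1
  if (max(counts) == min(counts)) return(rep(0.5, nrow(d)))
  (counts - min(counts)) / (max(counts) - min(counts))
}

#' Contact map of a trace (fixtures alias)
#'
#' Same definition the scoring module uses: C-alpha within `cutoff`,
#' |i - j| >= 3. See [buildContactMap()].
#'
#' @inheritParams buildContactMap
#' @return a [ContactMap-class].
#' @export
makeContactMap <- function(trace, cutoff = 8.0) buildContactMap(trace, cutoff)

#' Assemble a complete synthetic threading problem
#'
#' A template helix plus a noisy homolog query with profiles, secondary
#' structure and burial on both sides -- everything the default threading
#' force field needs -- together with the ground-truth alignment.
#'
#' @param nResidues template length.
#' @param coordinateNoiseSD homolog coordinate noise (Angstrom).
#' @param deletions deletion spec passed to [makeHomolog()].
#' @param mutationRate homolog substitution rate.
#' @param sharpness profile sharpness.
#' @param seed RNG seed.
#' @return list with `problem` (a [ThreadingProblem-class]) and `truth`.
#' @export
makeThreadingFixture <- function(nResidues = 60, coordinateNoiseSD = 0.3,
                                 deletions = list(), mutationRate = 0,
                                 sharpness = 0.9, seed = 1L) {
  tmpl <- makeHelixTrace(nResidues, seed = seed)
  hom <- makeHomolog(tmpl, coordinateNoiseSD, deletions, mutationRate,
                     seed = seed + 1L)
  qTrace <- hom$trace
  qProf <- makeProfile(qTrace@sequence, sharpness, seed = seed + 2L)
  qProf@ss3 <- makeSS2(qTrace)
  qProf@burial <- makeBurial(qTrace)
  tProf <- makeProfile(tmpl@sequence, sharpness, seed = seed + 3L)
  tProf@ss3 <- makeSS2(tmpl)
  tProf@burial <- makeBurial(tmpl)
  problem <- ThreadingProblem(ChainData(trace = qTrace, profile = qProf),
                              ChainData(trace = tmpl, profile = tProf))
  list(problem = problem, truth = hom$truth)
}

#' Write a minimal C-alpha-only PDB file for a trace
#'
#' @param trace a [StructureTrace-class].
#' @param path output file.
#' @param chain chain identifier.
#' @return invisibly, the path.
#' @export
writeCATrace <- function(trace, path, chain = "A") {
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  letters1 <- strsplit(trace@sequence, "")[[1]]
  res3 <- aa3[letters1]
  res3[is.na(res3)] <- "UNK"
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nResidues(trace))) {
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, res3[i], chain, i, trace@coords[i, 1], trace@coords[i, 2],
      trace@coords[i, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}
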