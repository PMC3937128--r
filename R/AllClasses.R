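#' Sampling constraints for block alignments
#'
#' The two technical restrictions on the block representation: no block may
#' be shorter than `minBlockLength` and an alignment must consist of at
#' least `minNumberOfBlocks` blocks (both default 4). The second rule only
#' guarantees every mover a chance to act; because neighbouring blocks may
#' abut with no gap, it does not restrict the space of distinct alignments.
#'
#' @slot minBlockLength minimum residues per block.
#' @slot minNumberOfBlocks minimum number of blocks per alignment.
#' @export
setClass("SamplingConstraints",
         representation(minBlockLength = "integer",
                        minNumberOfBlocks = "integer"),
         prototype(minBlockLength = 4L, minNumberOfBlocks = 4L),
         validity = function(object) {
           if (length(object@minBlockLength) != 1L ||
               length(object@minNumberOfBlocks) != 1L)
             return("constraints must be scalar")
           if (object@minBlockLength < 1L || object@minNumberOfBlocks < 1L)
             return("constraints must be >= 1")
           TRUE
         })

#' Constructor for SamplingConstraints
#'
#' @param minBlockLength minimum block length (default 4).
#' @param minNumberOfBlocks minimum block count (default 4).
#' @return A [SamplingConstraints-class] object.
#' @examples
#' SamplingConstraints()                 # the defaults: 4 and 4
#' SamplingConstraints(minBlockLength = 2)
#' @export
SamplingConstraints <- function(minBlockLength = 4L, minNumberOfBlocks = 4L) {
  new("SamplingConstraints",
      minBlockLength = as.integer(minBlockLength),
      minNumberOfBlocks = as.integer(minNumberOfBlocks))
}

#' Block-list alignment between two proteins
#'
#' An alignment between a query and a template is an ordered list of
#' gapless blocks. Block i aligns `length[i]` consecutive query residues
#' starting at `queryStart[i]` with the template residues starting at
#' `templateStart[i]` (1-based, closed intervals). Consecutive blocks must
#' not overlap in either sequence but may abut with no gap, so the
#' representation is redundant: [canonicalize()] merges abutting blocks and
#' two alignments are considered equal iff their canonical forms are equal.
#'
#' @slot blocks integer matrix with columns queryStart, templateStart,
#'   length; one row per block, ordered.
#' @slot queryLength,templateLength residue counts of the two chains.
#' @export
setClass("BlockAlignment",
         representation(blocks = "matrix",
                        queryLength = "integer",
                        templateLength = "integer"),
         validity = function(object) {
           b <- object@blocks
           if (!is.numeric(b) || ncol(b) != 3L)
             return("blocks must be a 3-column matrix")
           if (nrow(b) > 0) {
             if (any(b[, 3] < 1)) return("block lengths must be >= 1")
             if (any(b[, 1] < 1) || any(b[, 2] < 1))
               return("block starts must be >= 1")
             if (any(b[, 1] + b[, 3] - 1 > object@queryLength))
               return("block exceeds query length")
             if (any(b[, 2] + b[, 3] - 1 > object@templateLength))
               return("block exceeds template length")
             if (nrow(b) > 1) {
               dq <- b[-1, 1] - (b[-nrow(b), 1] + b[-nrow(b), 3])
               dt <- b[-1, 2] - (b[-nrow(b), 2] + b[-nrow(b), 3])
               if (any(dq < 0) || any(dt < 0))
                 return("blocks must be ordered and non-overlapping in both sequences")
             }
           }
           TRUE
         })

#' Construct a BlockAlignment
#'
#' @param queryStart,templateStart,length parallel integer vectors, one
#'   entry per block (1-based starts).
#' @param queryLength,templateLength chain lengths in residues.
#' @return A [BlockAlignment-class].
#' @examples
#' # one block aligning query 1..4 onto template 6..9
#' ba <- BlockAlignment(1, 6, 4, queryLength = 10, templateLength = 12)
#' residuePairs(ba)
#' @export
BlockAlignment <- function(queryStart = integer(), templateStart = integer(),
                           length = integer(), queryLength, templateLength) {
  b <- cbind(queryStart = as.integer(queryStart),
             templateStart = as.integer(templateStart),
             length = as.integer(length))
  new("BlockAlignment", blocks = b,
      queryLength = as.integer(queryLength),
      templateLength = as.integer(templateLength))
}

# internal: wrap a raw block matrix without re-deriving names
newBlockAlignment <- function(blocks, queryLength, templateLength) {
  storage.mode(blocks) <- "integer"
  colnames(blocks) <- c("queryStart", "templateStart", "length")
  new("BlockAlignment", blocks = blocks,
      queryLength = as.integer(queryLength),
      templateLength = as.integer(templateLength))
}

#' C-alpha trace of a protein chain
#'
#' Per-residue C-alpha coordinates (Angstrom) plus the one-letter sequence.
#'
#' @slot coords numeric n x 3 matrix of C-alpha coordinates.
#' @slot sequence single string of one-letter residue codes (X = unknown).
#' @export
setClass("StructureTrace",
         representation(coords = "matrix", sequence = "character"),
         validity = function(object) {
           if (ncol(object@coords) != 3L) return("coords must be n x 3")
           if (!all(is.finite(object@coords))) return("coordinates must be finite")
           if (length(object@sequence) != 1L) return("sequence must be a single string")
           if (nchar(object@sequence) != nrow(object@coords))
             return("coordinate count must equal sequence length")
           TRUE
         })

#' Construct a StructureTrace
#' @param coords numeric n x 3 matrix of C-alpha coordinates (Angstrom).
#' @param sequence one-letter sequence, a single string or character vector.
#' @return A [StructureTrace-class].
#' @export
StructureTrace <- function(coords, sequence) {
  if (length(sequence) > 1L) sequence <- paste(sequence, collapse = "")
  new("StructureTrace", coords = as.matrix(coords), sequence = sequence)
}

#' Per-position profile data for one chain
#'
#' Sequence profile (20-component frequencies and log-odds per position),
#' optionally augmented with 3-state secondary-structure probabilities
#' (columns H, E, C) and a predicted relative burial in \[0, 1\]. Columns of
#' the profile matrices follow the package's canonical amino-acid order.
#' Optional components are stored as zero-row/zero-length placeholders.
#'
#' @slot freqs n x 20 matrix of position-specific residue frequencies.
#' @slot logOdds n x 20 matrix of position-specific log-odds scores.
#' @slot ss3 n x 3 matrix of secondary-structure probabilities (H, E, C),
#'   or a 0-row matrix when absent.
#' @slot burial numeric vector of relative burial in \[0,1\], or length 0.
#' @export
setClass("Profile",
         representation(freqs = "matrix", logOdds = "matrix",
                        ss3 = "matrix", burial = "numeric"),
         validity = function(object) {
           n <- nrow(object@freqs)
           if (ncol(object@freqs) != 20L || ncol(object@logOdds) != 20L)
             return("freqs and logOdds must have 20 columns")
           if (nrow(object@logOdds) != n)
             return("freqs and logOdds must have the same number of rows")
           if (nrow(object@ss3) > 0) {
             if (ncol(object@ss3) != 3L) return("ss3 must have 3 columns (H, E, C)")
             if (nrow(object@ss3) != n) return("ss3 rows must match profile length")
             if (any(abs(rowSums(object@ss3) - 1) > 0.01))
               return("ss3 rows must sum to 1 (within 0.01)")
           }
           if (length(object@burial) > 0) {
             if (length(object@burial) != n)
               return("burial length must match profile length")
             if (any(object@burial < 0 | object@burial > 1))
               return("burial must lie in [0, 1]")
           }
           TRUE
         })

#' Construct a Profile
#' @param freqs n x 20 frequency matrix (rows are positions).
#' @param logOdds n x 20 log-odds matrix; defaults to log2(freqs / 0.05).
#' @param ss3 optional n x 3 matrix of H/E/C probabilities.
#' @param burial optional numeric vector of relative burial in \[0,1\].
#' @return A [Profile-class].
#' @export
Profile <- function(freqs, logOdds = NULL, ss3 = NULL, burial = NULL) {
  freqs <- as.matrix(freqs)
  colnames(freqs) <- AA_STANDARD
  if (is.null(logOdds)) logOdds <- log2(pmax(freqs, 1e-4) / 0.05)
  logOdds <- as.matrix(logOdds)
  colnames(logOdds) <- AA_STANDARD
  if (is.null(ss3)) ss3 <- matrix(numeric(), 0, 3)
  if (is.null(burial)) burial <- numeric()
  ss3 <- as.matrix(ss3)
  if (nrow(ss3) > 0) {
    ss3 <- ss3 / rowSums(ss3)
    colnames(ss3) <- c("H", "E", "C")
  }
  new("Profile", freqs = freqs, logOdds = logOdds, ss3 = ss3,
      burial = as.numeric(burial))
}

#' Template contact map
#'
#' The set of unordered residue pairs (i, j), |i - j| >= 3, whose reference
#' atoms lie within a cutoff distance. Built from a C-alpha trace by
#' [buildContactMap()]; contact-based energy terms transform these template
#' contacts onto the query through the current alignment.
#'
#' @slot pairs m x 2 integer matrix with i < j rows.
#' @slot cutoff contact cutoff distance in Angstrom.
#' @slot nres number of residues in the chain the map describes.
#' @export
setClass("ContactMap",
         representation(pairs = "matrix", cutoff = "numeric", nres = "integer"),
         validity = function(object) {
           p <- object@pairs
           if (ncol(p) != 2L) return("pairs must be m x 2")
           if (nrow(p) > 0) {
             if (any(p[, 1] >= p[, 2])) return("pairs must satisfy i < j")
             if (any(p[, 2] - p[, 1] < 3)) return("contacts require |i - j| >= 3")
             if (any(p < 1) || any(p > object@nres)) return("contact index out of range")
           }
           TRUE
         })

#' Per-chain input bundle
#'
#' Everything the scoring terms may need for one chain: the sequence,
#' optionally its C-alpha trace and optionally its profile data.
#'
#' @slot sequence one-letter sequence (single string).
#' @slot trace a [StructureTrace-class] or NULL.
#' @slot profile a [Profile-class] or NULL.
#' @export
setClass("ChainData",
         representation(sequence = "character", trace = "ANY", profile = "ANY"),
         validity = function(object) {
           if (length(object@sequence) != 1L) return("sequence must be a single string")
           n <- nchar(object@sequence)
           if (!is.null(object@trace)) {
             if (!is(object@trace, "StructureTrace")) return("trace must be a StructureTrace")
             if (nrow(object@trace@coords) != n)
               return("trace length must match sequence length")
           }
           if (!is.null(object@profile)) {
             if (!is(object@profile, "Profile")) return("profile must be a Profile")
             if (nrow(object@profile@freqs) != n)
               return("profile length must match sequence length")
           }
           TRUE
         })

#' Construct a ChainData bundle
#' @param sequence one-letter sequence; taken from `trace` when omitted.
#' @param trace optional [StructureTrace-class].
#' @param profile optional [Profile-class].
#' @return A [ChainData-class].
#' @export
ChainData <- function(sequence = NULL, trace = NULL, profile = NULL) {
  if (is.null(sequence)) {
    if (is.null(trace)) configError("ChainData needs a sequence or a trace")
    sequence <- trace@sequence
  }
  if (length(sequence) > 1L) sequence <- paste(sequence, collapse = "")
  new("ChainData", sequence = sequence, trace = trace, profile = profile)
}

#' A query/template alignment problem
#'
#' Bundles the query and template [ChainData-class] plus the template
#' contact map used by contact-based terms. When the template has a trace
#' and no map is given, a default C-alpha map (8 Angstrom, |i-j| >= 3) is
#' built automatically.
#'
#' @slot query,template [ChainData-class] bundles.
#' @slot contactMap a [ContactMap-class] or NULL.
#' @export
setClass("ThreadingProblem",
         representation(query = "ChainData", template = "ChainData",
                        contactMap = "ANY"))

#' Construct a ThreadingProblem
#' @param query,template [ChainData-class] bundles (or [StructureTrace-class]
#'   objects, which are wrapped).
#' @param contactMap optional [ContactMap-class] for the template.
#' @return A [ThreadingProblem-class].
#' @export
ThreadingProblem <- function(query, template, contactMap = NULL) {
  if (is(query, "StructureTrace")) query <- ChainData(trace = query)
  if (is(template, "StructureTrace")) template <- ChainData(trace = template)
  if (is.null(contactMap) && !is.null(template@trace))
    contactMap <- buildContactMap(template@trace)
  new("ThreadingProblem", query = query, template = template,
      contactMap = contactMap)
}

# ------------------------------------------------------------- scoring terms

#' Scoring-term class hierarchy
#'
#' All energy terms derive from the virtual class `ScoringTerm`. A
#' `ByAtomTerm` decomposes into a sum over aligned columns, so a move's
#' energy change can be evaluated over the affected columns only; a
#' `BigMatrixTerm` (a ByAtomTerm) can additionally be precomputed into a
#' query-length x template-length matrix at startup. `StructureBasedTerm`s
#' need the query coordinates and are re-evaluated in full at every move;
#' `ContactBasedTerm`s depend on the template contact map and are pairwise
#' decomposable but not precomputable.
#'
#' @slot name display label of the term.
#' @name ScoringTerm-class
#' @aliases ByAtomTerm-class BigMatrixTerm-class StructureBasedTerm-class
#'   ContactBasedTerm-class
#' @export
setClass("ScoringTerm", representation("VIRTUAL", name = "character"))

#' @export
setClass("ByAtomTerm", contains = "ScoringTerm", representation("VIRTUAL"))

#' @export
setClass("BigMatrixTerm", contains = "ByAtomTerm", representation("VIRTUAL"))

#' @export
setClass("StructureBasedTerm", contains = "ScoringTerm", representation("VIRTUAL"))

#' @export
setClass("ContactBasedTerm", contains = "ScoringTerm", representation("VIRTUAL"))

setClass("SubstitutionScore", contains = "BigMatrixTerm",
         representation(matrixName = "character", matrix = "matrix"))

setClass("MatrixScore", contains = "BigMatrixTerm",
         representation(matrix = "matrix"))

setClass("ProfileScore", contains = "BigMatrixTerm")

setClass("SecondaryScore", contains = "BigMatrixTerm")

setClass("EnvScore", contains = "BigMatrixTerm")

setClass("AsaScore", contains = "BigMatrixTerm")

setClass("GravyScore", contains = "BigMatrixTerm")

setClass("AffineGapTerm", contains = "ScoringTerm",
         representation(open = "numeric", extend = "numeric",
                        terminalFree = "logical"))

setClass("StructuralGapPenalty", contains = "ContactBasedTerm",
         representation(penalty = "numeric"))

setClass("GoLikeScore", contains = "ContactBasedTerm",
         representation(cutoff = "numeric"))

setClass("TwoBodyContact", contains = "ContactBasedTerm",
         representation(table = "matrix"))

setClass("TMScoreTerm", contains = "StructureBasedTerm",
         representation(thorough = "logical"))

setClass("RMSDTerm", contains = "StructureBasedTerm")

setClass("DaliTerm", contains = "StructureBasedTerm")

#' Weighted combination of scoring terms
#'
#' The force field: an ordered list of [ScoringTerm-class] objects with one
#' weight each. The total energy of an alignment is the weighted sum of the
#' term energies; similarity-type terms report negated values so the
#' sampler always minimizes.
#'
#' @slot terms list of [ScoringTerm-class] objects.
#' @slot weights numeric vector, one weight per term.
#' @export
setClass("ForceField",
         representation(terms = "list", weights = "numeric"),
         validity = function(object) {
           if (length(object@terms) != length(object@weights))
             return("one weight per term required")
           if (!all(vapply(object@terms, is, logical(1), "ScoringTerm")))
             return("terms must be ScoringTerm objects")
           TRUE
         })

#' Construct a ForceField
#' @param terms list of [ScoringTerm-class] objects.
#' @param weights numeric vector of weights (one per term).
#' @return A [ForceField-class].
#' @export
ForceField <- function(terms, weights) {
  names(weights) <- vapply(terms, function(t) t@name, character(1))
  new("ForceField", terms = terms, weights = as.numeric(weights))
}

# ------------------------------------------------------------- sampling types

#' Sampler configuration
#'
#' @slot temperatures strictly increasing positive dimensionless
#'   temperatures. The default ladder has the ten replica temperatures
#'   0.08, 0.1, 0.15, 0.2, 0.5, 1.0, 2.0, 5.0, 7.0, 10.0. In annealing mode
#'   the same set is visited from the hottest down.
#' @slot innerSteps proposals per replica per exchange cycle; NA means the
#'   default 200 x query length, resolved at run time.
#' @slot cycles number of exchange cycles.
#' @slot seed integer RNG seed.
#' @slot mode "replica_exchange" or "annealing".
#' @slot sampleEvery thin interval for the per-replica energy samples used
#'   to build histograms (0 disables sampling).
#' @slot maxRecords observer memory bound: number of distinct records kept.
#' @slot stopAfterStable stop when the best energy has been unchanged for
#'   this many consecutive cycles (0 = run all cycles).
#' @export
setClass("SamplerConfig",
         representation(temperatures = "numeric", innerSteps = "integer",
                        cycles = "integer", seed = "integer",
                        mode = "character", sampleEvery = "integer",
                        maxRecords = "integer", stopAfterStable = "integer"),
         validity = function(object) {
           tt <- object@temperatures
           if (length(tt) < 1 || any(tt <= 0)) return("temperatures must be positive")
           if (any(diff(tt) <= 0)) return("temperatures must be strictly increasing")
           if (!object@mode %in% c("replica_exchange", "annealing"))
             return("mode must be 'replica_exchange' or 'annealing'")
           if (object@mode == "replica_exchange" && length(tt) < 2)
             return("replica exchange needs at least 2 temperatures")
           if (!is.na(object@innerSteps) && object@innerSteps < 1)
             return("innerSteps must be >= 1")
           if (object@cycles < 1) return("cycles must be >= 1")
           TRUE
         })

#' Default replica-temperature ladder
#'
#' Ten dimensionless temperatures spanning 0.08 to 10; energy distributions
#' of neighbouring replicas overlap for a wide range of scoring schemes and
#' protein lengths, enabling a random walk in temperature space.
#'
#' @return numeric vector of length 10.
#' @export
defaultTemperatures <- function() {
  c(0.08, 0.1, 0.15, 0.2, 0.5, 1.0, 2.0, 5.0, 7.0, 10.0)
}

#' Construct a SamplerConfig
#' @param temperatures replica ladder; default [defaultTemperatures()].
#' @param innerSteps proposals per replica per cycle (NA: 200 x query length).
#' @param cycles exchange cycles (default 100).
#' @param seed RNG seed.
#' @param mode "replica_exchange" (default) or "annealing".
#' @param sampleEvery energy-sample thinning interval (default: chosen so
#'   roughly 100 samples per replica per cycle are kept).
#' @param maxRecords observer memory bound (default 1000 distinct records).
#' @param stopAfterStable early-stop patience in cycles (0 = off).
#' @return A [SamplerConfig-class].
#' @export
SamplerConfig <- function(temperatures = defaultTemperatures(),
                          innerSteps = NA_integer_, cycles = 100L,
                          seed = 1L, mode = "replica_exchange",
                          sampleEvery = NA_integer_, maxRecords = 1000L,
                          stopAfterStable = 0L) {
  new("SamplerConfig", temperatures = as.numeric(temperatures),
      innerSteps = as.integer(innerSteps), cycles = as.integer(cycles),
      seed = as.integer(seed), mode = mode,
      sampleEvery = as.integer(sampleEvery),
      maxRecords = as.integer(maxRecords),
      stopAfterStable = as.integer(stopAfterStable))
}

#' A scored, canonicalized alignment kept by the observers
#'
#' @slot alignment canonical [BlockAlignment-class].
#' @slot totalEnergy total force-field energy.
#' @slot perTermEnergies named numeric vector of unweighted term energies
#'   (length 0 when the breakdown was not computed for this record).
#' @slot replicaTemperature temperature at which the record was first seen.
#' @slot cycle exchange cycle at which the record was first seen.
#' @export
setClass("AlignmentRecord",
         representation(alignment = "BlockAlignment", totalEnergy = "numeric",
                        perTermEnergies = "numeric",
                        replicaTemperature = "numeric", cycle = "integer"))

#' Result of a sampling run
#'
#' @slot records list of [AlignmentRecord-class], ranked by energy.
#' @slot bestRecord the best-scoring record.
#' @slot samples list (one per replica) of thinned energy samples.
#' @slot temperatures the ladder used.
#' @slot moverStats data.frame of per-mover attempt/accept/infeasible counts.
#' @slot exchangeStats data.frame of per-neighbour-pair swap statistics.
#' @slot cyclesRun number of cycles actually executed.
#' @slot mode sampler mode.
#' @export
setClass("SamplingResult",
         representation(records = "list", bestRecord = "AlignmentRecord",
                        samples = "list", temperatures = "numeric",
                        moverStats = "data.frame", exchangeStats = "data.frame",
                        cyclesRun = "integer", mode = "character"))

#' A proposed alignment modification
#'
#' What a mover returns: the proposed alignment, the set of query columns
#' whose template partner changed (gained, lost or remapped), and the
#' mover's name. When geometry forbids the move, `feasible` is FALSE and
#' the proposal carries the unmodified alignment.
#'
#' @slot newAlignment proposed [BlockAlignment-class].
#' @slot changedQueryColumns integer vector of affected query residues.
#' @slot moverName label of the mover that produced the proposal.
#' @slot feasible FALSE when no feasible move existed.
#' @export
setClass("MoveProposal",
         representation(newAlignment = "BlockAlignment",
                        changedQueryColumns = "integer",
                        moverName = "character", feasible = "logical"))

#' A weighted set of movers
#'
#' @slot moverNames character vector of mover names.
#' @slot weights nonnegative proposal weights; a mover is selected with
#'   probability weight / sum(weights).
#' @export
setClass("MoverSet",
         representation(moverNames = "character", weights = "numeric"),
         validity = function(object) {
           if (length(object@moverNames) != length(object@weights))
             return("one weight per mover required")
           if (any(object@weights < 0)) return("weights must be nonnegative")
           if (sum(object@weights) <= 0) return("at least one positive weight required")
           if (!all(object@moverNames %in% MOVER_NAMES))
             return(paste("unknown mover; valid names:", paste(MOVER_NAMES, collapse = ", ")))
           TRUE
         })
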