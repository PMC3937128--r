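# Readers and writers for the external formats the engine touches: PDB
# C-alpha traces, FASTA, PSI-BLAST ASCII PSSMs, PSIPRED ss2, two-column
# burial files, PIR (Modeller) alignments and TSV reports.

#' Read a C-alpha trace from a PDB file
#'
#' First model only; one chain (the first, unless `chain` is given);
#' alternate location 'A' or blank preferred; residues without a C-alpha
#' are skipped with a warning; unknown residue names become 'X'.
#'
#' @param path PDB file.
#' @param chain chain identifier, default the file's first chain.
#' @return a [StructureTrace-class].
#' @export
readStructure <- function(path, chain = NULL) {
  if (!file.exists(path)) inputError("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) inputError("failed to parse PDB ", path,
                                                 ": ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain & at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) inputError("chain '", chain, "' not found in ", path)
  keep <- at$alt %in% c("", "A", NA)
  at <- at[keep, , drop = FALSE]
  # residues in file order, insertion codes resolved as encountered
  resKey <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  resKey <- factor(resKey, levels = unique(resKey))
  ca <- at[at$elety == "CA", , drop = FALSE]
  caKey <- paste(ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
  missing <- setdiff(levels(resKey), caKey)
  if (length(missing) > 0)
    warning(length(missing), " residue(s) without a C-alpha skipped in ", path)
  ca <- ca[!duplicated(caKey), , drop = FALSE]
  if (nrow(ca) == 0) inputError("no C-alpha atoms in ", path)
  letters1 <- bio3d::aa321(ca$resid)
  letters1[is.na(letters1) | nchar(letters1) != 1] <- "X"
  StructureTrace(cbind(ca$x, ca$y, ca$z), paste(letters1, collapse = ""))
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) inputError("no such file: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) inputError("failed to parse FASTA ",
                                                 path, ": ", conditionMessage(e)))
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

#' Write sequences to a FASTA file
#' @param sequences named character vector.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' The standard `-out_ascii_pssm` layout: a header, a residue-order line,
#' then one row per position with the position index, the residue, 20
#' log-odds columns and 20 percent-frequency columns. Columns are
#' reordered to the package's canonical residue order.
#'
#' @param path PSSM file.
#' @return a [Profile-class] (frequencies and log-odds only).
#' @export
readPSSM <- function(path) {
  if (!file.exists(path)) inputError("no such file: ", path)
  lines <- readLines(path)
  # the residue-order header is the line of 1-letter codes
  hdrIdx <- which(grepl("^\\s*[A-Z](\\s+[A-Z]){19,}\\s*$", lines))[1]
  if (is.na(hdrIdx)) inputError("no residue header found in PSSM ", path)
  order1 <- strsplit(trimws(lines[hdrIdx]), "\\s+")[[1]]
  aaOrder <- order1[seq_len(20)]
  rows <- list()
  for (l in lines[(hdrIdx + 1):length(lines)]) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 2 || is.na(suppressWarnings(as.integer(f[1])))) next
    rows[[length(rows) + 1]] <- f
  }
  if (length(rows) == 0) inputError("no PSSM rows in ", path)
  nnum <- length(rows[[1]]) - 2L
  if (nnum < 40) inputError("PSSM ", path, " has ", nnum,
                            " numeric columns per row; expected at least 40")
  logOdds <- matrix(NA_real_, length(rows), 20)
  freqs <- matrix(NA_real_, length(rows), 20)
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[i]][-(1:2)]))
    if (anyNA(vals[1:40])) inputError("malformed PSSM row ", i, " in ", path)
    logOdds[i, ] <- vals[1:20]
    freqs[i, ] <- vals[21:40] / 100
  }
  perm <- match(AA_STANDARD, aaOrder)
  if (anyNA(perm)) inputError("unexpected residue order in PSSM ", path)
  # rows of all-zero frequencies occur in sparse PSSMs; fall back to the
  # observed residue when renormalization is impossible
  freqs <- freqs[, perm, drop = FALSE]
  rs <- rowSums(freqs)
  resLetters <- vapply(rows, `[`, character(1), 2)
  for (i in which(rs == 0)) {
    k <- match(resLetters[i], AA_STANDARD)
    if (!is.na(k)) freqs[i, k] <- 1 else freqs[i, ] <- 1 / 20
  }
  rs <- rowSums(freqs)
  Profile(freqs = freqs / rs, logOdds = logOdds[, perm, drop = FALSE])
}

#' Write a profile as a PSI-BLAST-style ASCII PSSM
#'
#' @param profile a [Profile-class].
#' @param sequence the chain's one-letter sequence (one letter per row).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePSSM <- function(profile, sequence, path) {
  letters1 <- strsplit(sequence, "")[[1]]
  n <- nrow(profile@freqs)
  if (length(letters1) != n) inputError("sequence length does not match profile")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed"), con)
  writeLines(paste0("            ", paste(sprintf("%3s", AA_STANDARD), collapse = " "),
                    " ", paste(sprintf("%3s", AA_STANDARD), collapse = " ")), con)
  # real PSI-BLAST output rounds to integers; synthetic profiles are
  # written at 3 decimals so they survive a round trip
  for (i in seq_len(n)) {
    lo <- sprintf("%8.3f", profile@logOdds[i, ])
    fr <- sprintf("%8.3f", 100 * profile@freqs[i, ])
    writeLines(sprintf("%5d %s  %s %s  0.00 0.00", i, letters1[i],
                       paste(lo, collapse = " "), paste(fr, collapse = " ")), con)
  }
  invisible(path)
}

#' Read PSIPRED ss2 secondary-structure probabilities
#'
#' Rows of `index residue state pC pH pE`; probabilities are returned in
#' H/E/C column order and renormalized when their sum is within 0.05 of 1,
#' an error otherwise.
#'
#' @param path ss2 file.
#' @return n x 3 matrix with columns H, E, C.
#' @export
readSS2 <- function(path) {
  if (!file.exists(path)) inputError("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rows <- strsplit(trimws(lines), "\\s+")
  rows <- rows[vapply(rows, function(f)
    length(f) >= 6 && !is.na(suppressWarnings(as.integer(f[1]))), logical(1))]
  if (length(rows) == 0) inputError("no data rows in ss2 file ", path)
  ss <- matrix(NA_real_, length(rows), 3, dimnames = list(NULL, c("H", "E", "C")))
  for (i in seq_along(rows)) {
    p <- suppressWarnings(as.numeric(rows[[i]][4:6]))  # file order: C H E
    if (anyNA(p)) inputError("malformed ss2 row ", i, " in ", path)
    s <- sum(p)
    if (abs(s - 1) > 0.05)
      inputError("ss2 row ", i, " in ", path, " sums to ", signif(s, 3))
    ss[i, ] <- c(p[2], p[3], p[1]) / s
  }
  ss
}

#' Write 3-state probabilities as a PSIPRED-style ss2 file
#' @param ss3 n x 3 matrix with columns H, E, C.
#' @param sequence the chain's one-letter sequence.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSS2 <- function(ss3, sequence, path) {
  letters1 <- strsplit(sequence, "")[[1]]
  if (length(letters1) != nrow(ss3)) inputError("sequence length does not match ss3")
  states <- c("H", "E", "C")[max.col(ss3)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# PSF format file", con)
  writeLines("", con)
  for (i in seq_len(nrow(ss3)))
    writeLines(sprintf("%4d %s %s  %6.3f %6.3f %6.3f", i, letters1[i],
                       states[i], ss3[i, "C"], ss3[i, "H"], ss3[i, "E"]), con)
  invisible(path)
}

#' Read a two-column burial (relative solvent accessibility) file
#'
#' Rows of `index value` with values in \[0, 1\].
#'
#' @param path burial file.
#' @return numeric vector of burial values in position order.
#' @export
readASA <- function(path) {
  if (!file.exists(path)) inputError("no such file: ", path)
  tab <- tryCatch(read.table(path, header = FALSE),
                  error = function(e) inputError("failed to parse ASA file ",
                                                 path, ": ", conditionMessage(e)))
  if (ncol(tab) < 2) inputError("ASA file ", path, " needs two columns")
  v <- tab[[2]][order(tab[[1]])]
  if (any(v < 0 | v > 1)) inputError("burial values outside [0, 1] in ", path)
  as.numeric(v)
}

#' Write a two-column burial file
#' @param burial numeric vector in \[0, 1\].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeASA <- function(burial, path) {
  write.table(data.frame(seq_along(burial), sprintf("%.4f", burial)), path,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# wrap a sequence row at 70 characters
wrap70 <- function(s) {
  starts <- seq(1, nchar(s), by = 70)
  vapply(starts, function(i) substr(s, i, min(i + 69, nchar(s))), character(1))
}

#' Write an alignment in PIR (Modeller) format
#'
#' Two entries: the template as `structureX` with 1-based residue-span
#' fields, the query as `sequence`; gapped rows end with `*`. Unknown
#' header fields are filled with '.' placeholders.
#'
#' @param alignment a [BlockAlignment-class].
#' @param queryId,templateId entry identifiers.
#' @param querySeq,templateSeq one-letter sequences.
#' @param path output file.
#' @param templateChain chain id recorded in the structure entry.
#' @return invisibly, the path.
#' @export
writePIR <- function(alignment, queryId, querySeq, templateId, templateSeq,
                     path, templateChain = "A") {
  rows <- alignmentStrings(alignment, querySeq, templateSeq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(">P1;%s", templateId), con)
  writeLines(sprintf("structureX:%s:1:%s:%d:%s:.:.:.:.", templateId,
                     templateChain, nchar(templateSeq), templateChain), con)
  writeLines(wrap70(paste0(rows[2], "*")), con)
  writeLines(sprintf(">P1;%s", queryId), con)
  writeLines(sprintf("sequence:%s:1:.:%d:.:.:.:.:.", queryId,
                     nchar(querySeq)), con)
  writeLines(wrap70(paste0(rows[1], "*")), con)
  invisible(path)
}

# parse a PIR or gapped-FASTA file into id/row pairs
readGappedRows <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  entries <- list()
  id <- NULL
  seq <- character()
  isPir <- any(grepl("^>P1;", lines))
  expectDesc <- FALSE
  for (l in lines) {
    if (grepl("^>", l)) {
      if (!is.null(id)) entries[[id]] <- paste(seq, collapse = "")
      id <- sub("^>(P1;)?", "", l)
      id <- sub("\\s.*$", "", id)
      seq <- character()
      expectDesc <- isPir
    } else if (expectDesc) {
      expectDesc <- FALSE  # PIR description line, skip
    } else {
      seq <- c(seq, gsub("\\s", "", l))
    }
  }
  if (!is.null(id)) entries[[id]] <- paste(seq, collapse = "")
  lapply(entries, function(s) sub("\\*$", "", s))
}

#' Read a two-row gapped alignment (PIR or gapped FASTA)
#'
#' Converts the gapped rows into a canonical [BlockAlignment-class]; in a
#' PIR file the `structureX` entry is the template, otherwise the second
#' entry is. Enables the score-only mode for user-provided alignments.
#'
#' @param path PIR or aligned-FASTA file with exactly two entries.
#' @param queryLength,templateLength expected chain lengths; checked
#'   against the degapped rows when given.
#' @return list with `alignment` ([BlockAlignment-class]), `queryId`,
#'   `templateId`, `querySeq`, `templateSeq` (degapped).
#' @export
readAlignment <- function(path, queryLength = NULL, templateLength = NULL) {
  if (!file.exists(path)) inputError("no such file: ", path)
  rows <- readGappedRows(path)
  if (length(rows) != 2)
    inputError("alignment file ", path, " must contain exactly 2 entries, found ",
               length(rows))
  lines <- readLines(path)
  tmplFirst <- FALSE
  hdr <- grep("^>", lines)
  if (length(hdr) == 2 && grepl("^structure", lines[hdr[1] + 1]))
    tmplFirst <- TRUE
  qi <- if (tmplFirst) 2L else 1L
  ti <- if (tmplFirst) 1L else 2L
  qRow <- rows[[qi]]
  tRow <- rows[[ti]]
  if (nchar(qRow) != nchar(tRow))
    inputError("gapped rows have unequal length in ", path)
  qChars <- strsplit(qRow, "")[[1]]
  tChars <- strsplit(tRow, "")[[1]]
  qPos <- cumsum(qChars != "-")
  tPos <- cumsum(tChars != "-")
  both <- qChars != "-" & tChars != "-"
  qlen <- max(qPos, 0)
  tlen <- max(tPos, 0)
  if (!is.null(queryLength) && qlen != queryLength)
    inputError("query row in ", path, " has ", qlen, " residues; expected ",
               queryLength)
  if (!is.null(templateLength) && tlen != templateLength)
    inputError("template row in ", path, " has ", tlen, " residues; expected ",
               templateLength)
  pairs <- cbind(qPos[both], tPos[both])
  list(alignment = pairsToAlignment(pairs, qlen, tlen),
       queryId = names(rows)[qi], templateId = names(rows)[ti],
       querySeq = paste(qChars[qChars != "-"], collapse = ""),
       templateSeq = paste(tChars[tChars != "-"], collapse = ""))
}

#' Write a human-readable alignment report
#'
#' Query and template identifiers, per-term and total energies, and the
#' gapped two-row alignment. Energies are printed at 3 decimals.
#'
#' @param alignment a [BlockAlignment-class].
#' @param forceField a [ForceField-class].
#' @param problem a [ThreadingProblem-class].
#' @param path output file ("" prints to the console).
#' @param queryId,templateId identifiers used in the report.
#' @return invisibly, the energy breakdown list.
#' @export
writeAlignmentReport <- function(alignment, forceField, problem, path = "",
                                 queryId = "query", templateId = "template") {
  e <- totalEnergy(forceField, alignment, problem)
  rows <- alignmentStrings(alignment, problem@query@sequence,
                           problem@template@sequence)
  lines <- c(sprintf("# query: %s (%d aa)", queryId, nResidues(problem@query)),
             sprintf("# template: %s (%d aa)", templateId,
                     nResidues(problem@template)),
             sprintf("# aligned pairs: %d", nrow(residuePairs(alignment))),
             sprintf("term\t%s\tweighted", "energy"))
  for (i in seq_along(e$terms))
    lines <- c(lines, sprintf("%s\t%.3f\t%.3f", names(e$terms)[i], e$terms[i],
                              forceField@weights[i] * e$terms[i]))
  lines <- c(lines, sprintf("total\t%.3f\t%.3f", e$total, e$total), "",
             paste0(">", queryId), rows[1], paste0(">", templateId), rows[2])
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(e)
}

#' Write per-replica energy histograms as TSV
#'
#' Columns temperature, bin_center, count -- the data behind
#' replica-overlap diagnostic plots.
#'
#' @param result a [SamplingResult-class] from [runREMC()].
#' @param path output file.
#' @param bins number of bins.
#' @return invisibly, the histogram data.frame.
#' @export
writeHistogramsTSV <- function(result, path, bins = 30L) {
  h <- energyHistograms(result, bins)
  write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("temperature", "bin_center", "count"))
  invisible(h)
}
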