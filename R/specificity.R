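#' Digestion enzyme rule
#'
#' Describes the specificity of the digestion protease(s). The default
#' matches a tandem Lys-C + trypsin digestion: cleavage C-terminal to K or R,
#' no proline restriction (Trypsin/P convention). `ntermWindow` controls how
#' many leading protein positions count as the protein N-terminus; the
#' default of 2 absorbs initiator-methionine excision, so peptides starting
#' at position 1 or 2 are flagged as protein-terminal and excluded from the
#' proteolysis analysis.
#'
#' @param cleaveAfter residues the enzyme cuts after (P1 residues).
#' @param prolineBlock if `TRUE`, cleavage before proline is not enzymatic.
#' @param ntermWindow integer >= 1; start positions `<= ntermWindow` are
#'   protein-terminal.
#'
#' @return list of class `EnzymeRule`.
#' @export
enzymeRule <- function(cleaveAfter = c("K", "R"), prolineBlock = FALSE,
                       ntermWindow = 2L) {
  cleaveAfter <- unique(toupper(cleaveAfter))
  if (!length(cleaveAfter) || !all(cleaveAfter %in% AMINO_ACIDS))
    stop("cleaveAfter must be a non-empty subset of the amino-acid alphabet")
  if (ntermWindow < 1L) stop("ntermWindow must be >= 1")
  structure(list(cleaveAfter = cleaveAfter,
                 prolineBlock = isTRUE(prolineBlock),
                 ntermWindow = as.integer(ntermWindow)),
            class = "EnzymeRule")
}

#' Locate a peptide within a protein sequence
#'
#' @param peptide uppercase peptide sequence.
#' @param proteinSequence uppercase protein sequence.
#' @return integer vector of 1-based start positions of all (possibly
#'   overlapping) exact occurrences, ascending; empty if none.
#' @export
locatePeptide <- function(peptide, proteinSequence) {
  if (!nzchar(peptide)) stop("empty peptide")
  hits <- integer()
  from <- 1L
  repeat {
    i <- regexpr(peptide, substr(proteinSequence, from,
                                 nchar(proteinSequence)), fixed = TRUE)
    if (i == -1L) break
    pos <- from + as.integer(i) - 1L
    hits <- c(hits, pos)
    from <- pos + 1L
  }
  hits
}

#' Classify one peptide terminus against the enzyme rule
#'
#' N-side: `protein_terminal` when the peptide starts within the rule's
#' N-terminal window; else `enzymatic` when the preceding residue is a
#' cleavage residue (and, with the proline block, the first peptide residue
#' is not P); else `nonenzymatic`. C-side: `protein_terminal` when the
#' peptide ends at the protein C-terminus; else `enzymatic` when the last
#' peptide residue is a cleavage residue (proline check on the following
#' residue); else `nonenzymatic`.
#'
#' @param proteinSequence uppercase protein sequence.
#' @param start,end 1-based inclusive peptide coordinates.
#' @param side `"N"` or `"C"`.
#' @param rule an [enzymeRule()].
#' @return one of `"enzymatic"`, `"nonenzymatic"`, `"protein_terminal"`.
#' @export
classifyTerminus <- function(proteinSequence, start, end, side = c("N", "C"),
                             rule = enzymeRule()) {
  side <- match.arg(side)
  len <- nchar(proteinSequence)
  if (start < 1L || end > len || start > end)
    stop("peptide coordinates out of range: ", start, "..", end,
         " in protein of length ", len)
  if (side == "N") {
    if (start <= rule$ntermWindow) return("protein_terminal")
    prev <- substr(proteinSequence, start - 1L, start - 1L)
    firstres <- substr(proteinSequence, start, start)
    if (prev %in% rule$cleaveAfter &&
        !(rule$prolineBlock && firstres == "P")) return("enzymatic")
    "nonenzymatic"
  } else {
    if (end == len) return("protein_terminal")
    lastres <- substr(proteinSequence, end, end)
    nxt <- substr(proteinSequence, end + 1L, end + 1L)
    if (lastres %in% rule$cleaveAfter &&
        !(rule$prolineBlock && nxt == "P")) return("enzymatic")
    "nonenzymatic"
  }
}

# class from the two terminus statuses; protein_terminal counts as specific
# for the label (such peptides are flagged terminal_excluded and dropped
# downstream, so the label is informational only)
.specClass <- function(nstat, cstat) {
  n_non <- nstat == "nonenzymatic"
  c_non <- cstat == "nonenzymatic"
  if (!n_non && !c_non) "full"
  else if (n_non && !c_non) "semi_N"
  else if (!n_non && c_non) "semi_C"
  else "nonspecific"
}

.specRank <- c(full = 3L, semi_N = 2L, semi_C = 2L, nonspecific = 1L)

#' Classify a peptide's enzymatic specificity within one protein
#'
#' All occurrences of the peptide in the protein are classified; the
#' most-specific occurrence wins (full > semi > nonspecific; ties broken by
#' smallest start), which avoids over-calling endogenous proteolysis for
#' repeated sequences.
#'
#' @param peptide uppercase stripped peptide sequence.
#' @param proteinSequence uppercase protein sequence.
#' @param accession accession reported in the annotation.
#' @param rule an [enzymeRule()].
#'
#' @return one-row `data.frame`: `peptide`, `accession`, `start`, `end`,
#'   `nterm_status`, `cterm_status`, `spec_class`, `terminal_excluded`.
#' @export
classifyPeptide <- function(peptide, proteinSequence, accession = NA_character_,
                            rule = enzymeRule()) {
  starts <- locatePeptide(peptide, proteinSequence)
  if (!length(starts))
    stop("peptide '", peptide, "' does not occur in protein ", accession)
  best <- NULL
  for (s in starts) {
    e <- s + nchar(peptide) - 1L
    nst <- classifyTerminus(proteinSequence, s, e, "N", rule)
    cst <- classifyTerminus(proteinSequence, s, e, "C", rule)
    cand <- list(start = s, end = e, nstat = nst, cstat = cst,
                 class = .specClass(nst, cst))
    if (is.null(best) || .specRank[[cand$class]] > .specRank[[best$class]])
      best <- cand
  }
  data.frame(peptide = peptide, accession = accession,
             start = best$start, end = best$end,
             nterm_status = best$nstat, cterm_status = best$cstat,
             spec_class = best$class,
             terminal_excluded = best$nstat == "protein_terminal" |
               best$cstat == "protein_terminal",
             stringsAsFactors = FALSE)
}

#' Classify a full peptide table against a protein database
#'
#' @param peptides `data.frame` with columns `stripped_sequence`,
#'   `protein_group` (`;`-separated accessions) and `proteotypic`
#'   (e.g. `$peptides` of [readPeptideTable()]), one row per peptide.
#' @param proteins protein `data.frame` from [readFasta()].
#' @param rule an [enzymeRule()].
#' @param multimapPolicy `"most_specific"` keeps, for a multi-mapped peptide,
#'   the most specific classification across its mapped proteins (a peptide
#'   is full if it is full against any of them); `"proteotypic_only"` drops
#'   non-proteotypic peptides entirely.
#'
#' @return `data.frame` with one annotation row per retained peptide (same
#'   columns as [classifyPeptide()]); peptides whose accession cannot be
#'   resolved in the database, or that do not occur in any mapped protein,
#'   are dropped with a counted warning. Attribute `"dropped"` carries the
#'   counts (`unresolved`, `not_found`, `nonproteotypic`).
#' @export
classifyPeptides <- function(peptides, proteins, rule = enzymeRule(),
                             multimapPolicy = c("most_specific",
                                                "proteotypic_only")) {
  multimapPolicy <- match.arg(multimapPolicy)
  dropped <- c(unresolved = 0L, not_found = 0L, nonproteotypic = 0L)
  keep <- rep(TRUE, nrow(peptides))
  if (multimapPolicy == "proteotypic_only") {
    keep <- as.logical(peptides$proteotypic)
    dropped["nonproteotypic"] <- sum(!keep)
  }
  pep <- peptides[keep, , drop = FALSE]
  idx_list <- lapply(strsplit(pep$protein_group, ";", fixed = TRUE),
                     function(a) {
                       i <- match(a, proteins$accession)
                       as.integer(i[!is.na(i)])
                     })
  resolvable <- lengths(idx_list) > 0L
  dropped["unresolved"] <- sum(!resolvable)
  pep <- pep[resolvable, , drop = FALSE]
  idx_list <- idx_list[resolvable]
  cb <- classify_batch(pep$stripped_sequence, idx_list, proteins$sequence,
                       paste(rule$cleaveAfter, collapse = ""),
                       rule$prolineBlock, rule$ntermWindow)
  found <- cb$found
  dropped["not_found"] <- sum(!found)
  status_lab <- c("enzymatic", "nonenzymatic", "protein_terminal")
  class_lab <- c("full", "semi_N", "semi_C", "nonspecific")
  res <- data.frame(
    peptide = pep$stripped_sequence[found],
    accession = proteins$accession[cb$protein[found]],
    start = cb$start[found], end = cb$end[found],
    nterm_status = status_lab[cb$nstat[found] + 1L],
    cterm_status = status_lab[cb$cstat[found] + 1L],
    spec_class = class_lab[cb$class[found] + 1L],
    terminal_excluded = cb$excluded[found],
    stringsAsFactors = FALSE, row.names = NULL)
  if (sum(dropped[c("unresolved", "not_found")]) > 0L)
    warning(sum(dropped[c("unresolved", "not_found")]),
            " peptide(s) dropped (unmappable to the protein database)")
  attr(res, "dropped") <- dropped
  res
}

#' Extract cleavage events from semi-specific peptide annotations
#'
#' Every nonenzymatic terminus of a semi-specific (non-terminal) peptide
#' witnesses one endogenous cleavage. The event records the 1-based index of
#' the P1 residue (cleavage between `position` and `position + 1`) and the
#' P4..P4' residue window (8 residues, `X`-padded beyond the protein ends;
#' window position 5 is P1', the first residue after the scissile bond).
#'
#' @param annotations annotation `data.frame` from [classifyPeptides()].
#' @param proteins protein `data.frame` from [readFasta()].
#' @return `data.frame`: `peptide`, `accession`, `position`, `side`
#'   (`peptide_N` / `peptide_C`), `window`.
#' @export
extractCleavageEvents <- function(annotations, proteins) {
  seqs <- setNames(proteins$sequence, proteins$accession)
  sel <- annotations$spec_class %in% c("semi_N", "semi_C") &
    !annotations$terminal_excluded
  ann <- annotations[sel, , drop = FALSE]
  if (!nrow(ann))
    return(data.frame(peptide = character(), accession = character(),
                      position = integer(), side = character(),
                      window = character()))
  p1 <- ifelse(ann$spec_class == "semi_N", ann$start - 1L, ann$end)
  side <- ifelse(ann$spec_class == "semi_N", "peptide_N", "peptide_C")
  window <- vapply(seq_len(nrow(ann)), function(i) {
    .cleavageWindow(seqs[[ann$accession[i]]], p1[i])
  }, "")
  data.frame(peptide = ann$peptide, accession = ann$accession,
             position = p1, side = side, window = window,
             stringsAsFactors = FALSE)
}

# P4..P4' window around the bond after `p1`, 'X' beyond the protein ends
.cleavageWindow <- function(sequence, p1) {
  len <- nchar(sequence)
  pos <- (p1 - 3L):(p1 + 4L)
  res <- vapply(pos, function(p) {
    if (p < 1L || p > len) "X" else substr(sequence, p, p)
  }, "")
  paste(res, collapse = "")
}
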