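#' Read a protein database in FASTA format
#'
#' Accepts UniProt-style headers (`>sp|ACC|NAME description`) as well as bare
#' accession headers (`>ACC description`). Sequences are uppercased.
#'
#' @param path path to a FASTA file.
#'
#' @return `data.frame` with columns `accession`, `gene`, `sequence`. The gene
#'   symbol is taken from a `GN=` field when present, otherwise from the
#'   entry name (`ACC_NAME` dialect keeps the part before `_`), otherwise it
#'   equals the accession.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA: ", path)
  headers <- names(aa)
  seqs <- toupper(as.character(aa))
  first <- vapply(strsplit(headers, "[ \t]"), `[`, "", 1L)
  parts <- strsplit(first, "|", fixed = TRUE)
  acc <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) == 1L) return(p)
    if (length(p) >= 3L && nzchar(p[2L])) return(p[2L])
    stop("malformed FASTA header at record ", i, ": '", headers[i], "'")
  }, "")
  gene <- vapply(seq_along(headers), function(i) {
    gn <- regmatches(headers[i], regexpr("GN=[^ \t]+", headers[i]))
    if (length(gn)) return(sub("^GN=", "", gn))
    p <- parts[[i]]
    if (length(p) >= 3L) return(sub("_.*$", "", p[3L]))
    acc[i]
  }, "")
  if (any(!nzchar(seqs))) {
    stop("empty sequence for accession(s): ",
         paste(acc[!nzchar(seqs)], collapse = ", "))
  }
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  bad <- grepl("[^A-Z]", seqs)
  if (any(bad)) stop("invalid characters in sequence of: ",
                     paste(acc[bad], collapse = ", "))
  data.frame(accession = acc, gene = gene, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write a protein table to FASTA
#'
#' @param proteins `data.frame` with `accession`, `gene`, `sequence`.
#' @param path output path.
#' @export
writeFasta <- function(proteins, path) {
  hdr <- sprintf("sp|%s|%s_SYN GN=%s",
                 proteins$accession, proteins$gene, proteins$gene)
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read a peptide-level quantification table
#'
#' Parses a DIA-NN-report-like TSV. In the wide layout the required columns
#' are `protein_group`, `gene`, `stripped_sequence`, `proteotypic` and one
#' numeric column per sample. In the long layout the required columns are
#' those four plus `sample_id` and `intensity`. Empty cells and zero
#' intensities are treated as missing (DIA-NN convention, avoids log2(0));
#' multi-accession protein groups are `;`-separated.
#'
#' @param path path to a TSV file.
#' @param layout `"wide"` or `"long"`.
#'
#' @return list of class `PeptideTable` with elements
#'   `peptides` (`data.frame`: `stripped_sequence`, `protein_group`, `gene`,
#'   `proteotypic`) and `intensities` (numeric matrix, peptides x samples,
#'   raw linear scale, `NA` = missing). Row order follows the file.
#' @export
readPeptideTable <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  meta_cols <- c("protein_group", "gene", "stripped_sequence", "proteotypic")
  need <- if (layout == "wide") meta_cols else
    c(meta_cols, "sample_id", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("peptide table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  parse_int <- function(x) {
    x[!nzchar(trimws(x))] <- NA
    v <- suppressWarnings(as.numeric(x))
    if (any(!is.na(x) & is.na(v)))
      stop("non-numeric intensity value(s): ",
           paste(unique(x[!is.na(x) & is.na(v)]), collapse = ", "))
    if (any(v < 0, na.rm = TRUE)) stop("negative intensity values found")
    v[!is.na(v) & v == 0] <- NA
    v
  }
  if (layout == "wide") {
    sample_cols <- setdiff(names(df), meta_cols)
    if (!length(sample_cols)) stop("wide table has no sample columns")
    intens <- vapply(sample_cols, function(s) parse_int(df[[s]]),
                     numeric(nrow(df)))
    intens <- matrix(intens, nrow = nrow(df),
                     dimnames = list(NULL, sample_cols))
    pep <- df[meta_cols]
  } else {
    df$intensity <- parse_int(df$intensity)
    key <- paste(df$stripped_sequence, df$protein_group, sep = "\r")
    ukey <- unique(key)
    samples <- unique(df$sample_id)
    intens <- matrix(NA_real_, nrow = length(ukey), ncol = length(samples),
                     dimnames = list(NULL, samples))
    intens[cbind(match(key, ukey), match(df$sample_id, samples))] <-
      df$intensity
    pep <- df[!duplicated(key), c(meta_cols), drop = FALSE]
  }
  pep$proteotypic <- pep$proteotypic %in% c("1", "TRUE", "true", "T")
  n_acc <- lengths(strsplit(pep$protein_group, ";", fixed = TRUE))
  bad <- pep$proteotypic & n_acc > 1L
  if (any(bad))
    stop("proteotypic peptide(s) mapped to multiple accessions: ",
         paste(head(pep$stripped_sequence[bad]), collapse = ", "))
  if (any(n_acc < 1L) || any(!nzchar(pep$protein_group)))
    stop("peptide with no mapped accession")
  rownames(pep) <- NULL
  structure(list(peptides = pep, intensities = intens),
            class = "PeptideTable")
}

#' Read sample metadata
#'
#' Expected TSV columns: `sample_id`, `patient_id`, `compartment`
#' (NAT / PC / TUMOR), `tumor_diameter` (millimetres; may be empty for NAT),
#' `grade` (G1 / G2 / G3 / unknown) and `lesion_index` (integer >= 1; 1 =
#' primary, larger = metachronous lesion).
#'
#' @param path path to a TSV file.
#' @return validated `data.frame`.
#' @export
readMetadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "compartment", "tumor_diameter",
            "grade", "lesion_index")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("metadata lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(df$compartment), COMPARTMENTS)
  if (length(bad))
    stop("unknown compartment value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(COMPARTMENTS, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$tumor_diameter <- suppressWarnings(as.numeric(df$tumor_diameter))
  if (any(df$tumor_diameter <= 0, na.rm = TRUE))
    stop("tumor_diameter must be positive")
  df$lesion_index <- as.integer(df$lesion_index)
  if (any(is.na(df$lesion_index)) || any(df$lesion_index < 1L))
    stop("lesion_index must be an integer >= 1")
  df$grade[!df$grade %in% c("G1", "G2", "G3")] <- "unknown"
  df
}

#' Fill pseudocapsule tumor diameters from the matched tumor lesion
#'
#' A PC specimen is dissected from the capsule of a particular tumor lesion;
#' its `tumor_diameter` is inherited from the TUMOR row of the same
#' (`patient_id`, `lesion_index`) pair when absent.
#'
#' @param metadata metadata `data.frame` as from [readMetadata()].
#' @return metadata with PC diameters filled where a matched lesion exists.
#' @export
fillDiameters <- function(metadata) {
  tum <- metadata[metadata$compartment == "TUMOR", ]
  key <- paste(metadata$patient_id, metadata$lesion_index)
  tkey <- paste(tum$patient_id, tum$lesion_index)
  idx <- metadata$compartment == "PC" & is.na(metadata$tumor_diameter)
  metadata$tumor_diameter[idx] <- tum$tumor_diameter[match(key[idx], tkey)]
  metadata
}

#' Read gene sets from a GMT file
#'
#' Each line is `set_id<TAB>name<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to a GMT file.
#' @return named list of unique, non-empty character vectors (names are set
#'   ids); each element carries the set description as attribute `"name"`.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: '", l, "'")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("empty gene set: ", f[1L])
    structure(members, name = f[2L])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "", USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate gene set id in GMT")
  sets
}

#' Write a result table as TSV
#'
#' All writers in the package emit tab-separated text with a header row, `.`
#' decimal separator and empty string for missing values, so that write/read
#' round-trips are value-stable.
#'
#' @param x `data.frame` or matrix.
#' @param path output path.
#' @export
writeTable <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Write / read a QuantMatrix as TSV
#'
#' The on-disk layout is `feature_id` plus one column per sample; missing
#' cells are empty strings; values are printed with 15 significant digits so
#' the round trip is bit-stable at double precision.
#'
#' @param x a [QuantMatrix-class].
#' @param path file path.
#' @export
writeQuantMatrix <- function(x, path) {
  v <- quantValues(x)
  df <- data.frame(feature_id = rownames(v), stringsAsFactors = FALSE)
  for (s in colnames(v)) {
    col <- formatC(v[, s], digits = 15, format = "g")
    col[is.na(v[, s])] <- ""
    df[[s]] <- col
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeQuantMatrix
#' @param level quantification level of the stored matrix.
#' @param sampleData optional sample metadata to attach (see [QuantMatrix()]).
#' @export
readQuantMatrix <- function(path, level = c("protein", "peptide"),
                            sampleData = NULL) {
  level <- match.arg(level)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "feature_id") stop("not a QuantMatrix TSV: ", path)
  m <- as.matrix(df[-1L])
  storage.mode(m) <- "double"
  rownames(m) <- df$feature_id
  QuantMatrix(m, level = level, sampleData = sampleData)
}
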