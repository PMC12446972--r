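#' MaxLFQ-style roll-up of peptide intensities to protein abundances
#'
#' Protein abundances are computed exclusively from proteotypic peptides in
#' the Cox/Mann MaxLFQ formulation: for each protein group and each pair of
#' samples sharing at least `minShared` peptides, the median pairwise log2
#' peptide ratio is taken; per-sample protein values then minimise the sum of
#' squared deviations from those pairwise ratios (a Laplacian least-squares
#' system, solved per connected component in compiled code). Each component
#' is anchored so that the mean protein value over its samples equals the
#' mean of the per-sample mean observed peptide intensity, which makes the
#' roll-up exactly shift-equivariant per sample. Samples without any peptide
#' evidence stay missing.
#'
#' @param peptideTable a `PeptideTable` (see [readPeptideTable()]) with raw
#'   linear intensities.
#' @param sampleData optional sample metadata `data.frame` attached to the
#'   result.
#' @param minShared minimum number of shared peptides for a sample pair to
#'   contribute a ratio.
#' @param proteotypicOnly if `TRUE` (default, as in the originating
#'   workflow) only proteotypic peptides are used.
#'
#' @return protein-level [QuantMatrix-class] (log2 scale); rownames are
#'   protein group ids, `rowData` carries the gene symbol. Protein groups
#'   with zero usable peptides are dropped with a warning.
#' @export
rollupMaxLFQ <- function(peptideTable, sampleData = NULL, minShared = 1L,
                         proteotypicOnly = TRUE) {
  pep <- peptideTable$peptides
  intens <- peptideTable$intensities
  use <- if (proteotypicOnly) as.logical(pep$proteotypic) else
    rep(TRUE, nrow(pep))
  groups <- unique(pep$protein_group)
  keep_rows <- split(which(use), pep$protein_group[use])
  dropped <- setdiff(groups, names(keep_rows))
  if (length(dropped))
    warning(length(dropped),
            " protein group(s) without proteotypic peptides dropped")
  logm <- log2(intens)
  prof <- lapply(keep_rows, function(rows) {
    maxlfq_solve(logm[rows, , drop = FALSE], as.integer(minShared))
  })
  m <- if (length(prof)) do.call(rbind, prof) else
    matrix(numeric(0), 0L, ncol(intens))
  dimnames(m) <- list(as.character(names(keep_rows)), colnames(intens))
  gene <- pep$gene[match(rownames(m), pep$protein_group)]
  QuantMatrix(m, level = "protein", sampleData = sampleData,
              rowData = data.frame(gene = gene))
}

#' Two-tier completeness filtering
#'
#' `"core"` keeps proteins detected in at least `coreThreshold` (default
#' 70%) of the samples of *each* compartment — the stringent dataset.
#' `"extended"` keeps proteins detected in at least `extendedThreshold`
#' (default 50%) of the samples of *at least one* compartment, accommodating
#' compartment-restricted expression. Core survivors are always a subset of
#' extended survivors at the default thresholds.
#'
#' @param x protein-level [QuantMatrix-class] whose `colData` carries
#'   `compartment`.
#' @param mode `"core"` or `"extended"`.
#' @param coreThreshold,extendedThreshold presence fractions in (0, 1].
#' @return filtered [QuantMatrix-class], feature order preserved.
#' @export
completenessFilter <- function(x, mode = c("core", "extended"),
                               coreThreshold = 0.70,
                               extendedThreshold = 0.50) {
  mode <- match.arg(mode)
  if (coreThreshold <= 0 || coreThreshold > 1 ||
      extendedThreshold <= 0 || extendedThreshold > 1)
    stop("thresholds must be in (0, 1]")
  comp <- .compartments(x)
  if (any(table(comp) == 0L)) stop("compartment with zero samples")
  frac <- completenessByCompartment(x)
  keep <- if (mode == "core") {
    apply(frac >= coreThreshold, 1L, all)
  } else {
    apply(frac >= extendedThreshold, 1L, any)
  }
  x[keep, ]
}

#' Per-compartment presence fractions
#'
#' @param x a [QuantMatrix-class] with a `compartment` column in `colData`.
#' @return numeric matrix features x compartments of presence fractions.
#' @export
completenessByCompartment <- function(x) {
  comp <- .compartments(x)
  v <- quantValues(x)
  vapply(levels(comp), function(cp) {
    rowMeans(!is.na(v[, comp == cp, drop = FALSE]))
  }, numeric(nrow(v)))
}

#' Left-censored (MNAR) imputation
#'
#' Missing cells are drawn from a down-shifted Gaussian per sample
#' (MinProb/Perseus-style): `Normal(mu_s - shift * sd_s, (width * sd_s)^2)`
#' where `mu_s` and `sd_s` are the observed mean and standard deviation of
#' that sample. This encodes the missing-not-at-random assumption that
#' undetected proteins sit below the detection limit. Deterministic given
#' `seed`; present values are never altered.
#'
#' @param x a log2 [QuantMatrix-class]; every sample needs >= 3 present
#'   values.
#' @param seed integer seed for the imputation draws.
#' @param shift down-shift in units of the sample standard deviation.
#' @param width width of the imputation distribution in sd units.
#' @return complete [QuantMatrix-class] (no missing cells).
#' @export
imputeMNAR <- function(x, seed = 1L, shift = 1.8, width = 0.3) {
  v <- quantValues(x)
  n_present <- colSums(!is.na(v))
  if (any(n_present == 0L))
    stop("sample(s) entirely missing: ",
         paste(colnames(v)[n_present == 0L], collapse = ", "))
  if (any(n_present < 3L))
    stop("sample(s) with < 3 present values: ",
         paste(colnames(v)[n_present < 3L], collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (!any(miss)) next
    mu <- mean(v[!miss, j])
    s <- sd(v[!miss, j])
    v[miss, j] <- rnorm(sum(miss), mean = mu - shift * s, sd = width * s)
  }
  quantValues(x) <- v
  x
}

# save/restore the RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Median centering across samples
#'
#' Shifts each sample so its median over present values equals the global
#' median of those per-sample medians; compensates residual depth
#' differences after roll-up.
#'
#' @param x a log2 [QuantMatrix-class].
#' @return normalized [QuantMatrix-class].
#' @export
normalizeMedian <- function(x) {
  v <- quantValues(x)
  med <- apply(v, 2L, median, na.rm = TRUE)
  target <- median(med)
  quantValues(x) <- sweep(v, 2L, med - target, "-")
  x
}
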