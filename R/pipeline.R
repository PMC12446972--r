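#' Run the full compartment analysis on a synthetic cohort
#'
#' End-to-end orchestration used by the examples and the reproduction
#' script: simulate a cohort, classify peptide specificity, compute
#' per-sample proteolysis fractions with compartment tests, roll fully
#' tryptic proteotypic peptides up to protein abundances, median-centre,
#' apply the two-tier completeness filters, impute the extended matrix,
#' run the differential contrasts and PC-unique signature, the tumor-size
#' screen, trend clustering, marker correlations, the peptide/protein
#' fold-change concordance, and cleavage-motif enrichment of the
#' tumor-upregulated semi-tryptic peptides.
#'
#' @param config a [simConfig()].
#' @param seed integer seed driving every stochastic step.
#' @param outDir optional directory; when given, the main result tables are
#'   written there as TSV.
#' @return list with the intermediate objects (`cohort`, `annotations`,
#'   `fractions`, `fractionTests`, `proteinCore`, `proteinExtended`,
#'   `imputed`, `da` (list of contrasts), `signature`, `sizeCorr`,
#'   `trends`, `markerCorr`, `concordance`, `motif`) and a `summary`
#'   data.frame of headline numbers.
#' @export
runPipeline <- function(config = simConfig(), seed = 1L, outDir = NULL) {
  cohort <- simulateCohort(config, seed = seed)
  pt <- cohort$peptideTable
  ann <- classifyPeptides(pt$peptides, cohort$proteins)

  fractions <- semiFractionPerSample(ann, pt)
  fractionTests <- groupCompareFractions(fractions, cohort$metadata)

  # protein quantification from fully tryptic, non-terminal peptides
  idx <- match(pt$peptides$stripped_sequence, ann$peptide)
  fully <- !is.na(idx) & ann$spec_class[idx] == "full" &
    !ann$terminal_excluded[idx]
  protein <- rollupMaxLFQ(subsetPeptides(pt, fully),
                          sampleData = cohort$metadata)
  protein <- normalizeMedian(protein)
  core <- completenessFilter(protein, "core")
  extended <- completenessFilter(protein, "extended")
  imputed <- imputeMNAR(extended, seed = seed + 1L)

  da <- list(
    PC_vs_NAT = moderatedTTest(imputed, "PC", "NAT"),
    PC_vs_TUMOR = moderatedTTest(imputed, "PC", "TUMOR"),
    TUMOR_vs_NAT = moderatedTTest(imputed, "TUMOR", "NAT"))
  signature <- pcUniqueSignature(da$PC_vs_NAT, da$PC_vs_TUMOR)

  pc_q <- imputed[, sampleInfo(imputed)$compartment == "PC"]
  sizeCorr <- sizeCorrelation(pc_q, sampleInfo(pc_q)$tumor_diameter)
  trends <- trendClusters(imputed)
  markerCorr <- markerCorrelation(imputed, "PCNA",
                                  paste0("MCM", 2:7))

  # peptide-level DA (tumor vs NAT) on fully tryptic peptides for the
  # concordance read-out and on semi peptides for the motif analysis
  pep_qm <- .peptideQuantMatrix(pt, cohort$metadata)
  pep_imp <- imputeMNAR(.presenceFilter(pep_qm, 0.5), seed = seed + 2L)
  pep_da <- moderatedTTest(pep_imp, "TUMOR", "NAT")
  keep_pep <- pep_da$feature_id[pep_da$feature_id %in%
                                  pt$peptides$stripped_sequence[fully]]
  mapping <- data.frame(
    peptide_id = keep_pep,
    protein_id = pt$peptides$protein_group[
      match(keep_pep, pt$peptides$stripped_sequence)])
  mapping <- mapping[mapping$protein_id %in% da$TUMOR_vs_NAT$feature_id, ]
  concordance <- peptideProteinConcordance(pep_da, da$TUMOR_vs_NAT, mapping)

  semi_idx <- !is.na(idx) & ann$spec_class[idx] %in% c("semi_N", "semi_C") &
    !ann$terminal_excluded[idx]
  semi_seqs <- pt$peptides$stripped_sequence[semi_idx]
  up_semi <- pep_da$feature_id[pep_da$significant &
                                 pep_da$log2fc >= log2(1.5) &
                                 pep_da$feature_id %in% semi_seqs]
  motif <- NULL
  if (length(up_semi)) {
    ev <- extractCleavageEvents(ann[ann$peptide %in% up_semi, ],
                                cohort$proteins)
    if (nrow(ev)) motif <- motifEnrichment(ev, cohort$proteins)
  }

  comp_mean <- tapply(fractions$fraction_intensity,
                      cohort$metadata$compartment[
                        match(fractions$sample_id,
                              cohort$metadata$sample_id)], mean,
                      na.rm = TRUE)
  summary <- data.frame(
    quantity = c("n_peptides", "n_semi_peptides", "n_proteins_quantified",
                 "n_proteins_core", "n_proteins_extended",
                 "semi_intensity_fraction_NAT", "semi_intensity_fraction_PC",
                 "semi_intensity_fraction_TUMOR",
                 "pc_unique_up", "pc_unique_down",
                 "size_corr_positive", "size_corr_negative",
                 "trend_increasing", "trend_decreasing",
                 "peptide_protein_concordance_r"),
    value = c(nrow(pt$peptides), sum(semi_idx), nrow(protein),
              nrow(core), nrow(extended),
              comp_mean[["NAT"]], comp_mean[["PC"]], comp_mean[["TUMOR"]],
              length(signature$up), length(signature$down),
              sum(sizeCorr$direction == "positive"),
              sum(sizeCorr$direction == "negative"),
              sum(trends$cluster == "increasing"),
              sum(trends$cluster == "decreasing"),
              concordance$r))

  res <- list(cohort = cohort, annotations = ann, fractions = fractions,
              fractionTests = fractionTests, protein = protein,
              proteinCore = core, proteinExtended = extended,
              imputed = imputed, da = da, signature = signature,
              sizeCorr = sizeCorr, trends = trends,
              markerCorr = markerCorr, concordance = concordance,
              motif = motif, summary = summary)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeTable(fractions, file.path(outDir, "semi_fractions.tsv"))
    writeTable(fractionTests$pairwise,
               file.path(outDir, "fraction_tests.tsv"))
    writeQuantMatrix(protein, file.path(outDir, "protein_matrix.tsv"))
    for (nm in names(da))
      writeTable(da[[nm]], file.path(outDir, paste0("da_", nm, ".tsv")))
    writeTable(sizeCorr, file.path(outDir, "size_correlation.tsv"))
    writeTable(trends, file.path(outDir, "trend_clusters.tsv"))
    writeTable(summary, file.path(outDir, "summary.tsv"))
  }
  res
}

# peptide-level log2 QuantMatrix keyed by stripped sequence (first row wins
# for duplicated sequences)
.peptideQuantMatrix <- function(peptideTable, metadata) {
  keep <- !duplicated(peptideTable$peptides$stripped_sequence)
  m <- log2(peptideTable$intensities[keep, , drop = FALSE])
  rownames(m) <- peptideTable$peptides$stripped_sequence[keep]
  QuantMatrix(m, level = "peptide", sampleData = metadata,
              rowData = data.frame(
                gene = peptideTable$peptides$gene[keep]))
}

# keep features present in at least `frac` of all samples
.presenceFilter <- function(x, frac) {
  v <- quantValues(x)
  x[rowMeans(!is.na(v)) >= frac, ]
}
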