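#' Configuration of the synthetic three-compartment cohort
#'
#' Defines the study conditions emulated by [simulateCohort()]: a
#' patient-matched cohort of 34 patients contributing 54 tumor, 45
#' pseudocapsule and 31 normal-adjacent samples (metachronous tumor lesions
#' allowed), a random proteome digested in silico under tryptic constraints
#' (7-30 residues, one missed cleavage), compartment-dependent endogenous
#' proteolysis expressed as the share of total peptide intensity carried by
#' semi-tryptic peptides, planted compartment and tumor-size abundance
#' effects, patient random effects, and intensity-dependent (MNAR) plus
#' completely-random (MCAR) missingness.
#'
#' @param n_patients number of patients.
#' @param n_nat,n_pc,n_tumor samples per compartment.
#' @param n_metachronous_patients patients with metachronous tumor lesions.
#' @param n_proteins proteome size.
#' @param protein_length_range sequence length range (residues).
#' @param kr_frequency combined K+R residue frequency of the proteome.
#' @param peptide_length_range retained peptide length range.
#' @param max_missed maximum missed cleavages.
#' @param semi_shares named vector NAT/PC/TUMOR of the expected fraction of
#'   total (full + semi) peptide intensity carried by semi-tryptic peptides.
#' @param p1prime_weights named sampling weights for the residue in P1'
#'   position of endogenous cleavage events; residues not named get weight
#'   1. The default 8:1 preference for leucine mimics a protease with a
#'   strong P1' bias.
#' @param n_cleavage_events endogenous cleavage events across the proteome.
#' @param cleavage_hot_genes,cleavage_hot_share genes concentrating
#'   endogenous cleavage and the share of events assigned to them
#'   (emulating proteolysis focused on a few scaffold proteins).
#' @param effect_log2 planted compartment effect on log2 protein abundance.
#'   The default `log2(1.5) * 1.33` targets an observed protein-level fold
#'   change near 1.5 after imputation-driven attenuation.
#' @param size_r_target target Pearson correlation between PC abundance and
#'   tumor diameter for the size-slope gene panels.
#' @param marker_r target within-tumor correlation of the proliferation
#'   anchor (PCNA) with its replication panel (MCM2-7).
#' @param base_mean,base_sd log2 protein base abundance distribution.
#' @param peptide_offset_sd per-peptide response (flyability) sd, log2.
#' @param patient_sd patient random-effect sd per protein, log2.
#' @param noise_sd per-measurement Gaussian noise sd, log2.
#' @param mnar_midpoint,mnar_steepness logistic detection model: a cell of
#'   log2 value x is lost with probability
#'   `plogis((mnar_midpoint - x) / mnar_steepness)`.
#' @param mcar_rate additional independent missingness rate.
#' @param diameter_range tumor diameter range (mm), sampled log-uniformly.
#'
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(n_patients = 34L, n_nat = 31L, n_pc = 45L,
                      n_tumor = 54L, n_metachronous_patients = 12L,
                      n_proteins = 300L,
                      protein_length_range = c(150L, 1000L),
                      kr_frequency = 0.11,
                      peptide_length_range = c(7L, 30L),
                      max_missed = 1L,
                      semi_shares = c(NAT = 0.10, PC = 0.15, TUMOR = 0.25),
                      p1prime_weights = c(L = 8),
                      n_cleavage_events = 800L,
                      cleavage_hot_genes = c("COL1A1", "COL6A1"),
                      cleavage_hot_share = 0.75,
                      effect_log2 = log2(1.5) * 1.33,
                      size_r_target = 0.6,
                      marker_r = 0.6,
                      base_mean = 20, base_sd = 2,
                      peptide_offset_sd = 1.0,
                      patient_sd = 0.4,
                      noise_sd = 0.3,
                      mnar_midpoint = 17, mnar_steepness = 1.0,
                      mcar_rate = 0.02,
                      diameter_range = c(10, 90)) {
  stopifnot(n_tumor >= n_patients, n_pc <= n_tumor, n_nat <= n_patients,
            all(semi_shares >= 0 & semi_shares <= 1),
            identical(sort(names(semi_shares)), sort(COMPARTMENTS)),
            cleavage_hot_share >= 0, cleavage_hot_share <= 1,
            mcar_rate >= 0, mcar_rate <= 1, mnar_steepness > 0,
            n_proteins >= length(.panelGenes()$all))
  w <- setNames(rep(1, 20L), AMINO_ACIDS)
  w[names(p1prime_weights)] <- p1prime_weights
  structure(list(
    n_patients = as.integer(n_patients), n_nat = as.integer(n_nat),
    n_pc = as.integer(n_pc), n_tumor = as.integer(n_tumor),
    n_metachronous_patients = as.integer(n_metachronous_patients),
    n_proteins = as.integer(n_proteins),
    protein_length_range = protein_length_range,
    kr_frequency = kr_frequency,
    peptide_length_range = peptide_length_range,
    max_missed = as.integer(max_missed),
    semi_shares = semi_shares[COMPARTMENTS],
    p1prime_weights = w,
    n_cleavage_events = as.integer(n_cleavage_events),
    cleavage_hot_genes = cleavage_hot_genes,
    cleavage_hot_share = cleavage_hot_share,
    effect_log2 = effect_log2,
    size_r_target = size_r_target,
    marker_r = marker_r,
    base_mean = base_mean, base_sd = base_sd,
    peptide_offset_sd = peptide_offset_sd,
    patient_sd = patient_sd, noise_sd = noise_sd,
    mnar_midpoint = mnar_midpoint, mnar_steepness = mnar_steepness,
    mcar_rate = mcar_rate, diameter_range = diameter_range),
    class = "SimConfig")
}

# planted effect panels; gene symbols follow field conventions so that
# matrisome annotation and enrichment fixtures work on simulated data
.panelGenes <- function() {
  pc_up <- c("COL1A1", "COL1A2", "COL3A1", "COL6A1", "COL6A2", "COL6A3",
             "COL14A1", "FN1", "ELN", "FBN1", "POSTN", "LAMA4", "LAMB1",
             "TNC", "BGN", "DCN", "LUM", "ASPN", "LTBP1", "TIMP1", "MMP7",
             "MMP14", "HTRA1", "LOXL1", "TGFB2", "CCN2", "PDGFRB", "S100A4",
             "CD248", "SDC2")
  tumor_up <- c("HK1", "HK2", "PKM", "PFKP", "PFKM", "ALDOA", "ENO1",
                "ENO2", "GAPDH", "PGK1", "PGAM1", "LDHA", "SLC2A1", "TPI1",
                "GPI", "VEGFA", "CA9", "ANGPT2", "PFKL", "EGLN3")
  tumor_down <- c("NDUFS1", "NDUFS2", "NDUFV1", "NDUFA9", "SDHA", "SDHB",
                  "UQCRC1", "UQCRC2", "CYC1", "COX4I1", "COX5A", "COX6B1",
                  "ATP5F1A", "ATP5F1B", "ATP5PB", "ATP5MC1", "IDH3A", "FH",
                  "MDH2", "CS")
  size_pos <- c("C1QA", "C1QB", "C1QC", "C3", "C5", "C4B", "CFB", "CFH",
                "CD14", "CD163", "CASP1", "PYCARD", "ITGAX", "ELANE", "MPO",
                "GZMA", "GZMK", "PRF1", "CD4", "CD8A", "LYZ", "CTSS",
                "FCGR3A", "AIF1", "TLR2")
  size_neg <- c("ACO2", "IDH2", "SUCLA2", "SUCLG1", "OGDH", "DLD", "DLST",
                "PDHA1", "PDHB", "ETFA", "ETFB", "HADHA", "HADHB", "ACAT1",
                "CPT1A", "CPT2", "ACADM", "ACADVL", "ECHS1", "NDUFB8",
                "COX7A2", "UQCRB", "ATP5PD", "MDH1", "SDHC")
  marker <- c("PCNA", "MCM2", "MCM3", "MCM4", "MCM5", "MCM6", "MCM7")
  list(pc_up = pc_up, tumor_up = tumor_up, tumor_down = tumor_down,
       size_pos = size_pos, size_neg = size_neg, marker = marker,
       all = c(pc_up, tumor_up, tumor_down, size_pos, size_neg, marker))
}

#' Generate a random proteome
#'
#' Random amino-acid sequences with the configured K+R frequency (so that
#' tryptic peptides in the retained length range are plentiful); panel genes
#' are named with conventional symbols, the remainder generically. Genes
#' hosting concentrated endogenous cleavage are given long sequences so they
#' can carry many cleavage events.
#'
#' @param config a [simConfig()].
#' @return `data.frame`: `accession`, `gene`, `sequence`. Uses the current
#'   RNG state (seed via [set.seed()] or [simulateCohort()]).
#' @export
makeProteome <- function(config = simConfig()) {
  panels <- .panelGenes()
  n <- config$n_proteins
  genes <- c(panels$all,
             sprintf("GENE%04d", seq_len(max(0L, n - length(panels$all)))))
  genes <- genes[seq_len(n)]
  probs <- setNames(rep((1 - config$kr_frequency) / 18, 20L), AMINO_ACIDS)
  probs[c("K", "R")] <- config$kr_frequency / 2
  lens <- round(runif(n, config$protein_length_range[1L],
                      config$protein_length_range[2L]))
  hot <- genes %in% config$cleavage_hot_genes
  lens[hot] <- pmax(lens[hot], config$protein_length_range[2L] - 100L)
  seqs <- vapply(lens, function(L)
    paste(sample(AMINO_ACIDS, L, replace = TRUE, prob = probs),
          collapse = ""), "")
  data.frame(accession = sprintf("SP%04d", seq_len(n)), gene = genes,
             sequence = seqs, stringsAsFactors = FALSE)
}

#' In-silico tryptic digestion of one protein
#'
#' Enumerates all peptides whose termini are enzymatic or protein-terminal,
#' with at most `maxMissed` internal cleavage sites, within the retained
#' length range; duplicated sequences within the protein are removed.
#'
#' @param sequence uppercase protein sequence.
#' @param rule an [enzymeRule()].
#' @param maxMissed maximum missed cleavages.
#' @param lengthRange retained peptide length range.
#' @return `data.frame`: `peptide`, `start`, `end`, `missed`.
#' @export
digestProtein <- function(sequence, rule = enzymeRule(), maxMissed = 1L,
                          lengthRange = c(7L, 30L)) {
  L <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1L]]
  sites <- which(chars %in% rule$cleaveAfter)
  if (rule$prolineBlock)
    sites <- sites[sites == L | chars[pmin(sites + 1L, L)] != "P"]
  cuts <- sites[sites < L]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, L)
  nfrag <- length(starts)
  rows <- list()
  for (m in 0:maxMissed) {
    if (nfrag - m < 1L) break
    i <- seq_len(nfrag - m)
    s <- starts[i]; e <- ends[i + m]
    len <- e - s + 1L
    ok <- len >= lengthRange[1L] & len <= lengthRange[2L]
    if (any(ok))
      rows[[m + 1L]] <- data.frame(
        peptide = substring(sequence, s[ok], e[ok]),
        start = s[ok], end = e[ok], missed = m, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(), start = integer(), end = integer(),
               missed = integer())
  out <- out[!duplicated(out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all eligible semi-tryptic truncation products of one protein:
# an endogenous cut inside a tryptic fragment [a, b] at bond (p1, p1 + 1)
# yields semi_C [a, p1] or semi_N [p1 + 1, b]; the enzymatic terminus must
# not be protein-terminal and the product must be within the length range
.semiCandidates <- function(sequence, digest, rule = enzymeRule(),
                            lengthRange = c(7L, 30L)) {
  raw <- .semiCandidatesRaw(sequence, digest, rule, lengthRange)
  out <- data.frame(peptide = raw$peptide, start = raw$start,
                    end = raw$end, side = raw$side, p1 = raw$p1,
                    p1prime = raw$p1prime, stringsAsFactors = FALSE)
  out[!duplicated(out$peptide), , drop = FALSE]
}

# vector-based candidate enumeration (not deduplicated)
.semiCandidatesRaw <- function(sequence, digest, rule = enzymeRule(),
                               lengthRange = c(7L, 30L)) {
  empty <- list(peptide = character(), start = integer(), end = integer(),
                side = character(), p1 = integer(), p1prime = character())
  if (!nrow(digest)) return(empty)
  L <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1L]]
  reps <- digest$end - digest$start
  if (sum(reps) == 0L) return(empty)
  a <- rep(digest$start, reps)
  b <- rep(digest$end, reps)
  p1 <- unlist(lapply(reps, seq_len), use.names = FALSE) + a - 1L
  keep <- !(chars[p1] %in% rule$cleaveAfter)
  a <- a[keep]; b <- b[keep]; p1 <- p1[keep]
  lenC <- p1 - a + 1L
  okC <- lenC >= lengthRange[1L] & lenC <= lengthRange[2L] &
    a > rule$ntermWindow
  lenN <- b - p1
  okN <- lenN >= lengthRange[1L] & lenN <= lengthRange[2L] & b < L
  p1all <- c(p1[okC], p1[okN])
  list(peptide = c(substring(sequence, a[okC], p1[okC]),
                   substring(sequence, p1[okN] + 1L, b[okN])),
       start = c(a[okC], p1[okN] + 1L),
       end = c(p1[okC], b[okN]),
       side = rep(c("semi_C", "semi_N"), c(sum(okC), sum(okN))),
       p1 = p1all,
       p1prime = chars[p1all + 1L])
}

#' Sample endogenous cleavage products for one protein
#'
#' Draws `nEvents` distinct semi-tryptic truncation products from the
#' eligible internal cleavage positions of the protein, with sampling
#' weights proportional to the P1' residue preference of the (virtual)
#' endogenous protease.
#'
#' @param sequence uppercase protein sequence.
#' @param digest tryptic digest of the protein ([digestProtein()]).
#' @param nEvents number of cleavage events to draw.
#' @param p1primeWeights named numeric vector of P1' residue weights.
#' @param rule an [enzymeRule()].
#' @param lengthRange retained peptide length range.
#' @return `data.frame`: `peptide`, `start`, `end`, `side` (`semi_N` /
#'   `semi_C`), `p1`, `p1prime`; fewer rows than `nEvents` when the protein
#'   has fewer eligible products (with a warning when it has none).
#' @export
applyEndogenousCleavage <- function(sequence, digest, nEvents,
                                    p1primeWeights,
                                    rule = enzymeRule(),
                                    lengthRange = c(7L, 30L)) {
  cand <- .semiCandidates(sequence, digest, rule, lengthRange)
  if (!nrow(cand)) {
    if (nEvents > 0L) warning("no eligible cleavage site; protein skipped")
    return(cand)
  }
  w <- unname(p1primeWeights[cand$p1prime])
  w[is.na(w)] <- 1
  take <- min(nEvents, sum(w > 0))
  if (take == 0L) {
    if (nEvents > 0L) warning("no eligible cleavage site; protein skipped")
    return(cand[0, , drop = FALSE])
  }
  idx <- sample.int(nrow(cand), take, prob = w)
  out <- cand[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply intensity-dependent and random missingness
#'
#' Each cell of a linear-scale intensity matrix is deleted with probability
#' `plogis((midpoint - log2(x)) / steepness)` (detection limit model: low
#' intensities preferentially lost) plus an independent MCAR rate.
#'
#' @param x numeric matrix, linear intensities.
#' @param config a [simConfig()] (uses `mnar_midpoint`, `mnar_steepness`,
#'   `mcar_rate`).
#' @return matrix with deleted cells set to `NA`.
#' @export
applyMissingness <- function(x, config = simConfig()) {
  p_mnar <- plogis((config$mnar_midpoint - log2(x)) / config$mnar_steepness)
  p <- p_mnar + config$mcar_rate - p_mnar * config$mcar_rate
  x[runif(length(x)) < p] <- NA
  x
}

#' Simulate a complete synthetic cohort
#'
#' Generates a proteome, its in-silico tryptic digest, endogenous
#' semi-tryptic cleavage products with the configured compartment intensity
#' shares, a patient-matched sample sheet, and the peptide quantification
#' table with planted abundance effects and missingness. Fully deterministic
#' given `(config, seed)`.
#'
#' Construction of the peptide intensities (all on log2 scale before
#' exponentiation): protein base abundance + planted compartment effect
#' (PC-up / tumor-up / tumor-down panels) + tumor-size slope (PC samples of
#' the size panels, centred diameter) + shared proliferation factor (marker
#' panel, tumor samples) + patient random effect + per-peptide offset +
#' measurement noise. Semi-tryptic peptides are then scaled per compartment
#' so that their expected share of total (full + semi, terminal-excluded
#' removed) linear intensity equals `semi_shares`.
#'
#' @param config a [simConfig()].
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `SyntheticCohort`: `proteins` (data.frame),
#'   `peptideTable` (`PeptideTable`: metadata + linear intensity matrix with
#'   missingness), `metadata` (sample sheet), `truth` (planted ground truth
#'   for tests), `config`.
#' @export
simulateCohort <- function(config = simConfig(), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  panels <- .panelGenes()
  metadata <- .simMetadata(config)
  proteins <- makeProteome(config)
  rule <- enzymeRule()

  digests <- lapply(proteins$sequence, digestProtein, rule = rule,
                    maxMissed = config$max_missed,
                    lengthRange = config$peptide_length_range)

  full <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i) {
    d <- digests[[i]]
    if (!nrow(d)) return(NULL)
    data.frame(accession = proteins$accession[i], gene = proteins$gene[i],
               peptide = d$peptide, start = d$start, end = d$end,
               protein_length = nchar(proteins$sequence[i]),
               stringsAsFactors = FALSE)
  }))
  # collapse identical sequences across proteins into one protein group;
  # duplicated sequences are rare, so they get a slow path only
  full$terminal <- full$start <= rule$ntermWindow |
    full$end == full$protein_length
  dup_seqs <- unique(full$peptide[duplicated(full$peptide)])
  single <- !full$peptide %in% dup_seqs
  full_tab <- data.frame(
    stripped_sequence = full$peptide[single],
    protein_group = full$accession[single],
    gene = full$gene[single],
    proteotypic = TRUE,
    parent = full$accession[single],
    terminal = full$terminal[single],
    is_semi = FALSE, stringsAsFactors = FALSE, row.names = NULL)
  if (length(dup_seqs)) {
    dups <- full[!single, , drop = FALSE]
    grp <- split(seq_len(nrow(dups)), dups$peptide)
    dup_tab <- data.frame(
      stripped_sequence = names(grp),
      protein_group = vapply(grp, function(ii)
        paste(sort(unique(dups$accession[ii])), collapse = ";"), ""),
      gene = vapply(grp, function(ii)
        paste(sort(unique(dups$gene[ii])), collapse = ";"), ""),
      proteotypic = vapply(grp, function(ii)
        length(unique(dups$accession[ii])) == 1L, TRUE),
      parent = vapply(grp, function(ii) dups$accession[ii[1L]], ""),
      terminal = vapply(grp, function(ii) any(dups$terminal[ii]), TRUE),
      is_semi = FALSE, stringsAsFactors = FALSE, row.names = NULL)
    full_tab <- rbind(full_tab, dup_tab)
  }

  semi_tab <- .simSemiPeptides(proteins, digests, full_tab$stripped_sequence,
                               config, rule)
  pep <- rbind(full_tab, semi_tab)

  sim <- .simIntensities(pep, proteins, metadata, config, panels)
  observed <- applyMissingness(sim$linear, config)

  peptideTable <- structure(list(
    peptides = pep[c("stripped_sequence", "protein_group", "gene",
                     "proteotypic")],
    intensities = observed), class = "PeptideTable")
  rownames(peptideTable$peptides) <- NULL

  truth <- list(
    panels = panels, semi_shares = config$semi_shares,
    semi_scale = sim$semi_scale, effect_log2 = config$effect_log2,
    size_slope = sim$size_slope, is_semi = pep$is_semi,
    parent = pep$parent, terminal = pep$terminal,
    protein_log2 = sim$protein_log2,
    n_semi = sum(pep$is_semi), n_full = sum(!pep$is_semi),
    cleavage_hot_genes = config$cleavage_hot_genes,
    cleavage_hot_share = config$cleavage_hot_share)

  structure(list(proteins = proteins, peptideTable = peptideTable,
                 metadata = metadata, truth = truth, config = config),
            class = "SyntheticCohort")
}

# patient-matched sample sheet
.simMetadata <- function(config) {
  patients <- sprintf("Pt%02d", seq_len(config$n_patients))
  n_extra <- config$n_tumor - config$n_patients
  met <- sample(patients, config$n_metachronous_patients)
  extra <- rep(met, length.out = max(n_extra, 0L))  # round-robin extras
  lesions <- data.frame(patient_id = c(patients, extra),
                        stringsAsFactors = FALSE)
  lesions <- lesions[order(lesions$patient_id), , drop = FALSE]
  lesions$lesion_index <- unlist(lapply(
    split(seq_len(nrow(lesions)), lesions$patient_id), seq_along),
    use.names = FALSE)
  lr <- log2(config$diameter_range)
  lesions$diameter <- round(2^runif(nrow(lesions), lr[1L], lr[2L]), 1)
  lesions$grade <- sample(c("G1", "G2", "G3"), nrow(lesions),
                          replace = TRUE, prob = c(11, 40, 3))
  tum <- data.frame(
    sample_id = sprintf("TUM_%s_L%d", lesions$patient_id,
                        lesions$lesion_index),
    patient_id = lesions$patient_id, compartment = "TUMOR",
    tumor_diameter = lesions$diameter, grade = lesions$grade,
    lesion_index = lesions$lesion_index, stringsAsFactors = FALSE)
  pc_rows <- sort(sample.int(nrow(lesions), config$n_pc))
  pc <- data.frame(
    sample_id = sprintf("PC_%s_L%d", lesions$patient_id[pc_rows],
                        lesions$lesion_index[pc_rows]),
    patient_id = lesions$patient_id[pc_rows], compartment = "PC",
    tumor_diameter = lesions$diameter[pc_rows],
    grade = lesions$grade[pc_rows],
    lesion_index = lesions$lesion_index[pc_rows], stringsAsFactors = FALSE)
  nat_pat <- sort(sample(patients, config$n_nat))
  nat <- data.frame(
    sample_id = sprintf("NAT_%s", nat_pat), patient_id = nat_pat,
    compartment = "NAT", tumor_diameter = NA_real_, grade = "unknown",
    lesion_index = 1L, stringsAsFactors = FALSE)
  out <- rbind(nat, pc, tum)
  rownames(out) <- NULL
  out
}

# sample endogenous cleavage products across the proteome, concentrating
# the configured share of events on the designated hot genes
.simSemiPeptides <- function(proteins, digests, full_seqs, config, rule) {
  cands <- lapply(seq_len(nrow(proteins)), function(i) {
    cc <- .semiCandidatesRaw(proteins$sequence[i], digests[[i]], rule,
                             config$peptide_length_range)
    cc$accession <- rep(proteins$accession[i], length(cc$peptide))
    cc
  })
  cand <- data.frame(
    peptide = unlist(lapply(cands, `[[`, "peptide"), use.names = FALSE),
    p1prime = unlist(lapply(cands, `[[`, "p1prime"), use.names = FALSE),
    accession = unlist(lapply(cands, `[[`, "accession"), use.names = FALSE),
    stringsAsFactors = FALSE)
  cand <- cand[!cand$peptide %in% full_seqs, , drop = FALSE]
  cand <- cand[!duplicated(cand$peptide), , drop = FALSE]
  gene <- proteins$gene[match(cand$accession, proteins$accession)]
  hot <- gene %in% config$cleavage_hot_genes
  w <- unname(config$p1prime_weights[cand$p1prime])
  n_hot <- round(config$n_cleavage_events * config$cleavage_hot_share)
  n_other <- config$n_cleavage_events - n_hot
  wsample <- function(pool, size, prob) {
    if (!length(pool) || size < 1L) return(integer())
    pool[sample.int(length(pool), min(size, length(pool)), prob = prob)]
  }
  pick <- c(wsample(which(hot), n_hot, w[hot]),
            wsample(which(!hot), n_other, w[!hot]))
  sel <- cand[pick, , drop = FALSE]
  # keep only products that classify as semi-tryptic against their protein
  cb <- classify_batch(sel$peptide,
                       as.list(match(sel$accession, proteins$accession)),
                       proteins$sequence,
                       paste(rule$cleaveAfter, collapse = ""),
                       rule$prolineBlock, rule$ntermWindow)
  ok <- cb$found & cb$class %in% c(1L, 2L) & !cb$excluded
  sel <- sel[ok, , drop = FALSE]
  # drop products that also occur in another protein (keeps them proteotypic)
  big <- paste(proteins$sequence, collapse = "#")
  n_occ <- vapply(sel$peptide, function(pp)
    length(gregexpr(pp, big, fixed = TRUE)[[1L]]), 1L)
  sel <- sel[n_occ == 1L, , drop = FALSE]
  data.frame(
    stripped_sequence = sel$peptide, protein_group = sel$accession,
    gene = proteins$gene[match(sel$accession, proteins$accession)],
    proteotypic = TRUE, parent = sel$accession, terminal = FALSE,
    is_semi = TRUE, stringsAsFactors = FALSE, row.names = NULL)
}

# build the linear peptide intensity matrix with planted effects and the
# per-compartment semi-intensity calibration
.simIntensities <- function(pep, proteins, metadata, config, panels) {
  n_prot <- nrow(proteins)
  samples <- metadata$sample_id
  comp <- metadata$compartment
  n_samp <- length(samples)
  base <- rnorm(n_prot, config$base_mean, config$base_sd)
  P <- matrix(base, n_prot, n_samp,
              dimnames = list(proteins$accession, samples))
  g <- proteins$gene
  e <- config$effect_log2
  P[g %in% panels$pc_up, comp == "PC"] <-
    P[g %in% panels$pc_up, comp == "PC"] + e
  P[g %in% panels$tumor_up, comp == "TUMOR"] <-
    P[g %in% panels$tumor_up, comp == "TUMOR"] + e
  P[g %in% panels$tumor_down, comp == "TUMOR"] <-
    P[g %in% panels$tumor_down, comp == "TUMOR"] - e
  # tumor-size slope in PC, calibrated for the target Pearson r at the
  # approximate protein-level residual sd
  sigma <- sqrt(config$patient_sd^2 + config$noise_sd^2)
  pc_cols <- which(comp == "PC")
  d_pc <- metadata$tumor_diameter[pc_cols]
  d_ctr <- d_pc - mean(d_pc)
  slope <- config$size_r_target / sqrt(1 - config$size_r_target^2) *
    sigma / sd(d_pc)
  P[g %in% panels$size_pos, pc_cols] <-
    P[g %in% panels$size_pos, pc_cols] +
    matrix(slope * d_ctr, sum(g %in% panels$size_pos), length(pc_cols),
           byrow = TRUE)
  P[g %in% panels$size_neg, pc_cols] <-
    P[g %in% panels$size_neg, pc_cols] -
    matrix(slope * d_ctr, sum(g %in% panels$size_neg), length(pc_cols),
           byrow = TRUE)
  # shared proliferation factor couples the marker panel within the tumor
  tum_cols <- which(comp == "TUMOR")
  lambda <- sqrt(config$marker_r / (1 - config$marker_r)) * sigma
  fac <- rnorm(length(tum_cols))
  P[g %in% panels$marker, tum_cols] <-
    P[g %in% panels$marker, tum_cols] +
    matrix(lambda * fac, sum(g %in% panels$marker), length(tum_cols),
           byrow = TRUE)
  # patient random effect, shared across a patient's samples
  pat <- unique(metadata$patient_id)
  RE <- matrix(rnorm(n_prot * length(pat), 0, config$patient_sd),
               n_prot, length(pat))
  P <- P + RE[, match(metadata$patient_id, pat)]

  prow <- match(pep$parent, proteins$accession)
  offset <- rnorm(nrow(pep), 0, config$peptide_offset_sd)
  M0 <- P[prow, , drop = FALSE] + offset
  L0 <- 2^M0
  # calibrate the per-compartment semi intensity share on the pre-noise
  # expectation, excluding terminal-excluded full peptides (the fraction
  # read-out excludes them too)
  semi_scale <- setNames(numeric(3L), COMPARTMENTS)
  for (cp in COMPARTMENTS) {
    sc <- comp == cp
    Fc <- sum(L0[!pep$is_semi & !pep$terminal, sc])
    Sc <- sum(L0[pep$is_semi, sc])
    s <- config$semi_shares[[cp]]
    semi_scale[cp] <- s / (1 - s) * Fc / Sc
    L0[pep$is_semi, sc] <- L0[pep$is_semi, sc] * semi_scale[cp]
  }
  noise <- matrix(rnorm(length(L0), 0, config$noise_sd), nrow(L0))
  lin <- L0 * 2^noise
  dimnames(lin) <- list(NULL, samples)
  list(linear = lin, semi_scale = semi_scale, protein_log2 = P,
       size_slope = slope)
}

#' Subset a PeptideTable by row
#'
#' @param peptideTable a `PeptideTable`.
#' @param idx logical or integer row index.
#' @return subsetted `PeptideTable`.
#' @export
subsetPeptides <- function(peptideTable, idx) {
  structure(list(
    peptides = peptideTable$peptides[idx, , drop = FALSE],
    intensities = peptideTable$intensities[idx, , drop = FALSE]),
    class = "PeptideTable")
}

#' Write a synthetic cohort to disk
#'
#' Emits `cohort.fasta`, `peptides.tsv` (wide layout), `metadata.tsv` and
#' `truth.tsv` (planted panel membership, for tests only).
#'
#' @param cohort a `SyntheticCohort` from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeFasta(cohort$proteins, file.path(dir, "cohort.fasta"))
  pt <- cohort$peptideTable
  wide <- cbind(pt$peptides[c("protein_group", "gene", "stripped_sequence",
                              "proteotypic")],
                as.data.frame(pt$intensities))
  wide$proteotypic <- as.integer(wide$proteotypic)
  writeTable(wide, file.path(dir, "peptides.tsv"))
  writeTable(cohort$metadata, file.path(dir, "metadata.tsv"))
  panels <- cohort$truth$panels
  truth <- do.call(rbind, lapply(
    setdiff(names(panels), "all"), function(nm)
      data.frame(panel = nm, gene = panels[[nm]], stringsAsFactors = FALSE)))
  writeTable(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
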