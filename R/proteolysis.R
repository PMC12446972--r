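#' Per-sample fraction of semi-specific peptides
#'
#' The proteolysis read-out of the pipeline: for each sample, the number of
#' fully tryptic and semi-tryptic peptides with a measured intensity, the
#' count fraction semi / (semi + full), and the intensity fraction (sum of
#' raw linear intensities of semi peptides over the sum for full + semi).
#' Terminal-excluded peptides are removed from numerator and denominator;
#' nonspecific peptides (both termini nonenzymatic) are counted in neither.
#'
#' @param annotations annotation `data.frame` from [classifyPeptides()].
#' @param peptideTable a `PeptideTable` (see [readPeptideTable()]) with raw
#'   linear intensities.
#' @return `data.frame`: `sample_id`, `n_full`, `n_semi`, `fraction_count`,
#'   `fraction_intensity`. Samples with zero classified peptides get `NA`
#'   fractions with a warning.
#' @export
semiFractionPerSample <- function(annotations, peptideTable) {
  idx <- match(annotations$peptide, peptideTable$peptides$stripped_sequence)
  if (anyNA(idx))
    stop("annotation peptide(s) absent from the peptide table")
  keep <- !annotations$terminal_excluded &
    annotations$spec_class %in% c("full", "semi_N", "semi_C")
  idx <- idx[keep]
  is_semi <- annotations$spec_class[keep] != "full"
  intens <- peptideTable$intensities[idx, , drop = FALSE]
  samples <- colnames(intens)
  res <- lapply(samples, function(s) {
    x <- intens[, s]
    present <- !is.na(x)
    n_full <- sum(present & !is_semi)
    n_semi <- sum(present & is_semi)
    if (n_full + n_semi == 0L) {
      warning("sample ", s, " has zero classified peptides; fractions NA")
      return(data.frame(sample_id = s, n_full = 0L, n_semi = 0L,
                        fraction_count = NA_real_,
                        fraction_intensity = NA_real_))
    }
    data.frame(sample_id = s, n_full = n_full, n_semi = n_semi,
               fraction_count = n_semi / (n_semi + n_full),
               fraction_intensity = sum(x[present & is_semi]) /
                 sum(x[present]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare a per-sample statistic across compartments
#'
#' Emits both a rank-based and a parametric analysis, as is conventional for
#' per-sample proteolysis fractions: a Kruskal-Wallis omnibus with Dunn's
#' pairwise z tests (BH-adjusted across the pairwise contrasts, with tie
#' correction) and a one-way ANOVA with Tukey HSD pairwise comparisons.
#'
#' @param values `data.frame` with columns `sample_id` and the column named
#'   by `valueCol`.
#' @param metadata sample metadata with `sample_id` and `compartment`.
#' @param valueCol name of the value column (default
#'   `"fraction_intensity"`).
#' @return list with `omnibus` (`data.frame`: method, statistic, p) and
#'   `pairwise` (`data.frame`: contrast, method, estimate, statistic, p,
#'   adj_p). Dunn rows report the z statistic and mean-rank difference;
#'   Tukey rows report the mean difference and Tukey-adjusted p.
#' @export
groupCompareFractions <- function(values, metadata,
                                  valueCol = "fraction_intensity") {
  m <- merge(values, metadata[c("sample_id", "compartment")], by = "sample_id")
  m <- m[!is.na(m[[valueCol]]), ]
  m$group <- factor(m$compartment, levels = COMPARTMENTS)
  m <- m[!is.na(m$group), ]
  sizes <- table(m$group)
  usable <- names(sizes)[sizes >= 2L]
  if (length(usable) < 2L) stop("need >= 2 groups with >= 2 samples each")
  x <- m[[valueCol]]
  g <- m$group
  kw <- kruskal.test(x, g)
  fit <- aov(x ~ g)
  av <- summary(fit)[[1L]]
  omnibus <- data.frame(
    method = c("kruskal_wallis", "anova"),
    statistic = c(unname(kw$statistic), av[1L, "F value"]),
    p = c(kw$p.value, av[1L, "Pr(>F)"]))
  pairs <- utils::combn(COMPARTMENTS, 2L)
  skipped <- apply(pairs, 2L, function(pr) !all(pr %in% usable))
  if (any(skipped))
    warning("contrast(s) skipped (group with < 2 samples): ",
            paste(apply(pairs[, skipped, drop = FALSE], 2L, paste,
                        collapse = "-"), collapse = ", "))
  dunn <- .dunnTest(x, g)
  tk <- TukeyHSD(fit)$g
  tk_names <- rownames(tk)
  pw <- lapply(which(!skipped), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    d <- dunn[dunn$contrast == paste(a, b, sep = "-"), ]
    ti <- match(TRUE, tk_names %in% c(paste(a, b, sep = "-"),
                                      paste(b, a, sep = "-")))
    sign_flip <- if (tk_names[ti] == paste(b, a, sep = "-")) -1 else 1
    rbind(
      data.frame(contrast = paste(a, b, sep = "-"), method = "dunn",
                 estimate = d$mean_rank_diff, statistic = d$z,
                 p = d$p, adj_p = d$adj_p),
      data.frame(contrast = paste(a, b, sep = "-"), method = "tukey",
                 estimate = sign_flip * tk[ti, "diff"], statistic = NA_real_,
                 p = tk[ti, "p adj"], adj_p = tk[ti, "p adj"]))
  })
  pairwise <- do.call(rbind, pw)
  rownames(pairwise) <- NULL
  list(omnibus = omnibus, pairwise = pairwise)
}

# Dunn's post-hoc z tests on ranks with tie correction; BH across contrasts
.dunnTest <- function(x, g) {
  g <- droplevels(g)
  N <- length(x)
  r <- rank(x)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- table(g)
  lv <- levels(g)
  rows <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    a <- lv[i]; b <- lv[j]
    if (n[[a]] < 2L || n[[b]] < 2L) next
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    diff <- rbar[[a]] - rbar[[b]]
    z <- if (se > 0) diff / se else 0
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = paste(a, b, sep = "-"), mean_rank_diff = diff, z = z,
      p = 2 * pnorm(-abs(z)))
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bhAdjust(out$p)
  rownames(out) <- NULL
  out
}

#' Per-sample counts of distinct semi-specific peptides per gene
#'
#' Reproduces the per-protein proteolysis read-out (e.g. counting truncated
#' collagen peptides): for each sample and each requested gene, the number
#' of distinct semi-specific, non-terminal stripped sequences of that gene
#' with a measured intensity in the sample.
#'
#' @inheritParams semiFractionPerSample
#' @param genes character vector of gene symbols to report.
#' @return `data.frame`: `sample_id`, `gene`, `count`.
#' @export
semiCountsPerProtein <- function(annotations, peptideTable, genes) {
  pep <- peptideTable$peptides
  known <- genes %in% pep$gene
  if (any(!known)) {
    warning("unknown gene(s) skipped: ", paste(genes[!known], collapse = ", "))
    genes <- genes[known]
  }
  idx <- match(annotations$peptide, pep$stripped_sequence)
  semi <- annotations$spec_class %in% c("semi_N", "semi_C") &
    !annotations$terminal_excluded
  samples <- colnames(peptideTable$intensities)
  out <- expand.grid(sample_id = samples, gene = genes,
                     stringsAsFactors = FALSE)
  out$count <- 0L
  for (gn in genes) {
    rows <- which(semi & pep$gene[idx] == gn)
    if (!length(rows)) next
    seqs <- annotations$peptide[rows]
    m <- peptideTable$intensities[idx[rows], , drop = FALSE]
    for (s in samples) {
      present <- !is.na(m[, s])
      out$count[out$sample_id == s & out$gene == gn] <-
        length(unique(seqs[present]))
    }
  }
  out
}

#' Share of semi-specific peptides per protein family
#'
#' @inheritParams semiFractionPerSample
#' @param proteins protein `data.frame` from [readFasta()] (maps accession to
#'   gene).
#' @param familyMap named character vector, gene -> family name; genes not in
#'   the map fall into `"other"`.
#' @return `data.frame`: `family`, `n_semi_peptides`, `share`; shares sum
#'   to 1.
#' @export
proteinFamilyShare <- function(annotations, proteins, familyMap) {
  semi <- annotations[annotations$spec_class %in% c("semi_N", "semi_C") &
                        !annotations$terminal_excluded, , drop = FALSE]
  semi <- semi[!duplicated(semi$peptide), , drop = FALSE]
  gene <- proteins$gene[match(semi$accession, proteins$accession)]
  fam <- unname(familyMap[gene])
  fam[is.na(fam)] <- "other"
  tab <- table(fam)
  data.frame(family = names(tab), n_semi_peptides = as.integer(tab),
             share = as.numeric(tab) / sum(tab), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Cleavage-site motif enrichment matrix
#'
#' Builds the 20 x 8 (residues x P4..P4') log2 enrichment matrix of the
#' cleavage events against a background: for residue a at position p,
#' `log2[ (count(a,p) + pc) / (total(p) + 20 pc) / bg(a,p) ]`, with `X` pads
#' excluded from the counts. Background `"proteome"` uses the overall residue
#' frequency of the protein database (position-independent);
#' `"tryptic_sites"` uses the position-specific residue frequencies around
#' all in-silico fully tryptic cleavage sites, which discounts the trivial
#' K/R signal at P1.
#'
#' @param events cleavage event `data.frame` from [extractCleavageEvents()].
#' @param proteins protein `data.frame` from [readFasta()].
#' @param background `"proteome"` or `"tryptic_sites"`.
#' @param pseudocount Laplace pseudocount (> 0) applied to foreground and
#'   background counts.
#' @param rule an [enzymeRule()]; defines the tryptic sites for the
#'   `"tryptic_sites"` background.
#' @return numeric matrix, rows = 20 amino acids, columns = P4..P4', values
#'   log2 enrichment; attribute `"n_events"`.
#' @export
motifEnrichment <- function(events, proteins,
                            background = c("proteome", "tryptic_sites"),
                            pseudocount = 1, rule = enzymeRule()) {
  background <- match.arg(background)
  if (!nrow(events)) stop("zero cleavage events")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  positions <- c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")
  counts <- .windowCounts(events$window, positions)
  if (background == "proteome") {
    all_res <- strsplit(paste(proteins$sequence, collapse = ""), "")[[1L]]
    bgc <- table(factor(all_res, levels = AMINO_ACIDS))
    bgfreq <- matrix((as.numeric(bgc) + pseudocount) /
                       (sum(bgc) + 20 * pseudocount),
                     nrow = 20L, ncol = 8L,
                     dimnames = list(AMINO_ACIDS, positions))
  } else {
    wins <- unlist(lapply(proteins$sequence, function(sq) {
      sites <- which(strsplit(sq, "")[[1L]] %in% rule$cleaveAfter)
      sites <- sites[sites < nchar(sq)]
      vapply(sites, function(p1) .cleavageWindow(sq, p1), "")
    }))
    bgcounts <- .windowCounts(wins, positions)
    bgfreq <- sweep(bgcounts + pseudocount, 2L,
                    colSums(bgcounts) + 20 * pseudocount, "/")
  }
  fgfreq <- sweep(counts + pseudocount, 2L,
                  colSums(counts) + 20 * pseudocount, "/")
  out <- log2(fgfreq / bgfreq)
  attr(out, "n_events") <- nrow(events)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "background") <- background
  out
}

# residue x position counts over 8-mer windows, 'X' excluded
.windowCounts <- function(windows, positions) {
  counts <- matrix(0, nrow = 20L, ncol = 8L,
                   dimnames = list(AMINO_ACIDS, positions))
  ch <- do.call(rbind, strsplit(windows, ""))
  for (j in 1:8) {
    tab <- table(factor(ch[, j], levels = AMINO_ACIDS))
    counts[, j] <- as.numeric(tab)
  }
  counts
}
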