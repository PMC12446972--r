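#' Principal component analysis of samples
#'
#' Column-centred (optionally feature-standardised) SVD of the
#' samples x features matrix. The sign of each component is fixed so that
#' its largest-magnitude loading is positive.
#'
#' @param x a complete log2 [QuantMatrix-class] (impute first).
#' @param scale standardise features to unit variance before the SVD.
#' @return list with `scores` (samples x components), `loadings`
#'   (features x components) and `varianceExplained` (percentages,
#'   non-increasing).
#' @export
quantPCA <- function(x, scale = FALSE) {
  v <- quantValues(x)
  if (anyNA(v)) stop("matrix contains missing values; impute first")
  if (ncol(v) < 3L) stop("need >= 3 samples")
  m <- t(v)
  ctr <- colMeans(m)
  m <- sweep(m, 2L, ctr, "-")
  if (scale) {
    sds <- apply(m, 2L, sd)
    if (any(sds == 0)) stop("zero-variance feature(s); cannot scale")
    m <- sweep(m, 2L, sds, "/")
  }
  sv <- svd(m)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(ncomp)]
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*% diag(d, ncomp)
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  for (k in seq_len(ncomp)) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(scores) <- list(colnames(v), paste0("PC", seq_len(ncomp)))
  dimnames(loadings) <- list(rownames(v), paste0("PC", seq_len(ncomp)))
  list(scores = scores, loadings = loadings,
       varianceExplained = 100 * d^2 / sum(sv$d^2))
}

#' Monotone abundance trends across NAT, PC and tumor
#'
#' Deterministic replacement for co-expression clustering when the expected
#' structure is two opposite monotone clusters: each feature is z-scored
#' across samples, compartment means are computed, and the feature is called
#' `increasing` when mean(NAT) <= mean(PC) <= mean(TUMOR) with a total span
#' of at least `margin` standard deviations (`decreasing` symmetrically),
#' otherwise `none`.
#'
#' @param x a complete log2 [QuantMatrix-class] with compartment metadata.
#' @param margin minimum NAT-to-TUMOR span in (z-scored) sd units.
#' @return `data.frame`: `feature_id`, `cluster`, `mean_NAT`, `mean_PC`,
#'   `mean_TUMOR` (z-score units), `effect_size` (|TUMOR - NAT| in sd
#'   units).
#' @export
trendClusters <- function(x, margin = 0.5) {
  comp <- .compartments(x)
  v <- quantValues(x)
  if (anyNA(v)) stop("matrix contains missing values; impute first")
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, sd)
  z <- (v - mu) / ifelse(sdv > 0, sdv, 1)
  means <- vapply(COMPARTMENTS, function(cp)
    rowMeans(z[, comp == cp, drop = FALSE]), numeric(nrow(v)))
  span <- means[, "TUMOR"] - means[, "NAT"]
  inc <- means[, "NAT"] <= means[, "PC"] & means[, "PC"] <= means[, "TUMOR"] &
    span >= margin
  dec <- means[, "NAT"] >= means[, "PC"] & means[, "PC"] >= means[, "TUMOR"] &
    -span >= margin
  cluster <- ifelse(inc, "increasing", ifelse(dec, "decreasing", "none"))
  data.frame(feature_id = rownames(v), cluster = cluster,
             mean_NAT = means[, "NAT"], mean_PC = means[, "PC"],
             mean_TUMOR = means[, "TUMOR"], effect_size = abs(span),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tumor-size correlation screen
#'
#' Correlates each feature's log2 abundance (typically within the PC
#' compartment) with the matched tumor diameter; two-sided p-values from the
#' t transform of the correlation coefficient, BH-adjusted across features.
#'
#' @param x a log2 [QuantMatrix-class] restricted to the samples of
#'   interest.
#' @param diameters numeric vector of tumor diameters (mm), one per sample
#'   of `x` (or named by sample id). `NA` diameters are dropped.
#' @param alpha BH-adjusted significance level for the direction call.
#' @param method `"pearson"` (linear correlation) or `"spearman"`.
#' @return `data.frame`: `feature_id`, `r`, `n`, `p`, `adj_p`, `direction`
#'   (`positive` / `negative` / `ns`), `constant` flag for zero-variance
#'   features (reported `ns`).
#' @export
sizeCorrelation <- function(x, diameters, alpha = 0.05,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- quantValues(x)
  if (!is.null(names(diameters)))
    diameters <- diameters[colnames(v)]
  if (length(diameters) != ncol(v))
    stop("need one diameter per sample")
  ok <- !is.na(diameters)
  v <- v[, ok, drop = FALSE]
  d <- diameters[ok]
  if (length(d) < 5L) stop("need >= 5 samples with diameters")
  if (method == "spearman") d <- rank(d)
  r <- apply(v, 1L, function(row) {
    use <- !is.na(row)
    if (sum(use) < 3L || sd(row[use]) == 0 || sd(d[use]) == 0)
      return(c(NA_real_, sum(use)))
    rr <- if (method == "spearman")
      cor(rank(row[use]), d[use]) else cor(row[use], d[use])
    c(rr, sum(use))
  })
  rv <- r[1L, ]; n <- r[2L, ]
  tt <- rv * sqrt(n - 2) / sqrt(pmax(1 - rv^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), n - 2)
  adj <- bhAdjust(p)
  direction <- rep("ns", nrow(v))
  direction[!is.na(adj) & adj <= alpha & rv > 0] <- "positive"
  direction[!is.na(adj) & adj <= alpha & rv < 0] <- "negative"
  data.frame(feature_id = rownames(v), r = rv, n = as.integer(n), p = p,
             adj_p = adj, direction = direction, constant = is.na(rv),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Anchor-vs-panel correlations per compartment
#'
#' Pearson correlation of one anchor gene's abundance against each panel
#' gene, computed separately within each compartment's samples (pairwise
#' complete observations), e.g. PCNA against the MCM2-7 replication panel.
#'
#' @param x a log2 [QuantMatrix-class] with compartment metadata; genes are
#'   looked up in `rowData(x)$gene` when present, else in the rownames.
#' @param anchorGene anchor gene symbol.
#' @param panelGenes character vector of panel gene symbols.
#' @return `data.frame`: `compartment`, `gene`, `r`, `n`. Genes absent from
#'   the matrix yield a warning and `NA` rows.
#' @export
markerCorrelation <- function(x, anchorGene, panelGenes) {
  comp <- .compartments(x, require_all = FALSE)
  v <- quantValues(x)
  rd <- SummarizedExperiment::rowData(x)
  genes <- if ("gene" %in% names(rd)) as.character(rd$gene) else rownames(v)
  a_row <- match(anchorGene, genes)
  if (is.na(a_row)) stop("anchor gene not found: ", anchorGene)
  rows <- match(panelGenes, genes)
  if (anyNA(rows))
    warning("panel gene(s) not found: ",
            paste(panelGenes[is.na(rows)], collapse = ", "))
  out <- list()
  for (cp in levels(comp)) {
    sel <- comp == cp
    if (!any(sel)) next
    av <- v[a_row, sel]
    for (i in seq_along(panelGenes)) {
      if (is.na(rows[i])) {
        out[[length(out) + 1L]] <- data.frame(
          compartment = cp, gene = panelGenes[i], r = NA_real_, n = 0L)
        next
      }
      pv <- v[rows[i], sel]
      use <- !is.na(av) & !is.na(pv)
      rr <- if (sum(use) >= 3L && sd(av[use]) > 0 && sd(pv[use]) > 0)
        cor(av[use], pv[use]) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        compartment = cp, gene = panelGenes[i], r = rr, n = sum(use))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Peptide vs protein fold-change concordance
#'
#' Global Pearson correlation between peptide-level and parent-protein
#' log2 fold changes, plus the list of discordant peptides: peptides with a
#' significant change (`adj_p <= alpha`, `|log2fc| >= log2(fc)`) whose
#' parent protein is non-significant or regulated in the opposite
#' direction — candidates for domain-specific (proteolytic) regulation.
#'
#' @param peptideDA,proteinDA [moderatedTTest()] tables for the same
#'   contrast at peptide and protein level.
#' @param mapping `data.frame` with columns `peptide_id`, `protein_id`.
#' @param fc,alpha thresholds defining a significant peptide change.
#' @return list with `r` (global correlation), `n` (pairs) and `discordant`
#'   (`data.frame`: `peptide_id`, `protein_id`, `peptide_log2fc`,
#'   `protein_log2fc`, `reason`).
#' @export
peptideProteinConcordance <- function(peptideDA, proteinDA, mapping,
                                      fc = 1.5, alpha = 0.05) {
  pi <- match(mapping$peptide_id, peptideDA$feature_id)
  qi <- match(mapping$protein_id, proteinDA$feature_id)
  use <- !is.na(pi) & !is.na(qi)
  if (!any(use)) stop("no peptide-protein pairs shared between the tables")
  pep <- peptideDA[pi[use], ]
  prot <- proteinDA[qi[use], ]
  ok <- !is.na(pep$log2fc) & !is.na(prot$log2fc)
  r <- cor(pep$log2fc[ok], prot$log2fc[ok])
  lfc <- log2(fc)
  pep_sig <- !is.na(pep$adj_p) & pep$adj_p <= alpha & abs(pep$log2fc) >= lfc
  prot_sig <- !is.na(prot$adj_p) & prot$adj_p <= alpha
  opposite <- prot_sig & sign(prot$log2fc) != sign(pep$log2fc)
  disc <- pep_sig & (!prot_sig | opposite)
  discordant <- data.frame(
    peptide_id = pep$feature_id[disc],
    protein_id = prot$feature_id[disc],
    peptide_log2fc = pep$log2fc[disc],
    protein_log2fc = prot$log2fc[disc],
    reason = ifelse(opposite[disc], "opposite_sign", "protein_ns"),
    stringsAsFactors = FALSE)
  list(r = r, n = sum(ok), discordant = discordant)
}
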