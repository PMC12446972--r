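# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive every quantity from first principles on
# character vectors / explicit enumeration, sharing no code with the
# package internals.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomProtein <- function(len, kr = 0.11) {
  probs <- rep((1 - kr) / 18, 20)
  names(probs) <- AA20
  probs[c("K", "R")] <- kr / 2
  paste(sample(AA20, len, replace = TRUE, prob = probs), collapse = "")
}

# classify one terminus by direct residue inspection
bruteTerminus <- function(chars, start, end, side, cleave = c("K", "R"),
                          nterm_window = 2) {
  L <- length(chars)
  if (side == "N") {
    if (start <= nterm_window) return("protein_terminal")
    if (chars[start - 1] %in% cleave) "enzymatic" else "nonenzymatic"
  } else {
    if (end == L) return("protein_terminal")
    if (chars[end] %in% cleave) "enzymatic" else "nonenzymatic"
  }
}

bruteClassFromStatuses <- function(nst, cst) {
  n_non <- nst == "nonenzymatic"
  c_non <- cst == "nonenzymatic"
  if (n_non && c_non) "nonspecific"
  else if (n_non) "semi_N"
  else if (c_non) "semi_C"
  else "full"
}

# classify a peptide against a protein: every occurrence inspected, the
# most specific one kept (full > semi > nonspecific, earliest start wins)
bruteClassify <- function(peptide, protein, cleave = c("K", "R"),
                          nterm_window = 2) {
  chars <- strsplit(protein, "")[[1]]
  hits <- unlist(gregexpr(peptide, protein, fixed = TRUE))
  hits <- hits[hits > 0]
  # gregexpr misses overlapping hits; rescan manually
  starts <- integer()
  for (s in seq_len(nchar(protein) - nchar(peptide) + 1)) {
    if (substr(protein, s, s + nchar(peptide) - 1) == peptide)
      starts <- c(starts, s)
  }
  if (!length(starts)) return(NULL)
  rank <- c(full = 3, semi_N = 2, semi_C = 2, nonspecific = 1)
  best <- NULL
  for (s in starts) {
    e <- s + nchar(peptide) - 1
    nst <- bruteTerminus(chars, s, e, "N", cleave, nterm_window)
    cst <- bruteTerminus(chars, s, e, "C", cleave, nterm_window)
    cls <- bruteClassFromStatuses(nst, cst)
    cand <- list(start = s, end = e, nst = nst, cst = cst, cls = cls,
                 excl = nst == "protein_terminal" | cst == "protein_terminal")
    if (is.null(best) || rank[[cls]] > rank[[best$cls]]) best <- cand
  }
  best
}

# exhaustive tryptic digestion: test every substring for valid termini and
# the missed-cleavage budget
bruteDigest <- function(protein, max_missed = 1, len_range = c(7, 30),
                        cleave = c("K", "R")) {
  chars <- strsplit(protein, "")[[1]]
  L <- length(chars)
  out <- character()
  for (s in 1:L) {
    n_ok <- s == 1 || chars[s - 1] %in% cleave
    if (!n_ok) next
    for (e in s:min(L, s + len_range[2] - 1)) {
      if (e - s + 1 < len_range[1]) next
      c_ok <- e == L || chars[e] %in% cleave
      if (!c_ok) next
      internal <- if (e > s) sum(chars[s:(e - 1)] %in% cleave) else 0
      if (internal <= max_missed) out <- c(out, substr(protein, s, e))
    }
  }
  unique(out)
}

# BH step-up straight from the definition
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, m * p[o[j]] / j), 0)
    adj[o[i]] <- min(vals)
  }
  adj
}

# upper-tail hypergeometric by explicit pmf summation
bruteHyper <- function(N, K, n, k) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  js <- max(k, max(0, n - (N - K))):jmax
  sum(vapply(js, function(j)
    choose(K, j) * choose(N - K, n - j) / choose(N, n), 0))
}

# MaxLFQ oracle: explicit normal equations solved with a pseudoinverse,
# anchored to the mean of per-sample mean observed intensities
rollupOracle <- function(X, min_shared = 1) {
  n <- ncol(X)
  pairs <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sh <- !is.na(X[, i]) & !is.na(X[, j])
    if (sum(sh) >= min_shared && sum(sh) > 0)
      pairs[[length(pairs) + 1]] <-
        list(i = i, j = j, r = median(X[sh, i] - X[sh, j]))
  }
  has_data <- colSums(!is.na(X)) > 0
  # connected components over the pair graph
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (p in pairs) {
      m <- min(comp[p$i], comp[p$j])
      if (comp[p$i] != m || comp[p$j] != m) {
        comp[c(p$i, p$j)] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  v <- rep(NA_real_, n)
  for (cc in unique(comp[has_data])) {
    idx <- which(comp == cc & has_data)
    A <- matrix(0, length(idx), length(idx))
    b <- numeric(length(idx))
    for (p in pairs) {
      if (!(p$i %in% idx)) next
      ii <- match(p$i, idx); jj <- match(p$j, idx)
      A[ii, ii] <- A[ii, ii] + 1; A[jj, jj] <- A[jj, jj] + 1
      A[ii, jj] <- A[ii, jj] - 1; A[jj, ii] <- A[jj, ii] - 1
      b[ii] <- b[ii] + p$r; b[jj] <- b[jj] - p$r
    }
    sol <- MASS::ginv(A) %*% b
    anchor <- mean(colMeans(X[, idx, drop = FALSE], na.rm = TRUE))
    v[idx] <- sol - mean(sol) + anchor
  }
  v
}

# build a PeptideTable for one protein group from a log2 peptide matrix
pepTable <- function(log2mat, group = "P1", proteotypic = TRUE) {
  n <- nrow(log2mat)
  if (is.null(colnames(log2mat)))
    colnames(log2mat) <- paste0("S", seq_len(ncol(log2mat)))
  structure(list(
    peptides = data.frame(
      stripped_sequence = paste0("PEP", seq_len(n)),
      protein_group = group, gene = "G",
      proteotypic = proteotypic, stringsAsFactors = FALSE),
    intensities = 2^log2mat), class = "PeptideTable")
}

# small deterministic protein fixtures reused across files
toyProteins <- function() {
  data.frame(
    accession = c("P0TEST", "P1TEST"),
    gene = c("G0", "G1"),
    sequence = c("MKLVRAGDSTKNNFW", "MAAACDEFGHKLLLRSSSTV"),
    stringsAsFactors = FALSE)
}

# quick QuantMatrix builder
qmat <- function(values, level = "protein", sampleData = NULL,
                 rowData = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("F", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  QuantMatrix(values, level = level, sampleData = sampleData,
              rowData = rowData)
}

# memoised per-seed cohort statistics shared by the simulation-heavy
# acceptance checks (proteolysis shares and signature recovery)
.cohort_cache <- new.env(parent = emptyenv())

cohortStats <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  ch <- simulateCohort(simConfig(), seed = seed)
  pt <- ch$peptideTable
  ann <- classifyPeptides(pt$peptides, ch$proteins)
  fr <- semiFractionPerSample(ann, pt)
  comp <- ch$metadata$compartment[match(fr$sample_id, ch$metadata$sample_id)]
  frac_means <- tapply(fr$fraction_intensity, comp, mean, na.rm = TRUE)
  tests <- groupCompareFractions(fr, ch$metadata)
  dunn_tn <- tests$pairwise$adj_p[tests$pairwise$contrast == "NAT-TUMOR" &
                                    tests$pairwise$method == "dunn"]
  idx <- match(pt$peptides$stripped_sequence, ann$peptide)
  fully <- !is.na(idx) & ann$spec_class[idx] == "full" &
    !ann$terminal_excluded[idx]
  # duplicated tryptic sequences occasionally leave a protein group without
  # proteotypic peptides; the drop warning is asserted in the unit tests
  prot <- suppressWarnings(
    rollupMaxLFQ(subsetPeptides(pt, fully), sampleData = ch$metadata))
  prot <- normalizeMedian(prot)
  ext <- completenessFilter(prot, "extended")
  imp <- imputeMNAR(ext, seed = seed + 1000L)
  sig <- pcUniqueSignature(moderatedTTest(imp, "PC", "NAT"),
                           moderatedTTest(imp, "PC", "TUMOR"))
  up_genes <- ch$proteins$gene[match(sig$up, ch$proteins$accession)]
  truth_up <- ch$truth$panels$pc_up
  res <- list(
    frac_means = frac_means,
    dunn_tumor_nat = dunn_tn,
    recall = mean(truth_up %in% up_genes),
    fdr = if (length(up_genes)) mean(!up_genes %in% truth_up) else 0,
    cohort_seed = seed)
  .cohort_cache[[key]] <- res
  res
}
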