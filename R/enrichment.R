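#' Annotate genes with matrisome division and category
#'
#' Case-insensitive lookup of gene symbols in a matrisome category table
#' (columns `gene`, `division`, `category`). Genes not in the table are
#' annotated `non-matrisome` / `other`. A small representative table derived
#' from the standard matrisome nomenclature ships with the package; supply
#' a full table for production use.
#'
#' @param genes character vector of gene symbols.
#' @param table optional matrisome `data.frame`; defaults to the packaged
#'   table (`system.file("extdata", "matrisome_categories.tsv", ...)`).
#' @return `data.frame`: `gene`, `division`, `category`.
#' @export
annotateMatrisome <- function(genes, table = NULL) {
  if (is.null(table)) {
    path <- system.file("extdata", "matrisome_categories.tsv",
                        package = "proteocaps")
    table <- read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("gene", "division", "category")
  if (!all(need %in% names(table)))
    stop("matrisome table needs columns: ", paste(need, collapse = ", "))
  idx <- match(toupper(genes), toupper(table$gene))
  data.frame(
    gene = genes,
    division = ifelse(is.na(idx), "non-matrisome", table$division[idx]),
    category = ifelse(is.na(idx), "other", table$category[idx]),
    stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set (intersected with the universe): overlap `k` with the
#' query, set size `K`, query size `n`, universe size `N`; the p-value is
#' the upper-tail hypergeometric probability `P(X >= k)` and the fold
#' enrichment is `(k/n) / (K/N)`. BH adjustment across sets.
#'
#' @param query character vector of genes of interest (must be contained in
#'   the universe; others are dropped with a warning).
#' @param universe character vector of all testable genes.
#' @param geneSets named list of character vectors (e.g. [readGmt()]).
#' @param alpha BH-adjusted significance level for the `significant` flag.
#' @return `data.frame`: `set_id`, `set_name`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `p`, `adj_p`, `significant`, sorted by `p`.
#' @export
oraHypergeometric <- function(query, universe, geneSets, alpha = 0.05) {
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query) || !length(universe))
    stop("query and universe must be non-empty")
  out_of_universe <- setdiff(query, universe)
  if (length(out_of_universe)) {
    warning(length(out_of_universe), " query gene(s) not in universe dropped")
    query <- intersect(query, universe)
    if (!length(query)) stop("query empty after intersecting with universe")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(geneSets), function(id) {
    members <- intersect(geneSets[[id]], universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- if (K == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    fold <- if (K == 0L) NA_real_ else (k / n) / (K / N)
    nm <- attr(geneSets[[id]], "name")
    data.frame(set_id = id, set_name = if (is.null(nm)) id else nm,
               k = k, K = K, n = n, N = N, fold_enrichment = fold, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adj_p <- bhAdjust(res$p)
  res$significant <- res$adj_p <= alpha
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  res
}
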