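#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats aov TukeyHSD cor kruskal.test median na.omit pnorm
#'   prcomp pt quantile rnorm runif rpois sd setNames var phyper plogis
#'   p.adjust rbinom
#' @importFrom utils read.delim write.table head
NULL

COMPARTMENTS <- c("NAT", "PC", "TUMOR")
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' QuantMatrix: a features x samples log2 intensity matrix
#'
#' `QuantMatrix` extends [SummarizedExperiment::SummarizedExperiment] with a
#' `level` slot stating whether rows are peptides or proteins. The single
#' assay, `"log2intensity"`, holds log2-transformed intensities with `NA`
#' marking missing (not-detected) cells. Sample annotation (compartment,
#' patient, tumor diameter, grade, lesion index) lives in `colData`.
#'
#' @slot level character, `"peptide"` or `"protein"`.
#'
#' @seealso [QuantMatrix()] for construction, [quantValues()],
#'   [quantLevel()], [sampleInfo()] for access.
#' @export
setClass("QuantMatrix",
  contains = "SummarizedExperiment",
  slots = c(level = "character")
)

setValidity("QuantMatrix", function(object) {
  msg <- character()
  if (length(object@level) != 1L || !object@level %in% c("peptide", "protein"))
    msg <- c(msg, "level must be 'peptide' or 'protein'")
  if (!"log2intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2intensity' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate feature ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  v <- SummarizedExperiment::assay(object, "log2intensity")
  if (any(!is.finite(v) & !is.na(v)))
    msg <- c(msg, "all present values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a QuantMatrix
#'
#' @param values numeric matrix of log2 intensities (features x samples) with
#'   `NA` for missing cells; must have row and column names.
#' @param level `"peptide"` or `"protein"`.
#' @param sampleData optional `data.frame` of sample metadata; either one row
#'   per column of `values` in the same order, or containing a `sample_id`
#'   column used to match and reorder.
#' @param rowData optional `data.frame` of feature annotation (e.g. gene).
#'
#' @return A [QuantMatrix-class] object.
#' @export
QuantMatrix <- function(values, level = c("protein", "peptide"),
                        sampleData = NULL, rowData = NULL) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("'values' must have feature (row) and sample (column) names")
  if (nrow(values) == 0L && is.null(rownames(values)))
    rownames(values) <- character(0)
  storage.mode(values) <- "double"
  cd <- if (is.null(sampleData)) {
    S4Vectors::DataFrame(row.names = colnames(values))
  } else {
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% names(sampleData)) {
      idx <- match(colnames(values), sampleData$sample_id)
      if (anyNA(idx))
        stop("sampleData lacks rows for samples: ",
             paste(colnames(values)[is.na(idx)], collapse = ", "))
      sampleData <- sampleData[idx, , drop = FALSE]
    } else if (nrow(sampleData) != ncol(values)) {
      stop("sampleData must have one row per sample")
    }
    rownames(sampleData) <- colnames(values)
    S4Vectors::DataFrame(sampleData)
  }
  rd <- if (is.null(rowData)) {
    S4Vectors::DataFrame(row.names = rownames(values))
  } else {
    rowData <- as.data.frame(rowData)
    rownames(rowData) <- rownames(values)
    S4Vectors::DataFrame(rowData)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2intensity = values), colData = cd, rowData = rd)
  methods::new("QuantMatrix", se, level = level)
}

#' @describeIn QuantMatrix Quantification level ("peptide" or "protein").
#' @param x A `QuantMatrix`.
#' @export
quantLevel <- function(x) x@level

#' @describeIn QuantMatrix The log2 intensity matrix (`NA` = missing).
#' @export
quantValues <- function(x) SummarizedExperiment::assay(x, "log2intensity")

#' @describeIn QuantMatrix Sample metadata as a base `data.frame`.
#' @export
sampleInfo <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn QuantMatrix Replace the log2 intensity matrix.
#' @param value replacement matrix, same dimensions.
#' @export
`quantValues<-` <- function(x, value) {
  SummarizedExperiment::assay(x, "log2intensity") <- value
  methods::validObject(x)
  x
}

setMethod("show", "QuantMatrix", function(object) {
  v <- quantValues(object)
  cat(sprintf("QuantMatrix (%s level): %d features x %d samples\n",
              object@level, nrow(v), ncol(v)))
  miss <- mean(is.na(v))
  cat(sprintf("  missing: %.1f%%", 100 * miss))
  cd <- SummarizedExperiment::colData(object)
  if ("compartment" %in% names(cd)) {
    tab <- table(cd$compartment)
    cat(" | samples:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "))
  }
  cat("\n")
  invisible(NULL)
})

# internal: compartment factor of a QuantMatrix, with checks
.compartments <- function(x, require_all = TRUE) {
  cd <- SummarizedExperiment::colData(x)
  if (!"compartment" %in% names(cd))
    stop("sample metadata lacks a 'compartment' column")
  comp <- as.character(cd$compartment)
  bad <- setdiff(unique(comp), COMPARTMENTS)
  if (length(bad))
    stop("unknown compartment value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(COMPARTMENTS, collapse = ", "))
  if (require_all && !all(COMPARTMENTS %in% comp))
    stop("all three compartments (NAT, PC, TUMOR) must be present")
  factor(comp, levels = COMPARTMENTS)
}
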