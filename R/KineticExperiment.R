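#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
NULL

#' KineticExperiment: expression values on a kinetic dye-swap design
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one `log2` assay of normalized expression values (genes x observations),
#' the observation annotation as `colData`, and the [KineticDesign-class]
#' in `metadata(x)$design`. Genes with missing values are retained in the
#' object but excluded from model fitting.
#'
#' @export
setClass("KineticExperiment", contains = "SummarizedExperiment")

setValidity("KineticExperiment", function(object) {
  d <- S4Vectors::metadata(object)$design
  if (is.null(d) || !is(d, "KineticDesign"))
    return("metadata(x)$design must be a KineticDesign")
  if (!"log2" %in% assayNames(object))
    return("assay 'log2' is required")
  obs <- observations(d)
  if (ncol(object) != nrow(obs))
    return("column count must equal the design observation count")
  if (!identical(colnames(object), obs$obs_id))
    return("colnames must equal design obs_id, in design order")
  TRUE
})

#' Construct a KineticExperiment
#'
#' @param values numeric matrix, genes x observations, normalized log2
#'   expression; columns must follow the design observation order
#' @param design a [KineticDesign-class]
#' @param rowData optional per-gene annotation (e.g. simulation truth)
#' @return a [KineticExperiment-class]
#' @export
KineticExperiment <- function(values, design, rowData = NULL) {
  obs <- observations(design)
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- obs$obs_id
  se <- SummarizedExperiment(
    assays = list(log2 = values),
    colData = S4Vectors::DataFrame(obs, row.names = obs$obs_id),
    metadata = list(design = design))
  if (!is.null(rowData)) rowData(se) <- rowData
  new("KineticExperiment", se)
}

#' @describeIn KineticExperiment the experimental design
#' @param x a `KineticExperiment`
#' @export
kineticDesign <- function(x) {
  stopifnot(is(x, "KineticExperiment"))
  S4Vectors::metadata(x)$design
}

#' @describeIn KineticExperiment the log2 expression matrix
#' @export
expressionValues <- function(x) assay(x, "log2")

#' @describeIn KineticExperiment logical vector: gene has one or more
#'   missing values (excluded from model fitting)
#' @export
hasMissing <- function(x) apply(is.na(expressionValues(x)), 1L, any)

setMethod("show", "KineticExperiment", function(object) {
  cat("KineticExperiment:", nrow(object), "genes x", ncol(object),
      "observations\n")
  nm <- sum(hasMissing(object))
  if (nm) cat(" ", nm, "genes carry missing values (skipped by fitting)\n")
  show(kineticDesign(object))
})
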