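#' Write an expression matrix as TSV
#'
#' Genes in rows (first column `gene_id`), one column per observation id,
#' full precision so that write/read round-trips bit-exactly. Missing
#' values are written as empty cells.
#'
#' @param ke a [KineticExperiment-class]
#' @param path output path
#' @return the path, invisibly
#' @export
writeExpression <- function(ke, path) {
  Y <- expressionValues(ke)
  df <- data.frame(gene_id = rownames(Y),
                   format(Y, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(Y))) df[[j + 1L]][is.na(Y[, j])] <- ""
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix against its design
#'
#' Parses a tab-delimited matrix (first column `gene_id`, one column per
#' observation). Header columns must match the design's observation ids
#' exactly and in order; empty cells become missing values; malformed
#' numeric cells and duplicate gene ids are errors naming the offending
#' gene and column.
#'
#' @param matrix_path expression TSV path
#' @param design_path design TSV path (see [readDesign()]) or a
#'   [KineticDesign-class]
#' @return a [KineticExperiment-class]
#' @export
readExpression <- function(matrix_path, design_path) {
  design <- if (is(design_path, "KineticDesign")) design_path
            else readDesign(design_path)
  obs <- observations(design)
  raw <- read.delim(matrix_path, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  if (names(raw)[1L] != "gene_id") stop("first column must be gene_id")
  hdr <- names(raw)[-1L]
  if (!identical(hdr, obs$obs_id)) {
    bad <- c(setdiff(hdr, obs$obs_id), setdiff(obs$obs_id, hdr))
    stop("matrix columns do not match design observations: ",
         paste(unique(bad), collapse = ", "))
  }
  ids <- raw$gene_id
  if (anyDuplicated(ids))
    stop("duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  Y <- matrix(NA_real_, nrow = nrow(raw), ncol = length(hdr),
              dimnames = list(ids, hdr))
  for (j in seq_along(hdr)) {
    v <- raw[[j + 1L]]
    blank <- is.na(v) | v == ""
    num <- suppressWarnings(as.numeric(v))
    bad <- !blank & is.na(num)
    if (any(bad))
      stop("malformed value for gene ", ids[which(bad)[1L]],
           " in column ", hdr[j])
    Y[, j] <- num
  }
  KineticExperiment(Y, design)
}

#' Write the simulation truth table as TSV
#'
#' @param ke a simulated [KineticExperiment-class] (truth in `rowData`)
#' @param path output path
#' @export
writeTruthTable <- function(ke, path) {
  rd <- as.data.frame(rowData(ke))
  write.table(rd, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write plain-text gene sets
#'
#' One gene id per line (optionally a second tab-separated direction
#' column, ignored on read into the plain set).
#'
#' @param path file path
#' @param genes character vector of gene ids
#' @return `readGeneSet` returns a character vector
#' @export
readGeneSet <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' @rdname readGeneSet
#' @export
writeGeneSet <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
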