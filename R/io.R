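#' Read an expression matrix from TSV
#'
#' Expects rows = feature/gene ids (first column), columns = sample ids.
#' Lines starting with '!' (GEO series-matrix style annotation) or '#' are
#' skipped.
#'
#' @param path file path.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
readExpressionTSV <- function(path) {
  df <- read.delim(path, comment.char = "!", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write an expression matrix to TSV
#' @param m numeric matrix (features x samples).
#' @param path file path.
#' @export
writeExpressionTSV <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a clinical table from TSV
#'
#' Columns: \code{sample_id}, \code{endpoint_kind}, \code{time},
#' \code{event}, \code{label}, plus covariates.
#'
#' @param path file path.
#' @return data.frame with rownames set to sample ids.
#' @export
readClinicalTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stop("clinical table lacks a sample_id column")
  rownames(df) <- df$sample_id
  df
}

#' Read a two-column feature-to-gene map
#' @param path TSV with columns feature_id, gene_symbol (lines starting '!'
#'   or '#' are skipped).
#' @return Named character vector: feature id -> gene symbol.
#' @export
readGeneMap <- function(path) {
  df <- read.delim(path, comment.char = "!", stringsAsFactors = FALSE)
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors (or a single
#'   \linkS4class{GeneSignature}).
#' @param path file path.
#' @export
writeGMT <- function(sets, path) {
  if (is(sets, "GeneSignature")) sets <- setNames(list(sigGenes(sets)), sigName(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "ccpmeta", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
}

#' Read a newline-delimited gene list
#' @param path file path; blank lines and '#' comments ignored.
#' @return Character vector of gene symbols.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write per-sample signature scores to TSV
#' @param score a \linkS4class{SignatureScore}.
#' @param path file path.
#' @export
writeScoreTSV <- function(score, path) {
  write.table(data.frame(sample_id = names(scoreValues(score)),
                         score = unname(scoreValues(score))),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a cohort from expression + clinical TSV files
#'
#' @param expressionPath,clinicalPath,geneMapPath file paths; the gene map
#'   is optional (rows then taken as gene symbols).
#' @param cohortId cohort identifier.
#' @param endpointLabel optional endpoint override; by default inferred from
#'   the clinical table's endpoint_kind column via \code{\link{selectEndpoint}}.
#' @return A \linkS4class{PrognosticCohort}.
#' @export
readCohort <- function(expressionPath, clinicalPath, geneMapPath = NULL,
                       cohortId = "cohort", endpointLabel = NULL) {
  m <- readExpressionTSV(expressionPath)
  clin <- readClinicalTSV(clinicalPath)
  clin <- clin[match(colnames(m), clin$sample_id), , drop = FALSE]
  gm <- NULL
  if (!is.null(geneMapPath)) {
    map <- readGeneMap(geneMapPath)
    gm <- unname(map[rownames(m)])
  }
  if (is.null(endpointLabel)) {
    avail <- unique(clin$endpoint_kind)
    endpointLabel <- if (length(avail)) selectEndpoint(avail) else "OS"
  }
  kind <- if (identical(endpointLabel, "binary")) "binary" else "time_to_event"
  prognosticCohort(m, clin, geneMap = gm, endpointKind = kind,
                   endpointLabel = endpointLabel, cohortId = cohortId)
}
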