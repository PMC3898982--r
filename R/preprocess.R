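# Probe collapsing and z-normalization: the score-preparation steps applied
# to every cohort before any signature is computed.

.collapse_core <- function(m, geneMap) {
  if (length(geneMap) != nrow(m))
    stop("geneMap must supply one symbol per matrix row")
  mapped <- !is.na(geneMap) & nzchar(geneMap)
  if (!any(mapped)) stop("no mappable features")
  if (any(!mapped))
    message(sum(!mapped), " unmapped feature(s) dropped")
  m <- m[mapped, , drop = FALSE]
  geneMap <- geneMap[mapped]

  frac_missing <- rowMeans(is.na(m))
  # a gene is dropped when its best probe would still be missing in >50% of
  # samples; applied per probe before collapsing for simplicity
  lowcov <- frac_missing > 0.5
  if (any(lowcov)) {
    drop_genes <- setdiff(unique(geneMap[lowcov]), unique(geneMap[!lowcov]))
    warning(length(drop_genes), " gene(s) missing in >50% of samples dropped")
    keep <- !lowcov
    m <- m[keep, , drop = FALSE]
    geneMap <- geneMap[keep]
    if (nrow(m) == 0) stop("no mappable features")
  }

  means <- rowMeans(m, na.rm = TRUE)
  idx <- seq_len(nrow(m))
  by_gene <- split(idx, geneMap)          # within-gene order = input order
  win <- vapply(by_gene, function(ii) ii[which.max(means[ii])], 1L)
  # preserve first-appearance order of genes
  first <- vapply(by_gene, `[`, 1L, 1L)
  win <- win[order(first)]
  out <- m[win, , drop = FALSE]
  rownames(out) <- names(win)
  out
}

#' @rdname collapseProbes
setMethod("collapseProbes", "matrix", function(x, geneMap) {
  .collapse_core(x, as.character(geneMap))
})

#' @rdname collapseProbes
setMethod("collapseProbes", "PrognosticCohort", function(x) {
  out <- .collapse_core(assay(x, "exprs"), as.character(rowData(x)$gene_symbol))
  cls <- rowData(x)$gene_class
  se <- SummarizedExperiment(assays = list(exprs = out),
                             colData = colData(x),
                             rowData = DataFrame(gene_symbol = rownames(out),
                                                 row.names = rownames(out)))
  if (!is.null(cls)) {
    m <- match(rownames(out), rowData(x)$gene_symbol)
    rowData(se)$gene_class <- cls[m]
    rowData(se)$true_loading <- rowData(x)$true_loading[m]
  }
  metadata(se) <- metadata(x)
  metadata(se)$collapsed <- TRUE
  if (is(x, "SyntheticCohort"))
    new("SyntheticCohort", new("PrognosticCohort", se), truth = x@truth)
  else new("PrognosticCohort", se)
})

.znorm_core <- function(m, log2transform = FALSE) {
  if (ncol(m) < 2) stop("z-normalization needs at least 2 samples")
  if (log2transform) {
    if (any(m < 0, na.rm = TRUE)) stop("log2 transform requires non-negative values")
    m <- log2(m + 1)
  }
  mu <- rowMeans(m, na.rm = TRUE)
  sds <- apply(m, 1, sd, na.rm = TRUE)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) dropped (no cross-sample variance)")
    m <- m[!const, , drop = FALSE]
    mu <- mu[!const]; sds <- sds[!const]
  }
  (m - mu) / sds
}

#' @rdname zNormalize
setMethod("zNormalize", "matrix", function(x, log2transform = FALSE) {
  .znorm_core(x, log2transform)
})

#' @rdname zNormalize
setMethod("zNormalize", "PrognosticCohort", function(x, log2transform = FALSE) {
  out <- .znorm_core(assay(x, "exprs"), log2transform)
  keep <- rownames(out)
  se <- SummarizedExperiment(assays = list(exprs = out),
                             colData = colData(x),
                             rowData = rowData(x)[keep, , drop = FALSE])
  metadata(se) <- metadata(x)
  metadata(se)$normalized <- TRUE
  if (is(x, "SyntheticCohort"))
    new("SyntheticCohort", new("PrognosticCohort", se), truth = x@truth)
  else new("PrognosticCohort", se)
})

#' Collapse probes and z-normalize in one step
#' @param x a \linkS4class{PrognosticCohort}.
#' @param log2transform passed to \code{\link{zNormalize}}.
#' @return The cohort, gene-level and z-normalized.
#' @export
preprocessCohort <- function(x, log2transform = FALSE) {
  if (!isCollapsed(x)) x <- collapseProbes(x)
  zNormalize(x, log2transform = log2transform)
}
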