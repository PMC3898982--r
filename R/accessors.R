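#' @rdname accessors
setMethod("exprValues", "PrognosticCohort", function(x) assay(x, "exprs"))

#' @rdname accessors
setMethod("clinicalTable", "PrognosticCohort", function(x) {
  df <- as.data.frame(colData(x))
  df <- cbind(sample_id = colnames(x), df)
  rownames(df) <- colnames(x)
  df
})

#' @rdname accessors
setMethod("endpointKind", "PrognosticCohort", function(x) metadata(x)$endpointKind)

#' @rdname accessors
setMethod("endpointLabel", "PrognosticCohort", function(x) metadata(x)$endpointLabel)

#' @rdname accessors
setMethod("cohortId", "PrognosticCohort", function(x) metadata(x)$cohortId)

#' @rdname accessors
setMethod("isNormalized", "PrognosticCohort", function(x) isTRUE(metadata(x)$normalized))

#' @rdname accessors
setMethod("isCollapsed", "PrognosticCohort", function(x) isTRUE(metadata(x)$collapsed))

#' @rdname accessors
setMethod("truthRecord", "SyntheticCohort", function(x) x@truth)

#' @rdname accessors
setMethod("sigName", "GeneSignature", function(x) x@name)

#' @rdname accessors
setMethod("sigGenes", "GeneSignature", function(x) x@genes)

#' @rdname accessors
setMethod("scoreValues", "SignatureScore", function(x) x@values)

#' @rdname accessors
setMethod("scoreCoverage", "SignatureScore", function(x) x@coverage)

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec '%s': %d samples, %d genes (%d ccp, %d indep), %s endpoint\n",
              object@cohortId, object@nSamples, object@nGenes,
              object@nCcpGenes, object@nIndepGenes, object@endpointKind))
  cat(sprintf("  loadings U(%.2f, %.2f), noise sd %.2f, beta (prolif %.2f, indep %.2f), seed %d\n",
              object@loadingRange[1], object@loadingRange[2], object@noiseSd,
              object@betaProlif, object@betaIndep, as.integer(object@seed)))
})

setMethod("show", "PrognosticCohort", function(object) {
  cat(sprintf("%s '%s': %d features x %d samples; endpoint %s (%s)%s%s\n",
              class(object), cohortId(object), nrow(object), ncol(object),
              endpointLabel(object), endpointKind(object),
              if (isCollapsed(object)) "; gene-level" else "; probe-level",
              if (isNormalized(object)) "; z-normalized" else ""))
})

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s' (%d genes): %s%s\n", object@name,
              length(object@genes),
              paste(head(object@genes, 8), collapse = ", "),
              if (length(object@genes) > 8) ", ..." else ""))
})

setMethod("show", "SignatureScore", function(object) {
  cat(sprintf("SignatureScore '%s': %d samples, %d genes used (coverage %.2f)\n",
              object@signature, length(object@values), object@nGenesUsed,
              object@coverage))
})

setMethod("show", "PrognosticResult", function(object) {
  lab <- if (object@method == "auc") "AUC" else "HR"
  cat(sprintf("PrognosticResult [%s]: %s = %.3g (95%% CI %.3g-%.3g), p = %.3g, n = %d\n",
              object@method, lab, object@estimate, object@ciLow,
              object@ciHigh, object@p, object@n))
})

setMethod("show", "FittedModel", function(object) {
  if (length(object@terms) == 0) {
    cat("FittedModel: empty (no candidate entered)\n")
  } else {
    cat(sprintf("FittedModel: %d terms (%s), %d events\n",
                length(object@terms),
                paste(names(object@terms), collapse = ", "), object@nEvents))
  }
})

#' Extract estimate, CI and p from a PrognosticResult
#' @param x a \linkS4class{PrognosticResult}.
#' @return A one-row data.frame (estimate, ci_low, ci_high, p, n, method).
#' @export
resultRow <- function(x) {
  stopifnot(is(x, "PrognosticResult"))
  data.frame(estimate = x@estimate, ci_low = x@ciLow, ci_high = x@ciHigh,
             p = x@p, n = x@n, method = x@method)
}
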