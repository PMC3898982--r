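#' @name accessors
#' @title Accessors for ccpmeta classes
#' @param x an object.
#' @description Small accessor layer over the S4 classes: expression matrix,
#'   clinical table, endpoint kind/label, cohort id, preprocessing state,
#'   ground truth, signature contents and score values.
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))
#' @rdname accessors
#' @export
setGeneric("endpointKind", function(x) standardGeneric("endpointKind"))
#' @rdname accessors
#' @export
setGeneric("endpointLabel", function(x) standardGeneric("endpointLabel"))
#' @rdname accessors
#' @export
setGeneric("cohortId", function(x) standardGeneric("cohortId"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("isCollapsed", function(x) standardGeneric("isCollapsed"))
#' @rdname accessors
#' @export
setGeneric("truthRecord", function(x) standardGeneric("truthRecord"))
#' @rdname accessors
#' @export
setGeneric("sigName", function(x) standardGeneric("sigName"))
#' @rdname accessors
#' @export
setGeneric("sigGenes", function(x) standardGeneric("sigGenes"))
#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
#' @rdname accessors
#' @export
setGeneric("scoreCoverage", function(x) standardGeneric("scoreCoverage"))

#' Collapse probe-level rows to one row per gene
#'
#' For genes measured by several probes, the probe with the highest
#' across-sample mean expression is retained; exact ties are broken by input
#' row order. Unmapped features are dropped (with a message); genes missing
#' in more than half of the samples are dropped with a warning.
#'
#' @param x a \linkS4class{PrognosticCohort}, or a numeric matrix.
#' @param ... for the matrix method, \code{geneMap}: a character vector of
#'   gene symbols, one per row (NA = unmapped).
#' @return An object of the same class with one row per gene symbol.
#' @export
setGeneric("collapseProbes", function(x, ...) standardGeneric("collapseProbes"))

#' Z-normalize each gene row across samples
#'
#' Each non-constant row is transformed to mean 0, sd 1 (sample sd, divisor
#' n - 1). Constant rows carry no cross-sample information and are dropped
#' with a warning. Optionally applies log2(x + 1) first (RNA-seq counts).
#'
#' @param x a \linkS4class{PrognosticCohort} or a numeric matrix.
#' @param log2transform apply log2(x + 1) before normalizing (default FALSE;
#'   scores on RNA-seq data are computed on the normalized counts directly
#'   unless this is enabled).
#' @param ... unused.
#' @return Same class as the input, rows z-normalized.
#' @export
setGeneric("zNormalize", function(x, log2transform = FALSE, ...)
  standardGeneric("zNormalize"))

#' Score a gene signature on a normalized expression matrix
#'
#' The score of a sample is the unweighted mean of the z-normalized
#' expression of the signature genes present on the platform; genes absent
#' from the platform are dropped and the achieved coverage is recorded (a
#' warning is emitted below 50\% coverage).
#'
#' @param x a z-normalized \linkS4class{PrognosticCohort} or matrix.
#' @param signature a \linkS4class{GeneSignature}.
#' @param ... unused.
#' @return A \linkS4class{SignatureScore}.
#' @export
setGeneric("signatureScore", function(x, signature, ...)
  standardGeneric("signatureScore"))

#' Test a continuous score against a cohort's clinical endpoint
#'
#' Time-to-event endpoints: Cox proportional-hazards fit with the score as
#' the sole covariate (Efron ties); the hazard ratio per 1-unit score with
#' Wald CI, and the score-test p-value (the continuous-covariate analogue of
#' the log-rank test). Binary endpoints: AUC with a Mann-Whitney p-value and
#' a DeLong confidence interval.
#'
#' @param score a \linkS4class{SignatureScore} or named numeric vector.
#' @param clin a \linkS4class{PrognosticCohort} or a clinical data.frame
#'   (columns \code{time}/\code{event} or \code{label}; rownames or a
#'   \code{sample_id} column give sample ids).
#' @param ... unused.
#' @return A \linkS4class{PrognosticResult}.
#' @export
setGeneric("testContinuous", function(score, clin, ...)
  standardGeneric("testContinuous"))
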