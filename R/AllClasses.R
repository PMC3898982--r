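#' Specification of one synthetic cohort
#'
#' A \code{CohortSpec} fixes every parameter of the synthetic cohort
#' generator: sample and gene counts, the size of the correlated
#' proliferation (ccp) gene block and of the independently prognostic block,
#' factor-loading range and residual noise, log-hazard effects of the two
#' latent factors, the baseline hazard and censoring horizon of the
#' time-to-event endpoint (or the logistic parameters of a binary endpoint),
#' platform-emulation knobs (gene dropout, duplicated probes) and the seed.
#'
#' @slot nSamples,nGenes,nCcpGenes,nIndepGenes counts; the ccp and
#'   independent blocks must fit inside \code{nGenes}.
#' @slot loadingRange length-2 numeric, low/high of the uniform factor
#'   loading distribution.
#' @slot noiseSd residual expression noise standard deviation (> 0).
#' @slot betaProlif,betaIndep log-hazard per unit latent factor.
#' @slot baselineHazard baseline hazard per unit time (> 0).
#' @slot weibullShape Weibull shape of the event-time distribution; 1
#'   (default) gives exponential times, i.e. a constant baseline hazard.
#' @slot censorMax uniform censoring horizon (> 0).
#' @slot endpointKind "time_to_event" or "binary".
#' @slot endpointLabel clinical label of the endpoint ("OS", "DSS", "RFS",
#'   "PFS" for time-to-event; "binary" otherwise).
#' @slot binaryIntercept,binarySlope logistic model of a binary label on the
#'   latent proliferation factor.
#' @slot geneDropoutFrac,probeDupFrac platform emulation: fraction of genes
#'   removed (stratified by gene class), and fraction of retained genes that
#'   get a second, noisier probe mapped to the same symbol.
#' @slot seed integer master seed.
#' @slot cohortId cohort identifier.
#' @name CohortSpec-class
#' @rdname CohortSpec
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nSamples = "numeric", nGenes = "numeric",
    nCcpGenes = "numeric", nIndepGenes = "numeric",
    loadingRange = "numeric", noiseSd = "numeric",
    betaProlif = "numeric", betaIndep = "numeric",
    baselineHazard = "numeric", weibullShape = "numeric",
    censorMax = "numeric",
    endpointKind = "character", endpointLabel = "character",
    binaryIntercept = "numeric", binarySlope = "numeric",
    geneDropoutFrac = "numeric", probeDupFrac = "numeric",
    seed = "numeric", cohortId = "character"))

setValidity("CohortSpec", function(object) {
  bad <- function(field, msg) sprintf("invalid '%s': %s", field, msg)
  errs <- character()
  pos_int <- function(x) length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)
  if (!pos_int(object@nSamples)) errs <- c(errs, bad("nSamples", "must be a positive integer"))
  if (!pos_int(object@nGenes)) errs <- c(errs, bad("nGenes", "must be a positive integer"))
  if (!(length(object@nCcpGenes) == 1 && object@nCcpGenes >= 0)) errs <- c(errs, bad("nCcpGenes", "must be a non-negative count"))
  if (!(length(object@nIndepGenes) == 1 && object@nIndepGenes >= 0)) errs <- c(errs, bad("nIndepGenes", "must be a non-negative count"))
  if (length(errs) == 0 && object@nCcpGenes + object@nIndepGenes > object@nGenes)
    errs <- c(errs, bad("nCcpGenes", "nCcpGenes + nIndepGenes must not exceed nGenes"))
  if (length(object@loadingRange) != 2 || object@loadingRange[1] > object@loadingRange[2])
    errs <- c(errs, bad("loadingRange", "must be (low, high) with low <= high"))
  if (!(length(object@noiseSd) == 1 && object@noiseSd > 0)) errs <- c(errs, bad("noiseSd", "must be > 0"))
  if (!(length(object@baselineHazard) == 1 && object@baselineHazard > 0))
    errs <- c(errs, bad("baselineHazard", "must be > 0"))
  if (!(length(object@weibullShape) == 1 && object@weibullShape > 0))
    errs <- c(errs, bad("weibullShape", "must be > 0"))
  if (!(length(object@censorMax) == 1 && object@censorMax > 0)) errs <- c(errs, bad("censorMax", "must be > 0"))
  if (!object@endpointKind %in% c("time_to_event", "binary"))
    errs <- c(errs, bad("endpointKind", "must be 'time_to_event' or 'binary'"))
  if (!(object@geneDropoutFrac >= 0 && object@geneDropoutFrac <= 1))
    errs <- c(errs, bad("geneDropoutFrac", "must be in [0, 1]"))
  if (!(object@probeDupFrac >= 0 && object@probeDupFrac <= 1))
    errs <- c(errs, bad("probeDupFrac", "must be in [0, 1]"))
  if (!(length(object@seed) == 1 && is.finite(object@seed))) errs <- c(errs, bad("seed", "must be a finite integer"))
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

#' Create a cohort specification
#'
#' Defaults encode the study conditions of the synthetic multi-cohort
#' experiments: 150 patients, a 31-gene proliferation block with loadings
#' uniform on (0.5, 1), expression noise sd 0.7, log-hazard 0.7 per unit
#' latent factor, and a low-event censoring regime (baseline hazard 0.012,
#' uniform censoring on (0, 12); roughly a 10\% event rate) emulating
#' progression-type endpoints.
#'
#' @param nSamples,nGenes,nCcpGenes,nIndepGenes cohort dimensions.
#' @param loadingRange,noiseSd expression model parameters.
#' @param betaProlif,betaIndep log-hazard per unit latent factor.
#' @param baselineHazard,weibullShape,censorMax event-time model.
#' @param endpointKind "time_to_event" or "binary".
#' @param endpointLabel endpoint name stored with the clinical table;
#'   defaults to "OS" for time-to-event and "binary" otherwise.
#' @param binaryIntercept,binarySlope logistic model of a binary label.
#' @param geneDropoutFrac,probeDupFrac platform emulation fractions.
#' @param seed master seed.
#' @param cohortId cohort identifier.
#' @return A validated \linkS4class{CohortSpec}.
#' @examples
#' spec <- cohortSpec(nSamples = 100, nGenes = 200, seed = 7)
#' @export
cohortSpec <- function(nSamples = 150, nGenes = 1000, nCcpGenes = 31,
                       nIndepGenes = 20, loadingRange = c(0.5, 1),
                       noiseSd = 0.7, betaProlif = 0.7, betaIndep = 0.7,
                       baselineHazard = 0.012, weibullShape = 1,
                       censorMax = 12, endpointKind = "time_to_event",
                       endpointLabel = NULL, binaryIntercept = 0,
                       binarySlope = 1, geneDropoutFrac = 0,
                       probeDupFrac = 0, seed = 1, cohortId = "cohort01") {
  if (is.null(endpointLabel))
    endpointLabel <- if (endpointKind == "binary") "binary" else "OS"
  new("CohortSpec",
      nSamples = nSamples, nGenes = nGenes, nCcpGenes = nCcpGenes,
      nIndepGenes = nIndepGenes, loadingRange = as.numeric(loadingRange),
      noiseSd = noiseSd, betaProlif = betaProlif, betaIndep = betaIndep,
      baselineHazard = baselineHazard, weibullShape = weibullShape,
      censorMax = censorMax, endpointKind = endpointKind,
      endpointLabel = endpointLabel, binaryIntercept = binaryIntercept,
      binarySlope = binarySlope, geneDropoutFrac = geneDropoutFrac,
      probeDupFrac = probeDupFrac, seed = seed, cohortId = cohortId)
}

#' Expression and clinical data for one cohort
#'
#' Extends \code{SummarizedExperiment}: the assay holds the (probe- or
#' gene-level) expression matrix, \code{colData} the clinical table (time,
#' event or binary label, covariates), \code{rowData} the feature-to-gene
#' map, and \code{metadata} the cohort id, endpoint kind/label and the
#' preprocessing state (collapsed to genes; z-normalized).
#'
#' @name PrognosticCohort-class
#' @rdname PrognosticCohort
#' @exportClass PrognosticCohort
setClass("PrognosticCohort", contains = "SummarizedExperiment")

setValidity("PrognosticCohort", function(object) {
  errs <- character()
  if (anyDuplicated(colnames(object)))
    errs <- c(errs, "duplicate sample ids")
  if (nrow(object) > 0) {
    m <- assay(object)
    if (any(rowSums(!is.na(m)) == 0)) errs <- c(errs, "expression has an entirely-missing row")
  }
  kind <- metadata(object)$endpointKind
  cd <- colData(object)
  if (identical(kind, "time_to_event") && !all(c("time", "event") %in% colnames(cd)))
    errs <- c(errs, "time-to-event cohort lacks time/event columns")
  if (identical(kind, "binary") && !("label" %in% colnames(cd)))
    errs <- c(errs, "binary cohort lacks label column")
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

#' Build a PrognosticCohort from an expression matrix and clinical table
#'
#' @param exprs numeric matrix, features x samples; rownames are feature ids.
#' @param clinical data.frame with one row per sample. Must contain
#'   \code{time} and \code{event} (time-to-event) or \code{label} (binary);
#'   additional columns are treated as covariates. A \code{sample_id} column,
#'   if present, is matched against \code{colnames(exprs)}; otherwise rows
#'   are taken in column order.
#' @param geneMap optional character vector mapping features to gene symbols
#'   (NA for unmapped features); default assumes rows are already symbols.
#' @param endpointKind "time_to_event" or "binary".
#' @param endpointLabel endpoint name (e.g. "OS", "DSS", "PFS").
#' @param cohortId cohort identifier.
#' @param normalized,collapsed preprocessing state flags.
#' @return A \linkS4class{PrognosticCohort}.
#' @export
prognosticCohort <- function(exprs, clinical, geneMap = NULL,
                             endpointKind = c("time_to_event", "binary"),
                             endpointLabel = NULL, cohortId = "cohort",
                             normalized = FALSE, collapsed = is.null(geneMap)) {
  endpointKind <- match.arg(endpointKind)
  if (is.null(endpointLabel))
    endpointLabel <- if (endpointKind == "binary") "binary" else "OS"
  exprs <- as.matrix(exprs)
  if ("sample_id" %in% colnames(clinical)) {
    idx <- match(colnames(exprs), clinical$sample_id)
    if (anyNA(idx)) stop("clinical table is missing samples present in the expression matrix")
    clinical <- clinical[idx, , drop = FALSE]
  }
  rownames(clinical) <- colnames(exprs)
  rd <- DataFrame(gene_symbol = if (is.null(geneMap)) rownames(exprs) else unname(geneMap),
                  row.names = rownames(exprs))
  se <- SummarizedExperiment(assays = list(exprs = exprs),
                             colData = DataFrame(clinical),
                             rowData = rd)
  metadata(se) <- list(cohortId = cohortId, endpointKind = endpointKind,
                       endpointLabel = endpointLabel,
                       normalized = normalized, collapsed = collapsed)
  new("PrognosticCohort", se)
}

#' A simulated cohort carrying its ground truth
#'
#' Extends \linkS4class{PrognosticCohort} with a \code{truth} record: the
#' per-sample latent proliferation and independent factors, the per-gene
#' class labels (ccp / indep_prognostic / null) and true loadings over the
#' full pre-dropout gene universe, and the generating
#' \linkS4class{CohortSpec}.
#'
#' @slot truth list with elements \code{latentProlif}, \code{latentIndep},
#'   \code{geneClass}, \code{trueLoading}, \code{spec}.
#' @name SyntheticCohort-class
#' @rdname SyntheticCohort
#' @exportClass SyntheticCohort
setClass("SyntheticCohort", contains = "PrognosticCohort",
         representation(truth = "list"))

setValidity("SyntheticCohort", function(object) {
  tr <- object@truth
  need <- c("latentProlif", "latentIndep", "geneClass", "trueLoading", "spec")
  if (!all(need %in% names(tr))) return("truth record incomplete")
  spec <- tr$spec
  cls <- table(factor(tr$geneClass, levels = c("ccp", "indep_prognostic", "null")))
  if (cls[["ccp"]] != spec@nCcpGenes || cls[["indep_prognostic"]] != spec@nIndepGenes)
    return("truth gene_class counts do not match the spec")
  if (length(tr$latentProlif) != ncol(object))
    return("latent factor length does not match sample count")
  TRUE
})

#' A named gene set scored as a mean of normalized expression
#'
#' @slot name signature name.
#' @slot genes unique, non-empty character vector of gene symbols.
#' @name GeneSignature-class
#' @rdname GeneSignature
#' @exportClass GeneSignature
setClass("GeneSignature",
         representation(name = "character", genes = "character"))

setValidity("GeneSignature", function(object) {
  if (length(object@genes) == 0) return("signature is empty")
  if (anyDuplicated(object@genes)) return("signature genes are not unique")
  TRUE
})

#' Create a gene signature
#' @param name signature name.
#' @param genes character vector of gene symbols (duplicates removed).
#' @return A \linkS4class{GeneSignature}.
#' @export
geneSignature <- function(name, genes)
  new("GeneSignature", name = name, genes = unique(as.character(genes)))

#' Per-sample signature scores
#'
#' @slot values named numeric vector of per-sample scores.
#' @slot nGenesUsed number of signature genes found on the platform.
#' @slot coverage fraction of signature genes present, in (0, 1].
#' @slot signature name of the scored signature.
#' @name SignatureScore-class
#' @rdname SignatureScore
#' @exportClass SignatureScore
setClass("SignatureScore",
         representation(values = "numeric", nGenesUsed = "integer",
                        coverage = "numeric", signature = "character"))

setValidity("SignatureScore", function(object) {
  if (is.null(names(object@values))) return("scores must carry sample ids as names")
  if (!(object@coverage > 0 && object@coverage <= 1)) return("coverage must be in (0, 1]")
  TRUE
})

#' Result of a single prognostic test
#'
#' The universal result record: a hazard ratio (per 1-unit increase of the
#' predictor) or an AUC, its confidence interval, the p-value, the sample
#' size used and a method tag (\code{cox_continuous}, \code{auc},
#' \code{logrank_groups} or \code{lrt}).
#'
#' @slot estimate hazard ratio or AUC.
#' @slot ciLow,ciHigh confidence bounds (may be NA when undefined).
#' @slot p p-value.
#' @slot n samples used.
#' @slot method method tag.
#' @name PrognosticResult-class
#' @rdname PrognosticResult
#' @exportClass PrognosticResult
setClass("PrognosticResult",
         representation(estimate = "numeric", ciLow = "numeric",
                        ciHigh = "numeric", p = "numeric", n = "integer",
                        method = "character"))

setValidity("PrognosticResult", function(object) {
  if (!object@method %in% c("cox_continuous", "auc", "logrank_groups", "lrt"))
    return("unknown method tag")
  if (!is.na(object@p) && (object@p < 0 || object@p > 1)) return("p outside [0, 1]")
  est <- object@estimate
  if (!is.na(est)) {
    if (object@method == "auc" && (est < 0 || est > 1)) return("AUC outside [0, 1]")
    if (object@method != "auc" && est <= 0) return("hazard ratio must be > 0")
    if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
        !(object@ciLow <= est && est <= object@ciHigh))
      return("estimate outside its confidence interval")
  }
  TRUE
})

.prognosticResult <- function(estimate, ciLow, ciHigh, p, n, method)
  new("PrognosticResult", estimate = as.numeric(estimate),
      ciLow = as.numeric(ciLow), ciHigh = as.numeric(ciHigh),
      p = as.numeric(p), n = as.integer(n), method = method)

#' A fitted multivariate survival model with its selection trace
#'
#' @slot terms named vector of log-hazard coefficients of the final fit.
#' @slot loglik partial log-likelihood of the final fit.
#' @slot nEvents number of events.
#' @slot selectionTrace data.frame (term, p_at_entry) in entry order.
#' @slot fit the underlying \code{coxph} fit (or NULL when no term entered).
#' @name FittedModel-class
#' @rdname FittedModel
#' @exportClass FittedModel
setClass("FittedModel",
         representation(terms = "numeric", loglik = "numeric",
                        nEvents = "integer", selectionTrace = "data.frame",
                        fit = "ANY"))

setValidity("FittedModel", function(object) {
  if (!all(object@selectionTrace$term %in% names(object@terms)))
    return("selection trace contains terms absent from the final fit")
  TRUE
})
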