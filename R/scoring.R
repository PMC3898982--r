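.score_core <- function(m, signature, warn_coverage = 0.5) {
  genes <- sigGenes(signature)
  present <- intersect(genes, rownames(m))
  if (length(present) == 0) stop("signature absent from platform")
  coverage <- length(present) / length(genes)
  if (coverage < warn_coverage)
    warning(sprintf("signature '%s': only %d of %d genes on the platform (coverage %.2f)",
                    sigName(signature), length(present), length(genes), coverage))
  vals <- colMeans(m[present, , drop = FALSE], na.rm = TRUE)
  new("SignatureScore", values = vals, nGenesUsed = length(present),
      coverage = coverage, signature = sigName(signature))
}

#' @rdname signatureScore
setMethod("signatureScore", c("matrix", "GeneSignature"),
          function(x, signature, ...) .score_core(x, signature))

#' @rdname signatureScore
setMethod("signatureScore", c("PrognosticCohort", "GeneSignature"),
          function(x, signature, ...) {
  if (!isNormalized(x))
    stop("cohort must be z-normalized before scoring (see zNormalize)")
  .score_core(assay(x, "exprs"), signature)
})

#' The refined 12-gene proliferation signature
#'
#' The published refined signature, shipped under its published name
#' "CCP-12". Note the accompanying text prints 11 gene symbols for this
#' signature; the 11 printed genes are shipped as-is (the full supplementary
#' membership list is not reproduced here).
#'
#' @return A \linkS4class{GeneSignature}.
#' @export
ccp12Signature <- function() {
  geneSignature("CCP-12",
                c("BIRC5", "BUB1B", "CDC20", "CDCA8", "CENPF", "FOXM1",
                  "KIF11", "NUSAP1", "PTTG1", "TK1", "TOP2A"))
}
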