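# Score-adjustment analysis: residualize signature genes against the CCP
# score (vs a constant-only negative control), re-score, re-test, and
# classify each signature x cohort as lost / retained / not prognostic.

#' Residualize gene rows against a score
#'
#' Replaces each listed gene's expression row by the residuals of its
#' least-squares regression on (intercept, score), removing the component of
#' the gene's variation that is linear in the score. Untouched rows pass
#' through. Residuals are left unscaled (the scale of a single covariate
#' does not change its proportional-hazards p-value).
#'
#' @param m numeric matrix (genes x samples), normally z-normalized.
#' @param score a \linkS4class{SignatureScore} or numeric vector aligned
#'   with the matrix columns.
#' @param genes gene symbols to adjust (rows absent from the matrix are
#'   ignored).
#' @return The matrix with the listed rows residualized.
#' @export
adjustForScore <- function(m, score, genes) {
  s <- if (is(score, "SignatureScore")) scoreValues(score) else score
  if (!is.null(names(s)) && !is.null(colnames(m))) s <- s[colnames(m)]
  if (length(s) != ncol(m)) stop("score and matrix columns differ in length")
  if (sd(s) == 0) stop("constant score")
  rows <- intersect(genes, rownames(m))
  if (length(rows) == 0) return(m)
  cs <- s - mean(s)
  X <- m[rows, , drop = FALSE]
  b <- as.numeric(X %*% cs) / sum(cs^2)
  m[rows, ] <- (X - rowMeans(X)) - tcrossprod(b, cs)
  m
}

#' Constant-only "negative control" adjustment
#'
#' Subtracts each listed gene's mean (intercept-only regression): the
#' control arm of the adjustment analysis, which preserves all prognostic
#' signal up to centering.
#'
#' @inheritParams adjustForScore
#' @return The matrix with the listed rows centered.
#' @export
adjustControl <- function(m, genes) {
  rows <- intersect(genes, rownames(m))
  if (length(rows) == 0) return(m)
  X <- m[rows, , drop = FALSE]
  m[rows, ] <- X - rowMeans(X)
  m
}

#' Run the full adjustment analysis over signatures and cohorts
#'
#' For each (signature, cohort) pair: computes the CCP score from all CCP
#' genes present on the cohort's platform; builds a control-adjusted
#' (centered) and a CCP-adjusted (residualized) expression matrix for the
#' signature's genes; re-scores the signature as the unweighted mean of the
#' adjusted rows; tests both scores against the cohort's endpoint; and
#' classifies the pair as \code{lost} (prognostic in the control,
#' p < alpha, but not after CCP adjustment), \code{retained} (prognostic in
#' both) or \code{not_prognostic} (not prognostic in the control).
#'
#' @param signatures list of \linkS4class{GeneSignature} objects.
#' @param cohorts list of z-normalized \linkS4class{PrognosticCohort}s.
#' @param ccp the \linkS4class{GeneSignature} defining the CCP score.
#' @param alpha significance threshold on both sides of the classification
#'   (default 0.05).
#' @return List with \code{outcomes} (data.frame: signature, cohort,
#'   control_p, adjusted_p, category; pairs where the signature is absent
#'   from the platform are skipped with a message) and \code{summary}
#'   (per-signature lost / retained / not_prognostic counts and loss
#'   percentage).
#' @export
runAdjustmentAnalysis <- function(signatures, cohorts, ccp, alpha = 0.05) {
  if (length(signatures) == 0 || length(cohorts) == 0)
    stop("need at least one signature and one cohort")
  rows <- list()
  for (co in cohorts) {
    if (!isNormalized(co)) stop("cohorts must be z-normalized")
    m <- assay(co, "exprs")
    ccp_score <- tryCatch(signatureScore(co, ccp), error = function(e) NULL)
    if (is.null(ccp_score)) {
      message("cohort ", cohortId(co), ": CCP signature absent; skipped")
      next
    }
    clin <- clinicalTable(co)
    for (sig in signatures) {
      present <- intersect(sigGenes(sig), rownames(m))
      if (length(present) == 0) {
        message("signature ", sigName(sig), " absent from ", cohortId(co),
                "; skipped")
        next
      }
      ctrl <- adjustControl(m, present)
      adj <- adjustForScore(m, ccp_score, present)
      s_ctrl <- setNames(colMeans(ctrl[present, , drop = FALSE]), colnames(m))
      s_adj <- setNames(colMeans(adj[present, , drop = FALSE]), colnames(m))
      p_ctrl <- tryCatch(.test_continuous_core(s_ctrl, co)@p,
                         error = function(e) NA_real_)
      p_adj <- tryCatch(.test_continuous_core(s_adj, co)@p,
                        error = function(e) NA_real_)
      if (is.na(p_ctrl)) next
      category <- if (p_ctrl >= alpha) "not_prognostic"
        else if (!is.na(p_adj) && p_adj < alpha) "retained" else "lost"
      rows[[length(rows) + 1]] <- data.frame(
        signature = sigName(sig), cohort = cohortId(co),
        control_p = p_ctrl, adjusted_p = p_adj, category = category)
    }
  }
  outcomes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(signature = character(), cohort = character(),
               control_p = numeric(), adjusted_p = numeric(),
               category = character())
  summ <- do.call(rbind, lapply(split(outcomes, outcomes$signature), function(d)
    data.frame(signature = d$signature[1],
               n_lost = sum(d$category == "lost"),
               n_retained = sum(d$category == "retained"),
               n_not_prognostic = sum(d$category == "not_prognostic"),
               loss_pct = lossPercentage(d))))
  rownames(summ) <- NULL
  list(outcomes = outcomes, summary = summ)
}

#' Percentage of prognostic cohorts in which a signature's value is lost
#'
#' 100 * lost / (lost + retained), over the cohorts where the signature was
#' prognostic in the control arm; \code{NA} (not applicable) when the
#' signature was prognostic nowhere.
#'
#' @param outcomes data.frame of adjustment outcomes for one signature (a
#'   \code{category} column with values lost / retained / not_prognostic).
#' @return Numeric percentage, or \code{NA_real_}.
#' @export
lossPercentage <- function(outcomes) {
  stopifnot(nrow(outcomes) >= 1)
  lost <- sum(outcomes$category == "lost")
  retained <- sum(outcomes$category == "retained")
  if (lost + retained == 0) return(NA_real_)
  100 * lost / (lost + retained)
}
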