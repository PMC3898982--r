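# Survival / association machinery: endpoint selection, univariate tests,
# per-gene screening, Kaplan-Meier tertiles, forward-stepwise final models
# and nested added-value tests.

#' Select the analysis endpoint from the available kinds
#'
#' Time-to-event endpoints are preferred in the order DSS > OS > RFS (> PFS);
#' a binary endpoint (progressor / recurrence / nodal status, analysed by
#' AUC) is used only when no time-to-event endpoint exists.
#'
#' @param available character vector of endpoint kinds (subset of
#'   DSS, OS, RFS, PFS, binary).
#' @return The selected endpoint kind.
#' @examples
#' selectEndpoint(c("OS", "DSS"))  # "DSS"
#' @export
selectEndpoint <- function(available) {
  if (length(available) == 0) stop("no endpoints available")
  pri <- c("DSS", "OS", "RFS", "PFS")
  hit <- pri[pri %in% available]
  if (length(hit)) return(hit[[1]])
  if ("binary" %in% available) return("binary")
  stop("unknown endpoint kind(s): ", paste(available, collapse = ", "))
}

# normalize clinical input (cohort or data.frame) to a common list form
.clin_parts <- function(clin) {
  if (is(clin, "PrognosticCohort")) {
    df <- clinicalTable(clin)
    kind <- endpointKind(clin)
  } else {
    df <- as.data.frame(clin)
    if (!"sample_id" %in% colnames(df)) {
      if (is.null(rownames(df))) stop("clinical table needs sample ids")
      df$sample_id <- rownames(df)
    }
    kind <- if (all(c("time", "event") %in% colnames(df)) &&
                any(!is.na(df$time))) "time_to_event" else "binary"
  }
  list(ids = as.character(df$sample_id), kind = kind, df = df)
}

# single-covariate Cox fit via the fitting engine directly (fast path used
# by per-gene screens and subset resampling); Efron ties
.fast_cox <- function(x, y) {
  fit <- tryCatch(
    coxph.fit(matrix(x, ncol = 1), y, strata = NULL, offset = NULL,
              init = NULL, control = coxph.control(), weights = NULL,
              method = "efron", rownames = NULL),
    error = function(e) NULL)
  if (is.null(fit) || is.na(fit$coefficients[1])) return(NULL)
  beta <- unname(fit$coefficients[1])
  se <- sqrt(fit$var[1, 1])
  list(beta = beta, se = se, score_stat = fit$score,
       p_score = pchisq(fit$score, 1, lower.tail = FALSE),
       loglik = fit$loglik)
}

# AUC by the rank (Mann-Whitney) formula: wins + half-ties over all pairs
.auc_rank <- function(s, label) {
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  r <- rank(s)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.test_continuous_core <- function(s, clin) {
  cp <- .clin_parts(clin)
  ids <- intersect(names(s), cp$ids)
  dropped <- length(s) - length(ids)
  if (dropped > 0) message(dropped, " sample(s) without clinical data dropped")
  if (length(ids) < 3) stop("fewer than 3 samples after joining score and clinical data")
  df <- cp$df[match(ids, cp$ids), , drop = FALSE]
  s <- s[ids]
  if (sd(s) == 0) stop("constant score")
  if (cp$kind == "time_to_event") {
    ok <- !is.na(df$time) & !is.na(df$event)
    df <- df[ok, , drop = FALSE]; s <- s[ok]
    if (sum(df$event) == 0) stop("no events")
    fit <- coxph(Surv(df$time, df$event) ~ s, ties = "efron")
    beta <- unname(coef(fit)[1]); se <- sqrt(fit$var[1, 1])
    sm <- summary(fit)
    p <- unname(sm$sctest["pvalue"])
    .prognosticResult(exp(beta), exp(beta - qnorm(0.975) * se),
                      exp(beta + qnorm(0.975) * se), p, nrow(df),
                      "cox_continuous")
  } else {
    ok <- !is.na(df$label)
    df <- df[ok, , drop = FALSE]; s <- s[ok]
    if (length(unique(df$label)) < 2) stop("binary endpoint has a single class")
    auc <- .auc_rank(s, df$label)
    p <- suppressWarnings(
      wilcox.test(s[df$label == 1], s[df$label == 0])$p.value)
    ci <- tryCatch(suppressWarnings(
      as.numeric(pROC::ci.auc(response = df$label, predictor = s,
                              direction = "<", levels = c(0, 1),
                              method = "delong", quiet = TRUE))),
      error = function(e) rep(NA_real_, 3))
    .prognosticResult(auc, max(0, ci[1]), min(1, ci[3]), p, nrow(df), "auc")
  }
}

#' @rdname testContinuous
setMethod("testContinuous", c("SignatureScore", "ANY"),
          function(score, clin, ...) .test_continuous_core(scoreValues(score), clin))

#' @rdname testContinuous
setMethod("testContinuous", c("numeric", "ANY"),
          function(score, clin, ...) {
  if (is.null(names(score))) stop("score vector must carry sample ids as names")
  .test_continuous_core(score, clin)
})

#' Screen every gene for association with outcome
#'
#' Runs the univariate continuous test (Cox score test for time-to-event
#' endpoints, AUC / Mann-Whitney for binary endpoints) on each gene row of a
#' z-normalized cohort and returns the genes with p below \code{alpha}.
#'
#' @param cohort a z-normalized \linkS4class{PrognosticCohort}.
#' @param alpha significance threshold for the screen (default 0.01).
#' @return Character vector of prognostic gene symbols, with the full
#'   per-gene result table in \code{attr(, "results")} (columns gene,
#'   estimate, p, method; genes whose test failed are excluded and counted
#'   in \code{attr(, "n_excluded")}).
#' @export
geneScreen <- function(cohort, alpha = 0.01) {
  stopifnot(is(cohort, "PrognosticCohort"))
  if (!isNormalized(cohort)) stop("cohort must be z-normalized before screening")
  m <- assay(cohort, "exprs")
  cd <- clinicalTable(cohort)
  kind <- endpointKind(cohort)
  if (kind == "time_to_event") {
    ok <- !is.na(cd$time) & !is.na(cd$event)
    y <- Surv(cd$time[ok], cd$event[ok])
    if (sum(cd$event[ok]) == 0) stop("no events")
    m <- m[, ok, drop = FALSE]
    res <- lapply(seq_len(nrow(m)), function(i) {
      f <- .fast_cox(m[i, ], y)
      if (is.null(f)) return(NULL)
      data.frame(gene = rownames(m)[i], estimate = exp(f$beta),
                 p = f$p_score, method = "cox_continuous")
    })
  } else {
    ok <- !is.na(cd$label)
    lab <- cd$label[ok]
    m <- m[, ok, drop = FALSE]
    res <- lapply(seq_len(nrow(m)), function(i) {
      s <- m[i, ]
      p <- tryCatch(suppressWarnings(
        wilcox.test(s[lab == 1], s[lab == 0])$p.value),
        error = function(e) NA_real_)
      if (is.na(p)) return(NULL)
      data.frame(gene = rownames(m)[i], estimate = .auc_rank(s, lab),
                 p = p, method = "auc")
    })
  }
  failed <- sum(vapply(res, is.null, TRUE))
  if (failed > 0) message(failed, " gene(s) excluded (test failed)")
  tab <- do.call(rbind, res)
  hits <- tab$gene[tab$p < alpha]
  structure(hits, results = tab, alpha = alpha, n_excluded = failed)
}

#' Kaplan-Meier curves for score tertiles
#'
#' Splits samples at the empirical 33.3\% and 66.7\% score quantiles and
#' returns the product-limit curves per stratum. The reported p-value is
#' that of the continuous score (Cox score test), not a 3-group log-rank.
#'
#' @param score a \linkS4class{SignatureScore} or named numeric vector.
#' @param clin a \linkS4class{PrognosticCohort} or clinical data.frame with
#'   a time-to-event endpoint.
#' @return List with elements \code{strata} (factor low/mid/high),
#'   \code{thresholds}, \code{curves} (data.frame: stratum, time, n_risk,
#'   n_event, surv), and \code{result} (the continuous-score
#'   \linkS4class{PrognosticResult}).
#' @export
kmTertiles <- function(score, clin) {
  s <- if (is(score, "SignatureScore")) scoreValues(score) else score
  cp <- .clin_parts(clin)
  if (cp$kind != "time_to_event") stop("KM tertiles need a time-to-event endpoint")
  ids <- intersect(names(s), cp$ids)
  if (length(ids) < 6) stop("need at least 6 samples")
  df <- cp$df[match(ids, cp$ids), , drop = FALSE]
  s <- s[ids]
  q <- quantile(s, c(1/3, 2/3), names = FALSE)
  if (q[1] == q[2])
    stop("tied scores make the 33.3%/66.7% quantiles equal; strata undefined")
  strata_f <- cut(s, c(-Inf, q, Inf), labels = c("low", "mid", "high"))
  if (any(table(strata_f) == 0)) {
    empty <- names(which(table(strata_f) == 0))[1]
    stop(sprintf("score ties leave the '%s' tertile empty", empty))
  }
  sf <- survfit(Surv(df$time, df$event) ~ strata_f)
  stratum <- rep(sub("^strata_f=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(stratum = stratum, time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       surv = sf$surv)
  res <- .test_continuous_core(s, df)
  list(strata = strata_f, thresholds = q, curves = curves, result = res)
}

#' Forward-stepwise Cox model ("final model")
#'
#' Starting from the empty model, repeatedly adds the candidate with the
#' smallest Wald p-value, while that p-value is below \code{enterP}; there is
#' no removal step. Ties are broken by the smaller p then by term name. The
#' entry order and p-at-entry are recorded in the selection trace.
#'
#' @param clin a \linkS4class{PrognosticCohort} or clinical data.frame with
#'   a time-to-event endpoint.
#' @param candidates data.frame of numeric candidate predictors (rows must
#'   match the clinical samples; rownames or a sample_id attribute align
#'   them, otherwise row order is used).
#' @param enterP entry threshold (default 0.05).
#' @return A \linkS4class{FittedModel}; empty (no terms) when no candidate
#'   ever qualifies.
#' @export
stepwiseFinalModel <- function(clin, candidates, enterP = 0.05) {
  cp <- .clin_parts(clin)
  if (cp$kind != "time_to_event") stop("stepwise selection needs a time-to-event endpoint")
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) == 0) stop("no candidate predictors")
  df <- cp$df
  if (!is.null(rownames(candidates)) &&
      all(rownames(candidates) %in% cp$ids) &&
      !identical(rownames(candidates), as.character(seq_len(nrow(candidates))))) {
    ids <- intersect(cp$ids, rownames(candidates))
    df <- df[match(ids, cp$ids), , drop = FALSE]
    candidates <- candidates[ids, , drop = FALSE]
  } else if (nrow(candidates) != nrow(df)) {
    stop("candidates and clinical table have different sample counts")
  }
  ok <- !is.na(df$time) & !is.na(df$event) & complete.cases(candidates)
  df <- df[ok, , drop = FALSE]; candidates <- candidates[ok, , drop = FALSE]
  if (sum(df$event) < 5) stop("fewer than 5 events")
  y <- Surv(df$time, df$event)

  selected <- character()
  trace <- data.frame(term = character(), p_at_entry = numeric())
  repeat {
    remaining <- setdiff(colnames(candidates), selected)
    if (length(remaining) == 0) break
    entry_p <- vapply(remaining, function(term) {
      X <- as.matrix(candidates[, c(selected, term), drop = FALSE])
      fit <- tryCatch(suppressWarnings(coxph(y ~ X, ties = "efron")),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      co <- coef(fit); se <- sqrt(diag(fit$var))
      j <- length(co)
      if (is.na(co[j])) return(NA_real_)
      2 * pnorm(-abs(co[j] / se[j]))
    }, 0)
    entry_p <- entry_p[order(entry_p, names(entry_p))]  # ties: smallest p then name
    if (all(is.na(entry_p)) || entry_p[1] >= enterP) break
    best <- names(entry_p)[1]
    selected <- c(selected, best)
    trace <- rbind(trace, data.frame(term = best, p_at_entry = unname(entry_p[1])))
  }

  if (length(selected) == 0) {
    message("no candidate entered the model at p < ", enterP)
    return(new("FittedModel", terms = setNames(numeric(0), character(0)),
               loglik = NA_real_, nEvents = as.integer(sum(df$event)),
               selectionTrace = trace, fit = NULL))
  }
  X <- as.matrix(candidates[, selected, drop = FALSE])
  fit <- coxph(y ~ X, ties = "efron")
  terms <- setNames(as.numeric(coef(fit)), selected)
  new("FittedModel", terms = terms, loglik = fit$loglik[2],
      nEvents = as.integer(sum(df$event)), selectionTrace = trace, fit = fit)
}

#' Likelihood-ratio test for the added value of one predictor
#'
#' Fits the Cox model with the base predictors, then with the base
#' predictors plus the addition, and compares them by a 1-df likelihood
#' ratio test. This is the "does the score add prognostic value to the best
#' available clinical model" test.
#'
#' @param clin a \linkS4class{PrognosticCohort} or clinical data.frame with
#'   a time-to-event endpoint.
#' @param base data.frame of base predictors (may be NULL or zero-column for
#'   the null base model).
#' @param addition numeric vector (or single-column data.frame), the
#'   predictor whose added value is tested.
#' @return A \linkS4class{PrognosticResult} with \code{method = "lrt"}: the
#'   estimate is the addition's hazard ratio in the full model, the p-value
#'   the 1-df LRT p.
#' @export
addedValueTest <- function(clin, base, addition) {
  cp <- .clin_parts(clin)
  if (cp$kind != "time_to_event") stop("added-value test needs a time-to-event endpoint")
  if (is.data.frame(addition)) addition <- addition[[1]]
  df <- cp$df
  n <- nrow(df)
  if (!is.null(base)) base <- as.data.frame(base)
  if (!is.null(base) && ncol(base) > 0 && nrow(base) != n)
    stop("base predictors and clinical table differ in sample count")
  if (length(addition) != n) stop("addition and clinical table differ in sample count")
  ok <- !is.na(df$time) & !is.na(df$event) & !is.na(addition)
  if (!is.null(base) && ncol(base) > 0) ok <- ok & complete.cases(base)
  df <- df[ok, , drop = FALSE]; addition <- addition[ok]
  if (!is.null(base)) base <- base[ok, , drop = FALSE]
  if (sum(df$event) == 0) stop("no events")
  y <- Surv(df$time, df$event)

  has_base <- !is.null(base) && ncol(base) > 0
  Xfull <- cbind(if (has_base) as.matrix(base), addition = addition)
  fit1 <- tryCatch(suppressWarnings(coxph(y ~ Xfull, ties = "efron")),
                   error = function(e) stop("full model failed to converge: ",
                                            conditionMessage(e)))
  ll1 <- fit1$loglik[2]
  ll0 <- if (has_base) {
    fit0 <- suppressWarnings(coxph(y ~ as.matrix(base), ties = "efron"))
    fit0$loglik[2]
  } else fit1$loglik[1]
  lrt <- max(0, 2 * (ll1 - ll0))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  j <- ncol(Xfull)
  beta <- coef(fit1)[j]; se <- sqrt(diag(fit1$var))[j]
  if (is.na(beta)) {
    est <- NA_real_; lo <- NA_real_; hi <- NA_real_
  } else {
    est <- exp(beta)
    lo <- exp(beta - qnorm(0.975) * se); hi <- exp(beta + qnorm(0.975) * se)
  }
  .prognosticResult(est, lo, hi, p, nrow(df), "lrt")
}

#' @importFrom stats pnorm coef
NULL
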