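#' Simulate one cohort with known ground truth
#'
#' Generates an expression matrix and clinical table with the structure the
#' cross-cohort analyses assume. Per sample, a latent proliferation factor P
#' and an independent prognostic factor Q are drawn standard normal. A ccp
#' gene g has expression \code{mu_g + lambda_g * P + eps}, with baseline
#' brightness \code{mu_g ~ N(7, 1)}, loading \code{lambda_g} uniform on
#' \code{loadingRange} and noise \code{eps ~ N(0, noiseSd)}; independently
#' prognostic genes load on Q the same way; null genes are baseline plus
#' noise. Time-to-event outcomes follow a proportional-hazards model with
#' linear predictor \code{betaProlif * P + betaIndep * Q} (Weibull baseline,
#' shape 1 = exponential), censored uniformly on (0, censorMax); binary
#' labels are Bernoulli(plogis(binaryIntercept + binarySlope * P)). Clinical
#' covariates: stage and grade are coarsened (thresholded, noisy) correlates
#' of P, age ~ N(65, 10), gender ~ Bernoulli(0.5).
#'
#' Platform emulation: a fraction \code{geneDropoutFrac} of genes is removed,
#' stratified within each gene class (so a cohort retains exactly
#' \code{round((1 - frac) * nCcpGenes)} ccp genes); a fraction
#' \code{probeDupFrac} of the retained genes gets a second probe mapped to
#' the same symbol, 0.5 units dimmer with 1.5x the noise sd, so probe
#' collapsing by maximal mean has a deterministic expected winner.
#'
#' The RNG state is restored on exit; the same spec (same seed) reproduces
#' the cohort bit-identically.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return A \linkS4class{SyntheticCohort}.
#' @examples
#' co <- simulateCohort(cohortSpec(nSamples = 60, nGenes = 100, seed = 3))
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  with_seed(as.integer(spec@seed), .simulate_cohort_impl(spec))
}

.simulate_cohort_impl <- function(spec) {
  n <- as.integer(spec@nSamples); G <- as.integer(spec@nGenes)
  nC <- as.integer(spec@nCcpGenes); nI <- as.integer(spec@nIndepGenes)
  nN <- G - nC - nI
  symbols <- c(sprintf("CCP%03d", seq_len(nC)),
               sprintf("IPG%03d", seq_len(nI)),
               sprintf("NUL%04d", seq_len(nN)))
  gclass <- rep(c("ccp", "indep_prognostic", "null"), c(nC, nI, nN))
  ids <- sprintf("%s_S%04d", spec@cohortId, seq_len(n))

  P <- rnorm(n); Q <- rnorm(n)
  names(P) <- names(Q) <- ids
  lam <- numeric(G)
  lam[gclass == "ccp"] <- runif(nC, spec@loadingRange[1], spec@loadingRange[2])
  lam[gclass == "indep_prognostic"] <- runif(nI, spec@loadingRange[1], spec@loadingRange[2])
  mu <- rnorm(G, mean = 7, sd = 1)
  factor_of <- rbind(ccp = P, indep_prognostic = Q,
                     null = rep(0, n))[gclass, , drop = FALSE]
  X <- mu + lam * factor_of + matrix(rnorm(G * n, 0, spec@noiseSd), G, n)
  dimnames(X) <- list(symbols, ids)

  # clinical outcome
  if (spec@endpointKind == "time_to_event") {
    lp <- spec@betaProlif * P + spec@betaIndep * Q
    e <- rexp(n, 1)
    tt <- (e / (spec@baselineHazard * exp(lp)))^(1 / spec@weibullShape)
    cc <- runif(n, 0, spec@censorMax)
    time <- pmin(tt, cc)
    event <- as.integer(tt <= cc)
    label <- rep(NA_integer_, n)
  } else {
    time <- rep(NA_real_, n); event <- rep(NA_integer_, n)
    label <- rbinom(n, 1, plogis(spec@binaryIntercept + spec@binarySlope * P))
  }
  age <- round(rnorm(n, 65, 10), 1)
  gender <- rbinom(n, 1, 0.5)
  stage <- as.integer(P + rnorm(n, 0, 1) > 0)
  grade <- as.integer(P + rnorm(n, 0, 1.5) > 0.25)
  clinical <- data.frame(sample_id = ids, endpoint_kind = spec@endpointLabel,
                         time = time, event = event, label = label,
                         stage = stage, grade = grade, age = age,
                         gender = gender, stringsAsFactors = FALSE)

  # platform emulation: stratified dropout, then duplicated probes
  keep <- rep(TRUE, G)
  if (spec@geneDropoutFrac > 0) {
    for (cl in c("ccp", "indep_prognostic", "null")) {
      idx <- which(gclass == cl)
      ndrop <- round(spec@geneDropoutFrac * length(idx))
      if (ndrop > 0) keep[sample(idx, ndrop)] <- FALSE
    }
  }
  kept <- which(keep)
  probe_mat <- X[kept, , drop = FALSE]
  probe_sym <- symbols[kept]
  rownames(probe_mat) <- paste0(probe_sym, "_p1")
  if (spec@probeDupFrac > 0 && length(kept) > 0) {
    ndup <- round(spec@probeDupFrac * length(kept))
    if (ndup > 0) {
      dup <- sort(sample(seq_along(kept), ndup))
      gidx <- kept[dup]
      dup_mat <- (mu[gidx] - 0.5) + lam[gidx] * factor_of[gidx, , drop = FALSE] +
        matrix(rnorm(length(gidx) * n, 0, 1.5 * spec@noiseSd), length(gidx), n)
      rownames(dup_mat) <- paste0(symbols[gidx], "_p2")
      probe_mat <- rbind(probe_mat, dup_mat)
      probe_sym <- c(probe_sym, symbols[gidx])
    }
  }

  co <- prognosticCohort(probe_mat, clinical, geneMap = probe_sym,
                         endpointKind = spec@endpointKind,
                         endpointLabel = spec@endpointLabel,
                         cohortId = spec@cohortId, collapsed = FALSE)
  rowData(co)$gene_class <- gclass[match(probe_sym, symbols)]
  rowData(co)$true_loading <- lam[match(probe_sym, symbols)]
  truth <- list(latentProlif = P, latentIndep = Q,
                geneClass = setNames(gclass, symbols),
                trueLoading = setNames(lam, symbols), spec = spec)
  out <- new("SyntheticCohort", co, truth = truth)
  validObject(out)
  out
}

#' Simulate several independent cohorts sharing one gene-symbol universe
#'
#' Cohorts are generated independently; each spec's seed is offset by the
#' cohort's position in the list (seed + index), so two specs with the same
#' master seed still produce distinct cohorts. Gene symbols are assigned by
#' class and index, so signatures transfer across cohorts.
#'
#' @param specs non-empty list of \linkS4class{CohortSpec} objects.
#' @return Named list of \linkS4class{SyntheticCohort} objects.
#' @export
simulateMultiCohort <- function(specs) {
  if (length(specs) == 0) stop("'specs' must contain at least one CohortSpec")
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    stopifnot(is(spec, "CohortSpec"))
    if (identical(spec@cohortId, "cohort01") && i > 1)
      spec@cohortId <- sprintf("cohort%02d", i)
    spec@seed <- spec@seed + i
    out[[i]] <- simulateCohort(spec)
  }
  names(out) <- vapply(out, cohortId, "")
  out
}

#' The true proliferation signature of a synthetic cohort
#' @param x a \linkS4class{SyntheticCohort} (or its truth record).
#' @param name signature name.
#' @return A \linkS4class{GeneSignature} of the ccp-class genes.
#' @export
truthCcpSignature <- function(x, name = "CCP-true") {
  tr <- if (is(x, "SyntheticCohort")) truthRecord(x) else x
  geneSignature(name, names(tr$geneClass)[tr$geneClass == "ccp"])
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the expression matrix (TSV, rows = probes, columns = samples), the
#' clinical table (TSV), the probe-to-gene map (two-column TSV), the truth
#' sidecar (per-sample latent factors; per-gene class and loading) and a GMT
#' file with the true ccp gene set.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "PrognosticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- cohortId(cohort)
  paths <- c(expression = file.path(dir, paste0(id, "_expression.tsv")),
             clinical = file.path(dir, paste0(id, "_clinical.tsv")),
             gene_map = file.path(dir, paste0(id, "_gene_map.tsv")))
  writeExpressionTSV(exprValues(cohort), paths[["expression"]])
  write.table(clinicalTable(cohort), paths[["clinical"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(feature_id = rownames(cohort),
                         gene_symbol = rowData(cohort)$gene_symbol),
              paths[["gene_map"]], sep = "\t", quote = FALSE, row.names = FALSE)
  if (is(cohort, "SyntheticCohort")) {
    tr <- truthRecord(cohort)
    paths <- c(paths,
               truth_samples = file.path(dir, paste0(id, "_truth_samples.tsv")),
               truth_genes = file.path(dir, paste0(id, "_truth_genes.tsv")),
               ccp_gmt = file.path(dir, paste0(id, "_ccp_true.gmt")))
    write.table(data.frame(sample_id = names(tr$latentProlif),
                           latent_prolif = tr$latentProlif,
                           latent_indep = tr$latentIndep),
                paths[["truth_samples"]], sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_symbol = names(tr$geneClass),
                           gene_class = tr$geneClass,
                           true_loading = tr$trueLoading),
                paths[["truth_genes"]], sep = "\t", quote = FALSE, row.names = FALSE)
    writeGMT(setNames(list(sigGenes(truthCcpSignature(cohort))), "CCP_true"),
             paths[["ccp_gmt"]])
  }
  invisible(paths)
}
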