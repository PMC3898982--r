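# End-to-end study orchestration: preprocess -> score -> screen -> enrich ->
# adjust -> size-resampling -> refine -> report, driven by a config list or
# YAML file.

#' Demo study configuration over simulated cohorts
#'
#' Builds a self-contained configuration: several simulated cohorts on
#' "platforms" with increasing gene dropout, the true proliferation gene set
#' as the scored signature, a demo module catalog (the proliferation block,
#' the independent-prognostic block, and random modules), and two competitor
#' signatures for the adjustment analysis (one proliferation-correlated, one
#' built from the orthogonal independent block).
#'
#' @param outputDir directory for study artifacts.
#' @param seed master seed.
#' @param nCohorts number of simulated cohorts (default 5).
#' @param nSamples,nGenes per-cohort dimensions.
#' @param reps subsets per signature size in the resampling stage.
#' @param sizes signature sizes (default 1, 2, 4, ..., 30, 31).
#' @return A config list accepted by \code{\link{runStudy}}.
#' @export
demoStudyConfig <- function(outputDir, seed = 1, nCohorts = 5,
                            nSamples = 150, nGenes = 500, reps = 200,
                            sizes = .default_sizes()) {
  list(
    seed = seed,
    output_dir = outputDir,
    thresholds = list(screen_alpha = 0.01, fdr_cut = 0.20, sig_alpha = 0.05),
    sizes = sizes,
    reps = reps,
    refine_k = c(4, 7, 10, 12),
    simulate = list(n_cohorts = nCohorts, n_samples = nSamples,
                    n_genes = nGenes,
                    dropout = seq(0, 0.3, length.out = nCohorts)),
    ccp_signature = "truth",
    catalog = "demo",
    signatures = "demo")
}

.study_cohorts <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    nc <- sim$n_cohorts
    dropout <- rep(sim$dropout %||% 0, length.out = nc)
    specs <- lapply(seq_len(nc), function(i)
      cohortSpec(nSamples = sim$n_samples %||% 150,
                 nGenes = sim$n_genes %||% 500,
                 geneDropoutFrac = dropout[i],
                 probeDupFrac = sim$probe_dup %||% 0.1,
                 betaProlif = sim$beta_prolif %||% 0.7,
                 betaIndep = sim$beta_indep %||% 0.7,
                 seed = cfg$seed))
    simulateMultiCohort(specs)
  } else if (!is.null(cfg$cohorts)) {
    out <- lapply(seq_along(cfg$cohorts), function(i) {
      entry <- cfg$cohorts[[i]]
      readCohort(entry$expression, entry$clinical,
                 geneMapPath = entry$gene_map,
                 cohortId = entry$id %||% sprintf("cohort%02d", i),
                 endpointLabel = entry$endpoint)
    })
    names(out) <- vapply(out, cohortId, "")
    out
  } else stop("config must contain either 'simulate' or 'cohorts'")
}

.study_catalog <- function(cfg, cohorts) {
  if (identical(cfg$catalog, "demo")) {
    tr <- truthRecord(cohorts[[1]])
    universe <- names(tr$geneClass)
    ccp <- names(tr$geneClass)[tr$geneClass == "ccp"]
    ipg <- names(tr$geneClass)[tr$geneClass == "indep_prognostic"]
    catalog <- list(CELL_CYCLE_LIKE = ccp, INDEP_PROGNOSTIC = ipg)
    extra <- with_seed(as.integer(cfg$seed) + 101L, {
      lapply(1:10, function(i) sample(universe, 30))
    })
    names(extra) <- sprintf("RANDOM_MODULE_%02d", 1:10)
    c(catalog, extra)
  } else readGMT(cfg$catalog)
}

.study_signatures <- function(cfg, cohorts) {
  if (identical(cfg$signatures, "demo")) {
    tr <- truthRecord(cohorts[[1]])
    ccp <- names(tr$geneClass)[tr$geneClass == "ccp"]
    nul <- names(tr$geneClass)[tr$geneClass == "null"]
    ipg <- names(tr$geneClass)[tr$geneClass == "indep_prognostic"]
    with_seed(as.integer(cfg$seed) + 202L, list(
      geneSignature("prolif_correlated_sig", c(sample(ccp, min(10, length(ccp))),
                                               sample(nul, 5))),
      geneSignature("orthogonal_sig", ipg)))
  } else {
    sets <- list()
    for (path in cfg$signatures) sets <- c(sets, readGMT(path))
    lapply(names(sets), function(nm) geneSignature(nm, sets[[nm]]))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full cross-cohort study
#'
#' Executes every stage on a directory of cohorts (or simulated cohorts):
#' preprocessing (probe collapsing + z-normalization), CCP scoring and
#' univariate prognostic testing, the per-gene screen, module
#' over-representation with cross-cohort ranking and per-cohort top hits,
#' the CCP-adjustment analysis of competitor signatures, signature-size
#' resampling, and refined-signature construction. All numeric artifacts are
#' written as TSV/JSON under the configured output directory; a rerun with
#' the same config and seed reproduces them byte-identically.
#'
#' @param config a config list (see \code{\link{demoStudyConfig}}) or the
#'   path of a YAML file with the same structure.
#' @return Invisibly, a list with the per-stage results and artifact paths.
#' @export
runStudy <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(name) file.path(cfg$output_dir, name)
  thr <- cfg$thresholds %||% list()
  screen_alpha <- thr$screen_alpha %||% 0.01
  fdr_cut <- thr$fdr_cut %||% 0.20
  sig_alpha <- thr$sig_alpha %||% 0.05
  tsv <- function(df, path) write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE)

  cohorts <- .study_cohorts(cfg)
  cohorts <- lapply(cohorts, preprocessCohort)

  # signature to score
  ccp_sig <- if (identical(cfg$ccp_signature, "truth")) {
    truthCcpSignature(cohorts[[1]], name = "CCP-full")
  } else {
    sets <- readGMT(cfg$ccp_signature)
    geneSignature(names(sets)[1], sets[[1]])
  }

  # stage: score + univariate prognostic table
  score_rows <- lapply(cohorts, function(co) {
    sc <- signatureScore(co, ccp_sig)
    res <- testContinuous(sc, co)
    cbind(data.frame(cohort = cohortId(co), endpoint = endpointLabel(co),
                     n_genes_used = sc@nGenesUsed,
                     coverage = scoreCoverage(sc)), resultRow(res))
  })
  score_tab <- do.call(rbind, score_rows); rownames(score_tab) <- NULL
  tsv(score_tab, art("ccp_prognostic_table.tsv"))

  # per-cohort signature gene coverage (availability matrix)
  avail <- do.call(rbind, lapply(cohorts, function(co)
    data.frame(cohort = cohortId(co), gene = sigGenes(ccp_sig),
               measured = as.integer(sigGenes(ccp_sig) %in% rownames(co)))))
  tsv(avail, art("signature_availability.tsv"))

  # stage: per-gene screen + enrichment
  catalog <- .study_catalog(cfg, cohorts)
  enr_tables <- list()
  screen_rows <- list()
  for (co in cohorts) {
    hits <- suppressMessages(geneScreen(co, alpha = screen_alpha))
    screen_rows[[cohortId(co)]] <- data.frame(
      cohort = cohortId(co), n_tested = nrow(attr(hits, "results")),
      n_hits = length(hits))
    enr_tables[[cohortId(co)]] <- suppressMessages(
      overrepresentation(as.character(hits), rownames(co), catalog,
                         cohortId = cohortId(co)))
  }
  tsv(do.call(rbind, screen_rows), art("screen_summary.tsv"))
  enr_all <- do.call(rbind, lapply(enr_tables, function(t)
    cbind(cohort = attr(t, "cohort_id"), t)))
  tsv(enr_all, art("enrichment_tables.tsv"))
  ranked <- rankModules(enr_tables, fdrCut = fdr_cut)
  hits_per_cohort <- vapply(names(enr_tables), function(id)
    topHit(enr_tables, id, fdrCut = fdr_cut), "")
  ranked$top_hit_of <- vapply(ranked$module_id, function(m)
    paste(names(hits_per_cohort)[!is.na(hits_per_cohort) &
                                   hits_per_cohort == m], collapse = ","), "")
  tsv(ranked, art("module_ranking.tsv"))

  # stage: adjustment analysis
  signatures <- .study_signatures(cfg, cohorts)
  adj <- suppressMessages(
    runAdjustmentAnalysis(signatures, cohorts, ccp_sig, alpha = sig_alpha))
  tsv(adj$outcomes, art("adjustment_outcomes.tsv"))
  tsv(adj$summary, art("adjustment_summary.tsv"))

  # stage: size resampling + plateau + refinement
  curves <- suppressWarnings(
    randomSignatureCurves(sigGenes(ccp_sig), cohorts, sizes = cfg$sizes,
                          maxReps = cfg$reps %||% 500,
                          seed = cfg$seed, sigAlpha = sig_alpha))
  tsv(curves, art("size_curves.tsv"))
  plateaus <- vapply(split(curves, curves$cohort), plateauSize, 1L)
  tsv(data.frame(cohort = names(plateaus), plateau_size = unname(plateaus)),
      art("plateau_sizes.tsv"))

  consistency <- rankGenesByConsistency(cohorts, sigGenes(ccp_sig),
                                        alpha = sig_alpha)
  tsv(consistency, art("gene_consistency.tsv"))
  ks <- cfg$refine_k %||% c(4, 7, 10, 12)
  ks <- ks[ks <= nrow(consistency)]
  refined <- lapply(ks, function(k) refineSignature(consistency, k))
  writeGMT(setNames(lapply(refined, sigGenes),
                    vapply(refined, sigName, "")),
           art("refined_signatures.gmt"))

  summary <- list(
    package_version = as.character(packageVersion("ccpmeta")),
    seed = cfg$seed,
    n_cohorts = length(cohorts),
    endpoints = unname(vapply(cohorts, endpointLabel, "")),
    top_module = ranked$module_id[1],
    top_module_n_significant = ranked$n_cohorts_significant[1],
    ccp_prognostic_in = sum(score_tab$p < sig_alpha),
    median_plateau_size = as.numeric(median(plateaus, na.rm = TRUE)),
    refined_signatures = vapply(refined, sigName, ""))
  jsonlite::write_json(summary, art("study_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohorts = cohorts, ccp_signature = ccp_sig,
                 score_table = score_tab, enrichment = enr_tables,
                 ranking = ranked, top_hits = hits_per_cohort,
                 adjustment = adj, size_curves = curves,
                 plateaus = plateaus, consistency = consistency,
                 refined = refined, summary = summary,
                 output_dir = cfg$output_dir))
}
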