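test_that("cohort generation is deterministic and structurally valid", {
  spec <- cohortSpec(nSamples = 60, nGenes = 100, seed = 11,
                     geneDropoutFrac = 0.2, probeDupFrac = 0.25)
  a <- simulateCohort(spec)
  b <- simulateCohort(spec)
  expect_identical(exprValues(a), exprValues(b))
  expect_identical(clinicalTable(a), clinicalTable(b))
  expect_identical(truthRecord(a)$latentProlif, truthRecord(b)$latentProlif)

  tr <- truthRecord(a)
  expect_equal(as.integer(table(tr$geneClass)[c("ccp", "indep_prognostic")]),
               c(31, 20))
  # stratified dropout arithmetic: measured ccp genes = round(31 * 0.8)
  measured_ccp <- sum(unique(SummarizedExperiment::rowData(a)$gene_symbol) %in%
                        names(tr$geneClass)[tr$geneClass == "ccp"])
  expect_equal(measured_ccp, round(31 * 0.8))
  # duplicated probes map a second feature to an existing symbol
  expect_gt(nrow(a), length(unique(SummarizedExperiment::rowData(a)$gene_symbol)))
  # clinical and expression share the ordered sample set
  expect_identical(colnames(a), clinicalTable(a)$sample_id)
})

test_that("spec validation errors name the offending field", {
  expect_error(cohortSpec(nGenes = 10, nCcpGenes = 31), "nCcpGenes")
  expect_error(cohortSpec(noiseSd = 0), "noiseSd")
  expect_error(cohortSpec(loadingRange = c(1, 0.5)), "loadingRange")
  expect_error(cohortSpec(geneDropoutFrac = 1.5), "geneDropoutFrac")
})

test_that("multi-cohort generation offsets seeds and shares the gene universe", {
  spec <- cohortSpec(nSamples = 50, nGenes = 80, seed = 3)
  cohorts <- simulateMultiCohort(list(spec, spec))
  expect_length(cohorts, 2)
  # same master seed, different cohorts (offset rule)
  expect_false(identical(exprValues(cohorts[[1]])[1, ],
                         exprValues(cohorts[[2]])[1, ]))
  # shared symbol universe: signatures transfer
  expect_identical(names(truthRecord(cohorts[[1]])$geneClass),
                   names(truthRecord(cohorts[[2]])$geneClass))
  expect_error(simulateMultiCohort(list()), "at least one")

  # dropout series: measured ccp counts follow round(31 * (1 - frac))
  specs <- lapply(c(0, 0.2, 0.4), function(f)
    cohortSpec(nSamples = 40, nGenes = 80, seed = 5, geneDropoutFrac = f))
  cos <- simulateMultiCohort(specs)
  counts <- vapply(cos, function(co)
    sum(unique(SummarizedExperiment::rowData(co)$gene_symbol) %in%
          names(truthRecord(co)$geneClass)[truthRecord(co)$geneClass == "ccp"]),
    0L)
  expect_equal(unname(counts), c(31, round(31 * 0.8), round(31 * 0.6)))
})

test_that("ccp gene/latent correlations match the closed-form attenuation", {
  co <- simulateCohort(cohortSpec(nSamples = 300, nGenes = 80, nCcpGenes = 31,
                                  loadingRange = c(0.5, 1), noiseSd = 0.7,
                                  seed = 1))
  tr <- truthRecord(co)
  cp <- preprocessCohort(co)
  ccp <- names(tr$geneClass)[tr$geneClass == "ccp"]
  emp <- vapply(ccp, function(g)
    cor(SummarizedExperiment::assay(cp)[g, ], tr$latentProlif), 0)
  lam <- tr$trueLoading[ccp]
  oracle <- lam / sqrt(lam^2 + 0.7^2)
  expect_lt(abs(mean(emp) - mean(oracle)), 0.1)
})

test_that("null-effect cohorts give calibrated CCP-score confidence intervals", {
  # beta_prolif = beta_indep = 0: the 95% CI for the HR should cover 1
  covered <- 0L
  for (r in 1:200) {
    co <- small_cohort(seed = 5000 + r, n = 500, nGenes = 60,
                       betaProlif = 0, betaIndep = 0, nIndepGenes = 5)
    res <- testContinuous(signatureScore(co, truthCcpSignature(co)), co)
    covered <- covered + (res@ciLow <= 1 && 1 <= res@ciHigh)
  }
  expect_gte(covered, 0.93 * 200)
})

test_that("stronger proliferation effects give larger score Wald statistics", {
  wald_z <- function(res) {
    se <- (log(res@ciHigh) - log(res@ciLow)) / (2 * qnorm(0.975))
    abs(log(res@estimate)) / se
  }
  med_z <- vapply(c(0, 0.5, 1), function(beta) {
    zs <- vapply(1:50, function(r) {
      co <- small_cohort(seed = 800 + r, n = 150, nGenes = 60,
                         betaProlif = beta, betaIndep = 0, nIndepGenes = 5,
                         censorMax = 30)
      wald_z(testContinuous(signatureScore(co, truthCcpSignature(co)), co))
    }, 0)
    median(zs)
  }, 0)
  expect_true(all(diff(med_z) >= 0))
})

test_that("binary cohorts carry labels driven by the proliferation factor", {
  co <- simulateCohort(cohortSpec(nSamples = 400, nGenes = 60,
                                  endpointKind = "binary", binarySlope = 2,
                                  seed = 9))
  cl <- clinicalTable(co)
  expect_true(all(cl$label %in% c(0, 1)))
  expect_true(all(is.na(cl$time)))
  P <- truthRecord(co)$latentProlif
  expect_gt(mean(P[cl$label == 1]), mean(P[cl$label == 0]))
})

test_that("cohort files round-trip through the plain-text writers", {
  dir <- withr::local_tempdir()
  co <- simulateCohort(cohortSpec(nSamples = 30, nGenes = 60, seed = 2,
                                  probeDupFrac = 0.2))
  paths <- writeCohort(co, dir)
  expect_true(all(file.exists(paths)))
  back <- readCohort(paths[["expression"]], paths[["clinical"]],
                     paths[["gene_map"]], cohortId = "rt")
  expect_equal(exprValues(back), exprValues(co), tolerance = 1e-12)
  expect_equal(clinicalTable(back)$event, clinicalTable(co)$event)
  gmt <- readGMT(paths[["ccp_gmt"]])
  expect_identical(gmt$CCP_true, sigGenes(truthCcpSignature(co)))
})
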