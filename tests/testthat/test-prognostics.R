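make_clin_tte <- function(time, event, ids = sprintf("s%02d", seq_along(time)))
  data.frame(sample_id = ids, time = time, event = event)

make_clin_bin <- function(label, ids = sprintf("s%02d", seq_along(label)))
  data.frame(sample_id = ids, label = label)

test_that("endpoint selection follows the DSS > OS > RFS hierarchy", {
  expect_identical(selectEndpoint(c("OS", "DSS")), "DSS")
  expect_identical(selectEndpoint(c("RFS")), "RFS")
  expect_identical(selectEndpoint(c("binary", "RFS")), "RFS")
  expect_identical(selectEndpoint("binary"), "binary")
  expect_error(selectEndpoint(character(0)), "no endpoints")
  expect_error(selectEndpoint("bogus"), "unknown")
})

test_that("binary endpoints are evaluated by AUC with Mann-Whitney p", {
  # perfect separation
  s <- setNames(c(0.9, 0.8, 0.1, 0.2), sprintf("s%02d", 1:4))
  res <- testContinuous(s, make_clin_bin(c(1, 1, 0, 0)))
  expect_identical(res@method, "auc")
  expect_equal(res@estimate, 1.0)

  # tie pair: AUC equals (wins + 0.5 * ties) / pairs by exhaustive counting
  s2 <- setNames(c(0.9, 0.8, 0.5, 0.1, 0.2, 0.5), sprintf("s%02d", 1:6))
  lab2 <- c(1, 1, 1, 0, 0, 0)
  res2 <- testContinuous(s2, make_clin_bin(lab2))
  expect_equal(res2@estimate, brute_auc(s2, lab2))
  expect_true(res2@ciLow <= res2@estimate && res2@estimate <= res2@ciHigh)

  # random inputs against the pair-counting oracle
  for (r in 1:5) {
    set.seed(100 + r)
    n <- sample(10:60, 1)
    s3 <- setNames(round(rnorm(n), 1), sprintf("s%03d", 1:n))
    lab3 <- rbinom(n, 1, 0.4)
    if (length(unique(lab3)) < 2) next
    expect_equal(testContinuous(s3, make_clin_bin(lab3, names(s3)))@estimate,
                 brute_auc(s3, lab3))
  }
})

test_that("time-to-event tests report HR per unit score with the score-test p", {
  co <- small_cohort(seed = 60, n = 200, nGenes = 60, betaProlif = 1,
                     censorMax = 30)
  res <- testContinuous(signatureScore(co, truthCcpSignature(co)), co)
  expect_identical(res@method, "cox_continuous")
  expect_gt(res@estimate, 1)
  expect_lt(res@p, 0.01)

  # agrees with a hand-rolled coxph call
  s <- scoreValues(signatureScore(co, truthCcpSignature(co)))
  cl <- clinicalTable(co)
  fit <- survival::coxph(survival::Surv(cl$time, cl$event) ~ s)
  expect_equal(res@estimate, unname(exp(coef(fit))), tolerance = 1e-10)
  expect_equal(res@p, unname(summary(fit)$sctest["pvalue"]), tolerance = 1e-10)
})

test_that("degenerate prognostic-test inputs raise informative errors", {
  s <- setNames(rnorm(10), sprintf("s%02d", 1:10))
  expect_error(testContinuous(s, make_clin_tte(1:10, rep(0, 10))), "no events")
  flat <- setNames(rep(1, 10), sprintf("s%02d", 1:10))
  expect_error(testContinuous(flat, make_clin_tte(1:10, rep(1, 10))),
               "constant score")
})

test_that("the gene screen is calibrated on null cohorts and recalls true genes", {
  # all-null cohort: about alpha of genes flagged
  co <- small_cohort(seed = 70, n = 300, nGenes = 400, betaProlif = 0,
                     betaIndep = 0, censorMax = 30)
  hits <- geneScreen(co, alpha = 0.05)
  expect_lt(length(hits) / nrow(co), 0.12)
  expect_identical(sort(as.character(geneScreen(co, alpha = 1))),
                   sort(rownames(co)))

  # strong proliferation effect: most ccp genes recovered at alpha = 0.01
  recall <- vapply(1:10, function(r) {
    cs <- small_cohort(seed = 700 + r, n = 300, nGenes = 100, betaProlif = 1,
                       betaIndep = 0, loadingRange = c(0.9, 0.9),
                       censorMax = 30)
    tr <- truthRecord(cs)
    ccp <- names(tr$geneClass)[tr$geneClass == "ccp"]
    h <- geneScreen(cs, alpha = 0.01)
    length(intersect(h, ccp)) / length(intersect(ccp, rownames(cs)))
  }, 0)
  expect_gte(mean(recall), 0.8)
})

test_that("KM tertiles split at the empirical 33/67 quantiles", {
  s <- setNames(as.numeric(1:9), sprintf("s%02d", 1:9))
  clin <- make_clin_tte(rep(5, 9), rep(1, 9))
  km <- kmTertiles(s, clin)
  expect_equal(as.integer(table(km$strata)), rep(3L, 3))
  expect_identical(as.character(km$strata[s <= 3]), rep("low", 3))
  expect_identical(as.character(km$strata[s >= 7]), rep("high", 3))

  # an all-censored stratum stays at survival 1
  clin2 <- make_clin_tte(c(1:6, 7, 8, 9), c(rep(1, 6), 0, 0, 0))
  # monotone toy data separates perfectly; the Cox fit's convergence warning
  # is irrelevant to the curve shapes under test
  km2 <- suppressWarnings(kmTertiles(s, clin2))
  high <- km2$curves[km2$curves$stratum == "high", ]
  expect_true(all(high$surv == 1))

  expect_error(kmTertiles(setNames(rep(1, 9), names(s)), clin), "tertile|quantile|tied")
})

test_that("KM curves agree with a direct product-limit computation", {
  co <- small_cohort(seed = 81, n = 90, nGenes = 60, betaProlif = 1.2,
                     censorMax = 30)
  sc <- signatureScore(co, truthCcpSignature(co))
  km <- kmTertiles(sc, co)
  cl <- clinicalTable(co)
  for (st in c("low", "high")) {
    idx <- names(scoreValues(sc))[km$strata == st]
    pl <- product_limit(cl[idx, "time"], cl[idx, "event"])
    got <- km$curves[km$curves$stratum == st & km$curves$n_event > 0, ]
    expect_equal(got$surv, pl$surv, tolerance = 1e-12)
  }
  # strong effect: high tertile does worse at the latest shared time
  lowc <- km$curves[km$curves$stratum == "low", ]
  highc <- km$curves[km$curves$stratum == "high", ]
  expect_lt(min(highc$surv), min(lowc$surv))
})

test_that("forward stepwise selection enters informative terms in p order", {
  co <- small_cohort(seed = 91, n = 250, nGenes = 60, betaProlif = 1.2,
                     censorMax = 30)
  sc <- scoreValues(signatureScore(co, truthCcpSignature(co)))
  cl <- clinicalTable(co)
  withr::with_seed(17, {
    cand <- data.frame(score = unname(sc), noise = rnorm(length(sc)),
                       stage = cl$stage)
  })
  fm <- stepwiseFinalModel(co, cand)
  expect_true("score" %in% names(fm@terms))
  expect_identical(fm@selectionTrace$term[1], "score")
  expect_true(all(fm@selectionTrace$p_at_entry < 0.05))
  # deterministic: identical input, identical trace
  fm2 <- stepwiseFinalModel(co, cand)
  expect_identical(fm@selectionTrace, fm2@selectionTrace)

  # single strong candidate is selected
  fm3 <- stepwiseFinalModel(co, cand[, "score", drop = FALSE])
  expect_identical(names(fm3@terms), "score")

  # hopeless candidates yield a valid empty model
  withr::with_seed(18, junk <- data.frame(x = rnorm(nrow(cl))))
  expect_message(fm4 <- stepwiseFinalModel(co, junk), "no candidate")
  expect_length(fm4@terms, 0)
})

test_that("the prognostic score wins stepwise entry over pure noise", {
  first <- vapply(1:100, function(r) {
    co <- small_cohort(seed = 2000 + r, n = 150, nGenes = 60, betaProlif = 1,
                       betaIndep = 0, censorMax = 30)
    sc <- scoreValues(signatureScore(co, truthCcpSignature(co)))
    cand <- withr::with_seed(3000 + r,
      data.frame(score = unname(sc), noise = rnorm(length(sc))))
    fm <- stepwiseFinalModel(co, cand)
    length(fm@selectionTrace$term) > 0 && fm@selectionTrace$term[1] == "score"
  }, TRUE)
  expect_gte(mean(first), 0.95)
})

test_that("added-value LRT is consistent with nesting", {
  co <- small_cohort(seed = 95, n = 150, nGenes = 60, betaProlif = 1,
                     censorMax = 30)
  sc <- scoreValues(signatureScore(co, truthCcpSignature(co)))
  cl <- clinicalTable(co)

  # addition identical to a base covariate: no information, p = 1
  base <- data.frame(score = unname(sc))
  res <- addedValueTest(co, base, unname(sc))
  expect_equal(res@p, 1, tolerance = 1e-9)

  # empty base reduces to the single-covariate likelihood-ratio test
  res0 <- addedValueTest(co, NULL, unname(sc))
  fit <- survival::coxph(survival::Surv(cl$time, cl$event) ~ sc)
  expect_equal(res0@p, unname(summary(fit)$logtest["pvalue"]), tolerance = 1e-8)
})

test_that("added-value p-values are uniform under a pure-noise addition", {
  ps <- vapply(1:400, function(r) {
    co <- withr::with_seed(40000 + r, {
      n <- 100
      data.frame(sample_id = sprintf("s%03d", 1:n),
                 time = rexp(n, 0.1), event = rbinom(n, 1, 0.7),
                 stage = rbinom(n, 1, 0.5), noise = rnorm(n))
    })
    addedValueTest(co[, 1:4], co[, "stage", drop = FALSE], co$noise)@p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
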