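test_that("hypergeometric enrichment matches exhaustive enumeration", {
  universe <- sprintf("g%02d", 1:10)
  # module = gene list = universe: overlap is certain, p = 1
  tab <- overrepresentation(universe, universe, list(M = universe))
  expect_equal(tab$p, 1)

  # N=10, K=5, n=4, k=4: P = C(5,4) C(5,0) / C(10,4) = 5/210
  tab2 <- overrepresentation(universe[1:4], universe, list(M = universe[1:5]))
  expect_equal(tab2$k_overlap, 4L)
  expect_equal(tab2$p, 5 / 210, tolerance = 1e-12)
  expect_equal(tab2$p, enum_hyper_tail(10, 5, 4, 4), tolerance = 1e-12)

  # random configurations against the enumeration oracle (N <= 20)
  for (r in 1:10) {
    set.seed(500 + r)
    N <- sample(8:16, 1)
    uni <- sprintf("u%02d", 1:N)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    mod <- sample(uni, K)
    lst <- sample(uni, n)
    k <- length(intersect(mod, lst))
    tab <- overrepresentation(lst, uni, list(M = mod))
    oracle <- if (k == 0) 1 else enum_hyper_tail(N, K, n, k)
    expect_equal(tab$p, oracle, tolerance = 1e-10)
  }
})

test_that("the conservative one-removed variant and edge cases behave", {
  uni <- sprintf("g%02d", 1:10)
  t_plain <- overrepresentation(uni[1:4], uni, list(M = uni[1:5]))
  t_ease <- overrepresentation(uni[1:4], uni, list(M = uni[1:5]), ease = TRUE)
  expect_gt(t_ease$p, t_plain$p)
  expect_equal(t_ease$p, enum_hyper_tail(10, 5, 4, 3), tolerance = 1e-12)

  expect_warning(t0 <- overrepresentation(character(0), uni, list(M = uni[1:5])),
                 "empty")
  expect_equal(t0$p, 1)
  expect_error(overrepresentation("not_in_universe", uni, list(M = uni[1:3])),
               "outside the universe")
})

test_that("BH adjustment matches the step-up definition and is monotone", {
  uni <- sprintf("g%03d", 1:100)
  set.seed(3)
  catalog <- lapply(1:8, function(i) sample(uni, 20))
  names(catalog) <- sprintf("M%d", 1:8)
  lst <- sample(uni, 25)
  tab <- overrepresentation(lst, uni, catalog)
  expect_equal(tab$fdr, bh_stepup(tab$p), tolerance = 1e-12)
  expect_true(all(tab$fdr >= tab$p))
  o <- order(tab$p)
  expect_true(all(diff(tab$fdr[o]) >= -1e-12))

  # worked example: {0.01, 0.02, 0.03, 0.8} -> {0.04, 0.04, 0.04, 0.8}
  expect_equal(bh_stepup(c(0.01, 0.02, 0.03, 0.8)),
               p.adjust(c(0.01, 0.02, 0.03, 0.8), "BH"))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.8), "BH"),
               c(0.04, 0.04, 0.04, 0.8))
})

make_enr_table <- function(cohort, modules, fdrs, ps = fdrs / 2) {
  tab <- data.frame(module_id = modules, k_overlap = 1L, K_module = 5L,
                    n_list = 10L, N_universe = 100L, p = ps, fdr = fdrs)
  attr(tab, "cohort_id") <- cohort
  tab
}

test_that("module ranking counts significant cohorts first, then mean p", {
  t1 <- make_enr_table("c1", c("A", "B", "C"), c(0.01, 0.10, 0.50))
  t2 <- make_enr_table("c2", c("A", "B", "C"), c(0.05, 0.15, 0.60))
  t3 <- make_enr_table("c3", c("A", "B", "C"), c(0.02, 0.90, 0.70))
  r <- rankModules(list(t1, t2, t3), fdrCut = 0.20)
  expect_identical(r$module_id, c("A", "B", "C"))  # A in 3, B in 2, C in 0
  expect_equal(r$n_cohorts_significant, c(3L, 2L, 0L))

  # equal cohort counts: smaller mean p wins
  t4 <- make_enr_table("c1", c("X", "Y"), c(0.1, 0.1), ps = c(0.001, 0.01))
  t5 <- make_enr_table("c2", c("X", "Y"), c(0.1, 0.1), ps = c(0.001, 0.01))
  r2 <- rankModules(list(t4, t5), fdrCut = 0.20)
  expect_identical(r2$module_id, c("X", "Y"))

  # nothing under the cut: ranking falls back to mean p alone
  t6 <- make_enr_table("c1", c("P", "Q"), c(0.9, 0.5), ps = c(0.8, 0.3))
  r3 <- rankModules(list(t6), fdrCut = 0.20)
  expect_identical(r3$module_id, c("Q", "P"))
})

test_that("the per-cohort top hit requires significance in multiple cohorts", {
  # no module under the cut in >= 2 cohorts: none
  t1 <- make_enr_table("c1", c("A", "B"), c(0.05, 0.9))
  t2 <- make_enr_table("c2", c("A", "B"), c(0.5, 0.9))
  expect_true(is.na(topHit(list(t1, t2), "c1")))

  # a single qualifying module is returned
  t3 <- make_enr_table("c2", c("A", "B"), c(0.10, 0.9))
  expect_identical(topHit(list(t1, t3), "c2"), "A")

  # three-cohort fixture with a hand-enumerated answer: B qualifies (sig in
  # c1 and c2) and A qualifies (sig in c1, c3); in c1 B has the lower fdr
  u1 <- make_enr_table("c1", c("A", "B"), c(0.15, 0.02))
  u2 <- make_enr_table("c2", c("A", "B"), c(0.60, 0.10))
  u3 <- make_enr_table("c3", c("A", "B"), c(0.05, 0.70))
  expect_identical(topHit(list(u1, u2, u3), "c1"), "B")
  expect_identical(topHit(list(u1, u2, u3), "c3"), "A")
  expect_error(topHit(list(u1, u2, u3), "nope"), "unknown cohort")
})

test_that("the proliferation module ranks first when ccp genes drive hazard", {
  wins <- vapply(1:50, function(r) {
    specs <- lapply(1:3, function(i)
      cohortSpec(nSamples = 200, nGenes = 300, betaProlif = 0.7,
                 betaIndep = 0, censorMax = 30, seed = 9000 + 10 * r))
    cohorts <- lapply(simulateMultiCohort(specs), preprocessCohort)
    tr <- truthRecord(cohorts[[1]])
    catalog <- c(list(CELL_CYCLE = names(tr$geneClass)[tr$geneClass == "ccp"]),
                 withr::with_seed(r, {
                   s <- lapply(1:6, function(i) sample(names(tr$geneClass), 25))
                   names(s) <- sprintf("RAND%02d", 1:6)
                   s
                 }))
    tabs <- lapply(cohorts, function(co) {
      hits <- suppressMessages(geneScreen(co, alpha = 0.01))
      suppressMessages(overrepresentation(as.character(hits), rownames(co),
                                          catalog, cohortId = cohortId(co)))
    })
    rankModules(tabs)$module_id[1] == "CELL_CYCLE"
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})
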