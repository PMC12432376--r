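test_that("contingency counts match a brute-force tally", {
  sim <- simulateCohort(quickConfig(seed = 81L))
  co <- sim$cohort
  uni <- conditionUniverse(co, exclude = sim$conceptSet)
  M <- buildConditionMatrix(co, uni)
  cases <- intersect(caseIds(co), rownames(M))
  ctl <- setdiff(rownames(M), caseIds(co))[1:200]
  occ <- cohortOccurrences(co)
  for (concept in uni[c(1, 10, 25)]) {
    cnt <- contingencyCounts(M, cases, ctl, concept)
    withC <- unique(occ$person_id[occ$concept_id == concept])
    expect_equal(unname(cnt["a"]), length(intersect(cases, withC)))
    expect_equal(unname(cnt["c"]), length(intersect(ctl, withC)))
    expect_equal(sum(cnt[c("a", "b")]), length(cases))
    expect_equal(sum(cnt[c("c", "d")]), length(ctl))
  }
  expect_error(contingencyCounts(M, cases, c(ctl, cases[1]), uni[1]),
               "overlap")
})

test_that("odds ratio arithmetic and zero-cell correction", {
  expect_equal(oddsRatio(c(a = 20, b = 10, c = 10, d = 20)), 4.0)
  expect_equal(oddsRatio(c(a = 7, b = 7, c = 7, d = 7)), 1.0)
  # Haldane-Anscombe: (5.5 * 10.5) / (5.5 * 0.5)
  expect_equal(oddsRatio(c(a = 5, b = 5, c = 0, d = 10)),
               (5.5 * 10.5) / (5.5 * 0.5))
  # antitone under swapping case/control labels when no correction triggers
  set.seed(3)
  for (i in 1:20) {
    cnt <- c(a = sample(1:30, 1), b = sample(1:30, 1),
             c = sample(1:30, 1), d = sample(1:30, 1))
    swapped <- c(a = cnt[["c"]], b = cnt[["d"]], c = cnt[["a"]],
                 d = cnt[["b"]])
    expect_equal(oddsRatio(swapped), 1 / oddsRatio(cnt))
  }
})

test_that("hypergeometric tail matches exact enumeration", {
  # closed-form enumeration oracle, independent of phyper
  enumTail <- function(a, b, cc, d) {
    N <- a + b + cc + d; K <- a + cc; n <- a + b
    xs <- max(0, n - (N - K)):min(K, n)
    probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
    sum(probs[xs >= a])
  }
  expect_equal(hypergeomPvalue(c(a = 0, b = 5, c = 3, d = 7)), 1)
  # N=10, K=5, n=5, a=5: drawing all successes
  expect_equal(hypergeomPvalue(c(a = 5, b = 0, c = 0, d = 5)),
               choose(5, 5) / choose(10, 5))
  set.seed(4)
  for (i in 1:50) {
    cnt <- as.list(sample(0:7, 4, replace = TRUE))
    names(cnt) <- c("a", "b", "c", "d")
    expect_equal(
      hypergeomPvalue(unlist(cnt)),
      enumTail(cnt$a, cnt$b, cnt$c, cnt$d),
      tolerance = 1e-12
    )
  }
})

test_that("bonferroni and twice-the-mean aggregation follow their formulas", {
  expect_equal(bonferroni(0.001, 600), 0.6)
  expect_equal(bonferroni(0.2, 10), 1.0)
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_equal(aggregateReplicates(rep(2, 3), rep(0.01, 3))$aggregated_p,
               0.02)
  agg <- aggregateReplicates(c(1, 2, 3), c(0.01, 0.02, 0.03))
  expect_equal(agg$aggregated_p, 0.04)
  expect_equal(agg$mean_or, 2)
  expect_equal(aggregateReplicates(1, 1)$aggregated_p, 1)
  # permutation invariance and monotonicity in each replicate p
  set.seed(5)
  ps <- runif(30)
  ors <- rlnorm(30)
  base <- aggregateReplicates(ors, ps)
  prm <- sample(30)
  expect_identical(aggregateReplicates(ors[prm], ps[prm])$aggregated_p,
                   base$aggregated_p)
  ps2 <- ps; ps2[7] <- ps2[7] / 2
  expect_lte(aggregateReplicates(ors, ps2)$aggregated_p, base$aggregated_p)
})

test_that("runAssociation with k=1 reduces to a single corrected test doubled", {
  sim <- simulateCohort(quickConfig(seed = 91L))
  co <- sim$cohort
  sc <- fitPropensity(co, "demographic")
  bg <- intersect(backgroundIds(co), names(sc))
  m <- matchControls(sc, caseIds(co), bg, k = 1L)
  at <- runAssociation(co, m, conceptSet = sim$conceptSet)
  res <- assocResults(at)
  M <- buildConditionMatrix(co, res$concept_id,
                            persons = c(caseIds(co), controlIds(m)))
  ctl <- controlIds(m, replicate = 1)
  mTests <- nrow(res)
  for (concept in res$concept_id[c(1, 5, 20)]) {
    cnt <- contingencyCounts(M, caseIds(co), ctl, concept)
    expect_equal(
      res$aggregated_p[res$concept_id == concept],
      min(1, 2 * bonferroni(hypergeomPvalue(cnt), mTests))
    )
    expect_equal(res$mean_or[res$concept_id == concept],
                 oddsRatio(cnt))
  }
})

test_that("per-iteration universes and untested conditions are handled", {
  # hand-built: 2 cases, 2 controls per replicate, 2 replicates
  persons <- data.frame(
    person_id = c("a1", "a2", "b1", "b2", "b3", "b4"),
    age = 30, gender = "f", race = "w", ethnicity = "n", site = "s"
  )
  occ <- data.frame(
    person_id = c("a1", "a1", "a2", "b1", "b3", "a1", "a2"),
    concept_id = c("X", "Y", "X", "X", "Z", "E1", "E1"),
    start_date = as.Date("2020-01-01")
  )
  util <- data.frame(person_id = persons$person_id, n_visits = 1,
                     record_duration_days = 100)
  cs <- closeConceptSet("E1", NULL)
  co <- makeCohort(persons, occ, util, cs)
  matches <- data.frame(
    replicate = c(1L, 1L, 2L, 2L),
    case_id = c("a1", "a2", "a1", "a2"),
    control_id = c("b1", "b2", "b3", "b4"),
    case_score = 0.5, control_score = 0.5
  )
  m <- new("MatchedCohort", caseIds = c("a1", "a2"), matches = matches,
           k = 2L, variant = "demographic", covariates = "age")
  at <- runAssociation(co, m, conceptSet = cs)
  res <- assocResults(at)
  # Z occurs only in a replicate-2 control: untested in replicate 1
  expect_equal(res$n_replicates_tested[res$concept_id == "Z"], 1)
  expect_equal(at@replicateP[match("Z", res$concept_id), 1], 1)
  # universe sizes differ by replicate: rep1 tests {X, Y}, rep2 {X, Y, Z}
  pX1 <- hypergeomPvalue(c(a = 2, b = 0, c = 1, d = 1))
  pX2 <- hypergeomPvalue(c(a = 2, b = 0, c = 0, d = 2))
  expect_equal(at@replicateP[match("X", res$concept_id), ],
               c(min(1, 2 * pX1), min(1, 3 * pX2)))
  expect_error(
    runAssociation(co, m, conceptSet = closeConceptSet("nope", NULL),
                   alpha = 0.05, minPrevalence = 100L),
    "empty"
  )
})

test_that("the utilization filter requires significance in both arms", {
  mk <- function(ids, p) {
    res <- data.frame(
      concept_id = ids, n_case_with = 5L, mean_or = 2,
      aggregated_p = p, aggregated_p_depletion = 1,
      significant = p < 0.05, significant_depletion = FALSE,
      n_replicates_tested = 1
    )
    new("AssociationTable", results = res,
        replicateOR = matrix(2, length(ids), 1),
        replicateP = matrix(p, length(ids), 1),
        replicatePDepletion = matrix(1, length(ids), 1),
        alpha = 0.05, k = 1L)
  }
  primary <- mk(c("A", "B", "C"), c(0.01, 0.01, 0.5))
  util <- mk(c("A", "B", "D"), c(0.01, 0.9, 0.01))
  out <- applyUtilizationFilter(primary, util)
  flag <- setNames(out$significant_final, out$concept_id)
  expect_true(flag[["A"]])            # significant in both
  expect_false(flag[["B"]])           # primary only
  expect_false(flag[["C"]])           # neither
  expect_false(flag[["D"]])           # untested in primary -> non-significant
})

test_that("chapter-map annotation flows through to the final table", {
  sim <- simulateCohort(quickConfig(seed = 101L))
  co <- sim$cohort
  dir <- withr::local_tempdir()
  uni <- conditionUniverse(co, exclude = sim$conceptSet)
  data.table::fwrite(
    data.frame(concept_id = uni,
               chapter_label = rep(c("ch1", "ch2"), length.out = length(uni))),
    file.path(dir, "chapter_map.tsv"), sep = "\t"
  )
  cmap <- readChapterMap(file.path(dir, "chapter_map.tsv"))
  sc <- fitPropensity(co, "demographic")
  bg <- intersect(backgroundIds(co), names(sc))
  m <- matchControls(sc, caseIds(co), bg, k = 2L)
  at <- runAssociation(co, m, conceptSet = sim$conceptSet, chapterMap = cmap)
  res <- assocResults(at)
  expect_identical(res$chapter_label,
                   cmap$chapter_label[match(res$concept_id, cmap$concept_id)])
  final <- applyUtilizationFilter(at, at)
  expect_true("chapter_label" %in% names(final))
})
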