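test_that("concept set closure returns the root plus all descendants", {
  expect_identical(conceptMembers(closeConceptSet("R", NULL)), "R")
  edges <- data.frame(ancestor_id = c("R", "A", "X"),
                      descendant_id = c("A", "B", "Y"))
  expect_setequal(conceptMembers(closeConceptSet("R", edges)),
                  c("R", "A", "B"))
  # root present only as a leaf elsewhere
  expect_setequal(conceptMembers(closeConceptSet("B", edges)), "B")
})

test_that("concept set closure matches brute-force reachability on a random DAG", {
  set.seed(42)
  n <- 50
  nodes <- sprintf("N%02d", seq_len(n))
  # edges only from lower to higher index: guaranteed acyclic
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < 0.06
  edges <- data.frame(ancestor_id = nodes[pairs[keep, 1]],
                      descendant_id = nodes[pairs[keep, 2]])
  # oracle: breadth-first reachability over an adjacency list
  adj <- split(edges$descendant_id, edges$ancestor_id)
  bfs <- function(root) {
    seen <- root
    frontier <- root
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    sort(seen)
  }
  for (root in c("N01", "N10", "N25", "N49")) {
    expect_identical(sort(conceptMembers(closeConceptSet(root, edges))),
                     bfs(root))
  }
})

test_that("cyclic ancestor edges are rejected with a diagnostic", {
  edges <- data.frame(ancestor_id = c("A", "B", "C"),
                      descendant_id = c("B", "C", "A"))
  expect_error(closeConceptSet("A", edges), "cycle")
})

test_that("case and background selection partition the persons with conditions", {
  t <- tinyTables()
  cases <- selectCases(t$occurrences, t$conceptSet)
  bg <- selectBackground(t$occurrences, t$conceptSet)
  expect_identical(cases, c("X1", "X2"))
  expect_identical(bg, c("X3", "X4", "X5"))  # X6 (no conditions) excluded
  expect_length(intersect(cases, bg), 0)
  expect_setequal(c(cases, bg), unique(t$occurrences$person_id))

  # a person with only concept-set codes is a case, never background
  onlyEndo <- data.frame(person_id = "Z", concept_id = "E1",
                         start_date = as.Date("2020-01-01"))
  expect_identical(selectCases(onlyEndo, t$conceptSet), "Z")
  expect_length(selectBackground(onlyEndo, t$conceptSet), 0)
  expect_warning(selectCases(data.frame(person_id = "Z", concept_id = "C9",
                                        start_date = as.Date("2020-01-01")),
                             t$conceptSet),
                 "no cases")
})

test_that("first index date is the minimum concept-set date", {
  occ <- data.frame(
    person_id = c("P", "P", "Q"),
    concept_id = c("E1", "E2", "E1"),
    start_date = as.Date(c("2015-03-01", "2013-07-09", "2018-01-01"))
  )
  cs <- tinyTables()$conceptSet
  idx <- firstIndexDates(occ, cs)
  expect_identical(unname(idx["P"]), as.Date("2013-07-09"))
  expect_identical(unname(idx["Q"]), as.Date("2018-01-01"))
  expect_error(firstIndexDates(occ, cs, persons = c("P", "NOT_A_CASE")),
               "undefined")
})

test_that("pre-index restriction is strict and leaves controls untouched", {
  co <- tinyCohort()
  pre <- restrictPreIndex(co, tinyTables()$conceptSet)
  # X1: only C1 (2013-07-09) precedes the 2015-03-01 index; E1 and the
  # post-index C2 go
  occ1 <- cohortOccurrences(pre)
  expect_identical(occ1$concept_id[occ1$person_id == "X1"], "C1")
  # X2's only non-index condition is ON the index date -> dropped entirely
  expect_false("X2" %in% caseIds(pre))
  expect_false("X2" %in% cohortPersons(pre)$person_id)
  # background occurrences byte-identical
  bgOcc <- function(x) {
    o <- cohortOccurrences(x)
    o <- o[o$person_id %in% c("X3", "X4", "X5"), ]
    o[order(o$person_id, o$concept_id), ]
  }
  expect_equal(bgOcc(pre), bgOcc(co), ignore_attr = TRUE)
  expect_identical(names(indexDates(pre)), caseIds(pre))
})

test_that("condition matrix binarizes, matches group-by counts, is idempotent under duplication", {
  co <- tinyCohort()
  uni <- conditionUniverse(co, exclude = tinyTables()$conceptSet)
  expect_setequal(uni, c("C1", "C2", "C3"))
  M <- buildConditionMatrix(co, uni)
  expect_true(all(M@x == 1))
  # column sums equal per-condition distinct-patient counts
  occ <- cohortOccurrences(co)
  occ <- occ[occ$concept_id %in% uni, ]
  oracle <- tapply(occ$person_id, occ$concept_id,
                   function(p) length(unique(p)))
  expect_equal(Matrix::colSums(M)[names(oracle)], oracle,
               ignore_attr = TRUE)
  # duplicating every occurrence changes nothing
  co2 <- makeCohort(cohortPersons(co),
                    rbind(cohortOccurrences(co), cohortOccurrences(co)),
                    cohortUtilization(co), tinyTables()$conceptSet)
  expect_equal(as.matrix(buildConditionMatrix(co2, uni)), as.matrix(M))
  expect_error(buildConditionMatrix(co, character()), "empty")
})

test_that("cohort tables round-trip through write and read", {
  co <- tinyCohort()
  dir <- withr::local_tempdir()
  writeCohortTables(co, dir)
  data.table::fwrite(tinyTables()$edges,
                     file.path(dir, "concept_ancestor.tsv"), sep = "\t")
  back <- readCohortTables(dir, "E0")
  expect_equal(cohortPersons(back), cohortPersons(co), ignore_attr = TRUE)
  ord <- function(o) {
    o <- o[order(o$person_id, o$concept_id, o$start_date), ]
    rownames(o) <- NULL
    o
  }
  expect_equal(ord(cohortOccurrences(back)), ord(cohortOccurrences(co)))
  expect_equal(cohortUtilization(back), cohortUtilization(co),
               ignore_attr = TRUE)
  expect_identical(caseIds(back), caseIds(co))
  expect_equal(indexDates(back), indexDates(co))
})
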