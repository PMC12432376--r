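# two well-separated Gaussian blobs in 5 dimensions
blobs <- function(n = 60, sep = 20, seed = 9) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n / 2 * 5), ncol = 5),
               matrix(rnorm(n / 2 * 5, mean = sep), ncol = 5))
    rownames(x) <- paste0("p", seq_len(n))
    x
  })
}

test_that("PCA reduction respects rank, duplicates and reconstruction", {
  set.seed(10)
  base <- matrix(rbinom(12 * 3, 1, 0.5), 12, 3)
  x <- cbind(base, base, base[, 1] + 0)   # rank <= 3 plus centering
  x <- x[, sample(ncol(x))]
  rownames(x) <- paste0("r", 1:12)
  red <- reduceDimensions(x, 1000L)
  expect_lte(red$nComponents, ncol(x) - 1L)
  expect_equal(red$varianceExplained, 1, tolerance = 1e-10)

  # reconstruction error is ~0 once every component is kept (the component
  # count is capped at ncol - 1, so use a matrix whose rank fits that cap)
  y <- matrix(rbinom(30 * 7, 1, 0.4), 30, 7)
  y <- cbind(y, y[, 3])
  rownames(y) <- paste0("q", 1:30)
  redy <- reduceDimensions(y, 1000L)
  rec <- redy$scores %*% t(redy$rotation)
  rec <- sweep(rec, 2, colMeans(y), `+`)
  expect_lt(max(abs(rec - y)), 1e-8)

  # duplicated rows embed identically
  dup <- rbind(y, y[3, , drop = FALSE])
  rownames(dup) <- c(rownames(y), "dup")
  redd <- reduceDimensions(dup, 4L)
  expect_equal(redd$scores["dup", ], redd$scores["q3", ],
               ignore_attr = TRUE)
  expect_error(reduceDimensions(matrix(0, 5, 5)), "all-zero")
})

test_that("kNN graph is symmetric and respects blob separation", {
  x <- blobs()
  g <- buildKnnGraph(x, kNeighbors = 5L)
  expect_false(igraph::is_directed(g))
  expect_gte(min(igraph::degree(g)), 1)
  # no cross-blob edges at 20-SD separation
  ends <- igraph::as_edgelist(g)
  side <- function(v) as.integer(sub("p", "", v)) <= 30
  expect_true(all(side(ends[, 1]) == side(ends[, 2])))
  # exhaustive-distance oracle: each node's graph neighbourhood contains
  # its true nearest neighbour
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  for (v in c("p1", "p17", "p45")) {
    nn <- rownames(x)[which.min(d[v, ])]
    expect_true(nn %in% names(igraph::neighbors(g, v)))
  }
})

test_that("leiden partition recovers trivial community structure", {
  # two disconnected 6-cliques
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(6))
  igraph::V(g)$name <- paste0("v", 1:12)
  igraph::E(g)$weight <- 1
  cl <- leidenPartition(g, resolution = 1.0, seed = 1L)
  lab <- clusterLabels(cl)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:6])), 1)
  expect_equal(length(unique(lab[7:12])), 1)

  g1 <- igraph::make_full_graph(8)
  igraph::V(g1)$name <- paste0("w", 1:8)
  igraph::E(g1)$weight <- 1
  expect_equal(length(unique(clusterLabels(
    leidenPartition(g1, seed = 1L)))), 1)
  expect_error(leidenPartition(igraph::make_empty_graph(0)), "empty")
})

test_that("identical resolutions give identical partitions; labels partition the cases", {
  x <- blobs()
  g <- buildKnnGraph(x, kNeighbors = 5L)
  sw <- sweepResolution(g, c(1.0, 1.0), seed = 3L)
  expect_identical(clusterLabels(sw$results[[1]]),
                   clusterLabels(sw$results[[2]]))
  expect_equal(sw$stability["1", "1"], 1)
  lab <- clusterLabels(sw$results[[1]])
  expect_setequal(names(lab), rownames(x))
  u <- sort(unique(lab))
  expect_identical(u, seq_along(u) - 1L)
  expect_error(sweepResolution(g, numeric()), "empty")
})

test_that("cluster enrichment flags extreme and uniform conditions correctly", {
  set.seed(11)
  n <- 80
  labels <- setNames(rep(0:1, each = n / 2), paste0("p", 1:n))
  M <- cbind(
    onlyC1 = c(rep(0, n / 2), rbinom(n / 2, 1, 0.9)),  # cluster-1 only
    uniform = rbinom(n, 1, 0.5),
    rare = rbinom(n, 1, 0.05)
  )
  rownames(M) <- names(labels)
  enr <- clusterEnrichment(M, labels, alpha = 0.05)
  e1 <- enr[enr$cluster == 1 & enr$concept_id == "onlyC1", ]
  expect_true(e1$enriched && e1$exclusive)
  expect_false(any(enr$enriched[enr$concept_id == "uniform"]))
  # exclusive sets pairwise disjoint
  ex <- exclusiveSets(enr)
  expect_length(intersect(ex[["0"]], ex[["1"]]), 0)
  # enrichment reuses the shared hypergeometric/odds-ratio core
  cnt <- contingencyCounts(M, names(labels)[labels == 1],
                           names(labels)[labels == 0], "onlyC1")
  expect_equal(e1$p_value, hypergeomPvalue(cnt))
  expect_equal(e1$odds_ratio, oddsRatio(cnt))
  expect_equal(e1$corrected_p, bonferroni(hypergeomPvalue(cnt), 3))
})

test_that("umap embedding has the right shape, is seeded, and separates blobs", {
  x <- blobs()
  u1 <- umapEmbed(x, seed = 5L)
  u2 <- umapEmbed(x, seed = 5L)
  expect_equal(dim(u1), c(nrow(x), 2))
  expect_identical(u1, u2)
  lab <- rep(c(0, 1), each = 30)
  dm <- as.matrix(dist(u1))
  intra <- mean(dm[lab == 0, lab == 0])
  inter <- mean(dm[lab == 0, lab == 1])
  expect_gt(inter, intra)
  expect_error(umapEmbed(x[1:3, ]), "nrow")
})

test_that("the full clustering pipeline recovers planted case subgroups", {
  cfg <- simulationConfig(
    nCases = 300L, nBackground = 600L, nConditions = 80L,
    caseUtilizationShift = 1, nSubgroups = 3L, signatureBoost = 5,
    seed = 13L
  )
  sim <- simulateCohort(cfg)
  co <- sim$cohort
  uni <- conditionUniverse(co, persons = caseIds(co),
                           exclude = sim$conceptSet)
  M <- buildConditionMatrix(co, uni, persons = caseIds(co))
  out <- clusterCases(M, kNeighbors = 15L, resolution = 1.0, seed = 1L)
  lab <- clusterLabels(out$clusters)
  ari <- mclust::adjustedRandIndex(lab, sim$truth$subgroup[names(lab)])
  expect_gte(ari, 0.8)
  expect_equal(out$clusters@nComponentsUsed, out$reduction$nComponents)
})
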