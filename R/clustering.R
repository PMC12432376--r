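#' PCA reduction of the binary diagnosis matrix
#'
#' Centres the patient-by-condition matrix and projects it onto its leading
#' principal components; the number of components is capped by the matrix
#' dimensions (`min(targetComponents, nrow - 1, ncol - 1)`). Component signs
#' follow the convention that each component's largest-magnitude loading is
#' positive, so results are reproducible across runs and platforms.
#'
#' @param matrix binary matrix (sparse or dense) with person ids as
#'   rownames.
#' @param targetComponents requested dimensionality (default 1000; with
#'   fewer conditions than that, the rank cap applies and the embedding is
#'   lossless).
#' @return list with `scores` (patients x components), `varianceExplained`
#'   (fraction of total variance retained), `nComponents`, and `rotation`.
#' @export
reduceDimensions <- function(matrix, targetComponents = 1000L) {
  x <- as.matrix(matrix)
  if (all(x == 0)) stop("degenerate all-zero matrix")
  stopifnot(targetComponents >= 2L)
  ncomp <- min(targetComponents, nrow(x) - 1L, ncol(x) - 1L)
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = ncomp)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, `*`)
  rotation <- sweep(pc$rotation, 2L, flip, `*`)
  rownames(scores) <- rownames(x)
  list(
    scores = scores,
    varianceExplained = sum(pc$sdev[seq_len(ncomp)]^2) / sum(pc$sdev^2),
    nComponents = ncomp,
    rotation = rotation
  )
}

#' Build a symmetrised k-nearest-neighbour graph
#'
#' Connects each patient to its `kNeighbors` nearest Euclidean neighbours in
#' the embedding, symmetrises by union, and weights each edge with a
#' locally scaled Gaussian kernel
#' \eqn{w_{ij} = \exp(-d_{ij}^2 / (\sigma_i \sigma_j))}, where
#' \eqn{\sigma_i} is patient i's distance to its `kNeighbors`-th neighbour
#' (so neighbourhood weights adapt to local density). Ties in distance are
#' resolved by node index.
#'
#' @param embedding numeric matrix (patients x components) with rownames.
#' @param kNeighbors neighbours per node (default 15); must be < nrow.
#' @return an undirected weighted [igraph::graph] with a `kernel` graph
#'   attribute recording the weighting scheme.
#' @export
buildKnnGraph <- function(embedding, kNeighbors = 15L) {
  n <- nrow(embedding)
  kNeighbors <- as.integer(kNeighbors)
  stopifnot(kNeighbors >= 1L, kNeighbors < n)
  nn <- RANN::nn2(embedding, k = kNeighbors + 1L)
  idx <- nn$nn.idx[, -1L, drop = FALSE]
  d <- nn$nn.dists[, -1L, drop = FALSE]
  sigma <- pmax(d[, kNeighbors], 1e-12)
  i <- rep(seq_len(n), each = kNeighbors)
  j <- as.vector(t(idx))
  dv <- as.vector(t(d))
  w <- exp(-dv^2 / (sigma[i] * sigma[j]))
  adj <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n),
                              dimnames = list(rownames(embedding),
                                              rownames(embedding)))
  adj <- pmaxSparse(adj, Matrix::t(adj))   # union symmetrisation
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  g <- igraph::set_graph_attr(g, "kernel",
    "locally scaled gaussian: exp(-d^2/(sigma_i*sigma_j)), sigma = k-th NN distance")
  g
}

# elementwise max of two sparse matrices with identical dims
pmaxSparse <- function(a, b) {
  ta <- Matrix::summary(a)
  tb <- Matrix::summary(b)
  key <- paste(c(ta$i, tb$i), c(ta$j, tb$j))
  x <- c(ta$x, tb$x)
  mx <- tapply(x, key, max)
  ij <- do.call(rbind, strsplit(names(mx), " ", fixed = TRUE))
  Matrix::sparseMatrix(
    i = as.integer(ij[, 1L]), j = as.integer(ij[, 2L]), x = as.numeric(mx),
    dims = dim(a), dimnames = dimnames(a)
  )
}

#' Leiden community detection on a neighbourhood graph
#'
#' Partitions the graph with the Leiden algorithm under the modularity
#' objective (the flavour used by standard single-cell/EHR clustering
#' stacks) at the given resolution. Cluster ids are relabelled 0-based in
#' order of decreasing size; the partition is deterministic given the seed.
#'
#' @param graph an undirected weighted igraph (from [buildKnnGraph()]).
#' @param resolution Leiden resolution parameter (default 1.0).
#' @param seed RNG seed.
#' @param nIterations Leiden refinement iterations (default 10).
#' @return a [ClusterResult-class].
#' @export
leidenPartition <- function(graph, resolution = 1.0, seed = 0L,
                            nIterations = 10L) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  memb <- withSeed(seed, igraph::cluster_leiden(
    graph,
    objective_function = "modularity",
    resolution = resolution,
    weights = igraph::E(graph)$weight,
    n_iterations = nIterations
  )$membership)
  sz <- table(memb)
  relabel <- setNames(seq_along(sz) - 1L,
                      names(sort(sz, decreasing = TRUE)))
  labels <- as.integer(relabel[as.character(memb)])
  names(labels) <- igraph::V(graph)$name
  new("ClusterResult",
    labels = labels, resolution = resolution,
    nComponentsUsed = NA_integer_, varianceExplained = NA_real_,
    kNeighbors = NA_integer_, seed = as.integer(seed)
  )
}

#' Stratify cases end to end: PCA, kNN graph, Leiden
#'
#' Convenience pipeline over [reduceDimensions()], [buildKnnGraph()] and
#' [leidenPartition()], recording the PCA and graph settings in the result.
#'
#' @param matrix binary case-by-condition matrix.
#' @param targetComponents PCA dimensionality cap (default 1000).
#' @param kNeighbors kNN graph degree (default 15).
#' @param resolution Leiden resolution (default 1.0).
#' @param seed RNG seed.
#' @return list with `clusters` (a [ClusterResult-class]), `reduction` (see
#'   [reduceDimensions()]) and `graph`.
#' @export
clusterCases <- function(matrix, targetComponents = 1000L, kNeighbors = 15L,
                         resolution = 1.0, seed = 0L) {
  red <- reduceDimensions(matrix, targetComponents)
  g <- buildKnnGraph(red$scores, kNeighbors)
  cl <- leidenPartition(g, resolution = resolution, seed = seed)
  cl@nComponentsUsed <- as.integer(red$nComponents)
  cl@varianceExplained <- red$varianceExplained
  cl@kNeighbors <- as.integer(kNeighbors)
  list(clusters = cl, reduction = red, graph = g)
}

#' Sweep the Leiden resolution and report partition stability
#'
#' One partition per requested resolution (same seed throughout) plus the
#' matrix of pairwise adjusted Rand indices between them, quantifying how
#' stable the subgroupings are across the sweep.
#'
#' @param graph the neighbourhood graph.
#' @param resolutions non-empty numeric vector (e.g. `c(0.5, 0.75, 1.0)`).
#' @param seed RNG seed.
#' @return list with `results` (list of [ClusterResult-class], named by
#'   resolution) and `stability` (pairwise ARI matrix).
#' @export
sweepResolution <- function(graph, resolutions, seed = 0L) {
  if (!length(resolutions)) stop("empty resolution list")
  res <- lapply(resolutions, function(r)
    leidenPartition(graph, resolution = r, seed = seed))
  names(res) <- as.character(resolutions)
  nr <- length(res)
  stab <- matrix(1, nr, nr, dimnames = list(names(res), names(res)))
  if (nr > 1L) {
    for (i in seq_len(nr - 1L)) for (j in seq.int(i + 1L, nr)) {
      a <- mclust::adjustedRandIndex(res[[i]]@labels, res[[j]]@labels)
      stab[i, j] <- stab[j, i] <- a
    }
  }
  list(results = res, stability = stab)
}

#' Per-cluster condition enrichment and exclusivity
#'
#' Re-applies the package's enrichment core within the clustering: for each
#' cluster, the "cases" are its patients and the "controls" are all other
#' clusters' patients; each condition present in any patient gets a
#' zero-cell-corrected odds ratio and a hypergeometric upper-tail p-value,
#' Bonferroni-corrected by the size of the tested universe. A condition is
#' *enriched* in a cluster when its corrected p is below `alpha` and its
#' odds ratio exceeds 1, and *exclusive* when it is enriched in exactly one
#' cluster (so exclusive sets are pairwise disjoint by construction).
#'
#' @param matrix binary patient-by-condition matrix covering the clustered
#'   patients.
#' @param labels integer cluster labels named by person id (e.g.
#'   [clusterLabels()]).
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `cluster`, `concept_id`, `odds_ratio`,
#'   `p_value`, `corrected_p`, `enriched`, `exclusive`, `low_power`
#'   (singleton cluster flag); the `alpha` used is attached as an attribute.
#' @seealso [enrichedSets()], [exclusiveSets()]
#' @export
clusterEnrichment <- function(matrix, labels, alpha = 0.05) {
  stopifnot(!is.null(names(labels)),
            all(names(labels) %in% rownames(matrix)))
  M <- matrix[names(labels), , drop = FALSE]
  keep <- Matrix::colSums(M > 0) > 0
  M <- M[, keep, drop = FALSE]
  mTests <- ncol(M)
  if (!mTests) stop("no condition present in any clustered patient")
  clusters <- sort(unique(labels))
  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    inIds <- names(labels)[labels == cl]
    outIds <- names(labels)[labels != cl]
    a <- Matrix::colSums(M[inIds, , drop = FALSE] > 0)
    cc <- Matrix::colSums(M[outIds, , drop = FALSE] > 0)
    nIn <- length(inIds)
    nOut <- length(outIds)
    or <- oddsRatio(a, nIn - a, cc, nOut - cc)
    p <- hypergeomPvalue(a, nIn - a, cc, nOut - cc)
    pc <- bonferroni(p, mTests)
    out[[ci]] <- data.frame(
      cluster = cl, concept_id = colnames(M),
      odds_ratio = or, p_value = p, corrected_p = pc,
      enriched = pc < alpha & or > 1,
      low_power = nIn < 2L,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  enrCount <- table(res$concept_id[res$enriched])
  res$exclusive <- res$enriched &
    enrCount[res$concept_id] == 1L & !is.na(enrCount[res$concept_id])
  res$exclusive[is.na(res$exclusive)] <- FALSE
  attr(res, "alpha") <- alpha
  res
}

#' Enriched / exclusive condition sets per cluster
#'
#' @param enrichment data.frame from [clusterEnrichment()].
#' @return named list (one element per cluster id) of concept-id vectors.
#' @export
enrichedSets <- function(enrichment) {
  lapply(split(enrichment, enrichment$cluster),
         function(d) d$concept_id[d$enriched])
}

#' @rdname enrichedSets
#' @export
exclusiveSets <- function(enrichment) {
  lapply(split(enrichment, enrichment$cluster),
         function(d) d$concept_id[d$exclusive])
}

#' 2-D UMAP embedding for reporting
#'
#' Projects the PCA scores to two dimensions with UMAP for visualisation
#' only — clustering never uses these coordinates. Deterministic given the
#' seed (single-threaded layout optimisation).
#'
#' @param embedding numeric matrix (patients x components), at least 4 rows.
#' @param seed RNG seed.
#' @param nNeighbors UMAP neighbourhood size (default 15, capped at
#'   nrow - 1).
#' @return numeric matrix (patients x 2) with the input rownames.
#' @export
umapEmbed <- function(embedding, seed = 0L, nNeighbors = 15L) {
  stopifnot(nrow(embedding) >= 4L)
  coords <- withSeed(seed, uwot::umap(
    as.matrix(embedding),
    n_neighbors = min(nNeighbors, nrow(embedding) - 1L),
    n_threads = 1, n_sgd_threads = 0
  ))
  rownames(coords) <- rownames(embedding)
  colnames(coords) <- c("x", "y")
  coords
}
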