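#' Intersection of significant conditions across two data sources
#'
#' @param tableA,tableB data.frames carrying `concept_id` and
#'   `significant_final` (from [applyUtilizationFilter()]) or `significant`
#'   (from [runAssociation()] results).
#' @return sorted character vector of concepts significant in both.
#' @export
overlapSignificant <- function(tableA, tableB) {
  sig <- function(t) {
    col <- if ("significant_final" %in% names(t)) "significant_final"
           else "significant"
    t$concept_id[t[[col]]]
  }
  sort(intersect(sig(tableA), sig(tableB)))
}

#' Pearson correlation of log odds ratios on the shared significant set
#'
#' Natural-log odds ratios are correlated; the base is irrelevant to r and
#' its p-value (scale invariance). At least 3 shared conditions are required
#' for a reported correlation; degenerate (zero-variance) inputs yield a
#' structured "undefined" result rather than an error.
#'
#' @param tableA,tableB association tables carrying `concept_id` and
#'   `mean_or`.
#' @param shared concept ids to correlate over (e.g. from
#'   [overlapSignificant()]).
#' @return list with `r`, `p`, `n`, and `reason` (`NA` unless undefined).
#' @export
logOrCorrelation <- function(tableA, tableB, shared) {
  n <- length(shared)
  if (n < 3L)
    return(list(r = NA_real_, p = NA_real_, n = n,
                reason = "insufficient overlap (< 3 shared conditions)"))
  la <- log(tableA$mean_or[match(shared, tableA$concept_id)])
  lb <- log(tableB$mean_or[match(shared, tableB$concept_id)])
  stopifnot(all(is.finite(la)), all(is.finite(lb)))
  if (var(la) == 0 || var(lb) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n,
                reason = "zero variance in log odds ratios"))
  ct <- cor.test(la, lb, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, reason = NA_character_)
}

#' Jaccard similarity of two sets
#'
#' `|A intersect B| / |A union B|`, defined as 0 when both sets are empty.
#'
#' @param setA,setB vectors treated as sets.
#' @return numeric in \[0, 1\].
#' @export
jaccardIndex <- function(setA, setB) {
  u <- length(union(setA, setB))
  if (u == 0L) return(0)
  length(intersect(setA, setB)) / u
}

#' Match clusters across data sources by enriched-condition overlap
#'
#' Directional greatest-overlap matching (A to B, mirroring a
#' discovery-to-replication framing): each A-cluster with at least one
#' enriched condition shared with some B-cluster is matched to the B-cluster
#' with the largest overlap; ties are broken by larger Jaccard similarity,
#' then by smaller B cluster id. A-clusters overlapping nothing stay
#' unmatched; a B-cluster may receive several A-clusters. With
#' `mutual = TRUE` the reciprocal-best pairs are flagged as well.
#'
#' @param enrichA,enrichB [clusterEnrichment()] outputs (or named lists of
#'   enriched concept sets).
#' @param mutual also report whether each match is reciprocal-best.
#' @return list with `matches`: data.frame (`cluster_a`, `cluster_b`,
#'   `n_overlapping_enriched`, `fraction_a_covered`, `jaccard`, and
#'   `mutual` when requested), `unmatched_a`, `unmatched_b`.
#' @export
matchClusters <- function(enrichA, enrichB, mutual = FALSE) {
  setsA <- if (is.data.frame(enrichA)) enrichedSets(enrichA) else enrichA
  setsB <- if (is.data.frame(enrichB)) enrichedSets(enrichB) else enrichB
  best <- function(sets1, sets2) {
    rows <- lapply(names(sets1), function(a) {
      sa <- sets1[[a]]
      if (!length(sa)) return(NULL)
      ov <- vapply(sets2, function(sb) length(intersect(sa, sb)), integer(1))
      if (!length(ov) || max(ov) == 0L) return(NULL)
      jc <- vapply(sets2, function(sb) jaccardIndex(sa, sb), numeric(1))
      cand <- names(sets2)[ov == max(ov)]
      cand <- cand[jc[cand] == max(jc[cand])]
      b <- cand[order(as.numeric(cand))][1L]
      data.frame(
        cluster_a = as.integer(a), cluster_b = as.integer(b),
        n_overlapping_enriched = max(ov),
        fraction_a_covered = max(ov) / length(sa),
        jaccard = jc[[b]],
        row.names = NULL, stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  }
  mAB <- best(setsA, setsB)
  if (is.null(mAB))
    mAB <- data.frame(cluster_a = integer(), cluster_b = integer(),
                      n_overlapping_enriched = integer(),
                      fraction_a_covered = numeric(), jaccard = numeric())
  if (mutual) {
    mBA <- best(setsB, setsA)
    mAB$mutual <- vapply(seq_len(nrow(mAB)), function(i) {
      any(mBA$cluster_a == mAB$cluster_b[i] &
          mBA$cluster_b == mAB$cluster_a[i])
    }, logical(1))
  }
  list(
    matches = mAB,
    unmatched_a = setdiff(as.integer(names(setsA)), mAB$cluster_a),
    unmatched_b = setdiff(as.integer(names(setsB)), mAB$cluster_b)
  )
}

#' Full cross-source concordance report
#'
#' Bundles the shared-significant set, the log-odds-ratio correlation on it,
#' and the cluster matching into one object.
#'
#' @param assocA,assocB final association tables (see
#'   [applyUtilizationFilter()]).
#' @param enrichA,enrichB [clusterEnrichment()] outputs.
#' @param mutual passed to [matchClusters()].
#' @return list with `shared`, `correlation`, `clusterMatches`.
#' @export
concordanceReport <- function(assocA, assocB, enrichA, enrichB,
                              mutual = FALSE) {
  shared <- overlapSignificant(assocA, assocB)
  list(
    shared = shared,
    correlation = logOrCorrelation(assocA, assocB, shared),
    clusterMatches = matchClusters(enrichA, enrichB, mutual = mutual)
  )
}

#' Cross-tabulate cluster membership between two labelings
#'
#' Counts patients by (labeling-1 cluster, labeling-2 cluster) over the
#' intersection of the two labeled patient sets — e.g. pre-index versus
#' full-record clusterings of the same cases — in a long, flow-diagram-ready
#' format. Row/column marginals equal the per-cluster sizes on the shared
#' patients by construction.
#'
#' @param labelsPre,labelsFull integer cluster labels named by person id.
#' @return data.frame (`cluster_pre`, `cluster_full`, `n_patients`) covering
#'   all label combinations (including zero cells); patients present in only
#'   one labeling are reported via the `dropped` attribute.
#' @export
membershipCrosstab <- function(labelsPre, labelsFull) {
  shared <- intersect(names(labelsPre), names(labelsFull))
  if (!length(shared)) stop("the two labelings share no patients")
  tab <- table(cluster_pre = labelsPre[shared],
               cluster_full = labelsFull[shared])
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  out$cluster_pre <- as.integer(out$cluster_pre)
  out$cluster_full <- as.integer(out$cluster_full)
  names(out)[3L] <- "n_patients"
  out <- out[order(out$cluster_pre, out$cluster_full), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- setdiff(union(names(labelsPre), names(labelsFull)),
                                  shared)
  out
}

#' Export / read the cross-source bipartite cluster graph
#'
#' Writes the matched-cluster structure as a GraphML file (a standard text
#' graph-exchange format): one node per cluster with attributes `side`
#' (`"A"`/`"B"`), `size` (patient count) and `n_exclusive` (exclusively
#' enriched conditions), and one edge per match with attributes
#' `fraction_a_covered` and `jaccard`. `readBipartite()` round-trips the
#' file back into node and edge tables.
#'
#' @param matches result of [matchClusters()].
#' @param enrichA,enrichB [clusterEnrichment()] outputs (for `n_exclusive`).
#' @param sizesA,sizesB named numeric vectors of per-cluster patient counts.
#' @param file output path (`.graphml`).
#' @return `file`, invisibly.
#' @export
exportBipartite <- function(matches, enrichA, enrichB, sizesA, sizesB,
                            file) {
  exA <- exclusiveSets(enrichA)
  exB <- exclusiveSets(enrichB)
  nodeName <- function(side, id) {
    if (!length(id)) return(character())
    paste0(side, "_", id)
  }
  nodes <- data.frame(
    name = c(nodeName("A", names(sizesA)), nodeName("B", names(sizesB))),
    side = c(rep("A", length(sizesA)), rep("B", length(sizesB))),
    size = as.numeric(c(sizesA, sizesB)),
    n_exclusive = c(
      vapply(names(sizesA), function(i) length(exA[[i]] %||% character()),
             integer(1)),
      vapply(names(sizesB), function(i) length(exB[[i]] %||% character()),
             integer(1))
    ),
    stringsAsFactors = FALSE
  )
  m <- matches$matches
  edges <- data.frame(
    from = nodeName("A", m$cluster_a), to = nodeName("B", m$cluster_b),
    fraction_a_covered = m$fraction_a_covered, jaccard = m$jaccard,
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' @rdname exportBipartite
#' @param path a GraphML file written by [exportBipartite()].
#' @return `readBipartite` returns a list with `nodes` and `edges`
#'   data.frames mirroring what was exported.
#' @export
readBipartite <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  rownames(nodes) <- NULL
  splitId <- function(x) as.integer(sub("^[AB]_", "", x))
  if (nrow(edges)) {
    edges$cluster_a <- splitId(edges$from)
    edges$cluster_b <- splitId(edges$to)
  }
  list(nodes = nodes, edges = edges)
}
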