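#' 2x2 contingency counts for one condition
#'
#' @param matrix binary patient-by-condition matrix (rows named by person
#'   id), as from [buildConditionMatrix()].
#' @param caseIds,controlIds disjoint person id vectors present in the
#'   matrix rows.
#' @param concept concept id (a matrix column).
#' @return named numeric vector `c(a, b, c, d)`: cases with / without the
#'   condition, controls with / without.
#' @export
contingencyCounts <- function(matrix, caseIds, controlIds, concept) {
  if (length(intersect(caseIds, controlIds)))
    stop("caseIds and controlIds overlap")
  stopifnot(concept %in% colnames(matrix))
  a <- sum(matrix[caseIds, concept] > 0)
  cc <- sum(matrix[controlIds, concept] > 0)
  c(a = a, b = length(caseIds) - a, c = cc, d = length(controlIds) - cc)
}

#' Odds ratio of a 2x2 table, Haldane-Anscombe corrected at zero cells
#'
#' Returns `(a d) / (b c)` when every cell is positive; if any cell is zero,
#' 0.5 is added to all four cells (Haldane-Anscombe) so the ratio stays
#' finite and positive, which keeps replicate means well defined.
#'
#' All arguments are vectorised; `counts` may also be the vector returned by
#' [contingencyCounts()].
#'
#' @param counts numeric vector `c(a, b, c, d)`, or `a` alone with `b`, `c`,
#'   `d` supplied.
#' @param b,c,d remaining cells when `counts` is `a`.
#' @return positive numeric odds ratio(s).
#' @export
oddsRatio <- function(counts, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) {
    a <- counts[["a"]]; b <- counts[["b"]]
    cc <- counts[["c"]]; d <- counts[["d"]]
  } else {
    a <- counts; cc <- c
  }
  zero <- a == 0 | b == 0 | cc == 0 | d == 0
  h <- ifelse(zero, 0.5, 0)
  ((a + h) * (d + h)) / ((b + h) * (cc + h))
}

#' Hypergeometric enrichment p-value for a 2x2 table
#'
#' Upper-tail probability \eqn{P[X \ge a]} with \eqn{X \sim
#' \mathrm{Hypergeom}(N = a+b+c+d,\ K = a+c,\ n = a+b)}: the chance of
#' drawing at least `a` condition-positive patients when the case group of
#' size `n` is drawn at random from the pooled study group. With
#' `lower = TRUE` the analogous depletion tail \eqn{P[X \le a]} is returned
#' (used for protective associations). Vectorised like [oddsRatio()].
#'
#' @inheritParams oddsRatio
#' @param lower return the lower (depletion) tail instead.
#' @return p-value(s) in (0, 1].
#' @export
hypergeomPvalue <- function(counts, b = NULL, c = NULL, d = NULL,
                            lower = FALSE) {
  if (is.null(b)) {
    a <- counts[["a"]]; b <- counts[["b"]]
    cc <- counts[["c"]]; d <- counts[["d"]]
  } else {
    a <- counts; cc <- c
  }
  K <- a + cc
  N <- a + b + cc + d
  n <- a + b
  if (lower) phyper(a, K, N - K, n)
  else phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` where `m` is the number of conditions tested in the same
#' iteration.
#'
#' @param p p-value(s).
#' @param m number of tests (>= 1).
#' @return corrected p-value(s).
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

#' Aggregate odds ratios and corrected p-values across replicate groups
#'
#' The replicate summary used throughout the package: the arithmetic mean of
#' the per-replicate odds ratios, and an aggregated p-value defined as twice
#' the mean corrected p-value, capped at 1. The cap is needed because the
#' twice-the-mean combination rule can exceed 1; the rule itself is a valid
#' p-value combination for arbitrarily dependent replicates.
#'
#' @param ors numeric vector of per-replicate odds ratios.
#' @param correctedPs numeric vector of per-replicate corrected p-values
#'   (same length).
#' @return list with `mean_or` and `aggregated_p`.
#' @export
aggregateReplicates <- function(ors, correctedPs) {
  stopifnot(length(ors) == length(correctedPs), length(ors) >= 1L)
  list(mean_or = mean(ors), aggregated_p = min(1, 2 * mean(correctedPs)))
}

#' Replicated case-control comorbidity association analysis
#'
#' For each replicate control group g: the iteration's condition universe is
#' every analysed concept present in at least one case or one group-g
#' control; each such condition gets an odds ratio
#' (Haldane-Anscombe-corrected at zero cells) and hypergeometric enrichment
#' and depletion p-values, Bonferroni-corrected by that iteration's universe
#' size. Conditions absent from an iteration's universe contribute a
#' corrected p of 1 (and the zero-cell-corrected odds ratio), so aggregation
#' over the k replicates is always defined. Per condition, the replicate
#' odds ratios are averaged and the aggregated p is twice the mean corrected
#' p, capped at 1.
#'
#' @param cohort a [Cohort-class] (use [restrictPreIndex()] first for the
#'   pre-index analysis mode).
#' @param matched a [MatchedCohort-class] over this cohort's cases.
#' @param conceptSet optional case-defining [ConceptSet-class]; its members
#'   are excluded from the tested universe (they define the case roster, so
#'   testing them is circular).
#' @param alpha significance level for the `significant` flags (default
#'   0.05, applied to the aggregated p).
#' @param minPrevalence minimum patient count for a concept to enter the
#'   analysed universe.
#' @param chapterMap optional data.frame (`concept_id`, `chapter_label`) to
#'   annotate the results.
#' @return an [AssociationTable-class]. Its `results` slot has one row per
#'   condition with columns `concept_id`, `n_case_with`, `mean_or`,
#'   `aggregated_p` (enrichment), `aggregated_p_depletion`, `significant`,
#'   `significant_depletion`, `n_replicates_tested` and optionally
#'   `chapter_label`.
#' @export
runAssociation <- function(cohort, matched, conceptSet = NULL, alpha = 0.05,
                           minPrevalence = 1L, chapterMap = NULL) {
  stopifnot(is(cohort, "Cohort"), is(matched, "MatchedCohort"))
  cases <- matched@caseIds
  mt <- matched@matches
  if (any(tapply(mt$control_id, mt$replicate, length) == 0L))
    stop("a replicate group has zero controls")
  allIds <- c(cases, unique(mt$control_id))
  universe <- conditionUniverse(cohort, persons = allIds,
                                exclude = conceptSet,
                                minPrevalence = minPrevalence)
  if (!length(universe)) stop("empty condition universe")
  M <- buildConditionMatrix(cohort, universe, persons = allIds)
  k <- matched@k
  nCond <- length(universe)
  aCase <- Matrix::colSums(M[cases, , drop = FALSE] > 0)
  nCase <- length(cases)

  orMat <- matrix(NA_real_, nCond, k, dimnames = list(universe, NULL))
  pMat <- matrix(NA_real_, nCond, k)
  pMatLo <- matrix(NA_real_, nCond, k)
  tested <- matrix(FALSE, nCond, k)
  ctlByRep <- split(mt$control_id, mt$replicate)
  for (g in seq_len(k)) {
    ctl <- ctlByRep[[g]]
    cCtl <- Matrix::colSums(M[ctl, , drop = FALSE] > 0)
    nCtl <- length(ctl)
    present <- aCase > 0 | cCtl > 0
    mG <- sum(present)
    pUp <- hypergeomPvalue(aCase, nCase - aCase, cCtl, nCtl - cCtl)
    pLo <- hypergeomPvalue(aCase, nCase - aCase, cCtl, nCtl - cCtl,
                           lower = TRUE)
    orMat[, g] <- oddsRatio(aCase, nCase - aCase, cCtl, nCtl - cCtl)
    pMat[, g] <- ifelse(present, bonferroni(pUp, mG), 1)
    pMatLo[, g] <- ifelse(present, bonferroni(pLo, mG), 1)
    tested[, g] <- present
  }
  meanOR <- rowMeans(orMat)
  aggP <- pmin(1, 2 * rowMeans(pMat))
  aggPLo <- pmin(1, 2 * rowMeans(pMatLo))
  res <- data.frame(
    concept_id = universe,
    n_case_with = as.integer(aCase),
    mean_or = meanOR,
    aggregated_p = aggP,
    aggregated_p_depletion = aggPLo,
    significant = aggP < alpha,
    significant_depletion = aggPLo < alpha,
    n_replicates_tested = rowSums(tested),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(chapterMap))
    res$chapter_label <- chapterMap$chapter_label[
      match(res$concept_id, chapterMap$concept_id)]
  new("AssociationTable",
    results = res, replicateOR = orMat, replicateP = pMat,
    replicatePDepletion = pMatLo, alpha = alpha, k = k
  )
}

#' Dual utilization-matched significance filter
#'
#' A condition is significant in the final analysis only if it is
#' significant against the demographically matched controls *and* remains
#' significant against the utilization-matched controls; this removes
#' associations driven solely by healthcare contact frequency. Conditions
#' untested in either table are non-significant. Enrichment and depletion
#' tails are filtered separately.
#'
#' @param primary [AssociationTable-class] from demographic-only matching.
#' @param utilization [AssociationTable-class] from utilization-augmented
#'   matching on the same cases.
#' @param alpha significance level on the aggregated p (default 0.05).
#' @return data.frame with one row per condition in either universe:
#'   `concept_id`, `mean_or` (primary), `mean_or_utilization`,
#'   `aggregated_p_primary`, `aggregated_p_utilization`,
#'   `significant_primary`, `significant_utilization`, `significant_final`,
#'   and the depletion-tail analogues.
#' @export
applyUtilizationFilter <- function(primary, utilization, alpha = 0.05) {
  stopifnot(is(primary, "AssociationTable"),
            is(utilization, "AssociationTable"))
  p <- primary@results
  u <- utilization@results
  ids <- sort(union(p$concept_id, u$concept_id))
  ip <- match(ids, p$concept_id)
  iu <- match(ids, u$concept_id)
  val <- function(x, i, col, fill = NA_real_) {
    out <- rep(fill, length(i))
    ok <- !is.na(i)
    out[ok] <- x[[col]][i[ok]]
    out
  }
  pp <- val(p, ip, "aggregated_p", fill = 1)
  pu <- val(u, iu, "aggregated_p", fill = 1)
  dp <- val(p, ip, "aggregated_p_depletion", fill = 1)
  du <- val(u, iu, "aggregated_p_depletion", fill = 1)
  sigP <- pp < alpha
  sigU <- pu < alpha
  out <- data.frame(
    concept_id = ids,
    mean_or = val(p, ip, "mean_or"),
    mean_or_utilization = val(u, iu, "mean_or"),
    aggregated_p_primary = pp,
    aggregated_p_utilization = pu,
    significant_primary = sigP,
    significant_utilization = sigU,
    significant_final = sigP & sigU,
    aggregated_p_depletion_primary = dp,
    aggregated_p_depletion_utilization = du,
    significant_final_depletion = dp < alpha & du < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if ("chapter_label" %in% names(p))
    out$chapter_label <- p$chapter_label[ip]
  out
}
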