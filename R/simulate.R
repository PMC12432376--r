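#' Build a synthetic-cohort generator configuration
#'
#' Resolves all generator settings into a validated
#' [SimulationConfig-class]. Unspecified per-condition vectors are drawn
#' once, reproducibly from `seed`: baseline intercepts uniform on
#' \[-5, -2.5\] (per-condition background prevalence roughly 0.7--8%,
#' the sparse regime typical of coded diagnoses), case effects and
#' utilization effects zero (null conditions) unless supplied.
#'
#' Default study conditions: 2,000 cases against a 31-fold background (a
#' full 1:30 match stays feasible even after background persons with no
#' conditions drop out of the eligible pool), 200 conditions, a mean of 20 recorded visits
#' with negative-binomial dispersion `size = 2`, a 1.5-fold case utilization
#' shift (cases interact more with the healthcare system), 4 latent case
#' subgroups with 8 signature conditions each boosted by +5 logits
#' (within-subgroup prevalence ~0.6--0.75 against <=0.05 outside), record
#' spans of 1--10 years, and the index date at the 0.6 quantile of a case's
#' span so pre-index analyses retain most of the record.
#'
#' @param nCases,nBackground,nConditions cohort dimensions; `nBackground`
#'   defaults to `31 * nCases`.
#' @param demographics list with probability vectors `gender`, `race`,
#'   `ethnicity` and numbers `age_mean`, `age_sd`.
#' @param baselineLogit,caseEffect,utilizationEffect per-condition vectors
#'   (recycled from scalars); see [SimulationConfig-class].
#' @param caseUtilizationShift multiplier on mean visits for cases.
#' @param meanVisits,visitDispersion negative-binomial visit model.
#' @param nSubgroups,signatureConditions,signatureBoost latent case subgroup
#'   structure; `signatureConditions` defaults to `nSubgroups` disjoint
#'   blocks of 8 conditions taken from the end of the condition vector.
#' @param recordSpanDays length-2 range of record durations (days).
#' @param indexQuantile where along the record span the index date falls.
#' @param seed integer RNG seed.
#' @return a [SimulationConfig-class].
#' @seealso [simulateCohort()], [simulateTwoSites()]
#' @export
simulationConfig <- function(nCases = 2000L,
                             nBackground = 31L * nCases,
                             nConditions = 200L,
                             demographics = NULL,
                             baselineLogit = NULL,
                             caseEffect = 0,
                             utilizationEffect = 0,
                             caseUtilizationShift = 1.5,
                             meanVisits = 20,
                             visitDispersion = 2,
                             nSubgroups = 4L,
                             signatureConditions = NULL,
                             signatureBoost = 5,
                             recordSpanDays = c(365, 3650),
                             indexQuantile = 0.6,
                             seed = 1L) {
  if (is.null(demographics)) {
    demographics <- list(
      gender = c(female = 0.97, male = 0.02, unknown = 0.01),
      race = c(white = 0.45, asian = 0.15, black = 0.08, other = 0.22,
               unknown = 0.10),
      ethnicity = c(not_hispanic = 0.72, hispanic = 0.18, unknown = 0.10),
      age_mean = 38, age_sd = 12
    )
  }
  if (is.null(baselineLogit)) {
    baselineLogit <- withSeed(seed, runif(nConditions, -5, -2.5))
  }
  rec <- function(x) rep_len(as.numeric(x), nConditions)
  if (is.null(signatureConditions)) {
    per <- 8L
    need <- nSubgroups * per
    if (need > nConditions) stop("not enough conditions for default signatures")
    idx <- seq.int(nConditions - need + 1L, nConditions)
    signatureConditions <- split(idx, rep(seq_len(nSubgroups), each = per))
  }
  signatureConditions <- lapply(signatureConditions, as.integer)
  new("SimulationConfig",
    nCases = as.integer(nCases), nBackground = as.integer(nBackground),
    nConditions = as.integer(nConditions), demographics = demographics,
    baselineLogit = rec(baselineLogit), caseEffect = rec(caseEffect),
    utilizationEffect = rec(utilizationEffect),
    caseUtilizationShift = as.numeric(caseUtilizationShift),
    meanVisits = as.numeric(meanVisits),
    visitDispersion = as.numeric(visitDispersion),
    nSubgroups = as.integer(nSubgroups),
    signatureConditions = signatureConditions,
    signatureBoost = as.numeric(signatureBoost),
    recordSpanDays = as.numeric(recordSpanDays),
    indexQuantile = as.numeric(indexQuantile),
    seed = as.integer(seed)
  )
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a ground-truthed synthetic EHR cohort
#'
#' Generates one data source's flat tables with known ground truth:
#' demographics drawn independently of case status from the configured
#' margins; over-dispersed (negative-binomial) visit counts whose mean is
#' scaled by `caseUtilizationShift` for cases; and condition occurrence from
#' the per-person, per-condition logistic model
#' \deqn{\mathrm{logit}\, p_{ij} = \beta_{0j} + \beta_{\mathrm{case},j}
#'   \mathbb{1}[i\ \mathrm{case}] + \beta_{\mathrm{util},j}\log(1 + v_i) +
#'   b\,\mathbb{1}[i \in \mathrm{subgroup\ owning\ } j],}
#' with \eqn{v_i} the visit count and \eqn{b} the subgroup signature boost.
#' Each present condition is dated uniformly over the person's record span;
#' each case receives an index-concept occurrence (a member of the emitted
#' concept set) at the configured quantile of their span. Latent subgroups
#' apply to cases only. Output is byte-identical under a fixed seed.
#'
#' @param config a [SimulationConfig-class].
#' @param idPrefix prefix for person ids (used by [simulateTwoSites()] to
#'   keep site namespaces disjoint).
#' @return list with elements `cohort` (a [Cohort-class]), `conceptSet` (the
#'   case-defining [ConceptSet-class]), `ancestorEdges` (its hierarchy), and
#'   `truth`: a list with `caseFlags` (logical named by person id),
#'   `indexDates`, `caseEffect`, `trueLogOR` (the realized marginal
#'   case-vs-background log odds ratio implied by the generative model,
#'   which folds in any subgroup- or utilization-driven enrichment),
#'   `baselineLogit`, `utilizationEffect`,
#'   `confounded` (logical: null case effect but non-null utilization
#'   effect), `subgroup` (integer named by case id), `signatureConcepts`
#'   (list of concept-id vectors per subgroup), and `nVisits`.
#' @export
simulateCohort <- function(config, idPrefix = "P") {
  stopifnot(is(config, "SimulationConfig"))
  withSeed(config@seed, .simulateCohortImpl(config, idPrefix))
}

.simulateCohortImpl <- function(config, idPrefix) {
  nCase <- config@nCases
  nBg <- config@nBackground
  n <- nCase + nBg
  nc <- config@nConditions
  ids <- sprintf("%s%07d", idPrefix, seq_len(n))
  isCase <- c(rep(TRUE, nCase), rep(FALSE, nBg))
  dem <- config@demographics

  drawCat <- function(margin) {
    sample(names(margin), n, replace = TRUE, prob = margin)
  }
  persons <- data.frame(
    person_id = ids,
    age = round(pmin(pmax(rnorm(n, dem$age_mean, dem$age_sd), 18), 90), 1),
    gender = drawCat(dem$gender),
    race = drawCat(dem$race),
    ethnicity = drawCat(dem$ethnicity),
    site = idPrefix,
    stringsAsFactors = FALSE
  )

  mu <- config@meanVisits * ifelse(isCase, config@caseUtilizationShift, 1)
  nVisits <- rnbinom(n, size = config@visitDispersion, mu = mu)
  span <- round(runif(n, config@recordSpanDays[1], config@recordSpanDays[2]))
  recordStart <- as.Date("2005-01-01") + sample.int(3652L, n, replace = TRUE)
  utilization <- data.frame(
    person_id = ids, n_visits = nVisits, record_duration_days = span,
    stringsAsFactors = FALSE
  )

  subgroup <- sample.int(config@nSubgroups, nCase, replace = TRUE)

  eta <- matrix(config@baselineLogit, n, nc, byrow = TRUE)
  eta <- eta + tcrossprod(log1p(nVisits), config@utilizationEffect)
  eta[isCase, ] <- eta[isCase, ] + matrix(config@caseEffect, nCase, nc,
                                          byrow = TRUE)
  for (s in seq_len(config@nSubgroups)) {
    sig <- config@signatureConditions[[s]]
    if (length(sig))
      eta[which(isCase)[subgroup == s], sig] <-
        eta[which(isCase)[subgroup == s], sig] + config@signatureBoost
  }
  if (any(abs(eta) > 36))
    warning("some occurrence probabilities saturate at 0/1 after clamping")
  p <- plogis(eta)
  # realized marginal odds ratio of each condition, case vs background,
  # averaging the generative probabilities over the drawn visit counts and
  # subgroup memberships (the target a matched-demographics contrast
  # estimates, since demographics are independent of conditions here)
  pCase <- colMeans(p[isCase, , drop = FALSE])
  pBg <- colMeans(p[!isCase, , drop = FALSE])
  trueLogOR <- qlogis(pCase) - qlogis(pBg)
  occ <- which(matrix(runif(n * nc), n, nc) < p, arr.ind = TRUE)
  conceptIds <- sprintf("C%04d", seq_len(nc))
  occDates <- recordStart[occ[, 1L]] +
    floor(runif(nrow(occ)) * (span[occ[, 1L]] + 1))

  # case-defining concept hierarchy: a root with three descendants
  rootId <- "D0000"
  descIds <- c("D0001", "D0002", "D0003")
  ancestorEdges <- data.frame(ancestor_id = rootId, descendant_id = descIds,
                              stringsAsFactors = FALSE)
  conceptSet <- closeConceptSet(rootId, ancestorEdges)
  indexOffset <- floor(config@indexQuantile * span[seq_len(nCase)])
  indexDates <- recordStart[seq_len(nCase)] + indexOffset

  # assemble and sort by integer keys (radix) rather than id strings
  allConcepts <- c(conceptIds, descIds)
  iAll <- c(occ[, 1L], seq_len(nCase))
  jAll <- c(occ[, 2L], nc + sample.int(3L, nCase, replace = TRUE))
  dAll <- c(occDates, indexDates)
  ord <- order(iAll, jAll, dAll)
  occurrences <- data.frame(
    person_id = ids[iAll[ord]],
    concept_id = allConcepts[jAll[ord]],
    start_date = dAll[ord],
    stringsAsFactors = FALSE
  )

  cohort <- new("Cohort",
    persons = persons, occurrences = occurrences, utilization = utilization,
    caseIds = ids[seq_len(nCase)],
    indexDates = setNames(indexDates, ids[seq_len(nCase)])
  )
  truth <- list(
    caseFlags = setNames(isCase, ids),
    indexDates = setNames(indexDates, ids[seq_len(nCase)]),
    caseEffect = setNames(config@caseEffect, conceptIds),
    trueLogOR = setNames(trueLogOR, conceptIds),
    baselineLogit = setNames(config@baselineLogit, conceptIds),
    utilizationEffect = setNames(config@utilizationEffect, conceptIds),
    confounded = setNames(config@caseEffect == 0 &
                          config@utilizationEffect != 0, conceptIds),
    subgroup = setNames(subgroup, ids[seq_len(nCase)]),
    signatureConcepts = lapply(config@signatureConditions,
                               function(i) conceptIds[i]),
    nVisits = setNames(nVisits, ids)
  )
  list(cohort = cohort, conceptSet = conceptSet,
       ancestorEdges = ancestorEdges, truth = truth)
}

#' Simulate two sites sharing planted effects up to noise
#'
#' Site B's per-condition case effects equal site A's plus independent
#' Gaussian noise with standard deviation `siteNoiseSd` on the log-odds
#' scale; all other settings are shared unless `configB` overrides them.
#' Person id namespaces are disjoint (`A...`/`B...`) and each site's seed is
#' derived deterministically from the master seed.
#'
#' @param config master [SimulationConfig-class] (defines site A).
#' @param siteNoiseSd standard deviation of cross-site effect noise.
#' @param configB optional [SimulationConfig-class] for site B (its
#'   `caseEffect` is still overwritten by the noisy copy of A's).
#' @return list with elements `siteA` and `siteB`, each as returned by
#'   [simulateCohort()].
#' @export
simulateTwoSites <- function(config, siteNoiseSd = 0.2, configB = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  effB <- withSeed(config@seed + 90001L,
                   config@caseEffect + rnorm(config@nConditions, 0, siteNoiseSd))
  cfgA <- config
  cfgB <- if (is.null(configB)) config else configB
  cfgB@caseEffect <- as.numeric(effB)
  cfgA@seed <- config@seed
  cfgB@seed <- config@seed + 104729L
  list(
    siteA = simulateCohort(cfgA, idPrefix = "A"),
    siteB = simulateCohort(cfgB, idPrefix = "B")
  )
}

#' Write a simulation's ground truth to a flat table
#'
#' Emits `ground_truth.tsv` (per-condition planted effects) and
#' `ground_truth_persons.tsv` (case flags, subgroups, index dates) alongside
#' the cohort tables, so a simulated study round-trips through
#' [readCohortTables()] plus these files.
#'
#' @param sim a list as returned by [simulateCohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  writeCohortTables(sim$cohort, dir)
  data.table::fwrite(sim$ancestorEdges,
                     file.path(dir, "concept_ancestor.tsv"), sep = "\t")
  tr <- sim$truth
  data.table::fwrite(
    data.frame(concept_id = names(tr$caseEffect),
               case_effect = tr$caseEffect,
               baseline_logit = tr$baselineLogit,
               utilization_effect = tr$utilizationEffect,
               confounded = tr$confounded),
    file.path(dir, "ground_truth.tsv"), sep = "\t"
  )
  pid <- names(tr$caseFlags)
  data.table::fwrite(
    data.frame(person_id = pid,
               is_case = tr$caseFlags,
               subgroup = ifelse(pid %in% names(tr$subgroup),
                                 tr$subgroup[pid], NA_integer_),
               index_date = ifelse(pid %in% names(tr$indexDates),
                                   format(tr$indexDates[pid], "%Y-%m-%d"),
                                   NA_character_)),
    file.path(dir, "ground_truth_persons.tsv"), sep = "\t"
  )
  invisible(dir)
}
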