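#' @import methods
#' @importFrom stats plogis qlogis rnorm runif rbinom rnbinom phyper glm
#'   binomial cor.test prcomp quantile setNames var sd complete.cases
#' @importFrom utils head
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' ConceptSet: a root concept plus its hierarchy descendants
#'
#' A concept set is the transitive closure of a root concept under a
#' parent-to-child ancestor edge list, as used to define a case roster from
#' a coded condition hierarchy (e.g. the SNOMED descendants of a disease
#' concept in an OMOP vocabulary).
#'
#' @slot root character(1), the root concept identifier.
#' @slot members character, the root plus every descendant.
#'
#' @seealso [closeConceptSet()]
#' @export
setClass("ConceptSet",
  representation(root = "character", members = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@root) != 1L) msg <- c(msg, "root must be a single id")
    if (!object@root %in% object@members) msg <- c(msg, "root must be a member")
    if (anyDuplicated(object@members)) msg <- c(msg, "duplicate members")
    if (length(msg)) msg else TRUE
  }
)

#' Cohort: persons, dated condition occurrences and utilization summaries
#'
#' The central data container: one data source's person table, condition
#' occurrence table and per-person utilization summary, together with the
#' case roster and each case's index date (first concept-set diagnosis).
#'
#' @slot persons data.frame with columns `person_id`, `age`, `gender`,
#'   `race`, `ethnicity` and optionally `site`; one row per person.
#' @slot occurrences data.frame with columns `person_id`, `concept_id`,
#'   `start_date` (Date).
#' @slot utilization data.frame with columns `person_id`, `n_visits`,
#'   `record_duration_days`; one row per person.
#' @slot caseIds character, person ids of the cases.
#' @slot indexDates Date vector named by case id: each case's first
#'   concept-set diagnosis date.
#'
#' @seealso [makeCohort()], [readCohortTables()], [restrictPreIndex()]
#' @export
setClass("Cohort",
  representation(
    persons = "data.frame",
    occurrences = "data.frame",
    utilization = "data.frame",
    caseIds = "character",
    indexDates = "Date"
  ),
  validity = function(object) {
    msg <- character()
    p <- object@persons
    need <- c("person_id", "age", "gender", "race", "ethnicity")
    if (!all(need %in% names(p)))
      msg <- c(msg, paste("persons must have columns:", paste(need, collapse = ", ")))
    else {
      if (anyDuplicated(p$person_id)) msg <- c(msg, "duplicate person_id in persons")
      if (any(p$age < 0, na.rm = TRUE)) msg <- c(msg, "negative age")
    }
    o <- object@occurrences
    if (!all(c("person_id", "concept_id", "start_date") %in% names(o)))
      msg <- c(msg, "occurrences must have person_id, concept_id, start_date")
    else if (nrow(o) && !all(o$person_id %in% p$person_id))
      msg <- c(msg, "occurrences reference unknown person_id")
    u <- object@utilization
    if (nrow(u)) {
      if (!all(c("person_id", "n_visits", "record_duration_days") %in% names(u)))
        msg <- c(msg, "utilization must have person_id, n_visits, record_duration_days")
      else {
        if (anyDuplicated(u$person_id)) msg <- c(msg, "duplicate person_id in utilization")
        if (any(u$n_visits < 0 | u$record_duration_days < 0, na.rm = TRUE))
          msg <- c(msg, "negative utilization values")
      }
    }
    if (!all(object@caseIds %in% p$person_id))
      msg <- c(msg, "caseIds not all present in persons")
    if (length(object@indexDates) &&
        !setequal(names(object@indexDates), object@caseIds))
      msg <- c(msg, "indexDates must be named by exactly the caseIds")
    if (length(msg)) msg else TRUE
  }
)

#' MatchedCohort: replicate propensity-matched control groups
#'
#' The result of 1:k greedy nearest-neighbour matching without replacement on
#' a propensity score. Replicate group g holds each case's g-th nearest
#' selected control, so the k groups partition each case's matched controls
#' and no control is used twice anywhere in the match.
#'
#' @slot caseIds character, matched cases in processing order.
#' @slot matches data.frame with columns `replicate`, `case_id`,
#'   `control_id`, `case_score`, `control_score`.
#' @slot k integer(1), number of replicate control groups (30 by default
#'   upstream).
#' @slot variant character(1), `"demographic"` or `"utilization"`.
#' @slot covariates character, covariates entered into the propensity model.
#'
#' @seealso [matchControls()], [fitPropensity()]
#' @export
setClass("MatchedCohort",
  representation(
    caseIds = "character",
    matches = "data.frame",
    k = "integer",
    variant = "character",
    covariates = "character"
  ),
  validity = function(object) {
    msg <- character()
    m <- object@matches
    need <- c("replicate", "case_id", "control_id", "case_score", "control_score")
    if (!all(need %in% names(m))) {
      msg <- c(msg, paste("matches must have columns:", paste(need, collapse = ", ")))
      return(msg)
    }
    if (anyDuplicated(m$control_id))
      msg <- c(msg, "a control id is reused within or across replicate groups")
    if (length(intersect(m$control_id, object@caseIds)))
      msg <- c(msg, "a case id appears as a control")
    byrep <- split(m$case_id, m$replicate)
    if (length(byrep) != object@k)
      msg <- c(msg, sprintf("expected %d replicate groups, found %d", object@k, length(byrep)))
    for (g in byrep) {
      if (anyDuplicated(g) || !setequal(g, object@caseIds)) {
        msg <- c(msg, "each replicate group must map every case to exactly one control")
        break
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' AssociationTable: replicated case-control enrichment results
#'
#' Per-condition odds ratios and hypergeometric p-values computed against each
#' replicate control group, Bonferroni-corrected within each replicate's own
#' condition universe, and aggregated across replicates as the mean odds
#' ratio and twice the mean corrected p-value (capped at 1).
#'
#' @slot results data.frame, one row per condition (see [runAssociation()]
#'   for columns).
#' @slot replicateOR numeric matrix, conditions x replicates.
#' @slot replicateP numeric matrix of corrected upper-tail (enrichment)
#'   p-values, conditions x replicates.
#' @slot replicatePDepletion numeric matrix of corrected lower-tail p-values.
#' @slot alpha numeric(1), significance level used for the flags.
#' @slot k integer(1), number of replicates.
#'
#' @seealso [runAssociation()], [applyUtilizationFilter()]
#' @export
setClass("AssociationTable",
  representation(
    results = "data.frame",
    replicateOR = "matrix",
    replicateP = "matrix",
    replicatePDepletion = "matrix",
    alpha = "numeric",
    k = "integer"
  ),
  validity = function(object) {
    msg <- character()
    r <- object@results
    if (!"concept_id" %in% names(r)) msg <- c(msg, "results must have concept_id")
    if (nrow(r) != nrow(object@replicateOR) || nrow(r) != nrow(object@replicateP))
      msg <- c(msg, "replicate matrices must have one row per condition")
    if ("aggregated_p" %in% names(r) &&
        any(r$aggregated_p < 0 | r$aggregated_p > 1, na.rm = TRUE))
      msg <- c(msg, "aggregated_p outside [0,1]")
    if ("mean_or" %in% names(r) && any(r$mean_or <= 0, na.rm = TRUE))
      msg <- c(msg, "mean_or must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' ClusterResult: a partition of cases from Leiden community detection
#'
#' @slot labels integer vector of 0-based contiguous cluster ids, named by
#'   person id; clusters are numbered by decreasing size.
#' @slot resolution numeric(1), Leiden resolution parameter.
#' @slot nComponentsUsed integer(1), principal components actually used
#'   (NA when the partition was computed on a caller-supplied graph).
#' @slot varianceExplained numeric(1), fraction of variance retained by the
#'   PCA step (NA as above).
#' @slot kNeighbors integer(1), neighbours per node in the kNN graph.
#' @slot seed integer(1), RNG seed used for the partition.
#'
#' @seealso [leidenPartition()], [clusterCases()]
#' @export
setClass("ClusterResult",
  representation(
    labels = "integer",
    resolution = "numeric",
    nComponentsUsed = "integer",
    varianceExplained = "numeric",
    kNeighbors = "integer",
    seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    lab <- object@labels
    if (is.null(names(lab)) || anyDuplicated(names(lab)))
      msg <- c(msg, "labels must be uniquely named by person id")
    if (length(lab)) {
      u <- sort(unique(lab))
      if (!identical(u, seq_along(u) - 1L))
        msg <- c(msg, "cluster ids must be contiguous integers from 0")
    }
    if (object@resolution <= 0) msg <- c(msg, "resolution must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' SimulationConfig: generator settings for a synthetic EHR cohort
#'
#' Fully resolved configuration for [simulateCohort()]. Per-condition vectors
#' (baseline intercepts, planted case effects, utilization coefficients) have
#' length `nConditions`; subgroup signature sets are disjoint across
#' subgroups and index into the condition vector.
#'
#' @slot nCases integer(1) number of cases.
#' @slot nBackground integer(1) number of background (non-case) persons.
#' @slot nConditions integer(1) number of non-index conditions.
#' @slot demographics list of named probability vectors for `gender`, `race`,
#'   `ethnicity` plus `age_mean`/`age_sd` for the (truncated) age draw.
#' @slot baselineLogit numeric, per-condition intercept on the logit scale.
#' @slot caseEffect numeric, per-condition planted log odds ratio (0 = null).
#' @slot utilizationEffect numeric, per-condition coefficient on
#'   `log(1 + n_visits)` (confounder pathway).
#' @slot caseUtilizationShift numeric(1), multiplier on mean visit count for
#'   cases (1 = no differential utilization).
#' @slot meanVisits numeric(1), background mean visit count.
#' @slot visitDispersion numeric(1), negative-binomial size parameter.
#' @slot nSubgroups integer(1), number of latent case subgroups.
#' @slot signatureConditions list of integer vectors (one per subgroup):
#'   indices of that subgroup's signature conditions.
#' @slot signatureBoost numeric(1), additive logit boost for signature
#'   conditions within the owning subgroup.
#' @slot recordSpanDays numeric(2), min/max record duration in days.
#' @slot indexQuantile numeric(1) in (0,1): where along a case's record span
#'   the index (first concept-set) date falls.
#' @slot seed integer(1).
#'
#' @seealso [simulationConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
  representation(
    nCases = "integer",
    nBackground = "integer",
    nConditions = "integer",
    demographics = "list",
    baselineLogit = "numeric",
    caseEffect = "numeric",
    utilizationEffect = "numeric",
    caseUtilizationShift = "numeric",
    meanVisits = "numeric",
    visitDispersion = "numeric",
    nSubgroups = "integer",
    signatureConditions = "list",
    signatureBoost = "numeric",
    recordSpanDays = "numeric",
    indexQuantile = "numeric",
    seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    nc <- object@nConditions
    if (any(c(object@nCases, object@nBackground, nc) < 1L))
      msg <- c(msg, "counts must be positive")
    for (sl in c("baselineLogit", "caseEffect", "utilizationEffect"))
      if (length(slot(object, sl)) != nc)
        msg <- c(msg, sprintf("%s must have length nConditions", sl))
    for (v in object@demographics[c("gender", "race", "ethnicity")]) {
      if (is.null(v) || any(v < 0) || abs(sum(v) - 1) > 1e-8)
        msg <- c(msg, "demographic margins must be probability vectors summing to 1")
    }
    if (object@nSubgroups < 1L) msg <- c(msg, "nSubgroups must be >= 1")
    sig <- unlist(object@signatureConditions)
    if (anyDuplicated(sig))
      msg <- c(msg, "signature condition sets must be disjoint across subgroups")
    if (length(sig) && (any(sig < 1L) || any(sig > nc)))
      msg <- c(msg, "signature condition indices out of range")
    if (length(object@recordSpanDays) != 2L || any(object@recordSpanDays <= 0) ||
        diff(object@recordSpanDays) < 0)
      msg <- c(msg, "recordSpanDays must be an increasing positive pair")
    if (object@indexQuantile <= 0 || object@indexQuantile >= 1)
      msg <- c(msg, "indexQuantile must be in (0,1)")
    if (length(msg)) msg else TRUE
  }
)
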