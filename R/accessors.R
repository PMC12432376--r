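#' @describeIn ConceptSet-class member concept ids
#' @param x a `ConceptSet`
#' @export
conceptMembers <- function(x) {
  stopifnot(is(x, "ConceptSet"))
  x@members
}

#' Accessors for Cohort slots
#'
#' @param x a [Cohort-class] object.
#' @return `cohortPersons`, `cohortOccurrences`, `cohortUtilization` return
#'   the corresponding data.frame; `caseIds` the case person ids; `indexDates`
#'   a Date vector named by case id; `backgroundIds` the persons that are not
#'   cases.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
cohortPersons <- function(x) { stopifnot(is(x, "Cohort")); x@persons }

#' @rdname cohort-accessors
#' @export
cohortOccurrences <- function(x) { stopifnot(is(x, "Cohort")); x@occurrences }

#' @rdname cohort-accessors
#' @export
cohortUtilization <- function(x) { stopifnot(is(x, "Cohort")); x@utilization }

#' @rdname cohort-accessors
#' @export
caseIds <- function(x) { stopifnot(is(x, "Cohort")); x@caseIds }

#' @rdname cohort-accessors
#' @export
indexDates <- function(x) { stopifnot(is(x, "Cohort")); x@indexDates }

#' @rdname cohort-accessors
#' @export
backgroundIds <- function(x) {
  stopifnot(is(x, "Cohort"))
  setdiff(x@persons$person_id, x@caseIds)
}

#' Accessors for MatchedCohort and AssociationTable
#'
#' @param x a [MatchedCohort-class] or [AssociationTable-class] object.
#' @return `matchTable` returns the long replicate/case/control data.frame;
#'   `controlIds` the distinct matched control ids (optionally of one
#'   replicate); `assocResults` the per-condition results data.frame.
#' @param replicate optional replicate number to restrict `controlIds` to.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
matchTable <- function(x) { stopifnot(is(x, "MatchedCohort")); x@matches }

#' @rdname result-accessors
#' @export
controlIds <- function(x, replicate = NULL) {
  stopifnot(is(x, "MatchedCohort"))
  m <- x@matches
  if (!is.null(replicate)) m <- m[m$replicate == replicate, , drop = FALSE]
  unique(m$control_id)
}

#' @rdname result-accessors
#' @export
assocResults <- function(x) { stopifnot(is(x, "AssociationTable")); x@results }

#' Cluster labels of a ClusterResult
#'
#' @param x a [ClusterResult-class].
#' @return integer cluster ids (0-based, contiguous) named by person id.
#' @export
clusterLabels <- function(x) { stopifnot(is(x, "ClusterResult")); x@labels }

setMethod("show", "ConceptSet", function(object) {
  cat("ConceptSet: root", object@root, "with", length(object@members), "members\n")
})

setMethod("show", "Cohort", function(object) {
  cat("Cohort with", nrow(object@persons), "persons,",
      nrow(object@occurrences), "condition occurrences\n")
  cat("  cases:", length(object@caseIds),
      " background:", nrow(object@persons) - length(object@caseIds), "\n")
  if (length(object@indexDates))
    cat("  index dates:", format(min(object@indexDates)), "to",
        format(max(object@indexDates)), "\n")
})

setMethod("show", "MatchedCohort", function(object) {
  cat("MatchedCohort (", object@variant, " variant): ",
      length(object@caseIds), " cases x ", object@k,
      " replicate control groups\n", sep = "")
  cat("  covariates:", paste(object@covariates, collapse = ", "), "\n")
})

setMethod("show", "AssociationTable", function(object) {
  r <- object@results
  cat("AssociationTable:", nrow(r), "conditions x", object@k, "replicates",
      sprintf("(alpha = %g)\n", object@alpha))
  if ("significant" %in% names(r))
    cat("  enriched (aggregated p <", object@alpha, "):", sum(r$significant), "\n")
  if ("significant_depletion" %in% names(r))
    cat("  depleted:", sum(r$significant_depletion), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  tab <- table(object@labels)
  cat("ClusterResult:", length(object@labels), "patients in", length(tab),
      "clusters (resolution", object@resolution, ")\n")
  cat("  sizes:", paste(as.integer(tab), collapse = ", "), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nCases, "cases /", object@nBackground,
      "background /", object@nConditions, "conditions\n")
  cat("  planted effects:", sum(object@caseEffect != 0),
      " confounded:", sum(object@caseEffect == 0 & object@utilizationEffect != 0),
      " subgroups:", object@nSubgroups, " seed:", object@seed, "\n")
})
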