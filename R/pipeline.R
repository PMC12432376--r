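#' Run the full comorbidity study on one cohort
#'
#' End-to-end driver mirroring the package's intended workflow: select the
#' background pool, fit demographic-only and utilization-augmented
#' propensity models, build the k replicate matched control groups for each
#' variant, run the replicated association analysis against both, and apply
#' the dual utilization-matched significance filter. With
#' `mode = "pre-index"` the cohort is first restricted to each case's
#' pre-index history (controls keep their full records) and matching is
#' redone on the surviving cases.
#'
#' @param cohort a [Cohort-class].
#' @param conceptSet the case-defining [ConceptSet-class] (excluded from the
#'   tested universe).
#' @param k replicate control groups per case (default 30).
#' @param alpha significance level on the aggregated p (default 0.05).
#' @param mode `"full"` (whole record) or `"pre-index"`.
#' @param minPrevalence universe prevalence floor (see [conditionUniverse()]).
#' @param chapterMap optional concept-to-chapter annotation table.
#' @return list with `final` (the filtered association data.frame, see
#'   [applyUtilizationFilter()]), `primary` and `utilization`
#'   ([AssociationTable-class] objects), `matchedPrimary`,
#'   `matchedUtilization`, `balancePrimary`, `balanceUtilization`, and the
#'   (possibly restricted) `cohort`.
#' @export
runComorbidityStudy <- function(cohort, conceptSet, k = 30L, alpha = 0.05,
                                mode = c("full", "pre-index"),
                                minPrevalence = 1L, chapterMap = NULL) {
  mode <- match.arg(mode)
  if (mode == "pre-index") cohort <- restrictPreIndex(cohort, conceptSet)
  bg <- setdiff(intersect(cohort@persons$person_id,
                          unique(cohort@occurrences$person_id)),
                cohort@caseIds)
  arm <- function(variant) {
    sc <- fitPropensity(cohort, variant = variant, backgroundIds = bg)
    matchControls(sc, cohort@caseIds, bg, k = k)
  }
  mDem <- arm("demographic")
  mUtl <- arm("utilization")
  aDem <- runAssociation(cohort, mDem, conceptSet = conceptSet,
                         alpha = alpha, minPrevalence = minPrevalence,
                         chapterMap = chapterMap)
  aUtl <- runAssociation(cohort, mUtl, conceptSet = conceptSet,
                         alpha = alpha, minPrevalence = minPrevalence)
  list(
    final = applyUtilizationFilter(aDem, aUtl, alpha = alpha),
    primary = aDem, utilization = aUtl,
    matchedPrimary = mDem, matchedUtilization = mUtl,
    balancePrimary = standardizedMeanDifferences(cohort, mDem,
                                                 backgroundIds = bg),
    balanceUtilization = standardizedMeanDifferences(cohort, mUtl,
                                                     backgroundIds = bg),
    cohort = cohort
  )
}
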