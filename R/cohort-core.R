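#' Close a concept set over an ancestor hierarchy
#'
#' Builds the concept set used to define cases: the root concept plus the
#' transitive closure of its descendants under a parent-to-child edge list
#' (e.g. all SNOMED condition concepts descended from a disease concept in an
#' OMOP vocabulary). The edge list must be acyclic.
#'
#' @param root character(1) root concept id.
#' @param ancestorEdges data.frame with columns `ancestor_id`,
#'   `descendant_id` (direct parent -> child pairs). May be empty.
#' @return a [ConceptSet-class].
#' @examples
#' edges <- data.frame(ancestor_id = c("R", "A"), descendant_id = c("A", "B"))
#' conceptMembers(closeConceptSet("R", edges))
#' @export
closeConceptSet <- function(root, ancestorEdges = NULL) {
  stopifnot(is.character(root), length(root) == 1L)
  if (is.null(ancestorEdges) || nrow(ancestorEdges) == 0L) {
    return(new("ConceptSet", root = root, members = root))
  }
  stopifnot(all(c("ancestor_id", "descendant_id") %in% names(ancestorEdges)))
  ed <- data.frame(
    from = as.character(ancestorEdges$ancestor_id),
    to = as.character(ancestorEdges$descendant_id)
  )
  g <- igraph::graph_from_data_frame(ed, directed = TRUE)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    stop("ancestor edge list contains a cycle (e.g. through edge ",
         paste(attr(cyc, "vnames"), collapse = ", "), ")")
  }
  if (!root %in% igraph::V(g)$name) {
    return(new("ConceptSet", root = root, members = root))
  }
  reach <- igraph::subcomponent(g, root, mode = "out")
  new("ConceptSet", root = root, members = sort(unique(c(root, reach$name))))
}

#' Select cases from a condition occurrence table
#'
#' Cases are the persons with at least one occurrence of any concept in the
#' concept set, at any point in their record.
#'
#' @param occurrences data.frame with `person_id`, `concept_id`.
#' @param conceptSet a [ConceptSet-class].
#' @return character vector of case person ids (sorted).
#' @export
selectCases <- function(occurrences, conceptSet) {
  hit <- occurrences$concept_id %in% conceptMembers(conceptSet)
  out <- sort(unique(as.character(occurrences$person_id[hit])))
  if (!length(out)) warning("no cases found for this concept set")
  out
}

#' Select the background (never-diagnosed) population
#'
#' The background population comprises persons with at least one condition of
#' any kind and no occurrence in the concept set; it is disjoint from
#' [selectCases()] by construction. Persons with no conditions at all are
#' excluded.
#'
#' @inheritParams selectCases
#' @return character vector of background person ids (sorted).
#' @export
selectBackground <- function(occurrences, conceptSet) {
  pid <- as.character(occurrences$person_id)
  hit <- occurrences$concept_id %in% conceptMembers(conceptSet)
  sort(setdiff(unique(pid), unique(pid[hit])))
}

#' First concept-set diagnosis date per case
#'
#' @inheritParams selectCases
#' @param persons optional character vector of case ids to restrict to;
#'   default all cases found in `occurrences`.
#' @return Date vector named by person id: each case's earliest concept-set
#'   occurrence date.
#' @export
firstIndexDates <- function(occurrences, conceptSet, persons = NULL) {
  hit <- occurrences[occurrences$concept_id %in% conceptMembers(conceptSet), ,
                     drop = FALSE]
  if (!is.null(persons)) {
    missing <- setdiff(persons, hit$person_id)
    if (length(missing))
      stop("index date undefined for non-case person(s): ",
           paste(head(missing, 5L), collapse = ", "))
    hit <- hit[hit$person_id %in% persons, , drop = FALSE]
  }
  if (!nrow(hit)) return(setNames(as.Date(character()), character()))
  d <- as.Date(hit$start_date)
  agg <- tapply(as.numeric(d), as.character(hit$person_id), min)
  setNames(as.Date(as.vector(agg), origin = "1970-01-01"), names(agg))
}

#' Assemble a Cohort from its component tables
#'
#' Identifies the cases and their index dates from the concept set and
#' packages everything into a validated [Cohort-class]. Persons with no
#' condition occurrence at all are retained in the person table but are
#' neither cases nor part of the analysis background.
#'
#' @param persons,occurrences,utilization data.frames in the package's flat
#'   table schema (see [readCohortTables()]).
#' @param conceptSet a [ConceptSet-class] defining the cases.
#' @return a [Cohort-class].
#' @export
makeCohort <- function(persons, occurrences, utilization, conceptSet) {
  occurrences$person_id <- as.character(occurrences$person_id)
  occurrences$concept_id <- as.character(occurrences$concept_id)
  occurrences$start_date <- as.Date(occurrences$start_date)
  persons$person_id <- as.character(persons$person_id)
  utilization$person_id <- as.character(utilization$person_id)
  cases <- selectCases(occurrences, conceptSet)
  idx <- firstIndexDates(occurrences, conceptSet, cases)
  new("Cohort",
    persons = persons, occurrences = occurrences, utilization = utilization,
    caseIds = cases, indexDates = idx[cases]
  )
}

#' Restrict cases to their pre-index condition history
#'
#' For each case, keeps only condition occurrences dated strictly before that
#' case's index date (first concept-set diagnosis) and removes all
#' concept-set occurrences; cases left with no remaining occurrence are
#' dropped from the cohort. Background persons' occurrences are untouched —
#' controls contribute conditions from any time in their record.
#'
#' Same-day conditions are excluded: "prior to" is read strictly, the
#' conservative choice when the recording order within a day is unknown.
#'
#' @param cohort a [Cohort-class] with index dates populated.
#' @param conceptSet the case-defining [ConceptSet-class].
#' @return a new [Cohort-class].
#' @export
restrictPreIndex <- function(cohort, conceptSet) {
  stopifnot(is(cohort, "Cohort"), length(cohort@indexDates) > 0L)
  occ <- cohort@occurrences
  isCase <- occ$person_id %in% cohort@caseIds
  inSet <- occ$concept_id %in% conceptMembers(conceptSet)
  idx <- cohort@indexDates[occ$person_id[isCase]]
  keepCase <- rep(FALSE, nrow(occ))
  keepCase[isCase] <- !inSet[isCase] & as.Date(occ$start_date[isCase]) < idx
  keep <- ifelse(isCase, keepCase, TRUE)
  occ2 <- occ[keep, , drop = FALSE]
  survivors <- intersect(cohort@caseIds, unique(occ2$person_id))
  dropped <- setdiff(cohort@caseIds, survivors)
  keepPersons <- !(cohort@persons$person_id %in% dropped)
  new("Cohort",
    persons = cohort@persons[keepPersons, , drop = FALSE],
    occurrences = occ2[!(occ2$person_id %in% dropped), , drop = FALSE],
    utilization = cohort@utilization[
      !(cohort@utilization$person_id %in% dropped), , drop = FALSE],
    caseIds = survivors,
    indexDates = cohort@indexDates[survivors]
  )
}

#' Condition universe of a cohort
#'
#' All concepts occurring in at least one analysed patient, optionally
#' excluding the case-defining concept set (the default elsewhere in the
#' package, since those concepts define the case roster and testing them is
#' circular) and applying a minimum-prevalence floor.
#'
#' @param cohort a [Cohort-class].
#' @param persons optional person ids to restrict to.
#' @param exclude optional [ConceptSet-class] whose members are removed.
#' @param minPrevalence minimum number of distinct patients a concept must
#'   occur in (default 1).
#' @return sorted character vector of concept ids.
#' @export
conditionUniverse <- function(cohort, persons = NULL, exclude = NULL,
                              minPrevalence = 1L) {
  occ <- cohort@occurrences
  if (!is.null(persons)) occ <- occ[occ$person_id %in% persons, , drop = FALSE]
  if (!is.null(exclude))
    occ <- occ[!(occ$concept_id %in% conceptMembers(exclude)), , drop = FALSE]
  cnt <- tapply(occ$person_id, occ$concept_id, function(p) length(unique(p)))
  sort(names(cnt)[cnt >= minPrevalence])
}

#' Build the binary patient-by-condition matrix
#'
#' Entry (i, j) is 1 if patient i has at least one occurrence of condition j,
#' 0 otherwise (duplicate occurrences do not accumulate). Patients with no
#' occurrence of any universe condition get an all-zero row.
#'
#' @param cohort a [Cohort-class].
#' @param conditionUniverse character vector of concept ids forming the
#'   columns; must be non-empty.
#' @param persons person ids forming the rows; default all persons with at
#'   least one occurrence.
#' @return a sparse 0/1 [Matrix::sparseMatrix()] (`dgCMatrix`) with person
#'   ids as rownames and concept ids as colnames.
#' @export
buildConditionMatrix <- function(cohort, conditionUniverse, persons = NULL) {
  if (length(conditionUniverse) == 0L) stop("empty condition universe")
  occ <- cohort@occurrences
  if (is.null(persons)) persons <- sort(unique(occ$person_id))
  occ <- occ[occ$person_id %in% persons &
             occ$concept_id %in% conditionUniverse, , drop = FALSE]
  i <- match(occ$person_id, persons)
  j <- match(occ$concept_id, conditionUniverse)
  m <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(persons), length(conditionUniverse)),
    dimnames = list(persons, conditionUniverse),
    use.last.ij = TRUE
  )
  m@x[] <- 1
  m
}
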