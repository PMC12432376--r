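.tableSpecs <- list(
  person = list(
    file = "person.tsv",
    cols = c("person_id", "age", "gender", "race", "ethnicity", "site"),
    required = c("person_id", "age", "gender", "race", "ethnicity")
  ),
  condition_occurrence = list(
    file = "condition_occurrence.tsv",
    cols = c("person_id", "concept_id", "start_date"),
    required = c("person_id", "concept_id", "start_date")
  ),
  utilization = list(
    file = "utilization.tsv",
    cols = c("person_id", "n_visits", "record_duration_days"),
    required = c("person_id", "n_visits", "record_duration_days")
  )
)

.readTable <- function(path, required) {
  dt <- data.table::fread(path, data.table = FALSE,
                          na.strings = c("NA", ""))
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop(basename(path), " is missing column(s): ", paste(missing, collapse = ", "))
  for (col in intersect(c("person_id", "concept_id", "ancestor_id",
                          "descendant_id", "gender", "race", "ethnicity",
                          "site"), names(dt)))
    dt[[col]] <- as.character(dt[[col]])
  if ("start_date" %in% names(dt)) dt$start_date <- as.Date(dt$start_date)
  dt
}

#' Read a cohort from flat tables
#'
#' Reads `person.tsv`, `condition_occurrence.tsv` and `utilization.tsv` from
#' a directory (tab-separated by default; the delimiter is auto-detected, so
#' comma-separated files with the same names are accepted) and assembles a
#' [Cohort-class] using the supplied case-defining concept set. If
#' `concept_ancestor.tsv` is present and `conceptSet` is a root concept id,
#' the concept set is closed over that hierarchy first.
#'
#' All identifiers are treated as opaque strings; dates must be ISO-8601.
#'
#' @param dir directory containing the tables.
#' @param conceptSet a [ConceptSet-class], or a character(1) root concept id
#'   to be closed over `concept_ancestor.tsv` in `dir`.
#' @return a [Cohort-class].
#' @seealso [writeCohortTables()], [makeCohort()]
#' @export
readCohortTables <- function(dir, conceptSet) {
  tabs <- lapply(.tableSpecs, function(s)
    .readTable(file.path(dir, s$file), s$required))
  if (is.character(conceptSet)) {
    ancPath <- file.path(dir, "concept_ancestor.tsv")
    edges <- if (file.exists(ancPath))
      .readTable(ancPath, c("ancestor_id", "descendant_id")) else NULL
    conceptSet <- closeConceptSet(conceptSet, edges)
  }
  makeCohort(tabs$person, tabs$condition_occurrence, tabs$utilization,
             conceptSet)
}

#' Write a cohort to flat tables
#'
#' Emits the three cohort tables (tab-separated with headers) plus
#' `case_ids.tsv` (person_id, index_date) so the case roster round-trips.
#'
#' @param cohort a [Cohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohortTables <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(cohort@persons, file.path(dir, "person.tsv"), sep = "\t")
  occ <- cohort@occurrences
  occ$start_date <- format(as.Date(occ$start_date), "%Y-%m-%d")
  data.table::fwrite(occ, file.path(dir, "condition_occurrence.tsv"), sep = "\t")
  data.table::fwrite(cohort@utilization, file.path(dir, "utilization.tsv"),
                     sep = "\t")
  data.table::fwrite(
    data.frame(person_id = cohort@caseIds,
               index_date = format(cohort@indexDates[cohort@caseIds], "%Y-%m-%d")),
    file.path(dir, "case_ids.tsv"), sep = "\t"
  )
  invisible(dir)
}

#' Read an optional condition-to-chapter mapping
#'
#' A two-column table (`concept_id`, `chapter_label`) used only to annotate
#' association reports, e.g. a user-supplied SNOMED-to-ICD-chapter map.
#'
#' @param path path to the mapping table.
#' @return data.frame with character columns `concept_id`, `chapter_label`.
#' @export
readChapterMap <- function(path) {
  dt <- .readTable(path, c("concept_id", "chapter_label"))
  dt$concept_id <- as.character(dt$concept_id)
  dt$chapter_label <- as.character(dt$chapter_label)
  dt[, c("concept_id", "chapter_label")]
}
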