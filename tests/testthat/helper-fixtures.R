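# Small handcrafted cohort used across cohort-level tests.
# Persons: X1..X2 are cases ("E1"/"E2" concept-set codes), X3..X5 background,
# X6 has no conditions at all.
tinyTables <- function() {
  persons <- data.frame(
    person_id = paste0("X", 1:6),
    age = c(30, 41, 35, 28, 50, 44),
    gender = c("female", "female", "female", "male", "female", "female"),
    race = c("white", "asian", "white", "white", "black", "white"),
    ethnicity = rep("not_hispanic", 6),
    site = "S1",
    stringsAsFactors = FALSE
  )
  occurrences <- data.frame(
    person_id = c("X1", "X1", "X1", "X2", "X2", "X3", "X3", "X4", "X5"),
    concept_id = c("E1", "C1", "C2", "E2", "C1", "C1", "C3", "C2", "C3"),
    start_date = as.Date(c(
      "2015-03-01", "2013-07-09", "2016-01-01",   # X1: index 2015-03-01
      "2014-05-05", "2014-05-05",                 # X2: C1 on index date
      "2012-01-01", "2018-09-30", "2011-02-02", "2019-12-31"
    )),
    stringsAsFactors = FALSE
  )
  utilization <- data.frame(
    person_id = paste0("X", 1:6),
    n_visits = c(12L, 30L, 8L, 5L, 20L, 0L),
    record_duration_days = c(3000L, 2500L, 1800L, 900L, 4000L, 100L),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(ancestor_id = c("E0", "E0"),
                      descendant_id = c("E1", "E2"),
                      stringsAsFactors = FALSE)
  list(persons = persons, occurrences = occurrences,
       utilization = utilization, edges = edges,
       conceptSet = closeConceptSet("E0", edges))
}

tinyCohort <- function() {
  t <- tinyTables()
  makeCohort(t$persons, t$occurrences, t$utilization, t$conceptSet)
}

# Fast small simulation settings shared by several tests.
quickConfig <- function(seed = 1L, ...) {
  simulationConfig(nCases = 150L, nBackground = 3000L, nConditions = 60L,
                   caseUtilizationShift = 1, signatureBoost = 0,
                   seed = seed, ...)
}
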