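#' Fit a propensity score model
#'
#' Main-effects logistic regression of case status on the requested
#' covariates: categorical covariates are one-hot expanded with a dropped
#' reference level, age and the utilization covariates enter linearly. The
#' `"demographic"` variant uses age, gender, race and ethnicity (plus site
#' when more than one is present); the `"utilization"` variant adds the
#' number of recorded visits and the record duration. If the fit fails to
#' converge or separates perfectly, a ridge-stabilised fit (small L2
#' penalty via glmnet) is used instead, with a warning.
#'
#' @param cohort a [Cohort-class].
#' @param variant `"demographic"` or `"utilization"`, or supply `covariates`
#'   explicitly.
#' @param covariates optional character vector from `age`, `gender`, `race`,
#'   `ethnicity`, `site`, `n_visits`, `record_duration`.
#' @param backgroundIds persons forming the control pool; default every
#'   non-case with at least one condition occurrence.
#' @return numeric propensity scores in (0, 1) named by person id (cases
#'   first, then background), with attributes `variant` and `covariates`.
#' @export
fitPropensity <- function(cohort,
                          variant = c("demographic", "utilization"),
                          covariates = NULL, backgroundIds = NULL) {
  variant <- match.arg(variant)
  if (is.null(covariates)) {
    covariates <- c("age", "gender", "race", "ethnicity")
    if (length(unique(cohort@persons$site)) > 1L)
      covariates <- c(covariates, "site")
    if (variant == "utilization")
      covariates <- c(covariates, "n_visits", "record_duration")
  }
  allowed <- c("age", "gender", "race", "ethnicity", "site", "n_visits",
               "record_duration")
  if (!all(covariates %in% allowed))
    stop("unknown covariate(s): ",
         paste(setdiff(covariates, allowed), collapse = ", "))
  if (is.null(backgroundIds)) {
    withCond <- unique(cohort@occurrences$person_id)
    backgroundIds <- setdiff(intersect(cohort@persons$person_id, withCond),
                             cohort@caseIds)
  }
  if (!length(cohort@caseIds) || !length(backgroundIds))
    stop("need at least one case and one background person")

  ids <- c(cohort@caseIds, backgroundIds)
  df <- .covariateFrame(cohort, ids, covariates)
  y <- as.numeric(ids %in% cohort@caseIds)

  # constant covariates carry no information and break the design matrix
  informative <- vapply(df, function(col) length(unique(col)) >= 2L,
                        logical(1))
  df <- df[, informative, drop = FALSE]
  x <- if (ncol(df)) stats::model.matrix(~ ., data = df)[, -1L, drop = FALSE]
       else matrix(numeric(), length(y), 0L)
  scores <- NULL
  if (ncol(x) == 0L) {
    scores <- rep(mean(y), length(y))
  } else {
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ ., data = data.frame(y = y, x, check.names = FALSE),
          family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    fv <- stats::fitted(fit)
    if (sep || !fit$converged || any(fv < 1e-10 | fv > 1 - 1e-10)) {
      warning("propensity model separated or failed to converge; ",
              "using ridge-stabilised fit")
      rf <- suppressWarnings(
        glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = 1e-3, standardize = TRUE))
      scores <- as.numeric(stats::predict(rf, newx = x, type = "response"))
    } else {
      scores <- as.numeric(stats::fitted(fit))
    }
  }
  scores <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  structure(setNames(scores, ids), variant = variant, covariates = covariates)
}

.covariateFrame <- function(cohort, ids, covariates) {
  p <- cohort@persons[match(ids, cohort@persons$person_id), , drop = FALSE]
  u <- cohort@utilization[match(ids, cohort@utilization$person_id), ,
                          drop = FALSE]
  out <- list()
  for (cv in covariates) {
    out[[cv]] <- switch(cv,
      age = as.numeric(p$age),
      n_visits = as.numeric(u$n_visits),
      record_duration = as.numeric(u$record_duration_days),
      factor(p[[cv]])
    )
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Greedy 1:k nearest-neighbour matching without replacement
#'
#' Cases are processed in descending propensity-score order (hardest to
#' match first); each case takes its `k` nearest not-yet-used controls by
#' absolute score difference, ties broken by the smaller control id.
#' Replicate group g collects each case's g-th nearest selected control, so
#' the g groups partition the matched controls and no control is reused
#' anywhere. The procedure is deterministic given the scores.
#'
#' @param scores named numeric vector of propensity scores covering all
#'   cases and controls (as from [fitPropensity()]).
#' @param caseIds,backgroundIds character id vectors; must be disjoint and
#'   `length(backgroundIds) >= k * length(caseIds)`.
#' @param k controls per case (default 30).
#' @param caliper optional maximum |score difference|; `NULL` (default)
#'   disables it. With a caliper, a case with fewer than `k` in-caliper
#'   controls is an error.
#' @return a [MatchedCohort-class].
#' @export
matchControls <- function(scores, caseIds, backgroundIds, k = 30L,
                          caliper = NULL) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (length(intersect(caseIds, backgroundIds)))
    stop("caseIds and backgroundIds overlap")
  missing <- setdiff(c(caseIds, backgroundIds), names(scores))
  if (length(missing))
    stop("no score for: ", paste(head(missing, 5L), collapse = ", "))
  nCase <- length(caseIds)
  nBg <- length(backgroundIds)
  if (nBg < k * nCase)
    stop(sprintf(
      "insufficient controls: need %d (= %d cases x %d), have %d",
      k * nCase, nCase, k, nBg))

  cs <- scores[caseIds]
  bs <- scores[backgroundIds]
  ord <- order(bs, backgroundIds)      # score, then id for determinism
  s <- as.numeric(bs[ord])
  bid <- backgroundIds[ord]
  m <- length(s)

  # union-find style "nearest alive index" pointers with path compression
  parentL <- seq.int(0L, m)            # parentL[i+1] = nearest alive <= i
  parentR <- seq.int(1L, m + 1L)       # parentR[i]   = nearest alive >= i
  findL <- function(i) {
    j <- i
    while (j >= 1L && parentL[j + 1L] != j) j <- parentL[j + 1L]
    while (i >= 1L && parentL[i + 1L] != j) {   # path compression
      nxt <- parentL[i + 1L]
      parentL[i + 1L] <<- j
      i <- nxt
    }
    j
  }
  findR <- function(i) {
    j <- i
    while (j <= m && parentR[j] != j) j <- parentR[j]
    while (i <= m && parentR[i] != j) {
      nxt <- parentR[i]
      parentR[i] <<- j
      i <- nxt
    }
    j
  }

  caseOrd <- order(-cs, caseIds)
  recCase <- character(nCase * k)
  recCtl <- character(nCase * k)
  recRep <- integer(nCase * k)
  recCS <- numeric(nCase * k)
  recBS <- numeric(nCase * k)
  pos <- 0L
  for (ci in caseOrd) {
    cscore <- as.numeric(cs[ci])
    l <- findL(findInterval(cscore, s))
    r <- findR(findInterval(cscore, s) + 1L)
    for (g in seq_len(k)) {
      dl <- if (l >= 1L) cscore - s[l] else Inf
      dr <- if (r <= m) s[r] - cscore else Inf
      takeLeft <- if (dl < dr) TRUE
        else if (dr < dl) FALSE
        else if (is.infinite(dl)) stop("control pool exhausted")
        else bid[l] < bid[r]
      take <- if (takeLeft) l else r
      d <- min(dl, dr)
      if (!is.null(caliper) && d > caliper)
        stop(sprintf("case %s has only %d controls within the caliper",
                     caseIds[ci], g - 1L))
      pos <- pos + 1L
      recRep[pos] <- g
      recCase[pos] <- caseIds[ci]
      recCtl[pos] <- bid[take]
      recCS[pos] <- cscore
      recBS[pos] <- s[take]
      # remove `take` from the alive set
      parentL[take + 1L] <- take - 1L
      parentR[take] <- take + 1L
      if (takeLeft) l <- findL(take - 1L) else r <- findR(take + 1L)
    }
  }
  matches <- data.frame(
    replicate = recRep, case_id = recCase, control_id = recCtl,
    case_score = recCS, control_score = recBS, stringsAsFactors = FALSE
  )
  matches <- matches[order(matches$replicate, matches$case_id), , drop = FALSE]
  rownames(matches) <- NULL
  new("MatchedCohort",
    caseIds = caseIds[caseOrd], matches = matches, k = k,
    variant = attr(scores, "variant") %||% "demographic",
    covariates = attr(scores, "covariates") %||% character()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Covariate balance before and after matching
#'
#' Standardized mean differences (SMD = (mean_case - mean_control) / pooled
#' SD, pooled as the root mean of the two group variances) for every
#' expanded covariate: age, the indicator columns of each categorical level,
#' visit count and record duration. "Before" compares cases with the whole
#' background pool; "after" compares cases with the union of matched
#' controls. Covariates with zero pooled SD are reported as SMD 0 and
#' flagged.
#'
#' @param cohort a [Cohort-class].
#' @param matched a [MatchedCohort-class].
#' @param backgroundIds the pre-matching control pool; default every
#'   non-case with at least one occurrence.
#' @return data.frame with columns `covariate`, `smd_before`, `smd_after`,
#'   `zero_sd`.
#' @export
standardizedMeanDifferences <- function(cohort, matched,
                                        backgroundIds = NULL) {
  stopifnot(is(cohort, "Cohort"), is(matched, "MatchedCohort"))
  if (is.null(backgroundIds)) {
    withCond <- unique(cohort@occurrences$person_id)
    backgroundIds <- setdiff(intersect(cohort@persons$person_id, withCond),
                             cohort@caseIds)
  }
  cases <- matched@caseIds
  ctl <- unique(matched@matches$control_id)
  covs <- c("age", "gender", "race", "ethnicity", "n_visits",
            "record_duration")
  if (length(unique(cohort@persons$site)) > 1L)
    covs <- append(covs, "site", after = 4L)

  expand <- function(ids) {
    df <- .covariateFrame(cohort, ids, covs)
    mats <- lapply(names(df), function(nm) {
      col <- df[[nm]]
      if (is.factor(col) || is.character(col)) {
        lv <- sort(unique(as.character(col)))
        m <- vapply(lv, function(l) as.numeric(col == l),
                    numeric(length(col)))
        colnames(m) <- paste0(nm, lv)
        m
      } else {
        matrix(as.numeric(col), ncol = 1L, dimnames = list(NULL, nm))
      }
    })
    do.call(cbind, mats)
  }
  xc <- expand(cases)
  xb <- expand(backgroundIds)
  xa <- expand(ctl)
  cols <- sort(unique(c(colnames(xc), colnames(xb), colnames(xa))))
  getcol <- function(x, col) if (col %in% colnames(x)) x[, col] else
    rep(0, nrow(x))
  smd1 <- function(col, xctl) {
    a <- getcol(xc, col); b <- getcol(xctl, col)
    sdp <- sqrt((var(a) + var(b)) / 2)
    if (!is.finite(sdp) || sdp == 0) c(0, TRUE) else
      c((mean(a) - mean(b)) / sdp, FALSE)
  }
  before <- t(vapply(cols, smd1, numeric(2), xctl = xb))
  after <- t(vapply(cols, smd1, numeric(2), xctl = xa))
  data.frame(
    covariate = cols,
    smd_before = before[, 1L],
    smd_after = after[, 1L],
    zero_sd = before[, 2L] > 0 | after[, 2L] > 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
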