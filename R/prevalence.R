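adl_cols <- c("adl_bath", "adl_dress", "adl_eat", "adl_bed", "adl_toilet")
chronic_cols <- c("cd_arthritis", "cd_cancer", "cd_diabetes",
                  "cd_heart", "cd_lung", "cd_stroke")

survey_cols <- c("person_id", "sex", "age", "weight", adl_cols, chronic_cols)

item_cols <- function(definition) {
  switch(match.arg(definition, c("disability", "chronic")),
         disability = adl_cols,
         chronic = chronic_cols)
}

check_survey <- function(survey) {
  stopifnot(is.data.frame(survey))
  miss <- setdiff(survey_cols, names(survey))
  if (length(miss))
    stop("survey is missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(survey$weight)) || any(survey$weight <= 0))
    stop("all survey weights must be positive (zero/negative weights are rejected, not clamped)")
  if (any(!is.finite(survey$age)) || any(survey$age < 0))
    stop("ages must be non-negative")
  bad_sex <- setdiff(unique(survey$sex), c("woman", "man"))
  if (length(bad_sex))
    stop("unknown sex labels: ", paste(bad_sex, collapse = ", "))
  for (col in c(adl_cols, chronic_cols)) {
    v <- survey[[col]]
    if (!all(v %in% c(0, 1) | is.na(v)))
      stop("item column '", col, "' must be coded 1, 0 or missing")
  }
  invisible(TRUE)
}

#' Classify respondents as unhealthy, healthy, or missing
#'
#' Applies the "any difficulty / any diagnosis" rule: a respondent is
#' *unhealthy* when any relevant item is a yes, *healthy* when all relevant
#' items are no, and *missing* when no item is a yes but at least one is
#' unanswered.  A single yes dominates missing items, so partially answered
#' respondents with a reported condition are retained; respondents with only
#' no/missing answers are dropped from prevalence estimation.
#'
#' @param survey data frame of survey records (see [read_survey()] for the
#'   column schema); items coded 1 = yes, 0 = no, `NA` = missing.
#' @param definition `"disability"` (5 ADL items: bathing, dressing, eating,
#'   bed transfer, toileting) or `"chronic"` (6 physician-diagnosed
#'   conditions: arthritis, cancer, diabetes, heart condition, lung disease,
#'   stroke).
#' @return A character vector over records with values
#'   `"unhealthy"`, `"healthy"`, `"missing"`.
#' @examples
#' s <- data.frame(adl_bath = c(0, 1, NA), adl_dress = 0, adl_eat = 0,
#'                 adl_bed = c(0, NA, 0), adl_toilet = 0)
#' classify_unhealthy(s, "disability")
#' @export
classify_unhealthy <- function(survey, definition = c("disability", "chronic")) {
  definition <- match.arg(definition)
  cols <- item_cols(definition)
  miss <- setdiff(cols, names(survey))
  if (length(miss))
    stop("survey is missing item columns: ", paste(miss, collapse = ", "))
  items <- as.matrix(survey[, cols, drop = FALSE])
  any_yes <- rowSums(items == 1, na.rm = TRUE) > 0
  any_na <- rowSums(is.na(items)) > 0
  ifelse(any_yes, "unhealthy", ifelse(any_na, "missing", "healthy"))
}

#' Estimate a weighted age-group prevalence schedule
#'
#' For one sex and one health definition, computes the weighted proportion
#' unhealthy in each age group,
#' \deqn{\pi_x = \sum w_i 1[\mathrm{unhealthy}_i] / \sum w_i,}
#' over records classified non-missing by [classify_unhealthy()].  Ages at or
#' above the open group's start are pooled into it; respondents younger than
#' the first group are excluded.  The standard error is binomial on the
#' unweighted count, `sqrt(pi (1 - pi) / n)`, optionally inflated by a
#' design-effect multiplier to approximate a complex survey design.
#'
#' @param survey survey data frame (schema of [read_survey()]).
#' @param definition `"disability"` or `"chronic"`.
#' @param sex `"woman"` or `"man"`; records of the other sex are ignored.
#' @param groups age grid from [age_groups()] (data frame with `x`, `n`).
#' @param deff design-effect multiplier applied to the variance (default 1).
#' @return An object of class `prevalence_schedule`: a data frame with
#'   columns `x, n, pi, n_unweighted, se` and attributes `sex`, `definition`.
#' @examples
#' scn <- scenario_preset("null")
#' surv <- generate_survey(scn)$survey
#' prevalence_schedule(surv, "disability", "woman")
#' @export
prevalence_schedule <- function(survey, definition = c("disability", "chronic"),
                                sex = c("woman", "man"), groups = age_groups(),
                                deff = 1) {
  definition <- match.arg(definition)
  sex <- match.arg(sex)
  check_survey(survey)
  check_age_grid(groups$x, groups$n)
  stopifnot(is.numeric(deff), length(deff) == 1L, deff > 0)

  status <- classify_unhealthy(survey, definition)
  keep <- survey$sex == sex & survey$age >= groups$x[1L] & status != "missing"
  if (!any(keep))
    stop("no usable records for sex '", sex, "' at or above age ", groups$x[1L])
  age <- survey$age[keep]
  w <- survey$weight[keep]
  unhealthy <- status[keep] == "unhealthy"

  open_start <- groups$x[nrow(groups)]
  idx <- findInterval(pmin(age, open_start), groups$x)

  k <- nrow(groups)
  pi <- se <- numeric(k)
  n_unw <- integer(k)
  for (g in seq_len(k)) {
    in_g <- idx == g
    n_unw[g] <- sum(in_g)
    if (n_unw[g] == 0L)
      stop("age group starting at ", groups$x[g],
           " has no contributing records; merge groups or supply more data")
    pi[g] <- sum(w[in_g] * unhealthy[in_g]) / sum(w[in_g])
    se[g] <- sqrt(deff * pi[g] * (1 - pi[g]) / n_unw[g])
  }
  structure(data.frame(x = groups$x, n = groups$n, pi = pi,
                       n_unweighted = n_unw, se = se),
            class = c("prevalence_schedule", "data.frame"),
            sex = sex, definition = definition)
}

#' Assemble a prevalence schedule from known proportions
#'
#' Wraps already-computed group proportions (for example, the generating truth
#' of a synthetic scenario) in the container that [sullivan()] and
#' [decompose_gap()] consume.  With `n_unweighted = Inf` the schedule is
#' treated as sampling-free (zero standard error).
#'
#' @param groups age grid (`x`, `n`).
#' @param pi proportion unhealthy per group, each in \[0, 1\].
#' @param n_unweighted respondent count per group (scalar recycled); `Inf`
#'   for a deterministic schedule.
#' @param sex,definition labels carried on the schedule.
#' @return A `prevalence_schedule`.
#' @export
prevalence_known <- function(groups, pi, n_unweighted = Inf,
                             sex = NA_character_, definition = NA_character_) {
  check_age_grid(groups$x, groups$n)
  k <- nrow(groups)
  if (length(pi) != k) stop("'pi' must have one value per age group")
  if (any(!is.finite(pi)) || any(pi < 0 | pi > 1)) stop("'pi' must lie in [0, 1]")
  if (length(n_unweighted) == 1L) n_unweighted <- rep(n_unweighted, k)
  se <- ifelse(is.finite(n_unweighted),
               sqrt(pi * (1 - pi) / n_unweighted), 0)
  structure(data.frame(x = groups$x, n = groups$n, pi = pi,
                       n_unweighted = n_unweighted, se = se),
            class = c("prevalence_schedule", "data.frame"),
            sex = sex, definition = definition)
}

#' @export
print.prevalence_schedule <- function(x, digits = 4, ...) {
  cat("Age-group prevalence schedule (",
      attr(x, "definition"), ", ", attr(x, "sex"), ")\n", sep = "")
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE, ...)
  invisible(x)
}

#' Read or write survey records
#'
#' The survey CSV has header
#' `person_id,sex,age,weight,adl_bath,adl_dress,adl_eat,adl_bed,adl_toilet,`
#' `cd_arthritis,cd_cancer,cd_diabetes,cd_heart,cd_lung,cd_stroke`,
#' with items coded 1 = yes, 0 = no and empty = missing.
#'
#' @param path file path.
#' @return `read_survey()` returns the validated data frame;
#'   `write_survey()` returns `path` invisibly.
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_survey(df)
  df
}

#' @rdname read_survey
#' @param survey survey data frame.
#' @export
write_survey <- function(survey, path) {
  check_survey(survey)
  utils::write.csv(survey[, survey_cols], path, row.names = FALSE,
                   quote = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
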