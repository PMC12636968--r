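check_alignment <- function(lt, schedule, start_age) {
  i <- lt_row(lt, start_age)
  idx <- seq(i, nrow(lt))
  if (nrow(schedule) != length(idx) ||
      any(abs(schedule$x - lt$x[idx]) > 1e-9) ||
      any(is.finite(schedule$n) != is.finite(lt$n[idx])) ||
      any(abs(schedule$n[is.finite(schedule$n)] -
              lt$n[idx][is.finite(lt$n[idx])]) > 1e-9))
    stop("prevalence schedule groups must exactly cover the life-table groups ",
         "at or above age ", start_age)
  sx_lt <- attr(lt, "sex"); sx_s <- attr(schedule, "sex")
  if (!is.na(sx_lt) && !is.na(sx_s) && sx_lt != sx_s)
    stop("life table is for '", sx_lt, "' but schedule is for '", sx_s, "'")
  idx
}

#' Sullivan health expectancy
#'
#' Estimates healthy life expectancy at `start_age` by the Sullivan method:
#' life-table person-years in each age group are down-weighted by the
#' proportion of that group that is unhealthy,
#' \deqn{HLE(x_0) = \frac{1}{l(x_0)} \sum_{x \ge x_0} L_x (1 - \pi_x).}
#' With the disability definition this is disability-free life expectancy
#' (DFLE); with the chronic-disease definition, chronic-disease-free life
#' expectancy (CFLE).  The variance treats the life table as fixed (published
#' tables carry no sampling error here) and propagates only prevalence
#' sampling variation:
#' \deqn{Var = \frac{1}{l(x_0)^2} \sum_x L_x^2\, \pi_x(1-\pi_x)/n_x,}
#' with a normal-approximation confidence interval.
#'
#' @param lt a [lifetable()] covering `start_age` and above.
#' @param schedule a [prevalence_schedule()] whose groups exactly cover the
#'   life-table groups at or above `start_age`.
#' @param start_age age at which remaining expectancies are computed
#'   (default 60).
#' @param conf_level confidence level for the interval.
#' @return An object of class `health_expectancy` with components
#'   `definition, sex, start_age, total_le, hle, unhealthy_le, variance, se,
#'   ci_low, ci_high`.
#' @examples
#' lt <- lifetable(age_groups(), mx = 0.012 * exp(0.095 * (seq(60, 85, 5) - 60)))
#' sc <- prevalence_known(age_groups(), pi = seq(0.1, 0.6, by = 0.1),
#'                        n_unweighted = 500)
#' sullivan(lt, sc)
#' @references Sullivan, D. F. (1971). A single index of mortality and
#'   morbidity. HSMHA Health Reports 86, 347-354.
#' @export
sullivan <- function(lt, schedule, start_age = 60, conf_level = 0.95) {
  stopifnot(inherits(lt, "lifetable"), inherits(schedule, "prevalence_schedule"))
  idx <- check_alignment(lt, schedule, start_age)
  l0 <- lt$lx[idx[1L]]
  Lx <- lt$Lx[idx]
  hle <- sum(Lx * (1 - schedule$pi)) / l0
  total <- lt$ex[idx[1L]]

  if (any(schedule$n_unweighted <= 0))
    stop("every schedule group needs n_unweighted > 0 for the variance")
  variance <- sum(Lx^2 * schedule$pi * (1 - schedule$pi) / schedule$n_unweighted) / l0^2
  se <- sqrt(variance)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  structure(list(definition = attr(schedule, "definition"),
                 sex = attr(schedule, "sex") %||% attr(lt, "sex"),
                 start_age = start_age,
                 total_le = total, hle = hle, unhealthy_le = total - hle,
                 variance = variance, se = se,
                 ci_low = hle - z * se, ci_high = hle + z * se,
                 conf_level = conf_level),
            class = "health_expectancy")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' @export
print.health_expectancy <- function(x, digits = 3, ...) {
  lab <- switch(as.character(x$definition),
                disability = "Disability-free life expectancy (DFLE)",
                chronic = "Chronic-disease-free life expectancy (CFLE)",
                "Healthy life expectancy")
  cat(lab, " at age ", x$start_age,
      if (!is.na(x$sex %||% NA)) paste0(", ", x$sex), "\n", sep = "")
  cat(sprintf("  total LE: %.*f  healthy: %.*f  unhealthy: %.*f years\n",
              digits, x$total_le, digits, x$hle, digits, x$unhealthy_le))
  cat(sprintf("  %d%% CI for healthy years: [%.*f, %.*f]  (se %.*f)\n",
              round(100 * x$conf_level), digits, x$ci_low, digits, x$ci_high,
              digits, x$se))
  invisible(x)
}

#' @export
coef.health_expectancy <- function(object, ...) {
  c(total_le = object$total_le, hle = object$hle,
    unhealthy_le = object$unhealthy_le)
}

#' @export
confint.health_expectancy <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- matrix(c(object$hle - z * object$se, object$hle + z * object$se),
                nrow = 1,
                dimnames = list("hle", sprintf("%.1f %%",
                                               100 * c((1 - level) / 2, 1 - (1 - level) / 2))))
  out
}

#' Gender gap in health expectancy
#'
#' The gap is the women-minus-men difference in healthy years,
#' \eqn{\Delta = HLE_{women} - HLE_{men}}; its standard error assumes
#' independent samples by sex, `sqrt(var_w + var_m)`.
#'
#' @param women,men `health_expectancy` results for the same definition and
#'   start age.
#' @param conf_level confidence level for the gap interval.
#' @return An object of class `hle_gap` with `definition, start_age, delta,
#'   se, ci_low, ci_high` and the two inputs.
#' @export
gender_gap <- function(women, men, conf_level = 0.95) {
  stopifnot(inherits(women, "health_expectancy"),
            inherits(men, "health_expectancy"))
  if (!identical(women$definition, men$definition))
    stop("gap requires matching health definitions")
  if (women$start_age != men$start_age)
    stop("gap requires matching start ages")
  delta <- women$hle - men$hle
  se <- sqrt(women$variance + men$variance)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(definition = women$definition, start_age = women$start_age,
                 delta = delta, se = se,
                 ci_low = delta - z * se, ci_high = delta + z * se,
                 conf_level = conf_level, women = women, men = men),
            class = "hle_gap")
}

#' @export
print.hle_gap <- function(x, digits = 3, ...) {
  cat("Gender gap (women - men) in ",
      switch(as.character(x$definition), disability = "DFLE",
             chronic = "CFLE", "HLE"),
      " at age ", x$start_age, "\n", sep = "")
  cat(sprintf("  delta: %.*f years  (se %.*f, %d%% CI [%.*f, %.*f])\n",
              digits, x$delta, digits, x$se, round(100 * x$conf_level),
              digits, x$ci_low, digits, x$ci_high))
  invisible(x)
}

#' Write health-expectancy results or gaps to CSV
#'
#' @param results a list of `health_expectancy` objects, or of `hle_gap`
#'   objects for `write_gaps()`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_hle_results <- function(results, path) {
  if (inherits(results, "health_expectancy")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(definition = r$definition, sex = r$sex, start_age = r$start_age,
               total_le = r$total_le, hle = r$hle, unhealthy_le = r$unhealthy_le,
               se = r$se, ci_low = r$ci_low, ci_high = r$ci_high)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_hle_results
#' @export
write_gaps <- function(results, path) {
  if (inherits(results, "hle_gap")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(definition = r$definition, start_age = r$start_age,
               delta = r$delta, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
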