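#' Synthetic survey scenario
#'
#' A scenario fixes the data-generating process the analysis assumes: Gompertz
#' adult mortality per sex, logistic-in-age prevalence of poor health per sex
#' and health definition, heterogeneous positive survey weights, and
#' item-level missingness.  It is the ground truth against which the whole
#' pipeline (prevalence estimation, Sullivan expectancy, gap decomposition)
#' can be validated, since every population quantity has a closed form.
#'
#' Mortality follows \eqn{\mu(a) = \alpha e^{\beta a}} (hazard per
#' person-year at exact age `a`); prevalence follows
#' \eqn{\pi(a) = \mathrm{logit}^{-1}(\gamma_0 + \gamma_1 (a - 60))}, age
#' centred at 60.
#'
#' @param mortality named list `woman`/`man`, each `c(alpha, beta)`.
#' @param prevalence named list `disability`/`chronic`, each a named list
#'   `woman`/`man` of `c(gamma0, gamma1)`.
#' @param n_per_sex respondents drawn per sex.
#' @param weight_meanlog,weight_sdlog lognormal parameters of the analysis
#'   weights.
#' @param missingness probability, in \[0, 1), that an individual "no" item
#'   is unanswered (yes answers are never blanked, so a reported condition is
#'   never lost to missingness).
#' @param seed master seed; per-sex streams are derived from it so either
#'   sex can be regenerated alone.
#' @param groups age grid the survey covers.
#' @return An object of class `hle_scenario`.
#' @seealso [scenario_preset()] for ready-made regimes, [generate_survey()],
#'   [closed_form_hle()].
#' @export
scenario <- function(mortality, prevalence, n_per_sex = 20000,
                     weight_meanlog = 0, weight_sdlog = 0.5,
                     missingness = 0.005, seed = 4242,
                     groups = age_groups()) {
  for (sx in c("woman", "man")) {
    p <- mortality[[sx]]
    if (is.null(p) || length(p) != 2L || p[1L] <= 0)
      stop("mortality$", sx, " must be c(alpha, beta) with alpha > 0")
  }
  for (def in c("disability", "chronic"))
    for (sx in c("woman", "man"))
      if (is.null(prevalence[[def]][[sx]]) || length(prevalence[[def]][[sx]]) != 2L)
        stop("prevalence$", def, "$", sx, " must be c(gamma0, gamma1)")
  stopifnot(n_per_sex > 0, missingness >= 0, missingness < 1,
            weight_sdlog >= 0)
  check_age_grid(groups$x, groups$n)
  structure(list(mortality = mortality, prevalence = prevalence,
                 n_per_sex = as.integer(n_per_sex),
                 weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
                 missingness = missingness, seed = as.integer(seed),
                 groups = groups),
            class = "hle_scenario")
}

#' @export
print.hle_scenario <- function(x, ...) {
  cat("Synthetic health-expectancy scenario\n")
  for (sx in c("woman", "man"))
    cat(sprintf("  %-6s mortality: alpha %.3g, beta %.3g\n",
                sx, x$mortality[[sx]][1L], x$mortality[[sx]][2L]))
  for (def in c("disability", "chronic"))
    for (sx in c("woman", "man"))
      cat(sprintf("  %-10s %-6s prevalence: gamma0 %+.2f, gamma1 %.3f\n",
                  def, sx, x$prevalence[[def]][[sx]][1L],
                  x$prevalence[[def]][[sx]][2L]))
  cat(sprintf("  n per sex %d, weights lognormal(%.2f, %.2f), missingness %.2f, seed %d\n",
              x$n_per_sex, x$weight_meanlog, x$weight_sdlog, x$missingness,
              x$seed))
  invisible(x)
}

#' Named scenario presets
#'
#' Ready-made parameter sets mimicking qualitative regimes observed in
#' cross-national health-expectancy comparisons:
#' \describe{
#'   \item{`"null"`}{identical sexes; every true gap and component is zero.}
#'   \item{`"korea-like"`}{a large female survival advantage paired with a
#'     small female disability disadvantage, so the mortality component
#'     dwarfs the health component.}
#'   \item{`"portugal-like"`}{large mortality and disability components of
#'     opposite sign that nearly cancel, leaving a small total gap.}
#'   \item{`"denmark-like"`}{both components positive: women gain healthy
#'     years from surviving longer and from lower disability.}
#' }
#'
#' @param name preset name.
#' @param ... overrides passed on to [scenario()] (e.g. `n_per_sex`, `seed`).
#' @return An `hle_scenario`.
#' @export
scenario_preset <- function(name = c("null", "korea-like", "portugal-like",
                                     "denmark-like"), ...) {
  name <- match.arg(name)
  base_beta <- 0.11
  pars <- switch(name,
    "null" = list(
      mortality = list(woman = c(8e-6, base_beta), man = c(8e-6, base_beta)),
      prevalence = list(
        disability = list(woman = c(-1.5, 0.08), man = c(-1.5, 0.08)),
        chronic = list(woman = c(0.1, 0.05), man = c(0.1, 0.05)))),
    "korea-like" = list(
      mortality = list(woman = c(6e-6, base_beta), man = c(1.3e-5, base_beta)),
      prevalence = list(
        disability = list(woman = c(-1.5, 0.08), man = c(-1.6, 0.08)),
        chronic = list(woman = c(0.3, 0.05), man = c(0.0, 0.05)))),
    "portugal-like" = list(
      mortality = list(woman = c(6.2e-6, base_beta), man = c(1.3e-5, base_beta)),
      prevalence = list(
        disability = list(woman = c(-1.0, 0.08), man = c(-1.55, 0.08)),
        chronic = list(woman = c(0.5, 0.05), man = c(0.0, 0.05)))),
    "denmark-like" = list(
      mortality = list(woman = c(7e-6, base_beta), man = c(1.1e-5, base_beta)),
      prevalence = list(
        disability = list(woman = c(-1.7, 0.08), man = c(-1.45, 0.08)),
        chronic = list(woman = c(0.1, 0.05), man = c(0.15, 0.05)))))
  do.call(scenario, c(pars, list(...)))
}

group_midpoints <- function(groups) {
  ifelse(is.finite(groups$n), groups$x + groups$n / 2, groups$x + 5)
}

#' True mortality and prevalence schedules of a scenario
#'
#' `make_mortality_schedule()` discretises the scenario's Gompertz hazard to
#' the age grid: each group's mx is the hazard at the group midpoint, and the
#' open group uses the hazard 5 years above its start.
#' `make_prevalence_curve()` evaluates the logistic prevalence curve at the
#' same midpoints.
#'
#' @param scn an [scenario()].
#' @param sex `"woman"` or `"man"`.
#' @param groups age grid; defaults to the scenario's.
#' @return Numeric vector, one value per age group.
#' @export
make_mortality_schedule <- function(scn, sex = c("woman", "man"),
                                    groups = scn$groups) {
  stopifnot(inherits(scn, "hle_scenario"))
  sex <- match.arg(sex)
  p <- scn$mortality[[sex]]
  p[1L] * exp(p[2L] * group_midpoints(groups))
}

#' @rdname make_mortality_schedule
#' @param definition `"disability"` or `"chronic"`.
#' @export
make_prevalence_curve <- function(scn, sex = c("woman", "man"),
                                  definition = c("disability", "chronic"),
                                  groups = scn$groups) {
  stopifnot(inherits(scn, "hle_scenario"))
  sex <- match.arg(sex)
  definition <- match.arg(definition)
  g <- scn$prevalence[[definition]][[sex]]
  stats::plogis(g[1L] + g[2L] * (group_midpoints(groups) - 60))
}

#' True (radix-free) life table of a scenario sex
#'
#' Convenience wrapper: builds the abridged life table implied by
#' [make_mortality_schedule()].
#'
#' @inheritParams make_mortality_schedule
#' @return A [lifetable()].
#' @export
scenario_lifetable <- function(scn, sex = c("woman", "man"),
                               groups = scn$groups) {
  sex <- match.arg(sex)
  lifetable(groups, mx = make_mortality_schedule(scn, sex, groups), sex = sex)
}

sex_seed <- function(scn, sex) {
  # derived per-sex stream: master seed plus a fixed small offset
  scn$seed + if (sex == "woman") 1L else 2L
}

#' Generate a synthetic survey
#'
#' Draws respondents for both sexes.  Group counts are proportional to the
#' scenario life table's person-years Lx (stationary-population age
#' structure); ages are uniform integers within the group (the open group
#' spans ten single years).  The any-condition status is Bernoulli with the
#' group's true prevalence; item responses are then derived so the any-of-k
#' aggregate matches the drawn status exactly — one uniformly chosen positive
#' item when unhealthy, all "no" otherwise.  Weights are i.i.d. lognormal.
#' Each "no" item is independently blanked with the scenario's missingness
#' probability; positive items are never blanked, so an unhealthy
#' respondent's classification survives missingness (a single yes dominates).
#'
#' @param scn an [scenario()].
#' @param groups age grid; defaults to the scenario's.
#' @return A list with `survey` (data frame in the [read_survey()] schema)
#'   and `truth`, a list holding per sex the scenario life table and the true
#'   group prevalences per definition.
#' @export
generate_survey <- function(scn, groups = scn$groups) {
  stopifnot(inherits(scn, "hle_scenario"))
  check_age_grid(groups$x, groups$n)
  if (scn$n_per_sex <= 0) stop("scenario sample size must be positive")
  parts <- lapply(c("woman", "man"), function(sx) generate_sex(scn, sx, groups))
  survey <- rbind(parts[[1L]]$survey, parts[[2L]]$survey)
  rownames(survey) <- NULL
  truth <- list(woman = parts[[1L]]$truth, man = parts[[2L]]$truth)
  list(survey = survey, truth = truth)
}

generate_sex <- function(scn, sx, groups) {
  lt <- scenario_lifetable(scn, sx, groups)
  pi_dis <- make_prevalence_curve(scn, sx, "disability", groups)
  pi_chr <- make_prevalence_curve(scn, sx, "chronic", groups)
  n <- scn$n_per_sex
  k <- nrow(groups)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(sex_seed(scn, sx))

  counts <- as.integer(stats::rmultinom(1L, n, prob = lt$Lx))
  grp <- rep(seq_len(k), counts)
  width <- ifelse(is.finite(groups$n), groups$n, 10)
  age <- groups$x[grp] + floor(stats::runif(n) * width[grp])

  dis <- stats::rbinom(n, 1L, pi_dis[grp])
  chr <- stats::rbinom(n, 1L, pi_chr[grp])

  adl <- matrix(0, n, 5L)
  pick <- sample.int(5L, n, replace = TRUE)
  adl[cbind(which(dis == 1L), pick[dis == 1L])] <- 1
  cd <- matrix(0, n, 6L)
  pick6 <- sample.int(6L, n, replace = TRUE)
  cd[cbind(which(chr == 1L), pick6[chr == 1L])] <- 1

  weight <- stats::rlnorm(n, scn$weight_meanlog, scn$weight_sdlog)

  if (scn$missingness > 0) {
    blank_adl <- adl == 0 & matrix(stats::runif(5L * n) < scn$missingness, n, 5L)
    adl[blank_adl] <- NA
    blank_cd <- cd == 0 & matrix(stats::runif(6L * n) < scn$missingness, n, 6L)
    cd[blank_cd] <- NA
  }

  survey <- data.frame(person_id = paste0(substr(sx, 1L, 1L), seq_len(n)),
                       sex = sx, age = as.integer(age), weight = weight)
  survey[adl_cols] <- adl
  survey[chronic_cols] <- cd
  list(survey = survey,
       truth = list(lifetable = lt,
                    pi = list(disability = pi_dis, chronic = pi_chr)))
}

#' Closed-form expectancies of a scenario
#'
#' Ground truth by fine numerical integration of the scenario's continuous
#' hazard and prevalence curve: survival from `start_age` under Gompertz
#' mortality has the closed form
#' \eqn{S(a) = \exp\{-(\alpha/\beta)(e^{\beta a} - e^{\beta x_0})\}}, and
#' healthy life expectancy is \eqn{\int S(a)\,(1 - \pi(a))\,da},
#' evaluated by the trapezoid rule on a 0.01-year grid.  These truths anchor
#' the parameter-recovery tests of the sampled pipeline.
#'
#' @inheritParams make_prevalence_curve
#' @param start_age lower limit of the integral.
#' @param upper upper integration age (survival there is negligible).
#' @return Years (a single number).
#' @export
closed_form_hle <- function(scn, sex = c("woman", "man"),
                            definition = c("disability", "chronic"),
                            start_age = 60, upper = 130) {
  sex <- match.arg(sex)
  definition <- match.arg(definition)
  g <- scn$prevalence[[definition]][[sex]]
  integrate_survival(scn, sex, start_age, upper,
                     function(a) 1 - stats::plogis(g[1L] + g[2L] * (a - 60)))
}

#' @rdname closed_form_hle
#' @export
closed_form_le <- function(scn, sex = c("woman", "man"),
                           start_age = 60, upper = 130) {
  sex <- match.arg(sex)
  integrate_survival(scn, sex, start_age, upper, function(a) rep(1, length(a)))
}

integrate_survival <- function(scn, sex, start_age, upper, weight_fn, h = 0.01) {
  p <- scn$mortality[[sex]]
  a <- seq(start_age, upper, by = h)
  S <- exp(-(p[1L] / p[2L]) * (exp(p[2L] * a) - exp(p[2L] * start_age)))
  y <- S * weight_fn(a)
  h * (sum(y) - (y[1L] + y[length(y)]) / 2)
}

#' Truth-level decomposition of a scenario's gender gap
#'
#' Runs [decompose_gap()] on the scenario's exact (sampling-free) mortality
#' and prevalence schedules, i.e. the decomposition the pipeline would
#' produce with infinite data.
#'
#' @inheritParams make_prevalence_curve
#' @param start_age,n_steps passed to [decompose_gap()].
#' @return An `hle_decomposition`.
#' @export
decompose_truth <- function(scn, definition = c("disability", "chronic"),
                            start_age = 60, n_steps = 20) {
  definition <- match.arg(definition)
  groups <- scn$groups
  lts <- lapply(c(woman = "woman", man = "man"),
                function(sx) scenario_lifetable(scn, sx, groups))
  schedules <- lapply(c(woman = "woman", man = "man"), function(sx)
    prevalence_known(groups, make_prevalence_curve(scn, sx, definition, groups),
                     sex = sx, definition = definition))
  decompose_gap(lts$woman, lts$man, schedules$woman, schedules$man,
                start_age = start_age, n_steps = n_steps)
}
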