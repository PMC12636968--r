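#' Parameter vector and objective for health-expectancy decomposition
#'
#' The scalar function decomposed is Sullivan healthy life expectancy viewed
#' as a function of one sex's full parameter vector
#' \eqn{\theta = (m_{x_1},\dots,m_{x_k},\ \pi_{x_1},\dots,\pi_{x_k})}:
#' the age-group death rates (mortality block) followed by the age-group
#' proportions unhealthy (health block).  `hle_theta()` packs the two
#' schedules into a labelled vector; `hle_objective()` evaluates HLE at a
#' vector, rebuilding the abridged life table from the mx block each call.
#'
#' @param mx age-group central death rates (mortality block).
#' @param pi age-group proportions unhealthy (health block).
#' @param template a list with the age grid and conventions shared by all
#'   evaluations: `groups` (an [age_groups()] frame), `ax` (`NULL` for n/2),
#'   `start_age`, `radix`.  Build one with `hle_template()`.
#' @return `hle_theta()`: a named numeric vector with a `block` attribute
#'   labelling each entry `"mortality"` or `"health"`.
#'   `hle_objective()`: healthy life expectancy in years.
#' @examples
#' tpl <- hle_template(age_groups())
#' th <- hle_theta(mx = rep(0.05, 6), pi = rep(0.3, 6))
#' hle_objective(th, tpl)
#' @export
hle_theta <- function(mx, pi) {
  k <- length(mx)
  if (length(pi) != k) stop("'mx' and 'pi' must have one entry per age group")
  if (any(!is.finite(mx)) || any(mx <= 0)) stop("mx entries must be positive")
  if (any(!is.finite(pi)) || any(pi < 0 | pi > 1)) stop("pi entries must lie in [0, 1]")
  theta <- c(mx, pi)
  names(theta) <- c(paste0("mx_", seq_len(k)), paste0("pi_", seq_len(k)))
  attr(theta, "block") <- rep(c("mortality", "health"), each = k)
  theta
}

#' @rdname hle_theta
#' @param groups age grid data frame (`x`, `n`).
#' @param start_age start age of the expectancy.
#' @param ax optional ax values passed to [lifetable()].
#' @param radix life-table radix.
#' @export
hle_template <- function(groups = age_groups(), start_age = groups$x[1L],
                         ax = NULL, radix = 1e5) {
  check_age_grid(groups$x, groups$n)
  list(groups = groups, start_age = start_age, ax = ax, radix = radix)
}

#' @rdname hle_theta
#' @param theta parameter vector from [hle_theta()].
#' @export
hle_objective <- function(theta, template) {
  k <- nrow(template$groups)
  if (length(theta) != 2L * k)
    stop("theta length must be twice the number of age groups")
  mx <- theta[seq_len(k)]
  pi <- theta[k + seq_len(k)]
  if (any(pi < -1e-12 | pi > 1 + 1e-12))
    stop("prevalence entries left [0, 1] during evaluation")
  pi <- pmin(pmax(pi, 0), 1)
  lt <- lifetable(template$groups$x, template$groups$n, mx,
                  ax = template$ax, radix = template$radix)
  i <- lt_row(lt, template$start_age)
  idx <- seq(i, nrow(lt))
  sum(lt$Lx[idx] * (1 - pi[idx - i + 1L])) / lt$lx[i]
}

#' Continuous-change decomposition of a difference in a scalar functional
#'
#' Attributes the difference `f(theta2) - f(theta1)` to the individual
#' parameters by integrating partial effects along the straight-line path
#' between the two vectors (the Horiuchi-Wilmoth-Pletcher scheme).  The path
#' is sampled at `n_steps` midpoints; at each midpoint the contribution of
#' parameter i is the central difference of `f` under a displacement of
#' \eqn{\pm\delta_i/2}, \eqn{\delta_i = (\theta_{2,i}-\theta_{1,i})/n}.
#' Contributions are exactly additive up to a small residual, which is
#' reported and never redistributed.
#'
#' @param f scalar function of a parameter vector.  Extra arguments in `...`
#'   are passed through, so `f = hle_objective` with `template = tpl` works.
#' @param theta1,theta2 numeric parameter vectors of equal length (and equal
#'   names/block labels when present).  For a women-minus-men gap, `theta1`
#'   is men and `theta2` women.
#' @param n_steps number of path midpoints (default 20; residuals are then
#'   far below the 0.01-year reporting precision).
#' @param ... passed to `f`.
#' @return A list with `contributions` (named numeric, per parameter),
#'   `direct` = `f(theta2) - f(theta1)`, `total` = sum of contributions,
#'   `residual` = `total - direct`, and `n_steps`.
#' @examples
#' f <- function(th) th[1] * th[2]
#' decompose_cc(f, c(1, 2), c(3, 4), n_steps = 1000)$contributions
#' @references Horiuchi, S., Wilmoth, J. R., Pletcher, S. D. (2008).
#'   A decomposition method based on a model of continuous change.
#'   Demography 45, 785-801.
#' @export
decompose_cc <- function(f, theta1, theta2, n_steps = 20, ...) {
  p <- length(theta1)
  if (length(theta2) != p) stop("parameter vectors must have equal length")
  if (!is.null(names(theta1)) && !is.null(names(theta2)) &&
      !identical(names(theta1), names(theta2)))
    stop("parameter vector labels do not match")
  if (n_steps < 1) stop("n_steps must be at least 1")

  delta <- (theta2 - theta1) / n_steps
  contrib <- numeric(p)
  names(contrib) <- names(theta1)
  for (s in seq_len(n_steps)) {
    mid <- theta1 + (s - 0.5) / n_steps * (theta2 - theta1)
    for (i in seq_len(p)) {
      if (delta[i] == 0) next
      up <- mid; up[i] <- up[i] + delta[i] / 2
      dn <- mid; dn[i] <- dn[i] - delta[i] / 2
      fu <- f(up, ...); fd <- f(dn, ...)
      if (!is.finite(fu) || !is.finite(fd))
        stop("objective returned a non-finite value along the path")
      contrib[i] <- contrib[i] + (fu - fd)
    }
  }
  direct <- f(theta2, ...) - f(theta1, ...)
  total <- sum(contrib)
  list(contributions = contrib, direct = direct, total = total,
       residual = total - direct, n_steps = n_steps)
}

#' Stepwise-replacement decomposition (verification oracle)
#'
#' Replaces parameters of `theta1` by those of `theta2` one at a time and
#' credits each parameter with the change in `f` at its replacement, averaged
#' over replacement orders.  Contributions sum to `f(theta2) - f(theta1)`
#' exactly, which makes this an independent check on [decompose_cc()].  All
#' orderings are enumerated for up to 8 parameters; above that a declared
#' random sample of orderings with a fixed seed must be requested.
#'
#' @inheritParams decompose_cc
#' @param orderings `NULL` to enumerate all permutations (p <= 8), or the
#'   number of randomly sampled orderings.
#' @param seed seed for ordering sampling (required with `orderings`).
#' @return Named numeric vector of per-parameter contributions.
#' @export
decompose_stepwise <- function(f, theta1, theta2, orderings = NULL,
                               seed = NULL, ...) {
  p <- length(theta1)
  if (length(theta2) != p) stop("parameter vectors must have equal length")
  if (is.null(orderings)) {
    if (p > 8)
      stop("more than 8 parameters: declare a sampled number of 'orderings' and a 'seed'")
    perms <- all_permutations(p)
  } else {
    if (is.null(seed)) stop("sampled orderings require a 'seed'")
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    perms <- t(replicate(orderings, sample.int(p)))
  }
  contrib <- numeric(p)
  names(contrib) <- names(theta1)
  for (r in seq_len(nrow(perms))) {
    cur <- theta1
    f_prev <- f(cur, ...)
    for (i in perms[r, ]) {
      cur[i] <- theta2[i]
      f_new <- f(cur, ...)
      contrib[i] <- contrib[i] + (f_new - f_prev)
      f_prev <- f_new
    }
  }
  contrib / nrow(perms)
}

all_permutations <- function(p) {
  if (p == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(p - 1L)
  out <- matrix(0L, nrow(sub) * p, p)
  r <- 0L
  for (pos in seq_len(p)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], p,
                 sub[, seq(pos, p - 1L)[seq_len(p - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.matrix(blk)
    r <- r + nrow(sub)
  }
  out
}

#' Aggregate per-parameter contributions into mortality and health components
#'
#' @param contributions named or unnamed numeric vector of per-parameter
#'   contributions (years).
#' @param blocks character vector labelling each entry `"mortality"` or
#'   `"health"`; defaults to the `block` attribute of `contributions`.
#' @return A list with `mortality_component`, `health_component` and `total`
#'   (their sum), all in years.
#' @examples
#' aggregate_components(c(1.09, -1.25), c("mortality", "health"))
#' @export
aggregate_components <- function(contributions, blocks = attr(contributions, "block")) {
  if (is.null(blocks)) stop("every contribution must carry a block label")
  if (length(blocks) != length(contributions))
    stop("'blocks' must label every contribution")
  bad <- setdiff(unique(blocks), c("mortality", "health"))
  if (length(bad)) stop("unknown block labels: ", paste(bad, collapse = ", "))
  m <- sum(contributions[blocks == "mortality"])
  h <- sum(contributions[blocks == "health"])
  list(mortality_component = m, health_component = h, total = m + h)
}

#' Decompose a gender gap in health expectancy into mortality and health
#'
#' Splits the women-minus-men difference in Sullivan healthy life expectancy
#' into the part driven by sex differences in age-specific death rates and
#' the part driven by sex differences in age-specific prevalence of poor
#' health, using [decompose_cc()] on the full parameter vector (mx block +
#' prevalence block).  The two component sums add up to the directly computed
#' gap, up to the reported residual.
#'
#' @param lt_women,lt_men [lifetable()]s for each sex on the same age grid.
#' @param sched_women,sched_men [prevalence_schedule()]s covering the
#'   life-table groups at or above `start_age`.
#' @param start_age start age of the expectancy (default 60).
#' @param n_steps path midpoints for the continuous-change integral.
#' @param log_mx if `TRUE`, integrate along a straight line in log(mx) rather
#'   than mx (sensitivity check; default `FALSE`, rates on their raw scale).
#' @return An object of class `hle_decomposition`: per-age-group
#'   contributions split by block, component sums, the directly computed gap,
#'   the additivity residual and `n_steps`.
#' @examples
#' scn <- scenario_preset("korea-like")
#' d <- decompose_truth(scn, "disability")
#' d
#' @export
decompose_gap <- function(lt_women, lt_men, sched_women, sched_men,
                          start_age = 60, n_steps = 20, log_mx = FALSE) {
  stopifnot(inherits(lt_women, "lifetable"), inherits(lt_men, "lifetable"))
  iw <- check_alignment(lt_women, sched_women, start_age)
  im <- check_alignment(lt_men, sched_men, start_age)
  if (length(iw) != length(im) ||
      any(abs(lt_women$x[iw] - lt_men$x[im]) > 1e-9))
    stop("the two sexes must share the same age grid at or above start_age")

  groups <- data.frame(x = lt_women$x[iw], n = lt_women$n[iw])
  tpl <- hle_template(groups, start_age = start_age,
                      radix = attr(lt_women, "radix"))
  th_m <- hle_theta(lt_men$mx[im], sched_men$pi)
  th_w <- hle_theta(lt_women$mx[iw], sched_women$pi)
  blocks <- attr(th_m, "block")

  k <- nrow(groups)
  if (log_mx) {
    f <- function(th, template) {
      th[seq_len(k)] <- exp(th[seq_len(k)])
      hle_objective(th, template)
    }
    th_m[seq_len(k)] <- log(th_m[seq_len(k)])
    th_w[seq_len(k)] <- log(th_w[seq_len(k)])
  } else {
    f <- hle_objective
  }

  cc <- decompose_cc(f, th_m, th_w, n_steps = n_steps, template = tpl)
  comp <- aggregate_components(cc$contributions, blocks)

  per_age <- data.frame(
    block = blocks,
    x = rep(groups$x, 2L),
    contribution = unname(cc$contributions))
  structure(list(definition = attr(sched_women, "definition"),
                 start_age = start_age,
                 contributions = per_age,
                 mortality_component = comp$mortality_component,
                 health_component = comp$health_component,
                 total = comp$total,
                 direct_gap = cc$direct,
                 residual = cc$residual,
                 n_steps = n_steps,
                 log_mx = log_mx),
            class = "hle_decomposition")
}

#' @export
print.hle_decomposition <- function(x, digits = 3, ...) {
  cat("Decomposition of the gender gap (women - men) in ",
      switch(as.character(x$definition), disability = "DFLE",
             chronic = "CFLE", "HLE"),
      " at age ", x$start_age, "\n", sep = "")
  cat(sprintf("  mortality component: %+.*f years\n", digits, x$mortality_component))
  cat(sprintf("  health component:    %+.*f years\n", digits, x$health_component))
  cat(sprintf("  total:               %+.*f years (direct gap %+.*f, residual %.1e)\n",
              digits, x$total, digits, x$direct_gap, x$residual))
  cat("  path steps: ", x$n_steps,
      if (x$log_mx) "  (log-mx path)", "\n", sep = "")
  invisible(x)
}

#' Write a decomposition to CSV
#'
#' Writes the per-age contributions (`definition,block,x,contribution`)
#' followed by summary rows
#' (`mortality_component, health_component, total, direct_gap, residual,
#' n_steps`), encoded as pseudo-ages in the `block` column `"summary"`.
#'
#' @param d an `hle_decomposition`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(d, path) {
  stopifnot(inherits(d, "hle_decomposition"))
  per_age <- data.frame(definition = d$definition,
                        block = d$contributions$block,
                        x = as.character(d$contributions$x),
                        contribution = d$contributions$contribution)
  summ <- data.frame(definition = d$definition, block = "summary",
                     x = c("mortality_component", "health_component", "total",
                           "direct_gap", "residual", "n_steps"),
                     contribution = c(d$mortality_component, d$health_component,
                                      d$total, d$direct_gap, d$residual,
                                      d$n_steps))
  utils::write.csv(rbind(per_age, summ), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
summary.hle_decomposition <- function(object, ...) {
  wide <- stats::reshape(object$contributions, direction = "wide",
                         idvar = "x", timevar = "block")
  names(wide) <- sub("^contribution\\.", "", names(wide))
  wide$total <- wide$mortality + wide$health
  attr(wide, "reshapeWide") <- NULL
  rownames(wide) <- NULL
  wide
}

#' @export
plot.hle_decomposition <- function(x, ...) {
  s <- summary(x)
  m <- t(as.matrix(s[, c("mortality", "health")]))
  colnames(m) <- s$x
  graphics::barplot(m, beside = TRUE, legend.text = c("mortality", "health"),
                    xlab = "age group", ylab = "contribution (years)",
                    main = sprintf("Gap decomposition (%s), total %+.2f years",
                                   x$definition, x$total), ...)
  graphics::abline(h = 0)
  invisible(x)
}
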