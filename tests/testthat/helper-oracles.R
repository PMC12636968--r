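# Independent fine-grained life-table oracle built directly from a hazard
# function: exact interval death probabilities q = 1 - exp(-integral of mu),
# trapezoid person-years, and the same constant-hazard closure at `top` as
# the abridged construction so differences reflect group width only.
oracle_e <- function(hazard, from = 60, top = 85, width = 1) {
  a <- seq(from, top, by = width)
  k <- length(a) - 1L
  H <- vapply(seq_len(k), function(i)
    stats::integrate(hazard, a[i], a[i + 1L], rel.tol = 1e-10)$value, 0)
  q <- 1 - exp(-H)
  l <- cumprod(c(1, 1 - q))
  d <- l[seq_len(k)] * q
  L <- width * l[-1L] + (width / 2) * d
  L_open <- l[k + 1L] / hazard(top)
  (sum(L) + L_open) / l[1L]
}

gompertz <- function(alpha, beta) function(a) alpha * exp(beta * a)

group_mid <- function(grid) ifelse(is.finite(grid$n), grid$x + grid$n / 2, grid$x + 5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Abridged table of given width from the same hazard (midpoint rates),
# closed at `top` like the oracle.
abridged_from_hazard <- function(hazard, from = 60, top = 85, width = 5) {
  grid <- age_groups(from, top, width)
  mids <- ifelse(is.finite(grid$n), grid$x + grid$n / 2, grid$x)
  mx <- hazard(mids)
  mx[length(mx)] <- hazard(top)
  lifetable(grid, mx = mx)
}

# Brute-force respondent classifier, written over counts rather than the
# package's any()/all() logic.
classify_brute <- function(items) {
  n_yes <- sum(items == 1, na.rm = TRUE)
  n_no <- sum(items == 0, na.rm = TRUE)
  if (n_yes >= 1) "unhealthy"
  else if (n_no == length(items)) "healthy"
  else "missing"
}

# Two-group toy life table: l60 = radix, L = 4.5 and 10.0 person-years per
# unit radix (closed 60-64 with q = 0.2, open 65+ with m = 0.08).
toy_lifetable <- function() {
  lifetable(x = c(60, 65), n = c(5, Inf), mx = c(2 / 45, 0.08))
}

toy_groups <- function() data.frame(x = c(60, 65), n = c(5, Inf))

# Minimal valid survey data frame for classifier/prevalence tests.
make_survey <- function(age, sex = "woman", weight = 1,
                        adl = matrix(0, length(age), 5),
                        cd = matrix(0, length(age), 6)) {
  df <- data.frame(person_id = paste0("p", seq_along(age)), sex = sex,
                   age = age, weight = weight)
  colnames(adl) <- c("adl_bath", "adl_dress", "adl_eat", "adl_bed", "adl_toilet")
  colnames(cd) <- c("cd_arthritis", "cd_cancer", "cd_diabetes", "cd_heart",
                    "cd_lung", "cd_stroke")
  cbind(df, adl, cd)
}
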