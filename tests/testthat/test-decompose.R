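test_that("the objective reduces to life expectancy and scales with constant pi", {
  grid <- age_groups()
  tpl <- hle_template(grid)
  mx <- 8e-6 * exp(0.11 * group_mid(grid))
  lt <- lifetable(grid, mx = mx)
  th0 <- hle_theta(mx, rep(0, nrow(grid)))
  expect_equal(hle_objective(th0, tpl), life_expectancy(lt, 60),
               tolerance = 1e-12)
  th_p <- hle_theta(mx, rep(0.35, nrow(grid)))
  expect_equal(hle_objective(th_p, tpl), 0.65 * hle_objective(th0, tpl),
               tolerance = 1e-12)
  # two-group toy reuses the hand-computed Sullivan value
  tpl2 <- hle_template(toy_groups())
  th2 <- hle_theta(c(2 / 45, 0.08), c(0.2, 0.5))
  expect_equal(hle_objective(th2, tpl2), 8.6, tolerance = 1e-9)
})

test_that("identical endpoints decompose to zeros", {
  th <- c(1, 2, 3)
  res <- decompose_cc(function(t) sum(t^2), th, th)
  expect_true(all(res$contributions == 0))
  expect_equal(res$residual, 0)
  ora <- decompose_stepwise(function(t) sum(t^2), th, th)
  expect_true(all(ora == 0))
})

test_that("linear functionals decompose exactly for any step count", {
  b <- c(2, -1, 0.5)
  f <- function(t) sum(b * t) + 4
  t1 <- c(1, 1, 1)
  t2 <- c(2, 0, 3)
  for (ns in c(1, 3, 20)) {
    res <- decompose_cc(f, t1, t2, n_steps = ns)
    expect_equal(unname(res$contributions), b * (t2 - t1), tolerance = 1e-12)
    expect_equal(res$residual, 0, tolerance = 1e-12)
  }
  expect_equal(unname(decompose_stepwise(f, t1, t2)), b * (t2 - t1),
               tolerance = 1e-12)
})

test_that("the product toy case gives contributions (6, 4)", {
  f <- function(t) t[1] * t[2]
  ora <- decompose_stepwise(f, c(1, 2), c(3, 4))
  expect_equal(unname(ora), c(6, 4), tolerance = 1e-12)
  expect_equal(sum(ora), f(c(3, 4)) - f(c(1, 2)), tolerance = 1e-12)
  cc <- decompose_cc(f, c(1, 2), c(3, 4), n_steps = 1000)
  expect_equal(unname(cc$contributions), c(6, 4), tolerance = 1e-6)
})

test_that("continuous change matches the all-orderings oracle on toy objectives", {
  toys <- list(
    list(f = function(t) t[1] * t[2], t1 = c(1, 2), t2 = c(3, 4)),
    list(f = function(t) exp(t[1]) + t[2] * t[3],
         t1 = c(0.1, 1, 2), t2 = c(0.5, 2, 0.5)),
    list(f = function(t) t[1] * t[2] * t[3] + t[4]^2,
         t1 = c(1, 1, 1, 1), t2 = c(1.5, 0.5, 2, 2)))
  for (toy in toys) {
    ora <- decompose_stepwise(toy$f, toy$t1, toy$t2)
    cc <- decompose_cc(toy$f, toy$t1, toy$t2, n_steps = 1000)
    expect_lt(max(abs(cc$contributions - ora)), 0.01 * max(abs(ora)))
    expect_lt(abs(cc$residual), 1e-6)
  }
})

test_that("stepwise oracle guards parameter count and sampling declaration", {
  f <- function(t) sum(t)
  expect_error(decompose_stepwise(f, rep(0, 9), rep(1, 9)), "orderings")
  set9 <- decompose_stepwise(f, rep(0, 9), rep(1, 9), orderings = 50, seed = 5)
  expect_equal(unname(set9), rep(1, 9), tolerance = 1e-12)
  expect_error(decompose_stepwise(f, rep(0, 9), rep(1, 9), orderings = 10),
               "seed")
})

test_that("component aggregation sums blocks and flags unlabelled entries", {
  agg <- aggregate_components(c(1.09, -1.25), c("mortality", "health"))
  expect_equal(agg$total, -0.16, tolerance = 1e-12)
  agg2 <- aggregate_components(c(4.74, -0.35), c("mortality", "health"))
  expect_equal(agg2$total, 4.39, tolerance = 1e-12)
  expect_equal(aggregate_components(c(0, 0), c("mortality", "health"))$total, 0)
  expect_error(aggregate_components(c(1, 2)), "label")
  expect_error(aggregate_components(c(1, 2), c("mortality", "morbidity")),
               "unknown|block")
})

test_that("gap decomposition is additive, antisymmetric and convergent", {
  for (nm in c("null", "korea-like", "portugal-like", "denmark-like")) {
    scn <- scenario_preset(nm)
    d <- decompose_truth(scn, "disability")
    expect_equal(d$mortality_component + d$health_component, d$total,
                 tolerance = 1e-12)
    # default 20 steps keeps the residual far below reporting precision
    expect_lte(abs(d$residual), 1e-3)
    # residual magnitude non-increasing as the path is refined
    res <- vapply(c(5, 10, 20, 40), function(ns)
      abs(decompose_truth(scn, "disability", n_steps = ns)$residual), 0)
    expect_true(all(diff(res) <= 1e-12))
  }
  # the midpoint scheme is second order: refining the worst-case path by 16x
  # shrinks its residual by ~256x
  d20 <- decompose_truth(scenario_preset("korea-like"), "disability", n_steps = 20)
  d320 <- decompose_truth(scenario_preset("korea-like"), "disability", n_steps = 320)
  expect_lt(abs(d320$residual), abs(d20$residual) / 100)

  scn <- scenario_preset("portugal-like")
  groups <- scn$groups
  lts <- lapply(c(woman = "woman", man = "man"),
                function(sx) scenario_lifetable(scn, sx))
  scs <- lapply(c(woman = "woman", man = "man"), function(sx)
    prevalence_known(groups, make_prevalence_curve(scn, sx, "disability"),
                     sex = sx, definition = "disability"))
  fwd <- decompose_gap(lts$woman, lts$man, scs$woman, scs$man)
  # swapped direction: relabel sexes so the alignment checks pass
  attr(scs$woman, "sex") <- "man"; attr(scs$man, "sex") <- "woman"
  attr(lts$woman, "sex") <- "man"; attr(lts$man, "sex") <- "woman"
  bwd <- decompose_gap(lts$man, lts$woman, scs$man, scs$woman)
  expect_equal(fwd$contributions$contribution,
               -bwd$contributions$contribution, tolerance = 1e-9)
})

test_that("null blocks contribute nothing", {
  scn <- scenario_preset("korea-like")
  groups <- scn$groups
  lt_w <- scenario_lifetable(scn, "woman")
  lt_m <- scenario_lifetable(scn, "man")
  pi_w <- make_prevalence_curve(scn, "woman", "disability")
  pi_m <- make_prevalence_curve(scn, "man", "disability")
  sc <- function(pi, sx) prevalence_known(groups, pi, sex = sx,
                                          definition = "disability")
  # same prevalence, different mortality -> no health component
  d1 <- decompose_gap(lt_w, lt_m, sc(pi_w, "woman"), sc(pi_w, "man"))
  expect_lt(abs(d1$health_component), 1e-8)
  # same mortality, different prevalence -> no mortality component
  lt_m2 <- lt_w
  attr(lt_m2, "sex") <- "man"
  d2 <- decompose_gap(lt_w, lt_m2, sc(pi_w, "woman"), sc(pi_m, "man"))
  expect_lt(abs(d2$mortality_component), 1e-8)
})

test_that("preset truth decompositions carry their regime signatures", {
  d_null <- decompose_truth(scenario_preset("null"), "disability")
  expect_lt(abs(d_null$mortality_component), 1e-8)
  expect_lt(abs(d_null$health_component), 1e-8)

  d_kor <- decompose_truth(scenario_preset("korea-like"), "disability")
  expect_gte(d_kor$mortality_component, 5 * abs(d_kor$health_component))

  d_pt <- decompose_truth(scenario_preset("portugal-like"), "disability")
  expect_lt(abs(d_pt$total),
            min(abs(d_pt$mortality_component), abs(d_pt$health_component)) / 3)
  expect_gt(d_pt$mortality_component, 0)
  expect_lt(d_pt$health_component, 0)

  d_dk <- decompose_truth(scenario_preset("denmark-like"), "disability")
  expect_gt(d_dk$mortality_component, 0)
  expect_gt(d_dk$health_component, 0)
})
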