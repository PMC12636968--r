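test_that("mortality schedules follow the Gompertz hazard at midpoints", {
  grid <- age_groups()
  flat <- scenario(mortality = list(woman = c(0.02, 0), man = c(0.02, 0)),
                   prevalence = list(
                     disability = list(woman = c(-1, 0), man = c(-1, 0)),
                     chronic = list(woman = c(0, 0), man = c(0, 0))))
  expect_equal(make_mortality_schedule(flat, "woman"), rep(0.02, nrow(grid)))

  scn <- scenario_preset("null")
  mx <- make_mortality_schedule(scn, "man")
  scn2 <- scenario_preset("null")
  scn2$mortality$man[1] <- 2 * scn2$mortality$man[1]
  expect_equal(make_mortality_schedule(scn2, "man"), 2 * mx, tolerance = 1e-12)
  expect_true(all(diff(mx) > 0))
})

test_that("prevalence curves are logistic in age and bounded", {
  scn <- scenario_preset("null")
  piv <- make_prevalence_curve(scn, "woman", "disability")
  expect_true(all(diff(piv) > 0))
  expect_true(all(piv > 0 & piv < 1))
  mids <- group_mid(scn$groups)
  expect_equal(piv, stats::plogis(-1.5 + 0.08 * (mids - 60)), tolerance = 1e-12)

  flat <- scenario(mortality = scn$mortality,
                   prevalence = list(
                     disability = list(woman = c(-1, 0), man = c(-1, 0)),
                     chronic = list(woman = c(0, 0), man = c(0, 0))))
  expect_equal(make_prevalence_curve(flat, "man", "disability"),
               rep(stats::plogis(-1), nrow(scn$groups)), tolerance = 1e-12)
})

test_that("generated surveys are reproducible and satisfy record invariants", {
  scn <- scenario_preset("korea-like", n_per_sex = 2000)
  g1 <- generate_survey(scn)
  g2 <- generate_survey(scn)
  expect_identical(g1$survey, g2$survey)

  s <- g1$survey
  expect_equal(nrow(s), 2 * 2000)
  expect_true(all(s$weight > 0))
  expect_true(all(s$age >= 60 & s$age < 95))
  expect_true(all(s$sex %in% c("woman", "man")))
  items <- as.matrix(s[, grep("^(adl|cd)_", names(s))])
  expect_true(all(items %in% c(0, 1) | is.na(items)))
  # at most one positive item per definition by construction
  expect_true(all(rowSums(s[, grep("^adl_", names(s))] == 1, na.rm = TRUE) <= 1))
  expect_true(all(rowSums(s[, grep("^cd_", names(s))] == 1, na.rm = TRUE) <= 1))
})

test_that("zero prevalence or missingness produce the degenerate surveys", {
  scn <- scenario(mortality = list(woman = c(8e-6, 0.11), man = c(8e-6, 0.11)),
                  prevalence = list(
                    disability = list(woman = c(-30, 0), man = c(-30, 0)),
                    chronic = list(woman = c(0, 0.05), man = c(0, 0.05))),
                  n_per_sex = 1000, missingness = 0)
  s <- generate_survey(scn)$survey
  expect_identical(unique(classify_unhealthy(s, "disability")), "healthy")
  expect_false(anyNA(s[, grep("^cd_", names(s))]))
})

test_that("estimated prevalence tracks the generating truth", {
  scn <- scenario(mortality = list(woman = c(8e-6, 0.11), man = c(8e-6, 0.11)),
                  prevalence = list(
                    disability = list(woman = c(stats::qlogis(0.25), 0),
                                      man = c(stats::qlogis(0.25), 0)),
                    chronic = list(woman = c(0, 0.05), man = c(0, 0.05))),
                  n_per_sex = 10000, missingness = 0, seed = 8,
                  groups = data.frame(x = 60, n = Inf))
  ps <- prevalence_schedule(generate_survey(scn)$survey, "disability", "woman",
                            groups = scn$groups)
  expect_lt(abs(ps$pi - 0.25), 3 * ps$se)
})

test_that("closed-form truths obey their limiting identities", {
  scn <- scenario_preset("null")
  e60 <- closed_form_le(scn, "woman")
  flat0 <- scenario(mortality = scn$mortality,
                    prevalence = list(
                      disability = list(woman = c(-60, 0), man = c(-60, 0)),
                      chronic = list(woman = c(stats::qlogis(0.3), 0),
                                     man = c(stats::qlogis(0.3), 0))))
  expect_equal(closed_form_hle(flat0, "woman", "disability"), e60,
               tolerance = 1e-6)
  expect_equal(closed_form_hle(flat0, "woman", "chronic"), 0.7 * e60,
               tolerance = 1e-6)
  # symmetric scenario: both sexes share every truth
  expect_equal(closed_form_hle(scn, "woman", "disability"),
               closed_form_hle(scn, "man", "disability"), tolerance = 1e-12)
})

test_that("the full pipeline recovers closed-form healthy life expectancy", {
  scn <- scenario_preset("null", missingness = 0)
  gen <- generate_survey(scn)
  for (def in c("disability", "chronic")) {
    for (sx in c("woman", "man")) {
      h <- sullivan(gen$truth[[sx]]$lifetable,
                    prevalence_schedule(gen$survey, def, sx))
      expect_lt(abs(h$hle - closed_form_hle(scn, sx, def)), 0.15)
    }
  }
})

test_that("item missingness inflates estimated prevalence slightly (MNAR drop)", {
  # healthy records with a blanked item are dropped while any reported
  # condition survives, so the estimator drifts up with the missingness rate
  scn0 <- scenario_preset("null", missingness = 0)
  scn2 <- scenario_preset("null", missingness = 0.05)
  p0 <- prevalence_schedule(generate_survey(scn0)$survey, "disability", "woman")
  p2 <- prevalence_schedule(generate_survey(scn2)$survey, "disability", "woman")
  expect_true(mean(p2$pi - p0$pi) > 0)
  expect_true(all(p2$n_unweighted <= p0$n_unweighted))
})

test_that("unknown presets are rejected and the null preset is symmetric", {
  expect_error(scenario_preset("atlantis-like"))
  scn <- scenario_preset("null")
  expect_identical(scn$mortality$woman, scn$mortality$man)
  d <- decompose_truth(scn, "chronic")
  expect_equal(d$direct_gap, 0, tolerance = 1e-12)
})
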