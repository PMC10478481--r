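# Inequality gaps, sex averaging at reporting precision, percentage
# reductions, and the report container.

stats_row <- function(prev, onset, dur) {
  list(life_course_prevalence = prev, mean_age_onset = onset,
       mean_duration = dur)
}

test_that("gaps follow their sign conventions", {
  low <- stats_row(0.593, 43.5, 9.0)
  high <- stats_row(0.325, 45.4, 6.7)
  g <- gaps(low, high)
  expect_equal(g$prevalence_gap, 26.8, tolerance = 1e-9)
  expect_equal(g$onset_gap, 1.9, tolerance = 1e-9)
  expect_equal(g$duration_gap, 2.3, tolerance = 1e-9)
  # identical inputs: all gaps zero
  g0 <- gaps(low, low)
  expect_equal(unlist(g0), c(prevalence_gap = 0, onset_gap = 0,
                             duration_gap = 0))
})

test_that("gaps are antisymmetric in the two groups", {
  a <- stats_row(0.6, 42, 10)
  b <- stats_row(0.4, 45, 7)
  g_ab <- gaps(a, b)
  g_ba <- gaps(b, a)
  expect_equal(g_ab$prevalence_gap, -g_ba$prevalence_gap)
  expect_equal(g_ab$onset_gap, -g_ba$onset_gap)
  expect_equal(g_ab$duration_gap, -g_ba$duration_gap)
})

test_that("sex averaging uses decimal tie-away rounding", {
  gf <- list(prevalence_gap = 1.1, onset_gap = 2.2, duration_gap = -1.1)
  gm <- list(prevalence_gap = 2.2, onset_gap = 2.2, duration_gap = -2.2)
  avg <- sex_average(gf, gm)
  expect_equal(avg$prevalence_gap, 1.7) # 1.65 rounds away from zero
  expect_equal(avg$onset_gap, 2.2)     # equal inputs pass through
  expect_equal(avg$duration_gap, -1.7) # ties away from zero also below zero
})

test_that("round_half_away breaks ties away from zero in decimal arithmetic", {
  expect_equal(round_half_away(27.55), 27.6)
  expect_equal(round_half_away(-27.55), -27.6)
  expect_equal(round_half_away(2.25), 2.3)
  expect_equal(round_half_away(0.144, 2), 0.14)
})

test_that("percentage reduction behaves at the edges", {
  expect_equal(percent_reduction(26.8, 24.7), 100 * (26.8 - 24.7) / 26.8)
  expect_equal(percent_reduction(5, 5), 0)
  expect_equal(percent_reduction(5, 0), 100)
  expect_warning(res <- percent_reduction(0, 1), "zero")
  expect_true(is.na(res))
  # scale invariance
  expect_equal(percent_reduction(3 * 2.5, 3 * 1.5),
               percent_reduction(2.5, 1.5))
})

test_that("the report carries scenarios, gaps and reductions", {
  summary_df <- function(shift) {
    st <- strata()
    st$n <- 1000
    st$life_course_prevalence <- ifelse(st$edu == "low", 0.6 - shift, 0.4)
    st$mean_age_onset <- ifelse(st$edu == "low", 43, 45)
    st$mean_duration <- ifelse(st$edu == "low", 9, 7)
    st
  }
  obs <- summary_df(0)
  cfs <- list(
    counterfactual_smoking = summary_df(0.05),
    counterfactual_alcohol = summary_df(0.02),
    counterfactual_health_literacy = summary_df(0.01),
    counterfactual_diet = summary_df(0.01),
    counterfactual_joint = summary_df(0.08)
  )
  rep <- build_report(obs, cfs)
  expect_setequal(names(rep), c("observed", names(cfs)))
  for (name in names(cfs)) {
    expect_named(rep[[name]]$reductions, c("female", "male"))
    expect_length(rep[[name]]$reductions$female, 3)
  }
  expect_equal(rep$counterfactual_smoking$reductions$female$prevalence,
               100 * 5 / 20)
  # observed-only report has no reduction blocks
  rep0 <- build_report(obs)
  expect_named(rep0, "observed")
  expect_null(rep0$observed$reductions)
  # JSON round trip
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$counterfactual_joint$reductions$male$duration,
               rep$counterfactual_joint$reductions$male$duration,
               tolerance = 1e-12)
  expect_equal(back$observed$gaps$female$prevalence_gap,
               rep$observed$gaps$female$prevalence_gap, tolerance = 1e-12)
})

test_that("table arithmetic reproduces hand-computed gaps and reductions", {
  tab <- data.frame(
    sex = rep(c("female", "male"), each = 3),
    education = rep(c("high", "low", "low"), 2),
    scenario = rep(c("observed", "observed", "counterfactual_smoking"), 2),
    prevalence_percent = c(30.0, 50.0, 46.0, 40.0, 64.0, 60.0),
    onset_years = c(45.0, 43.0, 43.5, 44.0, 41.0, 41.5),
    duration_years = c(6.0, 9.0, 8.5, 7.0, 10.0, 9.4),
    stringsAsFactors = FALSE
  )
  res <- inequality_from_table(tab)
  expect_equal(res$observed$gaps$female$prevalence_gap, 20.0)
  expect_equal(res$observed$gaps$male$prevalence_gap, 24.0)
  expect_equal(res$observed$gaps$average$prevalence_gap, 22.0)
  expect_equal(res$observed$gaps$female$onset_gap, 2.0)
  expect_equal(res$counterfactual_smoking$gaps$female$prevalence_gap, 16.0)
  expect_equal(res$counterfactual_smoking$reductions$female$prevalence,
               100 * (20 - 16) / 20)
  expect_equal(res$counterfactual_smoking$reductions$male$duration,
               100 * (3.0 - 2.4) / 3.0)
})

test_that("reduction chart data mirrors the report", {
  st <- strata()
  st$n <- 10
  st$life_course_prevalence <- ifelse(st$edu == "low", 0.6, 0.4)
  st$mean_age_onset <- ifelse(st$edu == "low", 43, 45)
  st$mean_duration <- ifelse(st$edu == "low", 9, 7)
  st2 <- st
  st2$life_course_prevalence <- ifelse(st$edu == "low", 0.55, 0.4)
  rep <- build_report(st, list(counterfactual_smoking = st2))
  cd <- reduction_chart_data(rep, "prevalence")
  expect_equal(nrow(cd), 4) # 2 scenarios x 2 sexes
  expect_equal(cd$reduction_percent[cd$scenario == "counterfactual_smoking" &
                                      cd$sex == "female"], 25)
})
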