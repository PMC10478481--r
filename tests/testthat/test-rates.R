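# Rate estimation: baseline prevalence at 18, age-group interval
# probabilities via marginal standardization, Agresti correction, and the
# exponential annualization.

test_that("annualize implements the constant-hazard conversion", {
  expect_equal(annualize(0, 4), 0)
  expect_equal(annualize(0.2, 4), -log(0.8) / 4)
  expect_equal(annualize(0.2, 4), 0.05579, tolerance = 1e-4)
  # round trip: probability implied by the rate reproduces the input
  p <- c(0.01, 0.2, 0.7, 0.95)
  r <- annualize(p, 3.5)
  expect_equal(1 - exp(-r * 3.5), p, tolerance = 1e-12)
  # monotone in probability, rates nonnegative
  expect_true(all(diff(annualize(seq(0, 0.9, 0.1), 4)) > 0))
  expect_true(all(annualize(seq(0, 0.99, 0.01), 2) >= 0))
  expect_error(annualize(1, 4), "\\[0, 1\\)")
  expect_error(annualize(0.5, 0), "positive")
  # delta-method SE
  out <- annualize(0.2, 4, se = 0.02)
  expect_equal(out$se, 0.02 / (0.8 * 4))
})

test_that("prevalence at 18 recovers an age-independent truth", {
  cfg <- edu_only_config(40000, seed = 31, lam_low = 0.02, lam_high = 0.02,
                         mu = 0, p0 = 0.05)
  co <- generate_cohort(cfg)
  prev <- estimate_prevalence_at_18(co)
  expect_equal(nrow(prev), 4)
  for (i in 1:4) {
    expect_lt(abs(prev$probability[i] - 0.05), 3 * prev$se[i])
  }
})

test_that("prevalence at 18 recovers the generating logistic model", {
  # baseline log-odds: -3 + 0.05 * age, i.e. intercept -2.1 at age 18
  cfg <- edu_only_config(50000, seed = 32, lam_low = 0.02,
                         lam_high = 0.02, mu = 0, p0 = 0.5)
  cfg$baseline_prevalence_model$intercept <- -3 + 0.05 * 18
  cfg$baseline_prevalence_model$age <- 0.05
  co <- generate_cohort(cfg)
  prev <- estimate_prevalence_at_18(co)
  target <- plogis(-3 + 0.9) # 0.1091
  for (i in 1:4) {
    expect_lt(abs(prev$probability[i] - target), 3 * prev$se[i])
  }
})

test_that("separated strata fall back to the corrected proportion with a warning", {
  co <- tiny_cohort()
  co$mets_t1 <- FALSE # no baseline cases anywhere
  w <- capture_warnings(prev <- estimate_prevalence_at_18(co))
  expect_length(w, 4) # one warning per separated stratum
  expect_match(w, "Agresti", all = TRUE)
  expect_true(all(prev$corrected))
  expect_equal(prev$probability, rep(0.5 / 61, 4), tolerance = 1e-12)
})

test_that("interval probabilities match the closed form under a constant hazard", {
  cfg <- edu_only_config(40000, seed = 33, lam_low = 0.03, lam_high = 0.03,
                         mu = 0, p0 = 0)
  co <- generate_cohort(cfg)
  probs <- estimate_interval_probabilities(co, "incidence")
  target <- 1 - exp(-0.12) # 0.1131
  checked <- 0
  for (i in seq_len(nrow(probs))) {
    if (probs$absent[i] || probs$n_at_risk[i] < 200) next
    expect_lt(abs(probs$probability[i] - target), 3 * probs$se[i])
    expect_equal(probs$mean_followup[i], 4, tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_gte(checked, 30) # most of the 40 cells are well populated
})

test_that("marginal standardization reproduces empirical cell fractions", {
  # logistic score equations balance each age-group indicator, so the mean
  # fitted probability over a cell equals its empirical transition fraction
  cfg <- default_generator_config(n_participants = 20000, seed = 34)
  co <- generate_cohort(cfg)
  probs <- estimate_interval_probabilities(co, "incidence")
  d <- metsim:::at_risk_subset(co, "incidence")
  for (i in seq_len(nrow(probs))) {
    if (probs$absent[i] || probs$corrected[i]) next
    idx <- d$sex == probs$sex[i] & d$edu == probs$edu[i] &
      as.character(d$age_grp) == probs$age_group[i]
    expect_equal(probs$probability[i], mean(d$event[idx]),
                 tolerance = 1e-6)
  }
})

test_that("cells with zero events get the Agresti-corrected probability", {
  co <- tiny_cohort(n_per_stratum = 80, seed = 7)
  # force zero events in one cell: females/low aged [40,45)
  cell <- co$sex == "female" & co$edu_years == 10 &
    co$age_t1 >= 40 & co$age_t1 < 45
  co$mets_t4[cell] <- FALSE
  probs <- estimate_interval_probabilities(co, "incidence")
  row <- probs[probs$sex == "female" & probs$edu == "low" &
                 probs$age_group == "[40,45)", ]
  n <- sum(cell)
  expect_true(row$corrected)
  expect_equal(row$probability, 0.5 / (n + 1), tolerance = 1e-12)
})

test_that("estimated rates are nonnegative and carried through the CSV round trip", {
  cfg <- default_generator_config(n_participants = 15000, seed = 35)
  co <- generate_cohort(cfg)
  rates <- rbind(estimate_rates(co, "incidence"),
                 estimate_rates(co, "recovery"))
  expect_true(all(rates$rate_per_year[!rates$absent] >= 0))
  path <- tempfile(fileext = ".csv")
  write_rates(rates, path)
  back <- read_rates(path)
  expect_equal(back$rate_per_year, rates$rate_per_year, tolerance = 1e-9)
  expect_equal(back$sex, rates$sex)
  # validation catches broken files
  bad <- rates
  bad$age_hi[1] <- 17
  write_rates(bad, path)
  expect_error(read_rates(path), "invalid age bin")
})
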