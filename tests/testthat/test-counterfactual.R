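# Counterfactual reweighting and mediation analysis.

test_that("identity reweighting leaves the standardized rates unchanged", {
  # duplicate the low-education records as the high-education group (same
  # sex), so both education groups share the factor marginals exactly and
  # every weight is 1
  cfg <- default_generator_config(n_participants = 8000, seed = 51)
  co <- generate_cohort(cfg)
  low <- co[co$edu_years == 10, ]
  high <- low
  high$edu_years <- 16L
  high$id <- high$id + max(co$id)
  twin <- rbind(low, high)
  obs <- estimate_rates(twin, "incidence")
  cf <- counterfactual_rates(twin, c("smoking", "alcohol", "diet",
                                     "health_literacy"), "incidence")
  obs_low <- obs[obs$edu == "low" & !obs$absent & !obs$corrected, ]
  cf_low <- cf[!cf$absent, ]
  merged <- merge(obs_low, cf_low, by = c("sex", "age_group"))
  expect_gt(nrow(merged), 10)
  expect_equal(merged$rate_per_year.y, merged$rate_per_year.x,
               tolerance = 1e-12)
})

test_that("single-mediator counterfactual equals the two-term mixture by hand", {
  # one age bin, one binary mediator with P_low = (0.7, 0.3) and
  # P_high = (0.3, 0.7); the counterfactual probability must equal
  # sum_m P_high(m) p_hat(m)
  set.seed(61)
  n_low <- 1000
  n_high <- 1000
  make <- function(n, p_lowlit, edu_years, p_event, id0) {
    lit <- sample(c("low", "high"), n, replace = TRUE,
                  prob = c(p_lowlit, 1 - p_lowlit))
    data.frame(
      id = id0 + seq_len(n), sex = "female", edu_years = edu_years,
      age_t1 = runif(n, 20, 24.9), smoking = "never", alcohol = "none",
      diet = "healthy", health_literacy = lit, mets_t1 = FALSE,
      mets_t4 = runif(n) < p_event[lit], stringsAsFactors = FALSE
    )
  }
  co <- rbind(
    make(n_low, 0.7, 10L, c(low = 0.30, high = 0.10), 0),
    make(n_high, 0.3, 16L, c(low = 0.25, high = 0.08), n_low)
  )
  co$age_t4 <- co$age_t1 + 4
  cf <- counterfactual_rates(co, "health_literacy", "incidence")
  row <- cf[cf$sex == "female" & cf$age_group == "[20,25)", ]
  # hand-computed mixture: empirical per-category event fractions of the
  # low group weighted by the high group's observed category shares
  low <- co[co$edu_years == 10, ]
  high <- co[co$edu_years == 16, ]
  p_hat <- tapply(low$mets_t4, low$health_literacy, mean)
  p_high <- table(high$health_literacy) / nrow(high)
  expected_prob <- sum(p_high[names(p_hat)] * p_hat)
  expect_equal(row$probability, unname(expected_prob), tolerance = 1e-12)
})

test_that("joint weights factorize over independently generated factors", {
  cfg <- default_generator_config(n_participants = 6000, seed = 52)
  co <- generate_cohort(cfg)
  d <- metsim:::at_risk_subset(co, "incidence")
  d_low <- d[d$sex == "female" & d$edu == "low", ]
  d_high <- d[d$sex == "female" & d$edu == "high", ]
  w_joint <- metsim:::counterfactual_weights(d_low, d_high,
                                             c("smoking", "diet"))
  w_s <- metsim:::counterfactual_weights(d_low, d_high, "smoking")
  w_d <- metsim:::counterfactual_weights(d_low, d_high, "diet")
  expect_equal(w_joint, w_s * w_d, tolerance = 1e-12)
})

test_that("per-cell weights average to one on their own cell", {
  cfg <- default_generator_config(n_participants = 20000, seed = 53)
  co <- generate_cohort(cfg)
  d <- metsim:::at_risk_subset(co, "incidence")
  for (s in c("female", "male")) {
    d_low <- d[d$sex == s & d$edu == "low", ]
    d_high <- d[d$sex == s & d$edu == "high", ]
    cells <- unique(as.character(d_low$age_grp))
    for (cell in cells[1:3]) {
      dl <- d_low[as.character(d_low$age_grp) == cell, ]
      w <- metsim:::counterfactual_weights(dl, dl, "smoking")
      expect_equal(mean(w), 1, tolerance = 1e-9)
      # ratio weights against the cell's own marginal also average to 1
      dh <- d_high[as.character(d_high$age_grp) == cell, ]
      if (nrow(dh) > 50 &&
            all(names(table(dl$smoking)) %in%
                  names(table(dh$smoking)[table(dh$smoking) > 0]))) {
        w2 <- metsim:::counterfactual_weights(dl, dh, "smoking")
        expect_equal(mean(w2), 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("a category absent from the high-education group is an error", {
  co <- tiny_cohort(n_per_stratum = 50)
  co$smoking[co$edu_years == 10] <- "current"
  co$smoking[co$edu_years == 16] <- "never"
  # make events informative enough to fit
  expect_error(counterfactual_rates(co, "smoking", "incidence"),
               "absent from the high-education")
})

test_that("a factor unrelated to education and outcome mediates ~0%", {
  cfg <- default_generator_config(n_participants = 40000, seed = 54)
  # diet: no effect on incidence, same distribution in both groups
  cfg$incidence_model$diet[] <- 0
  cfg$mediator_distributions$low$diet <-
    cfg$mediator_distributions$high$diet
  co <- generate_cohort(cfg)
  med <- mediation_percentages(co, "incidence", factors = "diet")
  expect_lt(abs(med$mediated_percent), 5)
})

test_that("a fully mediating factor approaches 100%", {
  cfg <- default_generator_config(n_participants = 150000, seed = 55)
  # education affects incidence only through smoking; everyone starts
  # at risk and nobody recovers inside the interval, so the education
  # coefficient conditional on smoking is exactly zero in the generator
  cfg$baseline_prevalence_model$intercept <- -Inf
  cfg$recovery_model$intercept <- -Inf
  cfg$recovery_model$education[] <- 0
  cfg$incidence_model$education[] <- 0
  cfg$incidence_model$smoking <- c(never = 0, former = 0.45, current = 0.9)
  cfg$incidence_model$alcohol[] <- 0
  cfg$incidence_model$diet[] <- 0
  cfg$incidence_model$health_literacy[] <- 0
  # keep the remaining mediators balanced across education so they cannot
  # carry any of the (null) direct effect
  for (f in c("alcohol", "diet", "health_literacy")) {
    cfg$mediator_distributions$low[[f]] <-
      cfg$mediator_distributions$high[[f]]
  }
  co <- generate_cohort(cfg)
  med <- mediation_percentages(co, "incidence", factors = "smoking")
  expect_gt(med$mediated_percent, 88)
  expect_lt(med$mediated_percent, 112)
})

test_that("mediated percentage is invariant to category relabelling", {
  cfg <- default_generator_config(n_participants = 30000, seed = 56)
  co <- generate_cohort(cfg)
  med1 <- mediation_percentages(co, "incidence", factors = "smoking")
  relabel <- c(never = "z_none", former = "a_past", current = "m_now")
  co2 <- co
  co2$smoking <- unname(relabel[co$smoking])
  med2 <- mediation_percentages(co2, "incidence", factors = "smoking")
  expect_equal(med1$mediated_percent, med2$mediated_percent,
               tolerance = 1e-8)
})

test_that("the counterfactual pipeline runs end to end and is seed-stable", {
  cfg <- default_generator_config(n_participants = 15000, seed = 57)
  co <- generate_cohort(cfg)
  res1 <- run_counterfactual_pipeline(co, "smoking", n_per_group = 1000,
                                      seed = 4)
  res2 <- run_counterfactual_pipeline(co, "smoking", n_per_group = 1000,
                                      seed = 4)
  expect_equal(res1$summary, res2$summary)
  expect_equal(nrow(res1$summary), 4)
  # observed scenario via factors = NULL
  obs <- run_counterfactual_pipeline(co, NULL, n_per_group = 1000, seed = 4)
  expect_equal(nrow(obs$summary), 4)
})
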