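# Curve parameterization: polynomial and logistic fits, evaluation
# clipping, mean absolute error, and serialization.

# age-group rate points at the standard bin midpoints from a function
points_from_fn <- function(f) {
  bins <- metsim:::age_group_table()
  data.frame(age_lo = bins$age_lo, age_hi = bins$age_hi,
             rate_per_year = f(bins$midpoint))
}

test_that("quartic OLS interpolates a lower-degree polynomial exactly", {
  truth <- function(a) 1e-4 * (2 + 0.01 * a + 1e-4 * a^2)
  pts <- points_from_fn(truth)
  cv <- fit_recovery_poly(pts)
  expect_equal(unname(cv$params[1:3]),
               c(2e-4, 1e-6, 1e-8), tolerance = 1e-6)
  expect_lt(max(abs(cv$params[4:5])), 1e-10)
  expect_lt(curve_mae(cv, pts), 1e-12)
})

test_that("constant recovery points give a constant polynomial", {
  pts <- points_from_fn(function(a) rep(0.05, length(a)))
  cv <- fit_recovery_poly(pts)
  expect_equal(unname(cv$params[["c0"]]), 0.05, tolerance = 1e-6)
  ages <- seq(18, 65, 0.5)
  expect_equal(evaluate_curve(cv, ages), rep(0.05, length(ages)),
               tolerance = 1e-8)
})

test_that("noisy quartic recovery points are fitted within twice the noise", {
  truth <- function(a) 0.2 - 0.004 * a + 3e-5 * a^2 + 1e-7 * a^3 - 1e-9 * a^4
  set.seed(12)
  pts <- points_from_fn(truth)
  pts$rate_per_year <- pts$rate_per_year + rnorm(nrow(pts), 0, 1e-4)
  cv <- fit_recovery_poly(pts)
  bins <- metsim:::age_group_table()
  mae_truth <- mean(abs(evaluate_curve(cv, bins$midpoint) -
                          truth(bins$midpoint)))
  expect_lt(mae_truth, 2e-4)
})

test_that("fewer than five points is an error for the polynomial", {
  pts <- points_from_fn(function(a) rep(0.1, length(a)))[1:4, ]
  expect_error(fit_recovery_poly(pts), ">= 5")
})

test_that("logistic fit recovers noise-free parameters", {
  truth <- c(L = 0.08, k = 0.12, a0 = 45)
  pts <- points_from_fn(function(a) {
    truth[["L"]] / (1 + exp(-truth[["k"]] * (a - truth[["a0"]])))
  })
  cv <- fit_incidence_logit(pts)
  expect_equal(unname(cv$params), unname(truth), tolerance = 1e-4)
})

test_that("flat incidence points yield a flat fitted curve", {
  pts <- points_from_fn(function(a) rep(0.03, length(a)))
  cv <- fit_incidence_logit(pts)
  ages <- seq(18, 65, 0.25)
  expect_equal(evaluate_curve(cv, ages), rep(0.03, length(ages)),
               tolerance = 1e-6)
})

test_that("a fitted logistic with positive slope is nondecreasing in age", {
  pts <- points_from_fn(function(a) 0.06 / (1 + exp(-0.1 * (a - 40))))
  cv <- fit_incidence_logit(pts)
  expect_gt(cv$params[["k"]], 0)
  vals <- evaluate_curve(cv, seq(18, 65, 0.1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("evaluation clips at zero and checks the age range", {
  neg <- rate_curve("poly4", c(c0 = -1, c1 = 0, c2 = 0, c3 = 0, c4 = 0))
  expect_equal(evaluate_curve(neg, c(18, 40, 65)), c(0, 0, 0))
  logit <- rate_curve("logit3", c(L = 0.1, k = 0.2, a0 = 40))
  expect_equal(evaluate_curve(logit, 40), 0.05) # midpoint is L/2
  const <- constant_curve(0.02)
  expect_equal(evaluate_curve(const, 30), 0.02)
  expect_error(evaluate_curve(const, 17.9), "age must lie")
  expect_error(evaluate_curve(const, 65.1), "age must lie")
})

test_that("mean absolute error follows its definition", {
  cv <- constant_curve(0.05)
  pts <- data.frame(age_lo = c(20, 25), age_hi = c(25, 30),
                    rate_per_year = c(0.04, 0.06))
  expect_equal(curve_mae(cv, pts), 0.01)
  # identity: a curve against its own midpoint values
  self_pts <- points_from_fn(function(a) evaluate_curve(cv, a))
  expect_equal(curve_mae(cv, self_pts), 0)
  # invariant to point ordering
  expect_equal(curve_mae(cv, pts[2:1, ]), curve_mae(cv, pts))
})

test_that("the quartic fit never beats the best constant at the midpoints", {
  set.seed(77)
  for (rep in 1:5) {
    pts <- points_from_fn(function(a) {
      pmax(0.01 + 0.002 * (a - 18) + rnorm(length(a), 0, 0.005), 0)
    })
    cv <- fit_recovery_poly(pts)
    const <- constant_curve(mean(pts$rate_per_year))
    expect_lte(curve_mae(cv, pts), curve_mae(const, pts) + 1e-12)
  }
})

test_that("curve evaluation is continuous in age", {
  pts <- points_from_fn(function(a) 0.06 / (1 + exp(-0.1 * (a - 40))))
  cvs <- list(fit_incidence_logit(pts), fit_recovery_poly(pts))
  ages <- seq(18, 65 - 1e-6, length.out = 2000)
  for (cv in cvs) {
    jump <- abs(evaluate_curve(cv, ages + 1e-6) - evaluate_curve(cv, ages))
    expect_lt(max(jump), 1e-4)
  }
})

test_that("curves serialize to JSON and back", {
  rates <- NULL
  cfg <- default_generator_config(n_participants = 15000, seed = 44)
  co <- generate_cohort(cfg)
  rates <- rbind(estimate_rates(co, "incidence"),
                 estimate_rates(co, "recovery"))
  curves <- fit_all_curves(rates)
  path <- tempfile(fileext = ".json")
  write_curves(curves, path)
  back <- read_curves(path)
  for (s in c("female", "male")) {
    for (e in c("low", "high")) {
      for (k in c("incidence", "recovery")) {
        expect_equal(back[[s]][[e]][[k]]$params,
                     curves[[s]][[e]][[k]]$params, tolerance = 1e-12)
        expect_equal(back[[s]][[e]][[k]]$form, curves[[s]][[e]][[k]]$form)
      }
    }
  }
  # the reader rejects invalid asymptotes
  doc <- jsonlite::read_json(path)
  doc[[1]]$params$L <- -0.1
  doc[[1]]$form <- "logit3"
  doc[[1]]$params <- list(L = -0.1, k = 0.1, a0 = 40)
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_curves(path), "nonnegative")
})
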