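# Ground-truth-known synthetic two-wave cohort generator. Emulates the
# structure of a large Dutch population cohort: two measurement waves about
# four years apart, MetS status at each wave, sex, educational level
# (10 vs 16 years), and four categorical modifiable factors.

#' Default generator configuration
#'
#' Returns a complete `GeneratorConfig` describing the synthetic cohort: the
#' modifiable-factor distributions per educational level (published
#' cohort-study percentages; each category column renormalized to sum to 1,
#' raw percentages kept in `attr(, "raw_percent")`), the baseline-prevalence
#' model (logit scale), and the incidence and recovery hazard models
#' (log-hazard per year). Model coefficient sets contain an `intercept`
#' (value at age 18 for the reference group: female, high education,
#' reference mediator categories), an `age` slope per year since 18, an
#' optional `age_group` named vector of per-bin log offsets (for
#' piecewise-constant ground truth), and one named vector per covariate.
#'
#' @param n_participants Cohort size (default 93,249, the study's analytic
#'   sample).
#' @param seed Integer seed making [generate_cohort()] deterministic.
#' @param prop_female Proportion female (default 0.589).
#' @param prop_low_education Proportion with low (10-year) education.
#' @param followup_years_mean,followup_years_sd Follow-up gap distribution;
#'   Normal, truncated to `[1, 8]` years.
#' @return A list of class `"generator_config"`.
#' @export
default_generator_config <- function(n_participants = 93249,
                                     seed = 1,
                                     prop_female = 0.589,
                                     prop_low_education = 0.5,
                                     followup_years_mean = 4.0,
                                     followup_years_sd = 1.0) {
  raw <- list(
    low = list(
      smoking = c(never = 37.5, former = 38.9, current = 23.7),
      alcohol = c(none = 23.3, moderate = 40.9, problematic = 35.8),
      diet = c(healthy = 8.5, moderate = 80.3, unhealthy = 11.3),
      health_literacy = c(low = 32.4, high = 67.6)
    ),
    high = list(
      smoking = c(never = 63.4, former = 24.8, current = 11.8),
      # the published high-education alcohol column sums to 111.8%;
      # renormalization below treats the values as relative weights
      alcohol = c(none = 11.8, moderate = 59.6, problematic = 40.4),
      diet = c(healthy = 13.0, moderate = 81.6, unhealthy = 5.4),
      health_literacy = c(low = 8.5, high = 91.5)
    )
  )
  dists <- lapply(raw, function(edu) lapply(edu, function(p) p / sum(p)))
  attr(dists, "raw_percent") <- raw

  config <- list(
    n_participants = n_participants,
    seed = seed,
    prop_female = prop_female,
    prop_low_education = prop_low_education,
    followup_years_mean = followup_years_mean,
    followup_years_sd = followup_years_sd,
    mediator_distributions = dists,
    # Logit scale; calibrated so overall baseline MetS prevalence is ~14%
    # and the at-risk split roughly matches the study (~86% MetS-free).
    baseline_prevalence_model = list(
      intercept = -4.3, age = 0.065,
      sex = c(female = 0, male = 0.35),
      education = c(high = 0, low = 0.45),
      smoking = c(never = 0, former = 0.15, current = 0.30),
      alcohol = c(none = 0, moderate = -0.05, problematic = 0.15),
      diet = c(healthy = 0, moderate = 0.15, unhealthy = 0.35),
      health_literacy = c(high = 0, low = 0.20)
    ),
    # Log hazard per year: incidence rises with age (~0.010/yr at 18 to
    # ~0.052/yr at 65 for the reference group).
    incidence_model = list(
      intercept = log(0.010), age = 0.035,
      sex = c(female = 0, male = 0.30),
      education = c(high = 0, low = 0.30),
      smoking = c(never = 0, former = 0.10, current = 0.35),
      alcohol = c(none = 0, moderate = -0.05, problematic = 0.20),
      diet = c(healthy = 0, moderate = 0.10, unhealthy = 0.30),
      health_literacy = c(high = 0, low = 0.15)
    ),
    # Recovery declines mildly with age (~0.20/yr at 18).
    recovery_model = list(
      intercept = log(0.20), age = -0.02,
      sex = c(female = 0, male = -0.10),
      education = c(high = 0, low = -0.20),
      smoking = c(never = 0, former = -0.05, current = -0.15),
      alcohol = c(none = 0, moderate = 0, problematic = -0.10),
      diet = c(healthy = 0, moderate = -0.05, unhealthy = -0.15),
      health_literacy = c(high = 0, low = -0.10)
    )
  )
  class(config) <- "generator_config"
  validate_generator_config(config)
  config
}

validate_generator_config <- function(config) {
  stopifnot(config$n_participants > 0)
  for (edu in EDU_LEVELS) {
    d <- config$mediator_distributions[[edu]]
    for (f in MEDIATORS) {
      p <- d[[f]]
      if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
        stop("mediator distribution for '", f, "' (", edu,
             " education) must be nonnegative and sum to 1")
      }
      if (!setequal(names(p), MEDIATOR_LEVELS[[f]])) {
        stop("categories of '", f, "' must be exactly: ",
             paste(MEDIATOR_LEVELS[[f]], collapse = ", "))
      }
    }
  }
  invisible(config)
}

# Linear predictor of a coefficient-set model for each cohort row.
# `age` enters as (age - 18); an optional `age_group` named vector adds a
# per-bin offset, enabling piecewise-constant ground truth.
linear_predictor <- function(model, data) {
  lp <- rep(model$intercept, nrow(data))
  if (!is.null(model$age) && model$age != 0) {
    lp <- lp + model$age * (data$age_t1 - AGE_MIN)
  }
  if (!is.null(model$age_group)) {
    lp <- lp + unname(model$age_group[as.character(age_group(data$age_t1))])
  }
  lp <- lp + unname(model$sex[data$sex])
  lp <- lp + unname(model$education[edu_level(data$edu_years)])
  for (f in MEDIATORS) {
    if (!is.null(model[[f]])) lp <- lp + unname(model[[f]][data[[f]]])
  }
  lp
}

#' Generate a synthetic two-wave cohort
#'
#' Draws `n_participants` individuals: sex and education Bernoulli; baseline
#' age Uniform(18, 61); follow-up gap Normal(mean, sd) truncated to
#' `[1, 8]` years; modifiable factors sampled per education level from the
#' configured distributions; baseline MetS status from the logistic
#' baseline-prevalence model; and wave-4 status from the exact two-state
#' transition probabilities under constant per-person hazards
#' \eqn{\lambda = e^{lp_{inc}}}, \eqn{\mu = e^{lp_{rec}}} over the
#' individual's follow-up interval:
#' \deqn{P(MetS_{t4} | healthy_{t1}) = \frac{\lambda}{\lambda+\mu}
#'   (1 - e^{-(\lambda+\mu)\Delta t})}
#' \deqn{P(MetS_{t4} | MetS_{t1}) = \frac{\lambda}{\lambda+\mu}
#'   + \frac{\mu}{\lambda+\mu} e^{-(\lambda+\mu)\Delta t}}
#' No discrete-time approximation is involved, so the generating hazards are
#' analytic ground truth for parameter-recovery tests.
#'
#' @param config A `generator_config`, e.g. [default_generator_config()].
#' @return A data.frame with columns `id`, `sex`, `edu_years`, `age_t1`,
#'   `age_t4`, `mets_t1`, `mets_t4` (logical), `smoking`, `alcohol`, `diet`,
#'   `health_literacy`.
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  n <- config$n_participants
  set.seed(config$seed)

  sex <- ifelse(runif(n) < config$prop_female, "female", "male")
  edu_years <- ifelse(runif(n) < config$prop_low_education, 10L, 16L)
  edu <- edu_level(edu_years)

  age_t1 <- runif(n, AGE_MIN, 61)
  # follow-up gap: Normal truncated to [1, 8] by inverse-CDF
  m <- config$followup_years_mean
  s <- config$followup_years_sd
  gap <- if (s > 0) {
    qnorm(runif(n, pnorm(1, m, s), pnorm(8, m, s)), m, s)
  } else {
    rep(min(max(m, 1), 8), n)
  }
  age_t4 <- age_t1 + gap

  data <- data.frame(
    id = seq_len(n), sex = sex, edu_years = edu_years,
    age_t1 = age_t1, age_t4 = age_t4,
    stringsAsFactors = FALSE
  )
  for (f in MEDIATORS) {
    lev <- MEDIATOR_LEVELS[[f]]
    col <- character(n)
    for (e in EDU_LEVELS) {
      idx <- edu == e
      p <- config$mediator_distributions[[e]][[f]][lev]
      col[idx] <- sample(lev, sum(idx), replace = TRUE, prob = p)
    }
    data[[f]] <- col
  }

  data$mets_t1 <- runif(n) <
    plogis(linear_predictor(config$baseline_prevalence_model, data))

  lambda <- exp(linear_predictor(config$incidence_model, data))
  mu <- exp(linear_predictor(config$recovery_model, data))
  data$mets_t4 <- runif(n) <
    two_state_prob(data$mets_t1, lambda, mu, gap)

  data
}

#' Exact two-state occupancy probability
#'
#' Probability of being in the MetS state after `dt` years under constant
#' incidence hazard `lambda` and recovery hazard `mu`, given the starting
#' state.
#'
#' @param start_mets Logical vector: starting state is MetS.
#' @param lambda,mu Nonnegative hazards (per year); vectors recycled.
#' @param dt Elapsed time (years).
#' @return Probability vector in `[0, 1]`.
#' @export
two_state_prob <- function(start_mets, lambda, mu, dt) {
  tot <- lambda + mu
  # equilibrium share; 0/0 (both hazards zero) resolved below
  pi_mets <- ifelse(tot > 0, lambda / tot, 0)
  decay <- exp(-tot * dt)
  ifelse(start_mets,
         pi_mets + (1 - pi_mets) * decay,
         pi_mets * (1 - decay))
}

#' Write / read a cohort CSV
#'
#' Columns: `id, sex, edu_years, age_t1, age_t4, mets_t1, mets_t4, smoking,
#' alcohol, diet, health_literacy`; categories as lowercase strings,
#' booleans as 0/1.
#'
#' @param cohort Cohort data.frame as from [generate_cohort()].
#' @param path File path.
#' @return `read_cohort` returns the cohort data.frame with logical
#'   `mets_t1`/`mets_t4`.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$mets_t1 <- as.integer(out$mets_t1)
  out$mets_t4 <- as.integer(out$mets_t4)
  atomic_write(path, function(tmp) {
    write.csv(out, tmp, row.names = FALSE, quote = FALSE)
  })
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "sex", "edu_years", "age_t1", "age_t4",
                "mets_t1", "mets_t4", MEDIATORS)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("cohort file ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  x$mets_t1 <- as.logical(x$mets_t1)
  x$mets_t4 <- as.logical(x$mets_t4)
  bad <- which(x$age_t4 <= x$age_t1)
  if (length(bad) > 0) {
    stop("cohort file ", path, ": age_t4 <= age_t1 at row ", bad[1])
  }
  x
}
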