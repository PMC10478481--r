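# Estimation of MetS prevalence at age 18 and annual incidence/recovery
# rates per 5-year age group, by sex x education, from two-wave cohort data.
#
# Age-group interval probabilities come from a per-stratum logistic model of
# the transition indicator on age-group indicators plus the four modifiable
# factors; the cell probability is the average predicted probability over
# the at-risk records of that cell (marginal standardization), which the
# counterfactual module reuses with distribution-ratio weights.

#' Estimate MetS prevalence at age 18
#'
#' Per sex-by-education stratum, fits a logistic regression of baseline MetS
#' status on baseline age (continuous) and returns the predicted probability
#' at age 18 with a delta-method standard error. If a stratum shows complete
#' separation (all baseline statuses identical), the Agresti-corrected
#' empirical proportion `(k + 0.5) / (n + 1)` is returned with a warning.
#'
#' @param cohort Two-wave cohort data.frame (see [generate_cohort()]).
#' @return data.frame with columns `sex`, `edu`, `probability`, `se`, `n`,
#'   `corrected`.
#' @export
estimate_prevalence_at_18 <- function(cohort) {
  cohort$edu <- edu_level(cohort$edu_years)
  out <- strata()
  out$probability <- NA_real_
  out$se <- NA_real_
  out$n <- NA_integer_
  out$corrected <- FALSE
  for (i in seq_len(nrow(out))) {
    d <- cohort[cohort$sex == out$sex[i] & cohort$edu == out$edu[i], ]
    if (nrow(d) == 0) stop("no participants in stratum ", out$sex[i], "/",
                           out$edu[i])
    out$n[i] <- nrow(d)
    k <- sum(d$mets_t1)
    if (k == 0 || k == nrow(d)) {
      p <- (k + 0.5) / (nrow(d) + 1)
      out$probability[i] <- p
      out$se[i] <- sqrt(p * (1 - p) / (nrow(d) + 1))
      out$corrected[i] <- TRUE
      warning("separation in baseline prevalence for stratum ",
              out$sex[i], "/", out$edu[i],
              "; Agresti-corrected proportion used")
      next
    }
    fit <- suppressWarnings(
      glm(mets_t1 ~ age_t1, family = binomial(), data = d)
    )
    x0 <- c(1, AGE_MIN)
    lp <- sum(coef(fit) * x0)
    se_lp <- sqrt(drop(t(x0) %*% vcov(fit) %*% x0))
    p <- plogis(lp)
    out$probability[i] <- p
    out$se[i] <- p * (1 - p) * se_lp
  }
  out
}

# At-risk subset and transition indicator for a kind of transition.
at_risk_subset <- function(cohort, kind) {
  kind <- match.arg(kind, c("incidence", "recovery"))
  cohort$edu <- edu_level(cohort$edu_years)
  if (kind == "incidence") {
    d <- cohort[!cohort$mets_t1, ]
    d$event <- d$mets_t4
  } else {
    d <- cohort[cohort$mets_t1, ]
    d$event <- !d$mets_t4
  }
  d$age_grp <- age_group(d$age_t1)
  d
}

# Per-stratum transition model: event ~ age-group indicators + the four
# modifiable factors (terms with < 2 observed levels are dropped).
fit_transition_model <- function(d) {
  d$age_grp <- droplevels(d$age_grp)
  terms <- character(0)
  if (nlevels(d$age_grp) >= 2) terms <- "age_grp"
  for (f in MEDIATORS) {
    if (length(unique(d[[f]])) >= 2) terms <- c(terms, f)
  }
  if (length(terms) == 0) terms <- "1"
  fit <- suppressWarnings(
    glm(as.formula(paste("event ~", paste(terms, collapse = " + "))),
        family = binomial(), data = d,
        control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  )
  list(fit = fit, data = d)
}

# Weighted marginally standardized probability and delta-method SE for the
# records in `idx` (rows of model$data).
standardized_probability <- function(model, idx, w = NULL) {
  d <- model$data[idx, , drop = FALSE]
  if (is.null(w)) w <- rep(1, nrow(d))
  p <- suppressWarnings(predict(model$fit, newdata = d, type = "response"))
  X <- model.matrix(delete.response(terms(model$fit)), data = d,
                    xlev = model$fit$xlevels)
  wsum <- sum(w)
  prob <- sum(w * p) / wsum
  grad <- drop(t(X) %*% (w * p * (1 - p))) / wsum
  V <- vcov(model$fit)
  se <- sqrt(max(0, drop(t(grad) %*% V %*% grad)))
  list(probability = prob, se = se)
}

#' Estimate age-group transition probabilities
#'
#' Within each stratum, fits a logistic regression of the transition
#' indicator (incidence: MetS at wave 4 among those MetS-free at baseline;
#' recovery: MetS-free at wave 4 among those with MetS at baseline) on
#' 5-year age-group indicators plus the four modifiable factors, and returns
#' per age group the marginally standardized probability — the average
#' predicted probability over that cell's at-risk records at their observed
#' covariates — with a delta-method SE and the cell's mean follow-up time.
#'
#' Cells with zero (or all) events get the Agresti-corrected proportion
#' `(k + 0.5) / (n + 1)` and `corrected = TRUE`; empty cells are returned
#' with `absent = TRUE` and are skipped by curve fitting.
#'
#' @param cohort Two-wave cohort data.frame.
#' @param kind `"incidence"` or `"recovery"`.
#' @return data.frame with columns `sex`, `edu`, `kind`, `age_group`,
#'   `age_lo`, `age_hi`, `probability`, `se`, `mean_followup`, `n_at_risk`,
#'   `n_events`, `corrected`, `absent`.
#' @export
estimate_interval_probabilities <- function(cohort, kind) {
  kind <- match.arg(kind, c("incidence", "recovery"))
  d_all <- at_risk_subset(cohort, kind)
  if (nrow(d_all) == 0) stop("no at-risk records for kind '", kind, "'")
  bins <- age_group_table()
  st <- strata()
  res <- list()
  for (i in seq_len(nrow(st))) {
    d <- d_all[d_all$sex == st$sex[i] & d_all$edu == st$edu[i], ]
    out <- cbind(
      data.frame(sex = st$sex[i], edu = st$edu[i], kind = kind,
                 stringsAsFactors = FALSE),
      bins[c("age_group", "age_lo", "age_hi")]
    )
    out$probability <- NA_real_
    out$se <- NA_real_
    out$mean_followup <- NA_real_
    out$n_at_risk <- 0L
    out$n_events <- 0L
    out$corrected <- FALSE
    out$absent <- TRUE
    if (nrow(d) > 0) {
      model <- fit_transition_model(d)
      for (g in seq_len(nrow(bins))) {
        idx <- which(as.character(d$age_grp) == bins$age_group[g])
        if (length(idx) == 0) next
        n <- length(idx)
        k <- sum(d$event[idx])
        out$n_at_risk[g] <- n
        out$n_events[g] <- k
        out$mean_followup[g] <- mean(d$age_t4[idx] - d$age_t1[idx])
        out$absent[g] <- FALSE
        if (k == 0 || k == n) {
          p <- (k + 0.5) / (n + 1)
          out$probability[g] <- p
          out$se[g] <- sqrt(p * (1 - p) / (n + 1))
          out$corrected[g] <- TRUE
        } else {
          sp <- standardized_probability(model, idx)
          out$probability[g] <- sp$probability
          out$se[g] <- sp$se
        }
      }
    }
    res[[i]] <- out
  }
  do.call(rbind, res)
}

#' Convert an interval probability to an annual rate
#'
#' Assumes a constant hazard within the interval, matching the continuous-
#' time engine: `rate = -log(1 - p) / dt`. The SE is propagated by the delta
#' method: `se_rate = se_p / ((1 - p) dt)`.
#'
#' @param probability Interval transition probability in `[0, 1)`.
#' @param mean_followup Interval length (years), > 0.
#' @param se Optional SE of the probability.
#' @return If `se` is `NULL`, the rate vector (per year); otherwise a list
#'   with `rate` and `se`.
#' @export
annualize <- function(probability, mean_followup, se = NULL) {
  if (any(!is.na(probability) & (probability < 0 | probability >= 1))) {
    stop("probability must lie in [0, 1)")
  }
  if (any(!is.na(mean_followup) & mean_followup <= 0)) {
    stop("mean_followup must be positive")
  }
  rate <- -log(1 - probability) / mean_followup
  if (is.null(se)) return(rate)
  list(rate = rate, se = se / ((1 - probability) * mean_followup))
}

#' Estimate annual age-group transition rates
#'
#' Runs [estimate_interval_probabilities()] and annualizes each cell with
#' its own mean follow-up, giving one `AgeGroupRate` row per stratum x
#' 5-year age group.
#'
#' @inheritParams estimate_interval_probabilities
#' @return data.frame with columns `sex`, `edu`, `kind`, `age_lo`, `age_hi`,
#'   `rate_per_year`, `se`, `n_at_risk`, plus estimation metadata
#'   (`probability`, `mean_followup`, `corrected`, `absent`).
#' @export
estimate_rates <- function(cohort, kind) {
  probs <- estimate_interval_probabilities(cohort, kind)
  rates_from_probabilities(probs)
}

rates_from_probabilities <- function(probs) {
  ok <- !probs$absent
  probs$rate_per_year <- NA_real_
  probs$rate_se <- NA_real_
  ann <- annualize(probs$probability[ok], probs$mean_followup[ok],
                   probs$se[ok])
  probs$rate_per_year[ok] <- ann$rate
  probs$rate_se[ok] <- ann$se
  out <- probs[c("sex", "edu", "kind", "age_group", "age_lo", "age_hi",
                 "rate_per_year", "probability", "mean_followup",
                 "n_at_risk", "n_events", "corrected", "absent")]
  out$se <- probs$rate_se
  out[c("sex", "edu", "kind", "age_group", "age_lo", "age_hi",
        "rate_per_year", "se", "probability", "mean_followup", "n_at_risk",
        "n_events", "corrected", "absent")]
}

#' Write / read an age-group rates CSV
#'
#' Schema: `sex, edu, kind, age_lo, age_hi, rate_per_year, se, n_at_risk`.
#' The same schema is the reader target for externally published
#' transition-rate tables, which can then be fed directly to
#' [fit_all_curves()] and the simulator.
#'
#' @param rates data.frame as from [estimate_rates()] (extra columns are
#'   dropped on write).
#' @param path File path.
#' @return `read_rates` returns a validated rates data.frame.
#' @export
write_rates <- function(rates, path) {
  out <- rates[c("sex", "edu", "kind", "age_lo", "age_hi",
                 "rate_per_year", "se", "n_at_risk")]
  atomic_write(path, function(tmp) {
    write.csv(out, tmp, row.names = FALSE, quote = FALSE)
  })
}

#' @rdname write_rates
#' @export
read_rates <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("sex", "edu", "kind", "age_lo", "age_hi", "rate_per_year",
                "se")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("rates file ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!(x$age_lo >= AGE_MIN & x$age_lo < x$age_hi &
                   x$age_hi <= AGE_MAX))
  if (length(bad) > 0) {
    stop("rates file ", path, ": invalid age bin at row ", bad[1])
  }
  bad <- which(!is.na(x$rate_per_year) & x$rate_per_year < 0)
  if (length(bad) > 0) {
    stop("rates file ", path, ": negative rate at row ", bad[1])
  }
  if (is.null(x$n_at_risk)) x$n_at_risk <- NA_integer_
  if (is.null(x$absent)) x$absent <- is.na(x$rate_per_year)
  x
}

#' @importFrom stats delete.response terms
NULL
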