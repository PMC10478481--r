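# Mediation ranking of the modifiable factors and counterfactual transition
# rates in which the low-education group receives the high-education
# distribution of selected factors, via distribution-ratio reweighting of
# the marginally standardized age-group probabilities.

#' Percentage of the education effect mediated by each factor
#'
#' Difference method: per factor, logistic regressions of the transition
#' indicator on education (low vs high) plus 5-year age group, fitted
#' without and with the factor; the mediated percentage is
#' `100 (b_without - b_with) / b_without`, where `b` is the low-education
#' log-odds coefficient. Negative values (inconsistent mediation) are
#' reported as-is.
#'
#' @param cohort Two-wave cohort data.frame containing both education
#'   groups.
#' @param kind `"incidence"` or `"recovery"`.
#' @param factors Factors to assess (default all four).
#' @return data.frame with columns `factor`, `mediated_percent`,
#'   `beta_without`, `beta_with`. `mediated_percent` is `NA` with a warning
#'   when the unadjusted education coefficient is ~0.
#' @export
mediation_percentages <- function(cohort, kind, factors = MEDIATORS) {
  factors <- match.arg(factors, MEDIATORS, several.ok = TRUE)
  d <- at_risk_subset(cohort, kind)
  if (length(unique(d$edu)) < 2) {
    stop("cohort must contain both education groups")
  }
  d$edu <- factor(d$edu, levels = c("high", "low"))
  d$age_grp <- droplevels(d$age_grp)
  base_fit <- suppressWarnings(
    glm(event ~ edu + age_grp, family = binomial(), data = d)
  )
  b0 <- coef(base_fit)[["edulow"]]
  out <- data.frame(factor = factors, mediated_percent = NA_real_,
                    beta_without = b0, beta_with = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(factors)) {
    f <- factors[i]
    fit <- suppressWarnings(
      glm(as.formula(paste("event ~ edu + age_grp +", f)),
          family = binomial(), data = d)
    )
    b1 <- coef(fit)[["edulow"]]
    out$beta_with[i] <- b1
    if (abs(b0) < 1e-6) {
      warning("education coefficient ~0 for kind '", kind,
              "'; mediated percentage undefined")
    } else {
      out$mediated_percent[i] <- 100 * (b0 - b1) / b0
    }
  }
  out
}

#' Rank the modifiable factors by mean mediated percentage
#'
#' Averages each factor's incidence and recovery mediated percentages and
#' sorts decreasingly.
#'
#' @param cohort Two-wave cohort data.frame.
#' @param factors Factors to rank.
#' @return data.frame with columns `factor`, `mediated_percent_incidence`,
#'   `mediated_percent_recovery`, `mean_mediated_percent`, ordered by the
#'   mean.
#' @export
rank_mediators <- function(cohort, factors = MEDIATORS) {
  inc <- mediation_percentages(cohort, "incidence", factors)
  rec <- mediation_percentages(cohort, "recovery", factors)
  out <- data.frame(
    factor = inc$factor,
    mediated_percent_incidence = inc$mediated_percent,
    mediated_percent_recovery = rec$mediated_percent,
    stringsAsFactors = FALSE
  )
  out$mean_mediated_percent <-
    rowMeans(out[c("mediated_percent_incidence",
                   "mediated_percent_recovery")])
  out[order(-out$mean_mediated_percent), , drop = FALSE]
}

# Distribution-ratio weights for the low-education at-risk records of one
# sex: w_i = prod over factors of P_high(category_i) / P_low(category_i).
# Marginals are computed on the at-risk sets (stratum-wide by default, or
# within each age cell).
counterfactual_weights <- function(d_low, d_high, factors) {
  w <- rep(1, nrow(d_low))
  for (f in factors) {
    p_low <- table(d_low[[f]]) / nrow(d_low)
    p_high <- table(d_high[[f]]) / nrow(d_high)
    cats <- names(p_low)[p_low > 0]
    missing_cat <- setdiff(cats, names(p_high)[p_high > 0])
    if (length(missing_cat) > 0) {
      stop("category '", missing_cat[1], "' of factor '", f,
           "' is absent from the high-education at-risk set")
    }
    ratio <- as.numeric(p_high[d_low[[f]]]) / as.numeric(p_low[d_low[[f]]])
    w <- w * ratio
  }
  w
}

#' Counterfactual transition rates for the low-education strata
#'
#' Marginal standardization by reweighting: each low-education at-risk
#' record receives the weight
#' \deqn{w = \prod_{f} P_{high}(category_f) / P_{low}(category_f)}
#' over the selected factors (the joint product when all four are
#' selected), and the counterfactual age-group probability is the weighted
#' mean of the fitted transition model's predicted probabilities at the
#' observed covariates. Probabilities are annualized exactly as in
#' [estimate_rates()]. High-education rates are unaffected by construction
#' and are not returned here.
#'
#' @param cohort Two-wave cohort data.frame.
#' @param factors Subset of `c("smoking", "alcohol", "diet",
#'   "health_literacy")`; all four give the joint effect.
#' @param kind `"incidence"` or `"recovery"`.
#' @param marginals `"stratum"` (default): factor marginals from the
#'   stratum-wide at-risk set; `"cell"`: per age-group cell.
#' @return data.frame of counterfactual age-group rates for the two
#'   low-education strata (same schema as [estimate_rates()]).
#' @export
counterfactual_rates <- function(cohort, factors, kind,
                                 marginals = c("stratum", "cell")) {
  factors <- match.arg(factors, MEDIATORS, several.ok = TRUE)
  marginals <- match.arg(marginals)
  kind <- match.arg(kind, c("incidence", "recovery"))
  d_all <- at_risk_subset(cohort, kind)
  bins <- age_group_table()
  res <- list()
  for (s in intersect(SEXES, unique(d_all$sex))) {
    d_low <- d_all[d_all$sex == s & d_all$edu == "low", ]
    d_high <- d_all[d_all$sex == s & d_all$edu == "high", ]
    if (nrow(d_low) == 0 || nrow(d_high) == 0) {
      stop("both education groups required for sex ", s)
    }
    model <- fit_transition_model(d_low)
    d_low <- model$data
    w_all <- if (marginals == "stratum") {
      counterfactual_weights(d_low, d_high, factors)
    } else {
      NULL
    }
    out <- cbind(
      data.frame(sex = s, edu = "low", kind = kind,
                 stringsAsFactors = FALSE),
      bins[c("age_group", "age_lo", "age_hi")]
    )
    out$probability <- NA_real_
    out$prob_se <- NA_real_
    out$mean_followup <- NA_real_
    out$n_at_risk <- 0L
    out$absent <- TRUE
    for (g in seq_len(nrow(bins))) {
      idx <- which(as.character(d_low$age_grp) == bins$age_group[g])
      if (length(idx) == 0) next
      hidx <- which(as.character(age_group(d_high$age_t1)) ==
                      bins$age_group[g])
      w <- if (marginals == "stratum") {
        w_all[idx]
      } else {
        if (length(hidx) == 0) {
          stop("no high-education at-risk records in age group ",
               bins$age_group[g], " for per-cell marginals")
        }
        counterfactual_weights(d_low[idx, , drop = FALSE],
                               d_high[hidx, , drop = FALSE], factors)
      }
      sp <- standardized_probability(model, idx, w = w)
      out$probability[g] <- sp$probability
      out$prob_se[g] <- sp$se
      out$mean_followup[g] <- mean(d_low$age_t4[idx] - d_low$age_t1[idx])
      out$n_at_risk[g] <- length(idx)
      out$absent[g] <- FALSE
    }
    ok <- !out$absent
    out$rate_per_year <- NA_real_
    out$se <- NA_real_
    ann <- annualize(out$probability[ok], out$mean_followup[ok],
                     out$prob_se[ok])
    out$rate_per_year[ok] <- ann$rate
    out$se[ok] <- ann$se
    res[[s]] <- out[c("sex", "edu", "kind", "age_group", "age_lo",
                      "age_hi", "rate_per_year", "se", "probability",
                      "mean_followup", "n_at_risk", "absent")]
  }
  do.call(rbind, res)
}

# Observed rates estimated through the same standardization path, so the
# identity counterfactual matches them exactly. The note: for the identity
# check, estimate_rates() and counterfactual_rates(weights = 1) coincide
# because both average the same fitted probabilities.

#' Run a counterfactual scenario end to end
#'
#' Estimates observed rates for all strata and counterfactual rates for the
#' low-education strata, refits the continuous-age curves (observed curves
#' for high education, counterfactual curves for low education), simulates
#' the four-stratum cohort, and summarizes. The observed scenario is
#' obtained with `factors = NULL`.
#'
#' @param cohort Two-wave cohort data.frame.
#' @param factors `NULL` for the observed scenario, otherwise the factor
#'   subset handed to [counterfactual_rates()].
#' @param n_per_group Simulated individuals per stratum.
#' @param seed Integer seed (shared across scenarios for common random
#'   numbers).
#' @param marginals Passed to [counterfactual_rates()].
#' @param bound Optional common hazard bound passed to [simulate_cohort()].
#' @param observed_rates,prev18 Optional precomputed observed rates (both
#'   kinds, `rbind`-ed) and baseline prevalences, to avoid re-estimation
#'   across scenarios.
#' @return List with `summary` (per-stratum summary data.frame), `rates`,
#'   `curves`, and `life_courses`.
#' @export
run_counterfactual_pipeline <- function(cohort, factors, n_per_group,
                                        seed,
                                        marginals = "stratum",
                                        bound = NULL,
                                        observed_rates = NULL,
                                        prev18 = NULL) {
  if (is.null(observed_rates)) {
    observed_rates <- rbind(estimate_rates(cohort, "incidence"),
                            estimate_rates(cohort, "recovery"))
  }
  if (is.null(prev18)) prev18 <- estimate_prevalence_at_18(cohort)
  rates <- observed_rates
  if (!is.null(factors)) {
    for (k in c("incidence", "recovery")) {
      cf <- counterfactual_rates(cohort, factors, k, marginals = marginals)
      keep <- !(rates$edu == "low" & rates$kind == k)
      cf_aligned <- cf[names(cf) %in% names(rates)]
      common <- intersect(names(rates), names(cf_aligned))
      rates <- rbind(rates[keep, common], cf_aligned[common])
    }
  }
  curves <- fit_all_curves(rates)
  lcs <- simulate_cohort(curves, prev18, n_per_group, seed, bound = bound)
  list(summary = summarize_by_stratum(lcs), rates = rates,
       curves = curves, life_courses = lcs)
}
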