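# Ensemble percentile confidence intervals: perturb the age-group rates
# (and baseline prevalences) with normal draws scaled by their standard
# errors, refit the continuous-age curves, re-simulate at reduced size, and
# take the 2.5/97.5 percentiles of each summary measure across repetitions.

#' Perturb a set of age-group rates
#'
#' Each non-absent rate is replaced by an independent draw from
#' `Normal(rate, se)` truncated below at 0 (hazards cannot be negative).
#' Zero SEs reproduce the estimates exactly. Uses R's active RNG stream;
#' seed with `set.seed()` for reproducibility.
#'
#' @param rates data.frame of age-group rates with columns `rate_per_year`
#'   and `se`.
#' @return The data.frame with perturbed `rate_per_year`.
#' @export
draw_rate_set <- function(rates) {
  ok <- !is.na(rates$rate_per_year) & !is.na(rates$se)
  rates$rate_per_year[ok] <- rtruncnorm_lower(
    sum(ok), rates$rate_per_year[ok], rates$se[ok], lower = 0
  )
  rates
}

# Baseline prevalences perturbed the same way, truncated to [0, 1].
draw_prevalence_set <- function(prev18) {
  p <- rtruncnorm_lower(nrow(prev18), prev18$probability, prev18$se,
                        lower = 0)
  prev18$probability <- pmin(p, 1)
  prev18
}

#' Ensemble confidence intervals for the life-course summaries
#'
#' Runs `n_reps` repetitions: draw a perturbed rate set (and baseline
#' prevalences), refit the curves, simulate `n_individuals_per_rep / 4`
#' life courses per stratum, and compute the three summary measures per
#' stratum. Returns the 2.5 and 97.5 percentiles across repetitions
#' (linear interpolation between order statistics, `quantile` type 6, so
#' two repetitions give min and max), alongside the point estimates from a
#' main run at `n_main_per_group` with the unperturbed rates. A repetition
#' whose curve fit fails is redrawn once, then skipped and counted in
#' `attr(, "n_failed")`.
#'
#' @param rates Age-group rates for all strata, both kinds (`rbind` of the
#'   two [estimate_rates()] results), with `se`.
#' @param prev18 Baseline prevalences from [estimate_prevalence_at_18()].
#' @param n_reps Number of repetitions (the reference analysis uses 1000).
#' @param n_individuals_per_rep Total individuals per repetition, divisible
#'   by 4 (reference: 50,000, i.e. 12,500 per group).
#' @param n_main_per_group Group size of the main run supplying the point
#'   estimates (reference: 125,000).
#' @param seed Integer seed; repetitions get derived sub-seeds.
#' @return data.frame with columns `sex`, `edu`, `measure`, `point`,
#'   `lower`, `upper`; number of skipped repetitions in
#'   `attr(, "n_failed")`.
#' @export
run_ensemble <- function(rates, prev18, n_reps = 1000,
                         n_individuals_per_rep = 50000,
                         n_main_per_group = 125000, seed = 1) {
  stopifnot(n_reps >= 2, n_individuals_per_rep %% 4 == 0)
  n_grp <- n_individuals_per_rep / 4

  main_curves <- fit_all_curves(rates)
  main_lcs <- simulate_cohort(main_curves, prev18, n_main_per_group,
                              derive_seed(seed, "main"))
  main <- summarize_by_stratum(main_lcs)

  measures <- c("life_course_prevalence", "mean_age_onset", "mean_duration")
  reps <- vector("list", n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    summ <- NULL
    for (attempt in 1:2) {
      set.seed(derive_seed(seed, "draw", r, attempt))
      rates_r <- draw_rate_set(rates)
      prev_r <- draw_prevalence_set(prev18)
      curves_r <- tryCatch(fit_all_curves(rates_r), error = function(e) NULL)
      if (is.null(curves_r)) next
      lcs_r <- simulate_cohort(curves_r, prev_r, n_grp,
                               derive_seed(seed, "sim", r))
      summ <- summarize_by_stratum(lcs_r)
      break
    }
    if (is.null(summ)) {
      n_failed <- n_failed + 1L
      next
    }
    reps[[r]] <- summ
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  if (length(reps) < 2) stop("fewer than 2 successful repetitions")

  st <- strata()
  out <- list()
  for (i in seq_len(nrow(st))) {
    for (m in measures) {
      vals <- vapply(reps, function(x) {
        x[[m]][x$sex == st$sex[i] & x$edu == st$edu[i]]
      }, numeric(1))
      vals <- vals[!is.na(vals)]
      qs <- quantile(vals, c(0.025, 0.975), type = 6, names = FALSE)
      out[[length(out) + 1]] <- data.frame(
        sex = st$sex[i], edu = st$edu[i], measure = m,
        point = main[[m]][main$sex == st$sex[i] & main$edu == st$edu[i]],
        lower = qs[1], upper = qs[2],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  attr(out, "n_failed") <- n_failed
  out
}
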