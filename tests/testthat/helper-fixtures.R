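# Shared fixtures: toy life courses, hand-built cohorts, and generator
# configs with analytically known ground truth.

# Build one individual's episode table from alternating states and start
# ages (first start must be 18; episodes end at the next start, last at 65).
toy_lc <- function(id, states, starts, sex = "female", edu = "low") {
  data.table::data.table(
    id = id, sex = sex, edu = edu, state = states, start_age = starts,
    end_age = c(starts[-1], 65)
  )
}

# A generator config whose transition models depend only on education:
# constant hazards lam_low / lam_high (incidence) and mu (recovery), fixed
# 4-year follow-up, baseline prevalence p0 (age-independent).
edu_only_config <- function(n, seed, lam_low = 0.04, lam_high = 0.02,
                            mu = 0, p0 = 0) {
  cfg <- default_generator_config(n_participants = n, seed = seed,
                                  followup_years_sd = 0)
  zero <- function(model) {
    model$age <- 0
    for (f in c("sex", "education", "smoking", "alcohol", "diet",
                "health_literacy")) {
      model[[f]][] <- 0
    }
    model
  }
  base <- zero(cfg$baseline_prevalence_model)
  base$intercept <- if (p0 > 0) qlogis(p0) else -Inf
  inc <- zero(cfg$incidence_model)
  inc$intercept <- if (lam_high > 0) log(lam_high) else -Inf
  if (lam_high > 0) inc$education <- c(high = 0, low = log(lam_low / lam_high))
  rec <- zero(cfg$recovery_model)
  rec$intercept <- if (mu > 0) log(mu) else -Inf
  cfg$baseline_prevalence_model <- base
  cfg$incidence_model <- inc
  cfg$recovery_model <- rec
  cfg
}

# Valid single-row component set, all values below every threshold (female
# and male), no medication.
below_threshold_components <- function() {
  data.frame(
    waist_cm = 80, sbp_mmHg = 115, dbp_mmHg = 75,
    triglycerides_mmol_l = 1.0, hdl_mmol_l = 1.6, glucose_mmol_l = 4.8,
    bp_medication = FALSE, lipid_medication = FALSE,
    triglyceride_medication = FALSE, glucose_medication = FALSE,
    t2d_diagnosis = FALSE
  )
}

# Component values realizing an exact on/off pattern of the five criteria.
components_for_pattern <- function(pattern, sex) {
  male <- sex == "male"
  data.frame(
    waist_cm = if (pattern[1]) (if (male) 105 else 92) else 80,
    sbp_mmHg = if (pattern[2]) 135 else 118,
    dbp_mmHg = 78,
    triglycerides_mmol_l = if (pattern[3]) 2.1 else 1.1,
    hdl_mmol_l = if (pattern[4]) (if (male) 0.85 else 1.15) else
      (if (male) 1.4 else 1.6),
    glucose_mmol_l = if (pattern[5]) 6.2 else 4.9,
    bp_medication = FALSE, lipid_medication = FALSE,
    triglyceride_medication = FALSE, glucose_medication = FALSE,
    t2d_diagnosis = FALSE
  )
}

# Small hand-built two-wave cohort covering all four strata, mediators
# constant; ages spread over several bins.
tiny_cohort <- function(n_per_stratum = 60, seed = 42) {
  set.seed(seed)
  st <- strata()
  rows <- list()
  for (i in seq_len(nrow(st))) {
    rows[[i]] <- data.frame(
      id = seq_len(n_per_stratum) + (i - 1) * n_per_stratum,
      sex = st$sex[i],
      edu_years = if (st$edu[i] == "low") 10L else 16L,
      age_t1 = runif(n_per_stratum, 18, 60),
      smoking = "never", alcohol = "none", diet = "healthy",
      health_literacy = "high",
      mets_t1 = FALSE,
      mets_t4 = runif(n_per_stratum) < 0.2,
      stringsAsFactors = FALSE
    )
    rows[[i]]$age_t4 <- rows[[i]]$age_t1 + 4
  }
  do.call(rbind, rows)
}
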