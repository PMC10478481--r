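# NCEP-ATPIII classification of metabolic syndrome from component
# measurements, and a component generator for tests and demo data.

#' Classify metabolic syndrome from NCEP-ATPIII components
#'
#' MetS is present when at least three of the five NCEP-ATPIII criteria
#' are met: (1) waist circumference of 102 cm or more (male) / 88 cm or
#' more (female); (2) systolic BP of 130 mmHg or more, diastolic BP of
#' 85 mmHg or more, or use of blood-pressure-lowering medication;
#' (3) triglycerides of 1.7 mmol/L or more, or triglyceride medication;
#' (4) HDL cholesterol below 1.0 mmol/L (male) / 1.3 mmol/L (female), or
#' lipid-lowering medication; (5) fasting glucose of 5.6 mmol/L or more, a
#' type-2-diabetes diagnosis, or glucose-lowering medication.
#'
#' @param components A data.frame (or list of equal-length vectors) with
#'   numeric columns `waist_cm`, `sbp_mmHg`, `dbp_mmHg`,
#'   `triglycerides_mmol_l`, `hdl_mmol_l`, `glucose_mmol_l` and logical
#'   columns `bp_medication`, `lipid_medication`, `triglyceride_medication`,
#'   `glucose_medication`, `t2d_diagnosis`. All continuous values must be
#'   strictly positive and finite.
#' @param sex Character vector, `"female"` or `"male"`, recycled to the
#'   number of rows.
#' @return Logical vector: `TRUE` where >= 3 criteria are met.
#' @examples
#' classify_mets(data.frame(
#'   waist_cm = 105, sbp_mmHg = 135, dbp_mmHg = 80,
#'   triglycerides_mmol_l = 1.2, hdl_mmol_l = 1.2, glucose_mmol_l = 5.8,
#'   bp_medication = FALSE, lipid_medication = FALSE,
#'   triglyceride_medication = FALSE, glucose_medication = FALSE,
#'   t2d_diagnosis = FALSE
#' ), sex = "male")
#' @export
classify_mets <- function(components, sex) {
  x <- as.data.frame(components, stringsAsFactors = FALSE)
  num_fields <- c("waist_cm", "sbp_mmHg", "dbp_mmHg",
                  "triglycerides_mmol_l", "hdl_mmol_l", "glucose_mmol_l")
  bool_fields <- c("bp_medication", "lipid_medication",
                   "triglyceride_medication", "glucose_medication",
                   "t2d_diagnosis")
  missing_cols <- setdiff(c(num_fields, bool_fields), names(x))
  if (length(missing_cols) > 0) {
    stop("missing component fields: ", paste(missing_cols, collapse = ", "))
  }
  for (f in num_fields) {
    v <- x[[f]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("component '", f, "' must be strictly positive and finite")
    }
  }
  sex <- rep_len(match.arg(sex, SEXES, several.ok = TRUE), nrow(x))
  male <- sex == "male"

  crit <- mets_criteria(x, male)
  rowSums(crit) >= 3
}

# The five criterion indicators as a logical matrix (one column each).
mets_criteria <- function(x, male) {
  cbind(
    waist = x$waist_cm >= ifelse(male, 102, 88),
    bp = x$sbp_mmHg >= 130 | x$dbp_mmHg >= 85 | x$bp_medication,
    tg = x$triglycerides_mmol_l >= 1.7 | x$triglyceride_medication,
    hdl = x$hdl_mmol_l < ifelse(male, 1.0, 1.3) | x$lipid_medication,
    glucose = x$glucose_mmol_l >= 5.6 | x$t2d_diagnosis | x$glucose_medication
  )
}

#' Generate component measurements with a prescribed MetS status
#'
#' Draws a plausible set of NCEP-ATPIII component values such that
#' [classify_mets()] returns exactly `target_mets`: the number of criteria
#' met is sampled from 3-5 when the target is `TRUE` and 0-2 otherwise, and
#' each selected criterion is satisfied (or failed) through its measurement
#' value. Medication and diagnosis indicators are left `FALSE`.
#'
#' @param target_mets Logical scalar, the desired classification.
#' @param sex `"female"` or `"male"`.
#' @param n Number of component sets to draw.
#' @return A data.frame of `n` component rows (see [classify_mets()]).
#' @export
generate_components <- function(target_mets, sex, n = 1) {
  stopifnot(is.logical(target_mets), length(target_mets) == 1)
  sex <- match.arg(sex, SEXES)
  male <- sex == "male"
  waist_thr <- if (male) 102 else 88
  hdl_thr <- if (male) 1.0 else 1.3

  k <- if (target_mets) sample(3:5, n, replace = TRUE) else
    sample(0:2, n, replace = TRUE)
  met <- matrix(FALSE, n, 5)
  for (i in seq_len(n)) {
    if (k[i] > 0) met[i, sample(5, k[i])] <- TRUE
  }
  between <- function(ind, lo_met, hi_met, lo_not, hi_not) {
    ifelse(ind, runif(n, lo_met, hi_met), runif(n, lo_not, hi_not))
  }
  data.frame(
    waist_cm = between(met[, 1], waist_thr, waist_thr + 30, 65, waist_thr - 1),
    sbp_mmHg = between(met[, 2], 130, 180, 95, 128),
    dbp_mmHg = runif(n, 60, 84),
    triglycerides_mmol_l = between(met[, 3], 1.7, 4.5, 0.5, 1.65),
    hdl_mmol_l = between(met[, 4], 0.5, hdl_thr - 0.02,
                         hdl_thr + 0.02, 2.6),
    glucose_mmol_l = between(met[, 5], 5.6, 9.5, 3.9, 5.55),
    bp_medication = FALSE, lipid_medication = FALSE,
    triglyceride_medication = FALSE, glucose_medication = FALSE,
    t2d_diagnosis = FALSE
  )
}
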