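# Shared constants and small helpers.

# Simulation age window (years). Life courses run from AGE_MIN to AGE_MAX.
AGE_MIN <- 18
AGE_MAX <- 65
AGE_SPAN <- AGE_MAX - AGE_MIN # 47 years

# 5-year age bins over [18, 65). 47 is not divisible by 5; the 2-year
# remainder forms the first bin [18, 20).
AGE_BREAKS <- c(18, 20, seq(25, 65, by = 5))

SEXES <- c("female", "male")
EDU_LEVELS <- c("low", "high")
MEDIATORS <- c("smoking", "alcohol", "diet", "health_literacy")

MEDIATOR_LEVELS <- list(
  smoking = c("never", "former", "current"),
  alcohol = c("none", "moderate", "problematic"),
  diet = c("healthy", "moderate", "unhealthy"),
  health_literacy = c("low", "high")
)

#' The four sex-by-education strata
#'
#' @return A data.frame with columns `sex` and `edu` enumerating the four
#'   simulation groups (female/male crossed with low/high education).
#' @export
strata <- function() {
  out <- expand.grid(
    sex = SEXES, edu = EDU_LEVELS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out[order(out$sex, out$edu), , drop = FALSE]
}

stratum_key <- function(sex, edu) paste(sex, edu, sep = ".")

# Map years of education to the low/high dichotomy (10 vs 16 years).
edu_level <- function(edu_years) {
  ifelse(edu_years <= 12, "low", "high")
}

#' Assign ages to 5-year age groups
#'
#' Bins are half-open `[lo, hi)`: `[18,20), [20,25), ..., [60,65)`.
#'
#' @param age Numeric vector of ages in `[18, 65)`.
#' @return Factor with one level per bin, labelled `"[lo,hi)"`.
#' @export
age_group <- function(age) {
  stopifnot(all(age >= AGE_MIN & age < AGE_MAX))
  cut(age, breaks = AGE_BREAKS, right = FALSE,
      labels = age_group_labels())
}

age_group_labels <- function() {
  lo <- AGE_BREAKS[-length(AGE_BREAKS)]
  hi <- AGE_BREAKS[-1]
  sprintf("[%d,%d)", lo, hi)
}

age_group_table <- function() {
  lo <- AGE_BREAKS[-length(AGE_BREAKS)]
  hi <- AGE_BREAKS[-1]
  data.frame(
    age_group = age_group_labels(),
    age_lo = lo, age_hi = hi,
    midpoint = (lo + hi) / 2,
    stringsAsFactors = FALSE
  )
}

#' Round half away from zero
#'
#' Decimal rounding as used for reported one-decimal summaries: ties go away
#' from zero (so 27.55 -> 27.6), unlike [base::round()]'s banker's rounding.
#' Computed on the integer tenths scale to avoid binary-float tie artefacts.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
round_half_away <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Truncated-normal draw (lower bound only), via inverse CDF; sd = 0 returns
# the mean. Used for rate perturbation (hazards cannot be negative).
rtruncnorm_lower <- function(n, mean, sd, lower = 0) {
  out <- numeric(n)
  zero_sd <- sd <= 0
  out[zero_sd] <- pmax(mean[zero_sd], lower)
  if (any(!zero_sd)) {
    m <- mean[!zero_sd]
    s <- sd[!zero_sd]
    p_lo <- pnorm(lower, m, s)
    u <- runif(sum(!zero_sd), p_lo, 1)
    out[!zero_sd] <- qnorm(u, m, s)
  }
  pmax(out, lower) # guard against qnorm(1-eps) edge cases
}

# Derive a child seed (31-bit, strictly positive) from a master seed and a
# stream label, so pipeline stages and ensemble reps get stable independent
# seeds from one user-facing seed.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483647
  as.integer(h) + 1L
}

# Atomic write: write to a temp file in the same directory, then rename.
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
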