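# Life-course summary measures and the short-episode sensitivity transform.
# All operations take the long-format episode table produced by the engine
# (possibly containing several strata; the per-population functions ignore
# the stratum columns).

#' Life-course prevalence
#'
#' Fraction of individuals whose episode list contains at least one MetS
#' episode, including those who start at 18 with MetS.
#'
#' @param lcs Life-course episode table (long format).
#' @return Proportion in `[0, 1]`.
#' @export
life_course_prevalence <- function(lcs) {
  lcs <- data.table::as.data.table(lcs)
  if (nrow(lcs) == 0) stop("empty life-course table")
  ever <- lcs[, .(mets = any(state == "mets")), by = id]
  mean(ever$mets)
}

#' Mean age of MetS onset
#'
#' Mean starting age of the first MetS episode over eligible individuals:
#' those whose first episode is healthy and who have at least one MetS
#' episode. Individuals entering the simulation with MetS and those never
#' developing it are excluded.
#'
#' @param lcs Life-course episode table.
#' @return Years, or `NA` (with a warning) if no individual is eligible.
#' @export
mean_age_of_onset <- function(lcs) {
  lcs <- data.table::as.data.table(lcs)
  if (nrow(lcs) == 0) stop("empty life-course table")
  per <- lcs[order(start_age), .(
    starts_healthy = state[1] == "healthy",
    onset = if (any(state == "mets")) min(start_age[state == "mets"])
            else NA_real_
  ), by = id]
  eligible <- per[per$starts_healthy & !is.na(per$onset)]
  if (nrow(eligible) == 0) {
    warning("no individuals eligible for age of onset")
    return(NA_real_)
  }
  mean(eligible$onset)
}

#' Mean duration of MetS
#'
#' Mean total years spent in the MetS state among individuals who ever
#' have MetS (truncation at age 65 included; never-MetS individuals are
#' excluded from the denominator).
#'
#' @param lcs Life-course episode table.
#' @return Years, or `NA` if no individual ever has MetS.
#' @export
mean_duration <- function(lcs) {
  lcs <- data.table::as.data.table(lcs)
  if (nrow(lcs) == 0) stop("empty life-course table")
  per <- lcs[, .(dur = sum((end_age - start_age)[state == "mets"])),
             by = id]
  experienced <- per$dur[per$dur > 0]
  # an individual with a zero-length mets episode cannot occur (strictly
  # increasing start ages), so dur > 0 identifies experiencers
  if (length(experienced) == 0) return(NA_real_)
  mean(experienced)
}

#' Age-specific point prevalence
#'
#' At each grid age, the fraction of individuals whose covering episode
#' (episodes are half-open `[start_age, end_age)`) is a MetS episode.
#'
#' @param lcs Life-course episode table.
#' @param grid Ages in `[18, 65)`.
#' @return data.frame with columns `age` and `prevalence`.
#' @export
age_specific_prevalence <- function(lcs, grid = seq(AGE_MIN, 64, by = 1)) {
  lcs <- data.table::as.data.table(lcs)
  stopifnot(all(grid >= AGE_MIN & grid < AGE_MAX))
  n_ids <- data.table::uniqueN(lcs$id)
  mets_eps <- lcs[state == "mets"]
  prev <- vapply(grid, function(g) {
    sum(mets_eps$start_age <= g & mets_eps$end_age > g) / n_ids
  }, numeric(1))
  data.frame(age = grid, prevalence = prev)
}

#' Summary statistics per stratum
#'
#' Computes the three life-course summary measures (and optionally the
#' age-prevalence curve) for each sex-by-education stratum present.
#'
#' @param lcs Life-course episode table with `sex` and `edu` columns.
#' @param grid Optional age grid for the age-prevalence curve (`NULL` to
#'   skip).
#' @return data.frame with columns `sex`, `edu`, `n`,
#'   `life_course_prevalence`, `mean_age_onset`, `mean_duration`; the
#'   age-prevalence curves (if requested) in `attr(, "age_prevalence")`.
#' @export
summarize_by_stratum <- function(lcs, grid = NULL) {
  lcs <- data.table::as.data.table(lcs)
  st <- unique(lcs[, .(sex, edu)])
  data.table::setorder(st, sex, edu)
  rows <- list()
  curves <- list()
  for (i in seq_len(nrow(st))) {
    d <- lcs[sex == st$sex[i] & edu == st$edu[i]]
    rows[[i]] <- data.frame(
      sex = st$sex[i], edu = st$edu[i],
      n = data.table::uniqueN(d$id),
      life_course_prevalence = life_course_prevalence(d),
      mean_age_onset = suppressWarnings(mean_age_of_onset(d)),
      mean_duration = mean_duration(d),
      stringsAsFactors = FALSE
    )
    if (!is.null(grid)) {
      curves[[stratum_key(st$sex[i], st$edu[i])]] <-
        age_specific_prevalence(d, grid)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(grid)) attr(out, "age_prevalence") <- curves
  out
}

# Merge one individual's episodes: indices of "valid" episodes (duration >=
# min_duration); every short episode takes the state of the nearest
# preceding valid episode (leading shorts take the first following valid
# one); adjacent same-state episodes are then coalesced.
merge_one <- function(states, starts, ends, min_duration) {
  dur <- ends - starts
  valid <- which(dur >= min_duration)
  if (length(valid) == 0) {
    occ <- tapply(dur, states, sum)
    winner <- names(occ)[which.max(occ)]
    return(list(states = winner, starts = starts[1], ends = ends[length(ends)],
                degenerate = TRUE))
  }
  idx <- findInterval(seq_along(states), valid)
  idx[idx == 0] <- 1 # leading short episodes absorb forward
  new_states <- states[valid[idx]]
  keep <- c(TRUE, new_states[-1] != new_states[-length(new_states)])
  list(states = new_states[keep], starts = starts[keep],
       ends = c(starts[keep][-1], ends[length(ends)]), degenerate = FALSE)
}

#' Reassign episodes shorter than a minimum duration
#'
#' Sensitivity transform for transient threshold crossings: scanning from
#' age 18, every episode shorter than `min_duration` is absorbed into the
#' nearest preceding episode lasting at least `min_duration` (leading short
#' episodes are absorbed into the first such episode that follows), and
#' adjacent same-state episodes are coalesced. Total duration (47 years)
#' is conserved and the result is idempotent. If an individual has no
#' episode of sufficient duration, their whole life course becomes a single
#' episode of the state with the largest total occupancy (with a warning).
#'
#' @param lcs Life-course episode table.
#' @param min_duration Minimum episode duration in years (default 0.5, the
#'   6-month rule); 0 returns the input unchanged.
#' @return Episode table of the same format.
#' @export
merge_short_episodes <- function(lcs, min_duration = 0.5) {
  lcs <- data.table::as.data.table(lcs)
  if (min_duration <= 0) return(data.table::copy(lcs))
  n_degenerate <- 0L
  out <- lcs[order(start_age), {
    m <- merge_one(state, start_age, end_age, min_duration)
    if (m$degenerate) n_degenerate <<- n_degenerate + 1L
    list(sex = sex[1], edu = edu[1], state = m$states,
         start_age = m$starts, end_age = m$ends)
  }, by = id]
  if (n_degenerate > 0) {
    warning(n_degenerate, " individual(s) had no episode of duration >= ",
            min_duration, "; collapsed to the longest-occupancy state")
  }
  data.table::setcolorder(out, c("id", "sex", "edu", "state", "start_age",
                                 "end_age"))
  out[]
}
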