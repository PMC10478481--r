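# R interface to the continuous-time event engine. Life courses are kept in
# a long-format data.table (id, sex, edu, state, start_age, end_age): one
# row per episode, episodes half-open [start_age, end_age), first episode
# starting at age 18 and the last ending at exactly 65.

curve_to_engine <- function(curve) {
  stopifnot(inherits(curve, "rate_curve"))
  if (curve$form == "poly4") {
    list(form = 0L, params = as.numeric(curve$params))
  } else {
    list(form = 1L, params = c(as.numeric(curve$params), 0, 0))
  }
}

#' Upper bound of the total hazard of a curve pair
#'
#' Maximum of incidence + recovery hazard over `[18, 65]` on a 0.01-year
#' grid, times a 1.001 safety factor. This is the proposal rate the engine
#' thins against; supplying a common bound to two simulations couples them
#' pathwise under common random numbers.
#'
#' @param incidence,recovery `rate_curve` objects.
#' @return Scalar bound (per year).
#' @export
hazard_bound <- function(incidence, recovery) {
  ic <- curve_to_engine(incidence)
  rc <- curve_to_engine(recovery)
  hazard_bound_cpp(ic$form, ic$params, rc$form, rc$params, AGE_MIN, AGE_MAX)
}

#' Simulate life courses for one stratum
#'
#' Each individual starts at age 18 in the MetS state with probability
#' `init_prob`, then transitions between healthy and MetS following a
#' continuous-time Markov process with age-dependent hazards given by the
#' curves, truncated at age 65; mortality is not modelled. Event times are
#' sampled exactly by thinning/uniformization against a global bound of the
#' total hazard. Randomness comes from counter-based per-individual streams
#' keyed by `(seed, id_offset + i)`, so results for an individual do not
#' depend on how many others are simulated.
#'
#' @param n Number of individuals.
#' @param incidence,recovery `rate_curve` objects evaluable on `[18, 65]`.
#' @param init_prob Probability of starting in the MetS state at age 18.
#' @param seed Integer seed.
#' @param sex,edu Stratum labels attached to the output.
#' @param id_offset Added to the within-group index to form global ids.
#' @param bound Optional hazard bound; defaults to the curves' own
#'   [hazard_bound()]. Must be >= the maximum total hazard.
#' @return data.table with columns `id`, `sex`, `edu`, `state`
#'   (`"healthy"`/`"mets"`), `start_age`, `end_age`.
#' @export
simulate_group <- function(n, incidence, recovery, init_prob, seed,
                           sex = NA_character_, edu = NA_character_,
                           id_offset = 0, bound = NULL) {
  stopifnot(n > 0, init_prob >= 0, init_prob <= 1)
  ic <- curve_to_engine(incidence)
  rc <- curve_to_engine(recovery)
  raw <- simulate_group_cpp(as.integer(n), ic$form, ic$params, rc$form,
                            rc$params, init_prob, as.numeric(seed),
                            as.numeric(id_offset),
                            if (is.null(bound)) -1 else as.numeric(bound))
  dt <- data.table::data.table(
    id = raw$id + as.numeric(id_offset),
    sex = sex, edu = edu,
    state = ifelse(raw$state == 1L, "mets", "healthy"),
    start_age = raw$start_age
  )
  dt[, end_age := data.table::shift(start_age, type = "lead",
                                    fill = AGE_MAX), by = id]
  dt[]
}

#' Simulate the full four-stratum cohort
#'
#' Runs [simulate_group()] for each sex-by-education stratum with
#' stratum-specific curves and initial prevalence, equal group sizes, and
#' id blocks `(stratum index - 1) * n_per_group + 1..n_per_group`.
#' Reproducible given `seed`.
#'
#' @param curves Nested curve list (`curves[[sex]][[edu]]$incidence` /
#'   `$recovery`), as from [fit_all_curves()] or [read_curves()].
#' @param init_prob data.frame with columns `sex`, `edu`, `probability`
#'   (as from [estimate_prevalence_at_18()]).
#' @param n_per_group Individuals per stratum.
#' @param seed Integer seed.
#' @param bound Optional common hazard bound applied to every stratum.
#' @return data.table of episodes for all `4 * n_per_group` individuals.
#' @export
simulate_cohort <- function(curves, init_prob, n_per_group, seed,
                            bound = NULL) {
  stopifnot(n_per_group > 0)
  st <- strata()
  out <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    s <- st$sex[i]
    e <- st$edu[i]
    cv <- curves[[s]][[e]]
    if (is.null(cv$incidence) || is.null(cv$recovery)) {
      stop("curves missing for stratum ", s, "/", e)
    }
    p0 <- init_prob$probability[init_prob$sex == s & init_prob$edu == e]
    if (length(p0) != 1 || is.na(p0)) {
      stop("initial prevalence missing for stratum ", s, "/", e)
    }
    out[[i]] <- simulate_group(
      n_per_group, cv$incidence, cv$recovery, p0, seed,
      sex = s, edu = e, id_offset = (i - 1) * n_per_group, bound = bound
    )
  }
  data.table::rbindlist(out)
}

#' Simulate a single life course
#'
#' Convenience wrapper around [simulate_group()] for one individual.
#'
#' @inheritParams simulate_group
#' @param individual_id Global id selecting the individual's random stream.
#' @return data.table with this individual's episodes.
#' @export
simulate_individual <- function(incidence, recovery, init_prob, seed,
                                individual_id = 1, sex = NA_character_,
                                edu = NA_character_) {
  simulate_group(1, incidence, recovery, init_prob, seed, sex = sex,
                 edu = edu, id_offset = individual_id - 1)
}

#' Write / read life courses as CSV
#'
#' Long format: `id, sex, edu, state, start_age, end_age`, one row per
#' episode.
#'
#' @param lcs Life-course data.table.
#' @param path File path.
#' @return `read_life_courses` returns the validated data.table.
#' @export
write_life_courses <- function(lcs, path) {
  atomic_write(path, function(tmp) {
    data.table::fwrite(lcs, tmp)
  })
}

#' @rdname write_life_courses
#' @export
read_life_courses <- function(path) {
  x <- data.table::fread(path)
  required <- c("id", "sex", "edu", "state", "start_age", "end_age")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("life-course file ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  validate_life_courses(x)
  x
}

# Check the LifeCourse invariants: first episode starts at 18, starts
# strictly increasing, states alternate, total duration 47 per individual.
validate_life_courses <- function(lcs) {
  lcs <- data.table::as.data.table(lcs)
  chk <- lcs[, .(
    first18 = abs(start_age[1] - AGE_MIN) < 1e-9,
    increasing = all(diff(start_age) > 0) || .N == 1,
    alternating = .N == 1 || all(state[-1] != state[-.N]),
    total47 = abs(sum(end_age - start_age) - AGE_SPAN) < 1e-9
  ), by = id]
  bad <- chk[!(first18 & increasing & alternating & total47)]
  if (nrow(bad) > 0) {
    stop("life-course invariants violated for id ", bad$id[1])
  }
  invisible(TRUE)
}
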