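# Analytic oracle: solves the two-state Kolmogorov forward equations for
# the age-dependent model, providing ground truth against which the
# stochastic engine and the summary statistics are validated.
#
#   dP/da   = lambda(a) (1 - P) - mu(a) P     point prevalence
#   dS/da   = -lambda(a) S                    probability never in MetS
#   dOcc/da = P                               expected years with MetS
#   onset density f(a) = lambda(a) S(a)
#
# with P(18) = p0 and S(18) = 1 - p0.

oracle_rhs <- function(a, y, parms) {
  a <- min(max(a, AGE_MIN), AGE_MAX) # integrator may probe fractionally outside
  lam <- evaluate_curve(parms$incidence, a)
  mu <- evaluate_curve(parms$recovery, a)
  list(c(
    P = lam * (1 - y[["P"]]) - mu * y[["P"]],
    S = -lam * y[["S"]],
    Occ = y[["P"]],
    AOnset = a * lam * y[["S"]],
    Onset = lam * y[["S"]]
  ))
}

#' Solve the two-state forward equations
#'
#' Integrates point prevalence, never-MetS probability, expected occupancy,
#' and the onset-density moments over `[18, 65]` with an adaptive
#' stiff-capable integrator (`deSolve::ode`, `lsoda`, relative tolerance
#' 1e-8).
#'
#' @param incidence,recovery `rate_curve` objects.
#' @param p0 MetS prevalence at age 18.
#' @param grid Increasing age grid within `[18, 65]`; 18 is prepended if
#'   absent.
#' @return data.frame with columns `age`, `point_prevalence`, `never_prob`,
#'   `ever_prevalence`, `expected_occupancy`, and the running onset-density
#'   integrals `onset_mass` (\eqn{\int \lambda S}) and `onset_age_mass`
#'   (\eqn{\int a \lambda S}).
#' @export
oracle_solution <- function(incidence, recovery, p0,
                            grid = seq(AGE_MIN, AGE_MAX, by = 0.5)) {
  stopifnot(p0 >= 0, p0 <= 1, all(grid >= AGE_MIN & grid <= AGE_MAX),
            !is.unsorted(grid, strictly = TRUE))
  times <- if (abs(grid[1] - AGE_MIN) > 1e-12) c(AGE_MIN, grid) else grid
  y0 <- c(P = p0, S = 1 - p0, Occ = 0, AOnset = 0, Onset = 0)
  sol <- deSolve::ode(
    y = y0, times = times, func = oracle_rhs,
    parms = list(incidence = incidence, recovery = recovery),
    method = "lsoda", rtol = 1e-8, atol = 1e-12
  )
  if (attr(sol, "istate")[1] < 0) stop("forward-equation integration failed")
  sol <- as.data.frame(sol)
  sol <- sol[match(grid, sol$time), ]
  out <- data.frame(
    age = grid,
    point_prevalence = pmin(pmax(sol$P, 0), 1),
    never_prob = pmin(pmax(sol$S, 0), 1),
    expected_occupancy = sol$Occ,
    onset_mass = sol$Onset,
    onset_age_mass = sol$AOnset
  )
  out$ever_prevalence <- 1 - out$never_prob
  out
}

#' Point prevalence on an age grid (oracle)
#'
#' @inheritParams oracle_solution
#' @return Numeric vector `P(a)` along `grid`.
#' @export
oracle_point_prevalence <- function(incidence, recovery, p0, grid) {
  oracle_solution(incidence, recovery, p0, grid)$point_prevalence
}

#' Ever-prevalence on an age grid (oracle)
#'
#' Probability of having entered (or started in) the MetS state by each
#' grid age: `1 - S(a)` with `S' = -lambda S`, `S(18) = 1 - p0`.
#'
#' @inheritParams oracle_solution
#' @return Numeric vector along `grid`.
#' @export
oracle_ever_prevalence <- function(incidence, recovery, p0, grid) {
  oracle_solution(incidence, recovery, p0, grid)$ever_prevalence
}

#' Analytic life-course summary expectations (oracle)
#'
#' Computes the analytic counterparts of the three simulated summary
#' measures: life-course (ever) prevalence at 65; mean age of onset among
#' individuals who start healthy and develop MetS before 65,
#' \eqn{\int a \lambda S \, da / \int \lambda S \, da}; and mean years
#' lived with MetS among those who ever have it,
#' \eqn{\int_{18}^{65} P \, da / (1 - S(65))} (never-MetS individuals
#' contribute zero occupancy, so dividing by the ever-probability gives the
#' mean among experiencers).
#'
#' @inheritParams oracle_solution
#' @return List with `ever_prevalence_65`, `mean_age_onset` (`NA` if no
#'   onset mass), `mean_duration` (`NA` if ever-prevalence is 0).
#' @export
oracle_summary_expectations <- function(incidence, recovery, p0) {
  sol <- oracle_solution(incidence, recovery, p0,
                         grid = c(AGE_MIN, AGE_MAX))
  last <- nrow(sol)
  ever <- sol$ever_prevalence[last]
  onset <- if (sol$onset_mass[last] > 1e-12) {
    sol$onset_age_mass[last] / sol$onset_mass[last]
  } else {
    NA_real_
  }
  duration <- if (ever > 1e-12) {
    sol$expected_occupancy[last] / ever
  } else {
    NA_real_
  }
  list(ever_prevalence_65 = ever, mean_age_onset = onset,
       mean_duration = duration)
}
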