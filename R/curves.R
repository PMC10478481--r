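# Continuous-age parameterization of age-group rates: fourth-degree
# polynomial for recovery, three-parameter logistic ("logit curve") for
# incidence. Evaluation clips at zero so a fitted polynomial that dips
# negative yields a hazard of exactly 0 there.

#' Construct a rate curve
#'
#' @param form `"poly4"` (params `c0..c4` of `c0 + c1 a + ... + c4 a^4`) or
#'   `"logit3"` (params `L` asymptote in 1/yr, `k` slope per year of age,
#'   `a0` midpoint age; curve `L / (1 + exp(-k (a - a0)))`).
#' @param params Named numeric vector (`c0..c4`, or `L, k, a0`).
#' @param sex,edu,kind Optional stratum/kind labels carried for bookkeeping.
#' @return Object of class `"rate_curve"`.
#' @export
rate_curve <- function(form = c("poly4", "logit3"), params,
                       sex = NA_character_, edu = NA_character_,
                       kind = NA_character_) {
  form <- match.arg(form)
  expected <- if (form == "poly4") paste0("c", 0:4) else c("L", "k", "a0")
  params <- unlist(params)
  if (is.null(names(params)) || !identical(names(params), expected)) {
    if (length(params) != length(expected)) {
      stop("'", form, "' curve needs parameters ",
           paste(expected, collapse = ", "))
    }
    names(params) <- expected
  }
  if (form == "logit3" && params[["L"]] < 0) {
    stop("logit3 asymptote L must be nonnegative")
  }
  structure(
    list(form = form, params = params, sex = sex, edu = edu, kind = kind),
    class = "rate_curve"
  )
}

#' Constant-rate curve
#'
#' Convenience constructor: a `poly4` curve whose only nonzero coefficient
#' is the constant term.
#'
#' @param rate Constant hazard (per year).
#' @inheritParams rate_curve
#' @export
constant_curve <- function(rate, sex = NA_character_, edu = NA_character_,
                           kind = NA_character_) {
  rate_curve("poly4", c(c0 = rate, c1 = 0, c2 = 0, c3 = 0, c4 = 0),
             sex = sex, edu = edu, kind = kind)
}

#' Evaluate a rate curve at given ages
#'
#' Returns `max(0, f(age))`; ages must lie in `[18, 65]`.
#'
#' @param curve A `rate_curve`.
#' @param age Numeric vector of ages.
#' @return Nonnegative hazard values (per year).
#' @export
evaluate_curve <- function(curve, age) {
  stopifnot(inherits(curve, "rate_curve"))
  if (any(age < AGE_MIN | age > AGE_MAX)) {
    stop("age must lie in [", AGE_MIN, ", ", AGE_MAX, "]")
  }
  p <- curve$params
  v <- if (curve$form == "poly4") {
    p[["c0"]] + age * (p[["c1"]] + age * (p[["c2"]] + age * (p[["c3"]] +
      age * p[["c4"]])))
  } else {
    p[["L"]] / (1 + exp(-p[["k"]] * (age - p[["a0"]])))
  }
  pmax(v, 0)
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("<rate_curve %s%s: %s>\n",
              ifelse(is.na(x$sex), "", paste0(x$sex, "/", x$edu, " ")),
              ifelse(is.na(x$kind), "", x$kind), x$form))
  print(signif(x$params, 6))
  invisible(x)
}

# Points (midpoint, rate) from an AgeGroupRate data.frame, dropping absent
# cells.
curve_points <- function(points) {
  if (is.data.frame(points)) {
    keep <- !is.na(points$rate_per_year)
    if (!is.null(points$absent)) keep <- keep & !points$absent
    data.frame(age = (points$age_lo[keep] + points$age_hi[keep]) / 2,
               rate = points$rate_per_year[keep])
  } else {
    stop("points must be a data.frame of age-group rates")
  }
}

#' Fit a fourth-degree polynomial recovery curve
#'
#' Ordinary least squares of the age-group rates on `(1, a, a^2, a^3, a^4)`
#' at the bin midpoints.
#'
#' @param points data.frame of age-group rates (`age_lo`, `age_hi`,
#'   `rate_per_year`; absent cells dropped). At least 5 non-absent points.
#' @param sex,edu Optional stratum labels.
#' @return A `poly4` [rate_curve()].
#' @export
fit_recovery_poly <- function(points, sex = NA_character_,
                              edu = NA_character_) {
  pts <- curve_points(points)
  if (nrow(pts) < 5) {
    stop("need >= 5 non-absent points for a fourth-degree polynomial, got ",
         nrow(pts))
  }
  fit <- lm(rate ~ poly(age, 4, raw = TRUE), data = pts)
  co <- unname(coef(fit))
  co[is.na(co)] <- 0
  rate_curve("poly4", stats::setNames(co, paste0("c", 0:4)),
             sex = sex, edu = edu, kind = "recovery")
}

#' Fit a three-parameter logistic incidence curve
#'
#' Nonlinear least squares of `L / (1 + exp(-k (a - a0)))` at the bin
#' midpoints, via Levenberg-Marquardt with a grid of starting values
#' (`a0` in \{30, 40, 50\}, `k` in \{0.05, 0.2\}, `L = 1.5 max(rate)`); the
#' converged fit with the smallest residual sum of squares wins. Near-flat
#' inputs (rate spread < 1e-10) return the exact constant curve
#' `(L = 2 mean, k = 0)` directly, since the parameters are then
#' non-identifiable although the fitted values are not.
#'
#' @param points data.frame of age-group rates; at least 4 non-absent
#'   points.
#' @param sex,edu Optional stratum labels.
#' @return A `logit3` [rate_curve()].
#' @export
fit_incidence_logit <- function(points, sex = NA_character_,
                                edu = NA_character_) {
  pts <- curve_points(points)
  if (nrow(pts) < 4) {
    stop("need >= 4 non-absent points for the logistic curve, got ",
         nrow(pts))
  }
  if (diff(range(pts$rate)) < 1e-10) {
    return(rate_curve("logit3",
                      c(L = 2 * mean(pts$rate), k = 0, a0 = 41.5),
                      sex = sex, edu = edu, kind = "incidence"))
  }
  L0 <- 1.5 * max(pts$rate)
  starts <- expand.grid(L = L0, k = c(0.05, 0.2), a0 = c(30, 40, 50))
  best <- NULL
  best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rate ~ L / (1 + exp(-k * (age - a0))),
        data = pts,
        start = as.list(starts[i, ]),
        lower = c(L = 0, k = -5, a0 = -100),
        upper = c(L = Inf, k = 5, a0 = 200),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }
  if (is.null(best)) {
    stop("logistic curve fit failed to converge from every start ",
         "(best residual sum of squares: ", signif(best_rss, 4), ")")
  }
  co <- coef(best)
  rate_curve("logit3", c(L = co[["L"]], k = co[["k"]], a0 = co[["a0"]]),
             sex = sex, edu = edu, kind = "incidence")
}

#' Mean absolute error of a curve against age-group rates
#'
#' Mean over non-absent bins of `|evaluate_curve(curve, midpoint) - rate|`.
#'
#' @param curve A `rate_curve`.
#' @param points data.frame of age-group rates.
#' @return MAE (per year).
#' @export
curve_mae <- function(curve, points) {
  pts <- curve_points(points)
  if (nrow(pts) == 0) stop("no non-absent points")
  mean(abs(evaluate_curve(curve, pts$age) - pts$rate))
}

#' Fit curves for every stratum and kind
#'
#' Incidence rates get the logistic curve, recovery rates the fourth-degree
#' polynomial, per sex-by-education stratum.
#'
#' @param rates data.frame of age-group rates for all strata and both kinds
#'   (schema of [estimate_rates()] / [read_rates()]).
#' @return Nested list `curves[[sex]][[edu]]$incidence/$recovery` of
#'   `rate_curve` objects, with per-curve MAE in
#'   `attr(curve, "mae")`.
#' @export
fit_all_curves <- function(rates) {
  st <- strata()
  curves <- list()
  for (i in seq_len(nrow(st))) {
    s <- st$sex[i]
    e <- st$edu[i]
    for (k in c("incidence", "recovery")) {
      pts <- rates[rates$sex == s & rates$edu == e & rates$kind == k, ]
      if (nrow(pts) == 0) {
        stop("no rates for stratum ", s, "/", e, " kind ", k)
      }
      cv <- if (k == "incidence") {
        fit_incidence_logit(pts, sex = s, edu = e)
      } else {
        fit_recovery_poly(pts, sex = s, edu = e)
      }
      attr(cv, "mae") <- curve_mae(cv, pts)
      curves[[s]][[e]][[k]] <- cv
    }
  }
  curves
}

#' Serialize / read curves as JSON
#'
#' The document is keyed `"<sex>.<edu>.<kind>"`, each entry carrying `form`
#' and named `params`; the reader validates the curve invariants.
#'
#' @param curves Nested curve list as from [fit_all_curves()].
#' @param path File path.
#' @return `read_curves` returns the nested curve list.
#' @export
write_curves <- function(curves, path) {
  doc <- list()
  for (s in names(curves)) {
    for (e in names(curves[[s]])) {
      for (k in names(curves[[s]][[e]])) {
        cv <- curves[[s]][[e]][[k]]
        doc[[paste(s, e, k, sep = ".")]] <- list(
          form = cv$form, params = as.list(cv$params)
        )
      }
    }
  }
  atomic_write(path, function(tmp) {
    jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  doc <- jsonlite::read_json(path)
  curves <- list()
  for (key in names(doc)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 3) stop("bad curve key '", key, "' in ", path)
    entry <- doc[[key]]
    cv <- rate_curve(entry$form, unlist(entry$params),
                     sex = parts[1], edu = parts[2], kind = parts[3])
    curves[[parts[1]]][[parts[2]]][[parts[3]]] <- cv
  }
  curves
}
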