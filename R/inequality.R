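# Headline inequality measures: low-minus-high education gaps in
# life-course prevalence (percentage points), age of onset (years; positive
# when the low-educated develop MetS earlier), and duration (years), their
# sex averages, and the percentage reduction of each gap under a
# counterfactual scenario.

#' Education gaps in the three summary measures
#'
#' @param stats_low,stats_high Lists or one-row data.frames with fields
#'   `life_course_prevalence` (proportion in `[0, 1]`), `mean_age_onset`
#'   and `mean_duration` (years), for the low- and high-education group of
#'   the same sex.
#' @return List with `prevalence_gap` (percentage points,
#'   `100 (low - high)`), `onset_gap` (years, `high - low`; positive means
#'   earlier onset among the low educated), `duration_gap` (years,
#'   `low - high`). A gap is `NA` when either input summary is absent.
#' @export
gaps <- function(stats_low, stats_high) {
  list(
    prevalence_gap = 100 * (stats_low$life_course_prevalence -
                              stats_high$life_course_prevalence),
    onset_gap = stats_high$mean_age_onset - stats_low$mean_age_onset,
    duration_gap = stats_low$mean_duration - stats_high$mean_duration
  )
}

#' Sex-averaged gaps at reporting precision
#'
#' Arithmetic mean of the female and male gap, computed in decimal (tenths)
#' arithmetic on the one-decimal reported inputs and rounded half away from
#' zero to one decimal — the convention used for reported summary numbers,
#' so printed per-sex values average exactly to the printed mean.
#'
#' @param gaps_f,gaps_m Gap lists (see [gaps()]) for females and males.
#' @return List with the three averaged gaps.
#' @export
sex_average <- function(gaps_f, gaps_m) {
  avg1 <- function(a, b) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    ta <- round(a * 10)
    tb <- round(b * 10)
    sign_m <- (ta + tb) / 2
    sign(sign_m) * floor(abs(sign_m) + 0.5) / 10
  }
  list(
    prevalence_gap = avg1(gaps_f$prevalence_gap, gaps_m$prevalence_gap),
    onset_gap = avg1(gaps_f$onset_gap, gaps_m$onset_gap),
    duration_gap = avg1(gaps_f$duration_gap, gaps_m$duration_gap)
  )
}

#' Percentage reduction of a gap under a counterfactual
#'
#' `100 (gap_observed - gap_counterfactual) / gap_observed`.
#'
#' @param gap_observed Observed gap (nonzero).
#' @param gap_counterfactual Gap under the counterfactual.
#' @return Percentage; `NA` with a warning when the observed gap is 0.
#' @export
percent_reduction <- function(gap_observed, gap_counterfactual) {
  if (is.na(gap_observed) || is.na(gap_counterfactual)) return(NA_real_)
  if (gap_observed == 0) {
    warning("observed gap is zero; percentage reduction undefined")
    return(NA_real_)
  }
  100 * (gap_observed - gap_counterfactual) / gap_observed
}

# Gaps per sex from a per-stratum summary data.frame.
gaps_by_sex <- function(summary_df) {
  out <- list()
  for (s in SEXES) {
    row <- function(e) {
      as.list(summary_df[summary_df$sex == s & summary_df$edu == e, ])
    }
    out[[s]] <- gaps(row("low"), row("high"))
  }
  out
}

#' Build the inequality report
#'
#' Combines observed and counterfactual per-stratum summaries into a
#' report: per scenario the summary measures per stratum (prevalence on the
#' percent scale), the per-sex gaps, the sex-averaged gaps (reporting
#' precision), and — for counterfactual scenarios — the percentage
#' reduction of each observed gap.
#'
#' @param observed Per-stratum summary data.frame of the observed scenario
#'   (as from [summarize_by_stratum()]).
#' @param counterfactuals Named list of per-stratum summary data.frames,
#'   one per scenario (e.g. `counterfactual_smoking`, ...,
#'   `counterfactual_joint`); may be empty.
#' @param intervals Optional data.frame of interval estimates (from
#'   [run_ensemble()]) attached to the observed scenario.
#' @return Report list (class `"inequality_report"`).
#' @export
build_report <- function(observed, counterfactuals = list(),
                         intervals = NULL) {
  scenario_block <- function(summary_df) {
    measures <- list()
    for (i in seq_len(nrow(summary_df))) {
      key <- stratum_key(summary_df$sex[i], summary_df$edu[i])
      measures[[key]] <- list(
        life_course_prevalence_percent =
          100 * summary_df$life_course_prevalence[i],
        mean_age_onset = summary_df$mean_age_onset[i],
        mean_duration = summary_df$mean_duration[i],
        n = summary_df$n[i]
      )
    }
    g <- gaps_by_sex(summary_df)
    list(measures = measures, gaps = g,
         gaps_sex_average = sex_average(g$female, g$male))
  }
  report <- list(observed = scenario_block(observed))
  if (!is.null(intervals)) {
    iv <- list()
    for (i in seq_len(nrow(intervals))) {
      key <- paste(stratum_key(intervals$sex[i], intervals$edu[i]),
                   intervals$measure[i], sep = ".")
      iv[[key]] <- list(point = intervals$point[i],
                        lower = intervals$lower[i],
                        upper = intervals$upper[i])
    }
    report$observed$intervals <- iv
  }
  g_obs <- report$observed$gaps
  for (name in names(counterfactuals)) {
    block <- scenario_block(counterfactuals[[name]])
    red <- list()
    for (s in SEXES) {
      red[[s]] <- list(
        prevalence = percent_reduction(g_obs[[s]]$prevalence_gap,
                                       block$gaps[[s]]$prevalence_gap),
        onset = percent_reduction(g_obs[[s]]$onset_gap,
                                  block$gaps[[s]]$onset_gap),
        duration = percent_reduction(g_obs[[s]]$duration_gap,
                                     block$gaps[[s]]$duration_gap)
      )
    }
    block$reductions <- red
    report[[name]] <- block
  }
  class(report) <- "inequality_report"
  report
}

#' Write / read an inequality report as JSON
#'
#' @param report An `inequality_report` (see [build_report()]).
#' @param path File path.
#' @return `read_report` returns the report list.
#' @export
write_report <- function(report, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(unclass(report), tmp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  })
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  report <- jsonlite::read_json(path, simplifyVector = FALSE)
  null_to_na <- function(x) {
    if (is.list(x)) lapply(x, null_to_na) else if (is.null(x)) NA else x
  }
  report <- null_to_na(report)
  class(report) <- "inequality_report"
  report
}

#' Inequality arithmetic from a published summary table
#'
#' Given a table of reported point estimates (one-decimal percent scale for
#' prevalence, years for onset and duration) by sex, education and
#' scenario, computes the per-sex education gaps, their sex averages, and
#' per-scenario percentage reductions — the derived inequality numbers a
#' reader would reproduce from a published results table.
#'
#' @param table data.frame with columns `sex`, `education`
#'   (`"low"`/`"high"`), `scenario` (`"observed"`,
#'   `"counterfactual_smoking"`, ...), `prevalence_percent`, `onset_years`,
#'   `duration_years`.
#' @return List with per-scenario `gaps` (per sex + `average`) and, for
#'   counterfactual scenarios, `reductions`.
#' @export
inequality_from_table <- function(table) {
  required <- c("sex", "education", "scenario", "prevalence_percent",
                "onset_years", "duration_years")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0) {
    stop("summary table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  cell <- function(s, e, scen) {
    r <- table[table$sex == s & table$education == e &
                 table$scenario == scen, ]
    if (nrow(r) == 0 && scen != "observed" && e == "high") {
      # high-education rows are unchanged under counterfactuals
      r <- table[table$sex == s & table$education == e &
                   table$scenario == "observed", ]
    }
    if (nrow(r) != 1) stop("expected exactly one row for ", s, "/", e, "/",
                           scen)
    list(life_course_prevalence = r$prevalence_percent / 100,
         mean_age_onset = r$onset_years,
         mean_duration = r$duration_years)
  }
  scenarios <- unique(table$scenario)
  out <- list()
  for (scen in scenarios) {
    g <- list()
    for (s in SEXES) {
      g[[s]] <- lapply(gaps(cell(s, "low", scen), cell(s, "high", scen)),
                       round_half_away, digits = 1)
    }
    g$average <- sex_average(g$female, g$male)
    out[[scen]] <- list(gaps = g)
  }
  for (scen in setdiff(scenarios, "observed")) {
    red <- list()
    for (s in c(SEXES)) {
      red[[s]] <- list(
        prevalence = percent_reduction(
          out$observed$gaps[[s]]$prevalence_gap,
          out[[scen]]$gaps[[s]]$prevalence_gap),
        onset = percent_reduction(out$observed$gaps[[s]]$onset_gap,
                                  out[[scen]]$gaps[[s]]$onset_gap),
        duration = percent_reduction(out$observed$gaps[[s]]$duration_gap,
                                     out[[scen]]$gaps[[s]]$duration_gap)
      )
    }
    out[[scen]]$reductions <- red
  }
  out
}

#' Bar-chart data (and optional plot) of counterfactual gap reductions
#'
#' Returns tidy bar-chart data mirroring the report's reduction structure;
#' if `ggplot2` is installed and `plot = TRUE`, also builds the bar chart.
#'
#' @param report An `inequality_report` with counterfactual scenarios.
#' @param measure `"prevalence"`, `"onset"` or `"duration"`.
#' @param plot Build a ggplot object (requires `ggplot2`).
#' @return data.frame with columns `scenario`, `sex`, `gap`,
#'   `reduction_percent`; the ggplot object (if requested) in
#'   `attr(, "plot")`.
#' @export
reduction_chart_data <- function(report,
                                 measure = c("prevalence", "onset",
                                             "duration"),
                                 plot = FALSE) {
  measure <- match.arg(measure)
  gap_field <- paste0(measure, "_gap")
  scenarios <- setdiff(names(report), "observed")
  rows <- list()
  for (scen in c("observed", scenarios)) {
    for (s in SEXES) {
      rows[[length(rows) + 1]] <- data.frame(
        scenario = scen, sex = s,
        gap = report[[scen]]$gaps[[s]][[gap_field]],
        reduction_percent = if (scen == "observed") 0 else
          report[[scen]]$reductions[[s]][[measure]],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (plot && requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(out, ggplot2::aes(
      x = .data[["scenario"]], y = .data[["gap"]], fill = .data[["sex"]]
    )) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_text(ggplot2::aes(
        label = sprintf("%.1f%%", .data[["reduction_percent"]])
      ), position = ggplot2::position_dodge(width = 0.9), vjust = -0.3,
      size = 3) +
      ggplot2::labs(x = NULL, y = paste("education gap:", measure)) +
      ggplot2::theme_minimal()
    attr(out, "plot") <- p
  }
  out
}
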