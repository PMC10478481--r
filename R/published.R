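# Access to the bundled table of published life-course summary estimates.

#' Published life-course summary estimates
#'
#' Point estimates and 95% CIs of life-course MetS prevalence, mean age of
#' onset and mean duration, by sex, education and scenario, as reported by
#' the Dutch cohort-based microsimulation study whose transition-rate
#' framework this package implements. Used to demonstrate and test the
#' inequality arithmetic ([inequality_from_table()]); reproducing these
#' simulated values themselves additionally requires that study's published
#' transition-rate tables, which can be supplied through [read_rates()].
#'
#' @return data.frame with columns `sex`, `education`, `scenario`,
#'   `prevalence_percent` (+ `_lo`/`_hi`), `onset_years` (+ `_lo`/`_hi`),
#'   `duration_years` (+ `_lo`/`_hi`).
#' @export
published_summaries <- function() {
  path <- system.file("extdata", "published_summaries.csv",
                      package = "metsim", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
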