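#' Bundled US survey and model prevalence estimates
#'
#' Published aggregate current-smoking prevalence estimates for US
#' adults by gender and age group — TUS-CPS and NHIS survey estimates
#' with 95% CIs, alongside the no-vaping counterfactual model projection
#' (`no_nvp_model`) — for the validation period (1993-2012) or the
#' post-vaping comparison period (2012-2018).
#'
#' @param period `"1993-2012"` or `"2012-2018"`.
#' @return A [read_survey_series()] data frame.
#' @export
us_survey_prevalence <- function(period = c("1993-2012", "2012-2018")) {
  period <- match.arg(period)
  file <- if (period == "1993-2012") {
    "us_prevalence_1993_2012.csv"
  } else {
    "us_prevalence_2012_2018.csv"
  }
  read_survey_series(system.file("extdata", file, package = "smokesim",
                                 mustWork = TRUE))
}

#' Bundled published percent-change cells, 1993-2012
#'
#' The published percent changes in prevalence over 1993-1998,
#' 1998-2010 and 1998-2012 (percent units; negative = decline) matching
#' [us_survey_prevalence()]. Some published cells were computed from
#' unrounded sources and differ slightly from arithmetic on the printed
#' prevalences.
#'
#' @return Data frame `survey, gender, age_group, period_start,
#'   period_end, percent_change`.
#' @export
us_printed_changes <- function() {
  read.csv(system.file("extdata", "us_changes_1993_2012.csv",
                       package = "smokesim", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Bundled published 2012-2018 reduction cells
#'
#' The published relative reductions over 2012-2018, their differences
#' from the counterfactual, and the annualized columns with CI-derived
#' bounds (percent units).
#'
#' @return Data frame keyed by `survey, gender, age_group`.
#' @export
us_printed_reductions <- function() {
  read.csv(system.file("extdata", "us_reductions_2012_2018.csv",
                       package = "smokesim", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
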