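#' Reference chronic-stroke cohort tables
#'
#' Two small tables from a published 14-participant chronic post-stroke
#' aphasia cohort, shipped as example data and as inputs to the package's
#' self-checks.
#'
#' `example_cohort()` returns per-participant demographics and lesion
#' characteristics: age at scan (years), sex, months since stroke,
#' aphasia-severity score (WAB-AQ), aphasia type, lesion and cavitation
#' volumes (mm^3) and the percent-cavitation column as printed.
#'
#' `example_score_fits()` returns the per-participant linear-fit summaries
#' of mean lesion CBF against the ten damage scores, for each of the three
#' smoothing-placement pipelines: R-squared, the F(1,8) statistic, the
#' printed p value (`p_value`, verbatim; entries like "<0.0001" are
#' censored at the printed precision) with a numeric upper bound in
#' `p_upper`, and the sign of the fitted slope (`"-"`, `"+"`, or `"none"`
#' for the one participant with no detectable relationship).
#'
#' @return a data.frame (see above).
#' @export
example_cohort <- function() {
  utils::read.delim(system.file("extdata", "reference_cohort.tsv",
                                package = "strokecbf", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' @rdname example_cohort
#' @export
example_score_fits <- function() {
  d <- utils::read.delim(system.file("extdata", "reference_score_fits.tsv",
                                     package = "strokecbf", mustWork = TRUE),
                         colClasses = c(p_value = "character"),
                         stringsAsFactors = FALSE)
  d$p_upper <- as.numeric(sub("^<", "", d$p_value))
  d
}
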