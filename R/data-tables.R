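# Published Qinghai Lake Basin summary tables, shipped as plain-text data so
# the transition / grade accounting can be exercised (and checked against the
# published derived statistics) without any raster downloads.

extdata <- function(file) {
  p <- system.file("extdata", file, package = "fvcdyn")
  if (!nzchar(p)) stop("bundled table not found: ", file)
  p
}

#' Published basin FVC grade-transition matrices
#'
#' The three five-grade transition matrices (km^2) published for the Qinghai
#' Lake Basin: 2001-2022, 2001-2012 and 2012-2022.
#'
#' @param period `"2001_2022"`, `"2001_2012"` or `"2012_2022"`.
#' @return An `fvc_transition_matrix`.
#' @export
basin_transition_table <- function(period = c("2001_2022", "2001_2012",
                                              "2012_2022")) {
  period <- match.arg(period)
  df <- read.csv(extdata(paste0("qinghai_transition_", period, ".csv")),
                 check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  transition_matrix_from_area(m, df[[1]])
}

#' Published basin FVC grade areas (multi-year mean)
#'
#' @return Data frame with `class`, `area_km2`, `percentage` as published.
#' @export
basin_grade_areas <- function() {
  read.csv(extdata("qinghai_grade_areas.csv"))
}

#' Published basin trend-type areas
#'
#' Areas and shares of the five trend classes. The class labels follow the
#' authoritative classification rule (the published table's slope/Z sign
#' column pairings are transposed relative to it; areas are as printed).
#'
#' @return Data frame with `change_type`, `area_km2`, `percentage`.
#' @export
basin_trend_areas <- function() {
  read.csv(extdata("qinghai_trend_type_areas.csv"))
}

#' Published basin CV fluctuation-class shares
#'
#' @return Data frame with `cv_class`, `percentage`.
#' @export
basin_cv_shares <- function() {
  read.csv(extdata("qinghai_cv_type_percent.csv"))
}
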