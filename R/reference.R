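#' Published band-frequency reference table
#'
#' The published percent frequencies of the five axis bands within each
#' MULTICAGE-flagged ICT subpopulation, as printed in the source study's
#' frequency table. Useful as a worked input for
#' \code{\link{compare_band_proportions}} and for checking the analysis
#' chain against the published group statistics.
#'
#' @return data.frame with \code{band} and the five ICT scale columns,
#'   percentages.
#' @export
reference_band_frequencies <- function() {
  data.frame(
    band = band_levels(),
    internet          = c(1.22, 6.99, 68.39, 20.06, 3.34),
    cell_phone        = c(0.22, 8.19, 72.12, 16.59, 2.88),
    videogames        = c(1.30, 11.69, 71.43, 12.99, 2.60),
    instant_messaging = c(1.02, 9.49, 66.78, 18.64, 4.07),
    social_networks   = c(1.08, 7.53, 63.98, 23.12, 4.30),
    stringsAsFactors = FALSE)
}

#' Published demographic reference counts
#'
#' Sex-by-band counts of the source cohort (n = 807): age bands and
#' education bands.
#'
#' @return list of two data.frames (\code{age}, \code{education}) with
#'   columns \code{band}, \code{men}, \code{women}.
#' @export
reference_demographics <- function() {
  list(
    age = data.frame(
      band = age_bands(),
      men = c(4, 32, 38, 72, 88, 27),
      women = c(9, 96, 69, 141, 173, 58),
      stringsAsFactors = FALSE),
    education = data.frame(
      band = education_bands(),
      men = c(11, 16, 56, 19, 159),
      women = c(14, 14, 63, 60, 395),
      stringsAsFactors = FALSE))
}

#' Summarize cohort demographics
#'
#' Counts and percents by sex for each age and education band, in the
#' layout of a standard sample-demographics table, plus headline
#' percentages: percent women, percent aged 31-60, percent at university
#' level (student or degree).
#'
#' @param demographics data.frame with \code{sex} (\code{"man"} /
#'   \code{"woman"}), \code{age_band}, \code{education_band}; or a list of
#'   count tables shaped like \code{\link{reference_demographics}}.
#' @return list with \code{age} and \code{education} count/percent tables
#'   and \code{headline} (named numeric vector of percents).
#' @export
demographics_summary <- function(demographics) {
  if (is.data.frame(demographics)) {
    counts <- list(
      age = data.frame(
        band = age_bands(),
        men = as.numeric(table(factor(
          demographics$age_band[demographics$sex == "man"],
          levels = age_bands()))),
        women = as.numeric(table(factor(
          demographics$age_band[demographics$sex == "woman"],
          levels = age_bands()))),
        stringsAsFactors = FALSE),
      education = data.frame(
        band = education_bands(),
        men = as.numeric(table(factor(
          demographics$education_band[demographics$sex == "man"],
          levels = education_bands()))),
        women = as.numeric(table(factor(
          demographics$education_band[demographics$sex == "woman"],
          levels = education_bands()))),
        stringsAsFactors = FALSE))
  } else counts <- demographics
  n <- sum(counts$age$men + counts$age$women)
  pct <- function(k) 100 * k / n
  add_pct <- function(tab) {
    tab$total <- tab$men + tab$women
    tab$pct_men <- pct(tab$men); tab$pct_women <- pct(tab$women)
    tab$pct_total <- pct(tab$total)
    tab
  }
  age <- add_pct(counts$age); edu <- add_pct(counts$education)
  headline <- c(
    women = pct(sum(counts$age$women)),
    aged_31_60 = sum(age$pct_total[age$band %in% c("31-45", "46-60")]),
    university = sum(edu$pct_total[edu$band %in%
      c("university_student", "university_degree")]))
  list(age = age, education = edu, n = n, headline = headline)
}

#' Sample-size adequacy check
#'
#' The subjects-per-item rule for questionnaire studies: with \code{p}
#' total items over the administered instruments, the sample passes when
#' \code{n / p >= 10}; the minimum adequate n is \code{10 * p}.
#'
#' @param n_subjects sample size.
#' @param specs instrument specs (default the four bundled instruments,
#'   72 items in total).
#' @return list with \code{n}, \code{p}, \code{ratio} (2 decimals),
#'   \code{minimum_n}, \code{pass}.
#' @export
check_sample_size <- function(n_subjects, specs = default_instruments()) {
  p <- sum(vapply(specs, function(s) length(s$items), 0L))
  ratio <- round(n_subjects / p, 2)
  list(n = n_subjects, p = p, ratio = ratio, minimum_n = 10L * p,
       pass = ratio >= 10)
}
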