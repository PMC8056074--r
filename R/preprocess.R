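#' Ordinal covariate codes for age and education bands
#'
#' The cohort's demographics are collected as bands; for regression they
#' are coded as ordinal integers in band order: age \code{<18} = 1 through
#' \code{>60} = 6, education \code{primary} = 1 through
#' \code{university_degree} = 5. Any monotone coding is admissible; this
#' one is the package default and is isolated here.
#'
#' @param demographics data.frame with \code{subject_id}, \code{age_band},
#'   \code{education_band} (character, matching \code{\link{age_bands}} /
#'   \code{\link{education_bands}}).
#' @return data.frame with \code{subject_id}, \code{age_code},
#'   \code{education_code}.
#' @export
covariate_codes <- function(demographics) {
  a <- match(demographics$age_band, age_bands())
  e <- match(demographics$education_band, education_bands())
  if (anyNA(a)) stop("unknown age band: ",
                     demographics$age_band[which(is.na(a))[1L]])
  if (anyNA(e)) stop("unknown education band: ",
                     demographics$education_band[which(is.na(e))[1L]])
  data.frame(subject_id = demographics$subject_id,
             age_code = a, education_code = e, stringsAsFactors = FALSE)
}

#' @rdname covariate_codes
#' @export
age_bands <- function() c("<18", "18-25", "26-30", "31-45", "46-60", ">60")

#' @rdname covariate_codes
#' @export
education_bands <- function() c("primary", "secondary", "high_school",
                                "university_student", "university_degree")

#' Linearly rescale raw subscale scores to 0-100
#'
#' \code{normalized = (raw - min) / (max - min) * 100} with the theoretical
#' subscale ranges, so 0 is the lowest attainable score and 100 the highest.
#'
#' @param scores raw-stage score data.frame (from
#'   \code{\link{score_instrument}} or \code{\link{score_cohort}}).
#' @param specs instrument specs providing the theoretical ranges.
#' @param columns which columns to rescale; default every
#'   \code{<instrument>_<subscale>} column found, plus \code{PSI_total}.
#' @return data.frame of the same shape, stage \code{"normalized"};
#'   values in [0, 100].
#' @export
rescale_0_100 <- function(scores, specs = default_instruments(),
                          columns = NULL) {
  ranges <- theoretical_ranges(specs)
  if (is.null(columns)) columns <- intersect(names(ranges), names(scores))
  out <- scores
  for (cn in columns) {
    rng <- ranges[[cn]]
    if (is.null(rng)) stop("no theoretical range known for column ", cn)
    if (rng[2] == rng[1]) stop("degenerate range for column ", cn)
    x <- scores[[cn]]
    if (any(x < rng[1] | x > rng[2]))
      stop("raw scores outside theoretical range in column ", cn)
    out[[cn]] <- (x - rng[1]) / (rng[2] - rng[1]) * 100
  }
  attr(out, "stage") <- "normalized"
  out
}

# theoretical [min,max] per score column, incl. PSI_total
theoretical_ranges <- function(specs = default_instruments()) {
  out <- list()
  for (sp in specs) for (s in names(sp$subscales))
    out[[paste0(sp$name, "_", s)]] <- subscale_range(sp, s)
  if (!is.null(specs$PSI))
    out$PSI_total <- c(length(specs$PSI$items) * specs$PSI$response_min,
                       length(specs$PSI$items) * specs$PSI$response_max)
  out
}

#' Multivariate outlier exclusion by Mahalanobis distance
#'
#' Squared Mahalanobis distances to the sample mean under the sample
#' covariance (n-1 denominator) are compared with the chi-square quantile
#' at \code{1 - alpha} with as many degrees of freedom as score columns;
#' subjects above the threshold are excluded. With the default
#' \code{alpha = 0.001} this is the p < 0.001 exclusion criterion.
#'
#' @param scores data.frame containing \code{subject_id} and the score
#'   columns to screen.
#' @param columns score columns to use; default the 8 UPPS + OCDUS
#'   subscales (\code{\link{axis_columns}}).
#' @param alpha tail probability for exclusion (default 0.001).
#' @return list with \code{retained} (the filtered data.frame) and
#'   \code{report}, a list of class \code{"outlier_report"}: per-subject
#'   \code{distance2}, the \code{threshold}, its \code{df} and
#'   \code{quantile}, \code{excluded} subject ids and the
#'   \code{exclusion_fraction}.
#' @export
mahalanobis_filter <- function(scores, columns = axis_columns(),
                               alpha = 0.001) {
  m <- as.matrix(scores[, columns, drop = FALSE])
  if (nrow(m) <= ncol(m))
    stop("need more subjects than score columns for a covariance estimate")
  S <- stats::cov(m)
  sds <- sqrt(diag(S))
  if (any(sds == 0))
    stop("constant score column(s): ",
         paste(columns[sds == 0], collapse = ", "),
         "; covariance is singular")
  d2 <- tryCatch(stats::mahalanobis(m, colMeans(m), S),
                 error = function(e) stop("singular covariance over columns ",
                                          paste(columns, collapse = ", ")))
  thr <- stats::qchisq(1 - alpha, df = ncol(m))
  excl <- d2 > thr
  report <- structure(list(
    distance2 = stats::setNames(d2, scores$subject_id),
    threshold = thr, df = ncol(m), quantile = 1 - alpha,
    excluded = scores$subject_id[excl],
    exclusion_fraction = mean(excl)), class = "outlier_report")
  list(retained = scores[!excl, , drop = FALSE], report = report)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "Mahalanobis outlier screen: df = %d, chi-square threshold %.2f (p < %g)\n",
    x$df, x$threshold, 1 - x$quantile))
  cat(sprintf("  excluded %d of %d subjects (%.2f%%)\n", length(x$excluded),
              length(x$distance2), 100 * x$exclusion_fraction))
  invisible(x)
}

#' Residualize scores on age and education and standardize
#'
#' For each score column an ordinary least-squares regression
#' \code{score ~ age_code + education_code} is fitted jointly; the raw
#' residuals are divided by their sample SD (n-1), so every output column
#' has mean exactly 0 and SD exactly 1 over the cohort. This removes the
#' weak demographic trends from the subscale scores before the axis is
#' formed.
#'
#' If a covariate is constant it is dropped with a warning; if both are
#' constant, a plain Z-score is returned with a warning.
#'
#' @param scores normalized-stage score data.frame with \code{subject_id}.
#' @param covariates output of \code{\link{covariate_codes}} for the same
#'   subjects.
#' @param columns columns to residualize; default \code{\link{axis_columns}}.
#' @return data.frame with \code{subject_id} and the residualized Z
#'   columns, stage \code{"residual_z"}.
#' @export
residualize_z <- function(scores, covariates, columns = axis_columns()) {
  d <- merge(scores[, c("subject_id", columns)], covariates,
             by = "subject_id", sort = FALSE)
  if (nrow(d) < 3L) stop("need at least 3 subjects to residualize")
  use <- c(age_code = stats::var(d$age_code) > 0,
           education_code = stats::var(d$education_code) > 0)
  if (!all(use))
    warning("constant covariate(s) dropped from residualization: ",
            paste(names(use)[!use], collapse = ", "))
  rhs <- names(use)[use]
  X <- cbind(1, as.matrix(d[, rhs, drop = FALSE]))
  out <- d["subject_id"]
  for (cn in columns) {
    y <- d[[cn]]
    res <- if (length(rhs)) stats::lm.fit(X, y)$residuals else y - mean(y)
    s <- stats::sd(res)
    if (s == 0) stop("zero residual variance in column ", cn)
    out[[cn]] <- res / s
  }
  attr(out, "stage") <- "residual_z"
  out
}
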