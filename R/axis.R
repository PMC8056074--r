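#' Compute the Impulsivity-Compulsivity axis
#'
#' Per subject, the impulsive component is the arithmetic mean of the five
#' UPPS residual-Z subscales and the compulsive component the mean of the
#' three OCDUS residual-Z subscales; the axis is
#' \code{10 * (impulsive - compulsive)}. Positive values mark the
#' impulsive pole, negative values the compulsive pole. Because both
#' components are built from columns standardized on the same cohort, the
#' cohort mean of the axis is 0 by construction.
#'
#' @param z residual-Z stage score data.frame (from
#'   \code{\link{residualize_z}}) containing all eight axis subscales.
#' @param tie_rule band tie rule passed to \code{\link{classify_band}}.
#' @return data.frame of class \code{"axis_result"}: \code{subject_id},
#'   \code{impulsive_component}, \code{compulsive_component}, \code{axis},
#'   \code{band} (factor over the five bands, impulsive pole first).
#' @export
compute_axis <- function(z, tie_rule = c("balance", "moderate")) {
  missing_cols <- setdiff(axis_columns(), names(z))
  if (length(missing_cols))
    stop("missing residual-Z subscale column(s): ",
         paste(missing_cols, collapse = ", "))
  imp <- rowMeans(z[, upps_columns(), drop = FALSE])
  com <- rowMeans(z[, ocdus_columns(), drop = FALSE])
  ax <- 10 * (imp - com)
  out <- data.frame(subject_id = z$subject_id,
                    impulsive_component = imp,
                    compulsive_component = com,
                    axis = ax, stringsAsFactors = FALSE)
  out$band <- classify_band(ax, tie_rule = match.arg(tie_rule))
  class(out) <- c("axis_result", "data.frame")
  out
}

#' Band labels of the axis, impulsive pole first
#' @return character vector of the five band labels.
#' @export
band_levels <- function() c("high_impulsivity", "moderate_impulsivity",
                            "balance", "moderate_compulsivity",
                            "high_compulsivity")

#' Classify axis values into the five character bands
#'
#' Thresholds at +/-10 and +/-20: above +20 high impulsivity, (+10, +20]
#' moderate impulsivity, [-10, +10] balance, [-20, -10) moderate
#' compulsivity, below -20 high compulsivity. The published band
#' definitions overlap at exactly +/-10 and +/-20; the default
#' \code{tie_rule = "balance"} keeps the balance band maximal (exact
#' +/-10 is balance, exact +/-20 moderate), while \code{"moderate"}
#' assigns exact +/-10 to the moderate bands and exact +/-20 to the high
#' bands.
#'
#' @param axis numeric vector of finite axis values.
#' @param tie_rule how to break the overlapping boundary values.
#' @return factor over \code{\link{band_levels}}.
#' @export
classify_band <- function(axis, tie_rule = c("balance", "moderate")) {
  tie_rule <- match.arg(tie_rule)
  if (any(!is.finite(axis))) stop("non-finite axis value")
  lab <- if (tie_rule == "balance") {
    # boundaries join the band nearer to balance
    ifelse(axis >  20, "high_impulsivity",
    ifelse(axis >  10, "moderate_impulsivity",
    ifelse(axis >= -10, "balance",
    ifelse(axis >= -20, "moderate_compulsivity", "high_compulsivity"))))
  } else {
    # boundaries join the band farther from balance
    ifelse(axis >=  20, "high_impulsivity",
    ifelse(axis >=  10, "moderate_impulsivity",
    ifelse(axis >  -10, "balance",
    ifelse(axis >  -20, "moderate_compulsivity", "high_compulsivity"))))
  }
  factor(lab, levels = band_levels())
}

#' Descriptive summary of the axis distribution
#'
#' Mean, SD (n-1), minimum, type-7 (linear interpolation) quartiles,
#' maximum, adjusted Fisher-Pearson skewness and excess kurtosis.
#'
#' @param axis numeric vector of axis values (n >= 4 for the moment
#'   statistics; with fewer observations they are returned as \code{NA}).
#' @return list of class \code{"axis_descriptives"}.
#' @export
axis_descriptives <- function(axis) {
  n <- length(axis)
  q <- stats::quantile(axis, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  m <- mean(axis); s <- stats::sd(axis)
  if (n >= 4 && s > 0) {
    dev <- axis - m
    g1 <- mean(dev^3) / mean(dev^2)^1.5
    skew <- sqrt(n * (n - 1)) / (n - 2) * g1
    g2 <- mean(dev^4) / mean(dev^2)^2 - 3
    kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  } else {
    skew <- NA_real_; kurt <- NA_real_
  }
  structure(list(n = n, mean = m, sd = s, min = min(axis),
                 q1 = q[1], median = q[2], q3 = q[3], max = max(axis),
                 skewness = skew, excess_kurtosis = kurt),
            class = "axis_descriptives")
}

#' @export
print.axis_descriptives <- function(x, ...) {
  cat("Impulsivity-Compulsivity axis summary\n")
  cat(sprintf("  n = %d, mean = %.2f, SD = %.2f\n", x$n, x$mean, x$sd))
  cat(sprintf("  min %.2f | Q1 %.2f | median %.2f | Q3 %.2f | max %.2f\n",
              x$min, x$q1, x$median, x$q3, x$max))
  cat(sprintf("  skewness %.2f, excess kurtosis %.2f\n",
              x$skewness, x$excess_kurtosis))
  invisible(x)
}

#' Internal consistency of the axis with its components
#'
#' Pearson correlation (with p and JZS BF10) of the axis against the
#' impulsive component (must be positive: higher UPPS, more impulsive)
#' and against the compulsive component (must be negative).
#'
#' @param axis_result output of \code{\link{compute_axis}}.
#' @return list with \code{upps} and \code{ocdus}
#'   \code{\link{pearson_bf10}} results.
#' @export
axis_consistency <- function(axis_result) {
  list(upps = pearson_bf10(axis_result$axis,
                           axis_result$impulsive_component),
       ocdus = pearson_bf10(axis_result$axis,
                            axis_result$compulsive_component))
}

#' Band frequencies within the flagged ICT subpopulations
#'
#' For each MULTICAGE scale, restricts the cohort to subjects flagged on
#' that scale (percent >= 50) and reports the percent of those subjects in
#' each of the five axis bands. Columns sum to 100 up to rounding.
#'
#' @param axis_result output of \code{\link{compute_axis}}.
#' @param multicage output of \code{\link{score_multicage}} for the same
#'   subjects.
#' @param digits rounding applied to the reported percentages (default 2,
#'   as in published frequency tables); use \code{NULL} for unrounded.
#' @return data.frame, 5 band rows x 5 scale columns (plus \code{band}),
#'   in percent. Scales with no flagged subject give an \code{NA} column
#'   with a warning.
#' @export
band_frequency_table <- function(axis_result, multicage, digits = 2) {
  d <- merge(as.data.frame(axis_result)[c("subject_id", "band")],
             multicage, by = "subject_id", sort = FALSE)
  scales <- c("internet", "cell_phone", "videogames", "instant_messaging",
              "social_networks")
  out <- data.frame(band = band_levels(), stringsAsFactors = FALSE)
  for (s in scales) {
    sel <- d[[paste0("flag_", s)]]
    if (!any(sel)) {
      warning("no subjects flagged on scale '", s, "'")
      out[[s]] <- NA_real_
    } else {
      tab <- table(factor(d$band[sel], levels = band_levels()))
      pct <- as.numeric(tab) / sum(tab) * 100
      out[[s]] <- if (is.null(digits)) pct else round(pct, digits)
    }
  }
  out
}
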