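#' Validate an item response table against an instrument spec
#'
#' Checks completeness (every subject answered every item exactly once)
#' and response range. Errors name the offending subject and item.
#'
#' @param responses data.frame with columns \code{subject_id},
#'   \code{instrument}, \code{item}, \code{response} (long format).
#' @param spec an \code{instrument_spec}.
#' @return invisibly, the subset of \code{responses} for this instrument.
#' @export
validate_responses <- function(responses, spec) {
  need <- c("subject_id", "instrument", "item", "response")
  if (!all(need %in% names(responses)))
    stop("response table must have columns: ", paste(need, collapse = ", "))
  r <- responses[responses$instrument == spec$name, , drop = FALSE]
  if (nrow(r) == 0L) stop("no responses for instrument '", spec$name, "'")
  bad <- !(r$response %in% spec$response_min:spec$response_max) |
    r$response != round(r$response)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("out-of-range response %s for subject '%s', %s item %d",
                 format(r$response[i]), r$subject_id[i], spec$name, r$item[i]))
  }
  tab <- table(r$subject_id, factor(r$item, levels = spec$items))
  if (any(tab > 1L)) {
    ij <- which(tab > 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf("duplicate response for subject '%s', %s item %s",
                 rownames(tab)[ij[1L]], spec$name, colnames(tab)[ij[2L]]))
  }
  if (any(tab < 1L)) {
    ij <- which(tab < 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf("missing response for subject '%s', %s item %s",
                 rownames(tab)[ij[1L]], spec$name, colnames(tab)[ij[2L]]))
  }
  invisible(r)
}

#' Score one instrument
#'
#' Sums item responses per subscale after applying reverse keys, then
#' applies any scale-level inversion. Column names are
#' \code{<instrument>_<subscale>}.
#'
#' @inheritParams validate_responses
#' @return data.frame with \code{subject_id} and one column per subscale
#'   (stage \code{"raw"}, recorded in attribute \code{stage}).
#' @export
score_instrument <- function(responses, spec) {
  r <- validate_responses(responses, spec)
  rev <- r$item %in% spec$reverse_items
  r$response[rev] <- reverse_item(r$response[rev], spec$response_min,
                                  spec$response_max)
  subjects <- unique(r$subject_id)
  out <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  for (s in names(spec$subscales)) {
    sub <- r[r$item %in% spec$subscales[[s]], , drop = FALSE]
    agg <- tapply(sub$response, sub$subject_id, sum)
    sc <- as.numeric(agg[as.character(subjects)])
    if (s %in% spec$inverted_subscales) {
      rng <- subscale_range(spec, s)
      sc <- rng[1] + rng[2] - sc
    }
    out[[paste0(spec$name, "_", s)]] <- sc
  }
  attr(out, "stage") <- "raw"
  out
}

#' Score the MULTICAGE-ICT screening questionnaire
#'
#' Yes-counts per scale, percents of the scale maximum, the total percent,
#' and per-scale addiction-sign flags: a scale flags a subject when its
#' percent is greater than or equal to 50.
#'
#' @param responses long-format response table (see
#'   \code{\link{validate_responses}}); MULTICAGE items must be coded 0/1
#'   with 1 = "yes".
#' @param spec MULTICAGE \code{instrument_spec}; default the bundled one.
#' @param threshold flag threshold on the percent scale (default 50).
#' @return data.frame with \code{subject_id}, per-scale counts
#'   (\code{MULTICAGE_<scale>}), percents (\code{MULTICAGE_<scale>_pct}),
#'   \code{MULTICAGE_total} count and \code{MULTICAGE_total_pct}, and
#'   logical flags \code{flag_<scale>}, \code{flag_total}.
#' @export
score_multicage <- function(responses, spec = default_instruments()$MULTICAGE,
                            threshold = 50) {
  raw <- score_instrument(responses, spec)
  out <- raw["subject_id"]
  scales <- names(spec$subscales)
  total <- 0
  n_items <- 0L
  for (s in scales) {
    k <- length(spec$subscales[[s]])
    cnt <- raw[[paste0(spec$name, "_", s)]]
    out[[paste0(spec$name, "_", s)]] <- cnt
    out[[paste0(spec$name, "_", s, "_pct")]] <- cnt / k * 100
    total <- total + cnt
    n_items <- n_items + k
  }
  out[[paste0(spec$name, "_total")]] <- total
  out[[paste0(spec$name, "_total_pct")]] <- total / n_items * 100
  for (s in scales)
    out[[paste0("flag_", s)]] <- out[[paste0(spec$name, "_", s, "_pct")]] >= threshold
  out$flag_total <- out[[paste0(spec$name, "_total_pct")]] >= threshold
  out
}

#' Score every instrument of the battery
#'
#' @param responses long-format response table for all instruments.
#' @param specs named list of \code{instrument_spec}s
#'   (default \code{\link{default_instruments}}).
#' @return data.frame of raw subscale scores for UPPS, OCDUS and PSI
#'   (including \code{PSI_total}) merged with the MULTICAGE counts,
#'   percents and flags, one row per subject.
#' @export
score_cohort <- function(responses, specs = default_instruments()) {
  out <- NULL
  for (nm in names(specs)) {
    sc <- if (nm == "MULTICAGE") score_multicage(responses, specs[[nm]])
          else score_instrument(responses, specs[[nm]])
    if (nm == "PSI") {
      psi_cols <- paste0("PSI_", names(specs$PSI$subscales))
      sc$PSI_total <- rowSums(sc[psi_cols])
    }
    out <- if (is.null(out)) sc else merge(out, sc, by = "subject_id",
                                           sort = FALSE)
  }
  attr(out, "stage") <- "raw"
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = k/(k-1) (1 - \sum_i s_i^2 / s_T^2)} where \eqn{s_i^2} are
#' the item sample variances and \eqn{s_T^2} the variance of item sums
#' (both with \eqn{n-1} denominators).
#'
#' @param item_matrix numeric matrix, subjects in rows, items of one scale
#'   in columns; at least 2 items and 3 subjects.
#' @return the alpha coefficient (unitless).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2L) stop("need at least 2 items")
  if (nrow(m) < 3L) stop("need at least 3 subjects")
  vt <- stats::var(rowSums(m))
  if (vt <= 0) stop("zero total-score variance: alpha undefined")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
}
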