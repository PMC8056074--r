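#' Read a long-format item response CSV
#'
#' Expected columns: \code{subject_id,instrument,item,response} (UTF-8,
#' header required).
#'
#' @param path CSV file path.
#' @return data.frame in the long response format.
#' @export
read_responses_long <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "instrument", "item", "response")
  if (!all(need %in% names(d)))
    stop("expected columns ", paste(need, collapse = ","), " in ", path)
  d$item <- as.integer(d$item)
  d$response <- as.numeric(d$response)
  d
}

#' Read a wide-format item response CSV
#'
#' One row per subject; item columns named \code{<instrument>_<nn>} with a
#' zero-padded or plain item number, e.g. \code{UPPS_01} or \code{OCDUS_7}.
#' A \code{subject_id} column is required; other columns (demographics)
#' are ignored here.
#'
#' @param path CSV file path.
#' @return data.frame in the long response format.
#' @export
read_responses_wide <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(d)) stop("wide response CSV needs subject_id")
  wide_to_long_responses(d)
}

#' Convert wide item columns to the long response format
#'
#' @param d data.frame with \code{subject_id} and \code{<instrument>_<nn>}
#'   item columns.
#' @param instruments instrument names to look for.
#' @return long-format response data.frame.
#' @export
wide_to_long_responses <- function(d,
    instruments = c("UPPS", "OCDUS", "PSI", "MULTICAGE")) {
  pat <- paste0("^(", paste(instruments, collapse = "|"), ")_([0-9]+)$")
  cols <- grep(pat, names(d), value = TRUE)
  if (!length(cols)) stop("no item columns matching <instrument>_<number>")
  pieces <- lapply(cols, function(cn) {
    m <- regmatches(cn, regexec(pat, cn))[[1L]]
    data.frame(subject_id = d$subject_id, instrument = m[2L],
               item = as.integer(m[3L]), response = as.numeric(d[[cn]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out[order(match(out$instrument, instruments), out$item), , drop = FALSE]
}

#' Convert long responses to one wide row per subject
#'
#' Inverse of \code{\link{wide_to_long_responses}}; columns are named
#' \code{<instrument>_<nn>} with two-digit item numbers.
#'
#' @param responses long-format response table.
#' @return wide data.frame, one row per subject.
#' @export
long_to_wide_responses <- function(responses) {
  responses$col <- sprintf("%s_%02d", responses$instrument, responses$item)
  w <- stats::reshape(
    responses[c("subject_id", "col", "response")],
    idvar = "subject_id", timevar = "col", direction = "wide")
  names(w) <- sub("^response\\.", "", names(w))
  rownames(w) <- NULL
  w
}

#' Write a subject-score table to CSV
#'
#' @param scores data.frame of scores (any stage).
#' @param path output path.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
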