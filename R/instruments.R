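#' Instrument specification
#'
#' Describes the fixed structure of a self-report questionnaire: its items,
#' the admissible integer response range, which items are reverse-keyed,
#' which subscales exist (a partition of the items) and which subscale
#' scores are inverted after summation.
#'
#' Item reversal maps a response \eqn{x} on \eqn{[lo, hi]} to \eqn{lo + hi - x};
#' subscale inversion maps a summed score \eqn{s} on \eqn{[LO, HI]} to
#' \eqn{LO + HI - s}. Both are involutions.
#'
#' @param name instrument name, e.g. \code{"UPPS"}.
#' @param items integer vector of item identifiers.
#' @param response_min,response_max inclusive integer response bounds.
#' @param subscales named list; each element the item ids of one subscale.
#'   Must partition \code{items}.
#' @param reverse_items item ids whose responses are reverse-keyed before
#'   summation.
#' @param inverted_subscales subscale names whose summed score is inverted.
#' @return an object of class \code{"instrument_spec"}.
#' @export
instrument_spec <- function(name, items, response_min, response_max,
                            subscales, reverse_items = integer(),
                            inverted_subscales = character()) {
  items <- as.integer(items)
  if (anyDuplicated(items)) stop("duplicate item identifiers in '", name, "'")
  all_sub <- unlist(subscales, use.names = FALSE)
  if (anyDuplicated(all_sub))
    stop("subscales of '", name, "' overlap: items must belong to exactly one subscale")
  if (!setequal(all_sub, items))
    stop("subscales of '", name, "' do not partition its items")
  if (!all(reverse_items %in% items))
    stop("reverse-keyed items not among '", name, "' items")
  if (!all(inverted_subscales %in% names(subscales)))
    stop("unknown inverted subscale for '", name, "'")
  if (response_max <= response_min) stop("degenerate response range")
  structure(
    list(name = name, items = items,
         response_min = as.integer(response_min),
         response_max = as.integer(response_max),
         subscales = lapply(subscales, as.integer),
         reverse_items = as.integer(reverse_items),
         inverted_subscales = inverted_subscales),
    class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("Instrument spec: %s (%d items, responses %d..%d)\n",
              x$name, length(x$items), x$response_min, x$response_max))
  for (s in names(x$subscales)) {
    rng <- subscale_range(x, s)
    cat(sprintf("  %-22s items {%s} score range [%d, %d]%s\n", s,
                paste(x$subscales[[s]], collapse = ","), rng[1], rng[2],
                if (s %in% x$inverted_subscales) " (inverted)" else ""))
  }
  if (length(x$reverse_items))
    cat("  reverse-keyed items:", paste(x$reverse_items, collapse = ","), "\n")
  invisible(x)
}

#' Theoretical score range of a subscale
#'
#' @param spec an \code{instrument_spec}.
#' @param subscale subscale name.
#' @return integer vector \code{c(min, max)} of attainable summed scores.
#' @export
subscale_range <- function(spec, subscale) {
  k <- length(spec$subscales[[subscale]])
  if (k == 0L) stop("unknown subscale: ", subscale)
  c(k * spec$response_min, k * spec$response_max)
}

#' Reverse-key an item response
#'
#' @param x integer response(s).
#' @param lo,hi inclusive response bounds.
#' @return \code{lo + hi - x}.
#' @export
reverse_item <- function(x, lo, hi) lo + hi - x

#' Default instrument specifications
#'
#' The four instruments of the ICT use/abuse battery:
#' \describe{
#'   \item{UPPS}{20-item short UPPS-P impulsivity scale, responses 1..4,
#'     five 4-item subscales (negative urgency, lack of premeditation,
#'     lack of perseverance, sensation seeking, positive urgency), each
#'     scored 4..16. The urgency and sensation-seeking subscale scores are
#'     inverted so all subscales point toward higher impulsivity.}
#'   \item{OCDUS}{12-item obsessive-compulsive use scale adapted to ICT,
#'     responses 1..7, items 6 and 12 reverse-keyed; three factors:
#'     thought interference (6 items), desire control (4 items),
#'     resistance (2 items).}
#'   \item{PSI}{20-item prefrontal symptom inventory screening form,
#'     responses 0..4; three factors plus the total used downstream.}
#'   \item{MULTICAGE}{20 dichotomous items, five 4-item scales screening
#'     problematic use of the Internet, cell phone, videogames, instant
#'     messaging and social networks.}
#' }
#'
#' The published sources give subscale sizes but not item lists for OCDUS
#' and PSI, so the item assignments here are editable defaults: the OCDUS
#' resistance factor is pinned to the two reverse-keyed items \{6, 12\}
#' (the only 2-item factor consistent with its printed 2..14 score range),
#' desire/control to \{8..11\}, thought interference to the remaining six.
#' PSI factor membership affects reporting only; all downstream models use
#' the PSI total.
#'
#' @return named list of \code{instrument_spec} objects
#'   (\code{UPPS}, \code{OCDUS}, \code{PSI}, \code{MULTICAGE}).
#' @export
default_instruments <- function() {
  list(
    UPPS = instrument_spec(
      "UPPS", 1:20, 1, 4,
      subscales = list(
        negative_urgency   = 1:4,
        lack_premeditation = 5:8,
        lack_perseverance  = 9:12,
        sensation_seeking  = 13:16,
        positive_urgency   = 17:20),
      inverted_subscales = c("negative_urgency", "positive_urgency",
                             "sensation_seeking")),
    OCDUS = instrument_spec(
      "OCDUS", 1:12, 1, 7,
      subscales = list(
        thought_interference = c(1:5, 7L),
        desire_control       = 8:11,
        resistance           = c(6L, 12L)),
      reverse_items = c(6L, 12L)),
    PSI = instrument_spec(
      "PSI", 1:20, 0, 4,
      subscales = list(
        behavioral_control = 1:7,
        emotional_control  = 8:14,
        social_behavior    = 15:20)),
    MULTICAGE = instrument_spec(
      "MULTICAGE", 1:20, 0, 1,
      subscales = list(
        internet          = 1:4,
        cell_phone        = 5:8,
        videogames        = 9:12,
        instant_messaging = 13:16,
        social_networks   = 17:20))
  )
}

# canonical column names of the 8 subscales entering the axis
upps_columns <- function() paste0("UPPS_", c("negative_urgency",
  "lack_premeditation", "lack_perseverance", "sensation_seeking",
  "positive_urgency"))

ocdus_columns <- function() paste0("OCDUS_", c("thought_interference",
  "desire_control", "resistance"))

#' Column names of the eight axis subscales
#'
#' The five UPPS and three OCDUS subscale columns, in the order used
#' throughout the pipeline.
#' @return character vector of length 8.
#' @export
axis_columns <- function() c(upps_columns(), ocdus_columns())
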