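#' Histogram of the axis distribution
#'
#' Population histogram of the Impulsivity-Compulsivity axis with the
#' band boundaries at +/-10 and +/-20 marked.
#'
#' @param x an \code{\link{compute_axis}} result.
#' @param breaks passed to \code{hist}.
#' @param ... further arguments to \code{hist}.
#' @return invisibly, the \code{hist} object.
#' @export
plot.axis_result <- function(x, breaks = 30, ...) {
  h <- graphics::hist(x$axis, breaks = breaks,
                      main = "Impulsivity-Compulsivity axis",
                      xlab = "axis (impulsive pole positive)", ...)
  graphics::abline(v = c(-20, -10, 10, 20), lty = c(3, 2, 2, 3),
                   col = "grey40")
  invisible(h)
}

#' Image of a decision-region grid
#'
#' Displays p(compulsive) over the feature plane with the uncertain band
#' around p = 0.5 left white.
#'
#' @param x a \code{\link{decision_region}} result.
#' @param ... further arguments to \code{image}.
#' @return invisibly, \code{x}.
#' @export
plot.decision_region_grid <- function(x, ...) {
  fcols <- attr(x, "feature_cols")
  delta <- attr(x, "delta")
  xs <- sort(unique(x[[1L]])); ys <- sort(unique(x[[2L]]))
  p <- matrix(x$p_compulsive[order(x[[2L]], x[[1L]])],
              nrow = length(xs))
  p[p >= 0.5 - delta & p <= 0.5 + delta] <- NA  # uncertain zone in white
  graphics::image(xs, ys, p, col = grDevices::hcl.colors(64, "Blue-Red"),
                  zlim = c(0, 1), xlab = fcols[1L], ylab = fcols[2L],
                  main = "p(compulsive) decision regions", ...)
  invisible(x)
}
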