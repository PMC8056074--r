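#' Kolmogorov-Smirnov normality gate
#'
#' One-sample KS test of \code{x} against a normal with the sample mean
#' and SD, used only to decide between parametric and nonparametric
#' follow-up tests. Estimating the reference parameters from the same
#' sample makes the classical KS p anti-conservative; set
#' \code{lilliefors = TRUE} for the corrected version.
#'
#' @param x numeric vector, n >= 5.
#' @param lilliefors use the Lilliefors correction
#'   (\code{nortest::lillie.test}) instead of the classical KS p.
#' @return list with \code{statistic}, \code{p}, \code{method} and the
#'   gate verdict \code{normal} (\code{p >= 0.05}). Zero-variance input
#'   returns a non-normal verdict with a warning.
#' @export
ks_normality <- function(x, lilliefors = FALSE) {
  if (length(x) < 5L) stop("need n >= 5 for the normality gate")
  if (stats::sd(x) == 0) {
    warning("zero variance: treated as non-normal")
    return(list(statistic = NA_real_, p = 0, method = "degenerate",
                normal = FALSE))
  }
  res <- if (lilliefors) {
    lt <- nortest::lillie.test(x)
    list(statistic = unname(lt$statistic), p = lt$p.value,
         method = "Lilliefors-corrected KS")
  } else {
    kt <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    list(statistic = unname(kt$statistic), p = kt$p.value,
         method = "one-sample KS, estimated parameters")
  }
  res$normal <- res$p >= 0.05
  res
}

#' Effect-size label for a correlation-type coefficient
#'
#' small for r < 0.30, medium for 0.30 <= r < 0.50, large for r >= 0.50.
#'
#' @param r coefficient magnitude.
#' @return one of \code{"small"}, \code{"medium"}, \code{"large"}.
#' @export
effect_size_label <- function(r) {
  r <- abs(r)
  ifelse(r >= 0.50, "large", ifelse(r >= 0.30, "medium", "small"))
}

#' Mann-Whitney U test with Rosenthal effect size
#'
#' \code{Ux} counts pairs with x > y plus half the ties; the headline
#' statistic is \code{min(Ux, Uy)}. The z approximation uses the
#' tie-corrected variance and a 0.5 continuity correction toward the null
#' mean; the Rosenthal coefficient is \code{|z| / sqrt(n1 + n2)}. Both
#' one- and two-sided normal-approximation p-values are reported.
#'
#' @param x,y numeric samples.
#' @param alternative \code{"two.sided"} (default) or \code{"one.sided"};
#'   selects which p is reported as \code{$p}, both are always returned.
#' @return object of class \code{"group_test_result"}: \code{U},
#'   \code{U_x}, \code{U_y}, \code{n1}, \code{n2}, \code{z},
#'   \code{p_one_sided}, \code{p_two_sided}, \code{p}, \code{sidedness},
#'   \code{rosenthal_r}, \code{effect_size}.
#' @export
mann_whitney_rosenthal <- function(x, y,
                                   alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  rk <- rank(c(x, y))
  R1 <- sum(rk[seq_len(n1)])
  Ux <- R1 - n1 * (n1 + 1) / 2
  Uy <- n1 * n2 - Ux
  U <- min(Ux, Uy)
  mu <- n1 * n2 / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
  # min-side U never exceeds mu, so the continuity correction is +0.5
  z <- if (sigma == 0) 0 else (U - mu + if (U < mu) 0.5 else 0) / sigma
  p1 <- stats::pnorm(z)
  p2 <- min(1, 2 * p1)
  structure(list(U = U, U_x = Ux, U_y = Uy, n1 = n1, n2 = n2, z = z,
                 p_one_sided = p1, p_two_sided = p2,
                 p = if (alternative == "two.sided") p2 else p1,
                 sidedness = alternative,
                 rosenthal_r = abs(z) / sqrt(n),
                 effect_size = effect_size_label(abs(z) / sqrt(n))),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), z = %.3f\n",
              x$U, x$n1, x$n2, x$z))
  cat(sprintf("  p (one-sided) = %.4f, p (two-sided) = %.4f [reported: %s]\n",
              x$p_one_sided, x$p_two_sided, x$sidedness))
  cat(sprintf("  Rosenthal r = %.3f (%s effect)\n", x$rosenthal_r,
              x$effect_size))
  invisible(x)
}

# Gauss hypergeometric 2F1(a, b; c; z) by series, valid here for z in
# [0, 1) with large c (c = n - 1/2); terms computed in log space.
hyp2f1_series <- function(a, b, cc, z, tol = 1e-15, max_terms = 100000L) {
  if (z < 0 || z >= 1) stop("series requires 0 <= z < 1")
  if (z == 0) return(1)
  lterm <- 0; s <- 1
  for (k in seq_len(max_terms)) {
    lterm <- lterm + log(a + k - 1) + log(b + k - 1) - log(cc + k - 1) +
      log(z) - log(k)
    t <- exp(lterm)
    s <- s + t
    if (t < tol * s) return(s)
  }
  stop("2F1 series did not converge")
}

# log density of the sample correlation r given population rho, n
# (bivariate normal; Hotelling's 2F1 form)
log_dcorr <- function(r, rho, n) {
  lgamma(n - 1) - lgamma(n - 0.5) + log(n - 2) - 0.5 * log(2 * pi) +
    ((n - 1) / 2) * log1p(-rho^2) + ((n - 4) / 2) * log1p(-r^2) -
    (n - 1.5) * log1p(-rho * r) +
    log(hyp2f1_series(0.5, 0.5, n - 0.5, (rho * r + 1) / 2))
}

#' Pearson correlation with JZS Bayes factor and credible interval
#'
#' Pearson r with its two-sided p, plus the default
#' Jeffreys-Zellner-Siow Bayes factor BF10 for a nonzero correlation:
#' the exact sampling density of r given rho under the bivariate normal
#' is integrated against a stretched-beta prior on rho (default
#' \code{kappa = 1}, i.e. uniform on (-1, 1)) and divided by the density
#' at rho = 0. The 95\% credible interval is taken from the normalized
#' posterior on a rho grid. Evidence labels: BF10 < 1 none,
#' 1 <= BF10 < 10 weak-to-moderate, >= 10 strong.
#'
#' @param x,y numeric vectors, n >= 4, nonzero variance.
#' @param kappa prior scale of the stretched beta
#'   (\code{Beta(1/kappa, 1/kappa)} stretched to (-1, 1)); default 1.
#' @param ci credible-interval mass (default 0.95).
#' @return object of class \code{"correlation_result"}: \code{r},
#'   \code{n}, \code{p}, \code{bf10}, \code{ci_lower}, \code{ci_upper},
#'   \code{evidence}.
#' @export
pearson_bf10 <- function(x, y, kappa = 1, ci = 0.95) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 4L) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y)
  r <- unname(ct$estimate)
  post <- correlation_posterior(r, n, kappa, ci = ci)
  structure(list(r = r, n = n, p = ct$p.value, bf10 = post$bf10,
                 ci_lower = post$ci[1], ci_upper = post$ci[2],
                 ci_mass = ci,
                 evidence = bf_evidence_label(post$bf10)),
            class = "correlation_result")
}

bf_evidence_label <- function(bf10) {
  ifelse(bf10 >= 10, "strong",
         ifelse(bf10 >= 1, "weak-moderate", "none"))
}

# posterior of rho on a grid + BF10 by adaptive quadrature
correlation_posterior <- function(r, n, kappa = 1, ci = 0.95,
                                  grid_n = 2001L) {
  a <- 1 / kappa
  lprior <- function(rho) stats::dbeta((rho + 1) / 2, a, a, log = TRUE) -
    log(2)
  # near-perfect correlation: likelihood collapses to a spike at r
  if (abs(r) > 1 - 1e-12)
    return(list(bf10 = Inf, ci = c(r, r)))
  l0 <- log_dcorr(r, 0, n)
  # work relative to the likelihood peak so large n cannot overflow
  lmax <- log_dcorr(r, r, n)
  f <- Vectorize(function(rho) exp(log_dcorr(r, rho, n) - lmax +
                                     lprior(rho)))
  marg <- stats::integrate(f, -1, 1, rel.tol = 1e-9,
                           stop.on.error = FALSE)$value
  bf10 <- exp(log(marg) + lmax - l0)
  rho <- seq(-1 + 1e-9, 1 - 1e-9, length.out = grid_n)
  lp <- vapply(rho, function(p) log_dcorr(r, p, n) + lprior(p), 0)
  w <- exp(lp - max(lp))
  cdf <- cumsum(w) / sum(w)
  lo <- rho[which(cdf >= (1 - ci) / 2)[1L]]
  hi <- rho[which(cdf >= 1 - (1 - ci) / 2)[1L]]
  list(bf10 = bf10, ci = c(lo, hi))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "Pearson r = %.3f (n = %d), p = %.4g, BF10 = %.4g [%s evidence]\n",
    x$r, x$n, x$p, x$bf10, x$evidence))
  cat(sprintf("  %g%% credible interval: [%.3f, %.3f]\n", 100 * x$ci_mass,
              x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Compare impulsive vs compulsive band proportions across ICT scales
#'
#' From a band-by-scale percent-frequency table (five bands, five
#' MULTICAGE scales, as produced by \code{\link{band_frequency_table}}),
#' pools the two impulsivity-band rows across the five scales into a
#' 10-value impulsive group and the two compulsivity-band rows into a
#' 10-value compulsive group, and contrasts them with
#' \code{\link{mann_whitney_rosenthal}}.
#'
#' @param freq_table data.frame with a \code{band} column over
#'   \code{\link{band_levels}} and one numeric column per ICT scale.
#' @return list with \code{test} (a \code{group_test_result}) and
#'   \code{impulsive} / \code{compulsive} group summaries
#'   (mean, median, sd, iqr, values).
#' @export
compare_band_proportions <- function(freq_table) {
  if (!"band" %in% names(freq_table) ||
      !setequal(freq_table$band, band_levels()))
    stop("freq_table must contain the five axis bands")
  num_cols <- names(freq_table)[vapply(freq_table, is.numeric, TRUE)]
  if (length(num_cols) < 1L) stop("no numeric scale columns")
  m <- as.matrix(freq_table[match(band_levels(), freq_table$band), num_cols,
                            drop = FALSE])
  if (anyNA(m)) stop("malformed table: missing percentages")
  rownames(m) <- band_levels()
  imp <- as.numeric(m[c("high_impulsivity", "moderate_impulsivity"), ])
  com <- as.numeric(m[c("moderate_compulsivity", "high_compulsivity"), ])
  summarize <- function(v) list(mean = mean(v),
                                median = stats::median(v),
                                sd = stats::sd(v),
                                iqr = stats::IQR(v), values = v)
  list(test = mann_whitney_rosenthal(imp, com),
       impulsive = summarize(imp), compulsive = summarize(com))
}
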