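make_z <- function(upps, ocdus, ids = NULL) {
  n <- if (is.matrix(upps)) nrow(upps) else 1L
  upps <- matrix(upps, nrow = n, ncol = 5)
  ocdus <- matrix(ocdus, nrow = n, ncol = 3)
  d <- data.frame(subject_id = if (is.null(ids)) paste0("s", seq_len(n))
                  else ids)
  d[upps_columns()] <- upps
  d[ocdus_columns()] <- ocdus
  d
}

test_that("axis is 10 x (mean UPPS Z - mean OCDUS Z)", {
  ax <- compute_axis(make_z(c(1, 1, 1, 1, 1), c(0, 0, 0)))
  expect_equal(ax$axis, 10)
  expect_equal(ax$impulsive_component, 1)
  expect_equal(ax$compulsive_component, 0)
  # equal component values cancel exactly
  ax0 <- compute_axis(make_z(rep(0.73, 5), rep(0.73, 3)))
  expect_equal(ax0$axis, 0)
  expect_error(compute_axis(make_z(1, 0)[-2]), "missing residual-Z")
})

test_that("cohort-level axis mean is zero by construction", {
  p <- default_products()
  expect_lt(abs(mean(p$ax$axis)), 1e-8)
})

test_that("band classification follows the +/-10, +/-20 thresholds", {
  expect_equal(as.character(classify_band(c(25, 15, 0, -15, -25))),
               c("high_impulsivity", "moderate_impulsivity", "balance",
                 "moderate_compulsivity", "high_compulsivity"))
  # boundary handling: default keeps balance maximal
  expect_equal(as.character(classify_band(c(-10, 10, -20, 20))),
               c("balance", "balance", "moderate_compulsivity",
                 "moderate_impulsivity"))
  # alternative tie rule pushes boundaries outward
  expect_equal(as.character(classify_band(c(-10, 10, -20, 20),
                                          tie_rule = "moderate")),
               c("moderate_compulsivity", "moderate_impulsivity",
                 "high_compulsivity", "high_impulsivity"))
  expect_error(classify_band(c(1, NA)), "non-finite")
  # monotone: larger axis value never maps to a more compulsive band
  x <- sort(runif(200, -40, 40))
  bands <- as.integer(classify_band(x))   # level 1 = most impulsive
  expect_true(all(diff(bands) <= 0))
})

test_that("axis descriptives match their definitions", {
  sym <- c(-3, -1, 0, 1, 3)
  d <- axis_descriptives(sym)
  expect_equal(d$skewness, 0)
  expect_equal(d$mean, 0)
  expect_true(d$q1 <= d$median && d$median <= d$q3)
  set.seed(21)
  big <- axis_descriptives(rnorm(10000))
  expect_lt(abs(big$skewness), 0.1)
  expect_lt(abs(big$excess_kurtosis), 0.1)
  # higher moments undefined below n = 4
  expect_true(is.na(axis_descriptives(c(1, 2, 3))$skewness))
})

test_that("axis correlates positively with UPPS and negatively with OCDUS", {
  p <- default_products()
  cons <- axis_consistency(p$ax)
  expect_gt(cons$upps$r, 0)
  expect_lt(cons$ocdus$r, 0)
  # degenerate case: constant OCDUS makes the axis proportional to UPPS
  set.seed(22)
  z <- make_z(matrix(rnorm(100 * 5), 100), matrix(0, 100, 3))
  ax <- compute_axis(z)
  expect_equal(cor(ax$axis, ax$impulsive_component), 1)
})

test_that("independent components give the geometric axis-component correlation", {
  set.seed(23)
  n <- 2000
  z <- make_z(matrix(rnorm(n * 5), n), matrix(rnorm(n * 3), n))
  ax <- compute_axis(z)
  r_obs <- pearson_bf10(ax$axis, ax$impulsive_component)$r
  # brute-force empirical oracle
  expect_equal(r_obs, cor(ax$axis, ax$impulsive_component))
  # var(meanU) = 1/5, var(axis/10) = 1/5 + 1/3 under independence
  expect_equal(r_obs, sqrt((1 / 5) / (1 / 5 + 1 / 3)), tolerance = 0.05)
  expect_lt(pearson_bf10(ax$axis, ax$compulsive_component)$r, 0)
})

test_that("axis is invariant to affine rescaling of a raw subscale, end to end", {
  p <- default_products()
  norm2 <- p$norm
  norm2$OCDUS_resistance <- 0.42 * norm2$OCDUS_resistance + 3
  filt2 <- mahalanobis_filter(norm2)
  expect_identical(filt2$retained$subject_id, p$filt$retained$subject_id)
  z2 <- residualize_z(filt2$retained, p$codes)
  ax2 <- compute_axis(z2)
  expect_equal(ax2$axis, p$ax$axis, tolerance = 1e-8)
})

test_that("compute_axis commutes with subject reordering", {
  p <- default_products()
  set.seed(24)
  perm <- sample(nrow(p$z))
  ax2 <- compute_axis(p$z[perm, ])
  expect_equal(ax2$axis[match(p$ax$subject_id, ax2$subject_id)], p$ax$axis)
})

test_that("band frequency columns are percentages that sum to 100", {
  p <- default_products()
  mc <- p$scores[p$scores$subject_id %in% p$ax$subject_id,
                 c("subject_id", grep("^MULTICAGE|^flag_",
                                      names(p$scores), value = TRUE))]
  tab <- band_frequency_table(p$ax, mc, digits = NULL)
  for (s in names(tab)[-1]) expect_equal(sum(tab[[s]]), 100)
  expect_equal(sum(as.integer(table(p$ax$band))), nrow(p$ax))
  # all flagged subjects deeply compulsive -> 100% in the bottom band
  ids <- paste0("s", 1:20)
  axr <- structure(data.frame(subject_id = ids,
                              band = factor("high_compulsivity",
                                            band_levels())),
                   class = c("axis_result", "data.frame"))
  mc0 <- data.frame(subject_id = ids, flag_internet = TRUE,
                    flag_cell_phone = TRUE, flag_videogames = TRUE,
                    flag_instant_messaging = TRUE,
                    flag_social_networks = TRUE)
  tab0 <- band_frequency_table(axr, mc0)
  expect_true(all(tab0[tab0$band == "high_compulsivity", -1] == 100))
  # a scale with no flagged subjects is reported as NA with a warning
  mc0$flag_internet <- FALSE
  expect_warning(tabna <- band_frequency_table(axr, mc0), "internet")
  expect_true(all(is.na(tabna$internet)))
})

test_that("compulsive bands outweigh impulsive bands among flagged subjects", {
  p <- default_products()
  mc <- p$scores[p$scores$subject_id %in% p$ax$subject_id,
                 c("subject_id", grep("^MULTICAGE|^flag_",
                                      names(p$scores), value = TRUE))]
  tab <- band_frequency_table(p$ax, mc)
  for (s in names(tab)[-1]) {
    imp <- sum(tab[[s]][tab$band %in% c("high_impulsivity",
                                        "moderate_impulsivity")])
    com <- sum(tab[[s]][tab$band %in% c("moderate_compulsivity",
                                        "high_compulsivity")])
    expect_gt(com, imp)
  }
})
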