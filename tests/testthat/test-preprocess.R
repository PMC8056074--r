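test_that("chi-square exclusion threshold matches a quadrature oracle", {
  thr <- qchisq(0.999, df = 8)
  expect_equal(thr, 26.12448, tolerance = 1e-5)
  # independent oracle: integrate the chi-square density up to thr
  cdf <- integrate(function(x) dchisq(x, df = 8), 0, thr,
                   rel.tol = 1e-10)$value
  expect_equal(cdf, 0.999, tolerance = 1e-8)
})

test_that("Mahalanobis filter excludes ~0.1-0.4% of clean MVN data", {
  set.seed(11)
  p <- 8; n <- 5000
  Sigma <- 0.4 + diag(0.6, p)
  X <- matrix(rnorm(n * p), n) %*% chol(Sigma)
  d <- data.frame(subject_id = seq_len(n), X)
  names(d)[-1] <- axis_columns()
  res <- mahalanobis_filter(d)
  expect_gte(res$report$exclusion_fraction, 0.001)
  expect_lte(res$report$exclusion_fraction, 0.004)
  expect_equal(nrow(res$retained) + length(res$report$excluded), n)
})

test_that("a planted extreme subject is excluded and the filter is affine-invariant", {
  set.seed(12)
  n <- 300
  X <- matrix(rnorm(n * 8), n)
  X[7, ] <- X[7, ] + 10          # 10 SD shift on every column
  d <- data.frame(subject_id = paste0("s", 1:n), X)
  names(d)[-1] <- axis_columns()
  res <- mahalanobis_filter(d)
  expect_true("s7" %in% res$report$excluded)
  # invariance under an invertible linear map plus shift
  A <- matrix(c(2, 0.5, rep(0, 62)), 8, 8) + diag(8)
  d2 <- d
  d2[axis_columns()] <- as.matrix(d[axis_columns()]) %*% A + 5
  res2 <- mahalanobis_filter(d2)
  expect_equal(res2$report$distance2, res$report$distance2,
               tolerance = 1e-8)
  # exclusion fraction non-increasing as the threshold quantile rises
  f <- sapply(c(0.01, 0.001, 1e-4),
              function(a) mahalanobis_filter(d, alpha = a)$report$exclusion_fraction)
  expect_true(all(diff(f) <= 0))
  # constant column reported by name
  d3 <- d; d3$UPPS_negative_urgency <- 1
  expect_error(mahalanobis_filter(d3), "UPPS_negative_urgency")
})

test_that("0-100 rescaling maps theoretical ranges to percent", {
  raw <- data.frame(subject_id = c("a", "b", "c"),
                    UPPS_negative_urgency = c(7, 16, 10))
  out <- rescale_0_100(raw, columns = "UPPS_negative_urgency")
  expect_equal(out$UPPS_negative_urgency, c(25, 100, 50))
  bad <- data.frame(subject_id = "a", UPPS_negative_urgency = 3)
  expect_error(rescale_0_100(bad, columns = "UPPS_negative_urgency"),
               "outside theoretical range")
})

test_that("residualization yields exact zero-mean unit-SD columns", {
  p <- default_products()
  z <- p$z
  for (cn in axis_columns()) {
    expect_lt(abs(mean(z[[cn]])), 1e-8)
    expect_lt(abs(sd(z[[cn]]) - 1), 1e-8)
  }
})

test_that("residuals match a closed-form normal-equations oracle", {
  scores <- data.frame(
    subject_id = paste0("s", 1:6),
    UPPS_negative_urgency = c(30, 45, 52, 61, 40, 76))
  cov_codes <- data.frame(subject_id = paste0("s", 1:6),
                          age_code = c(1, 2, 2, 3, 5, 6),
                          education_code = c(2, 3, 5, 4, 5, 1))
  z <- residualize_z(scores, cov_codes, columns = "UPPS_negative_urgency")
  X <- cbind(1, cov_codes$age_code, cov_codes$education_code)
  y <- scores$UPPS_negative_urgency
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  expect_equal(z$UPPS_negative_urgency, as.numeric(res / sd(res)),
               tolerance = 1e-10)
})

test_that("residual Z reduces to plain Z when covariates carry no signal", {
  set.seed(13)
  n <- 2000
  scores <- data.frame(subject_id = seq_len(n),
                       UPPS_negative_urgency = rnorm(n, 50, 15))
  cov_codes <- data.frame(subject_id = seq_len(n),
                          age_code = sample(1:6, n, TRUE),
                          education_code = sample(1:5, n, TRUE))
  z <- residualize_z(scores, cov_codes, columns = "UPPS_negative_urgency")
  plain <- scale(scores$UPPS_negative_urgency)[, 1]
  expect_gte(cor(z$UPPS_negative_urgency, plain), 0.99)
})

test_that("residual Z is invariant to positive affine transforms of a column", {
  p <- default_products()
  norm2 <- p$filt$retained
  norm2$UPPS_sensation_seeking <- 3.7 * norm2$UPPS_sensation_seeking + 11
  z2 <- residualize_z(norm2, p$codes)
  expect_equal(z2$UPPS_sensation_seeking, p$z$UPPS_sensation_seeking,
               tolerance = 1e-10)
})

test_that("constant covariates degrade gracefully with warnings", {
  set.seed(14)
  scores <- data.frame(subject_id = 1:50,
                       UPPS_negative_urgency = rnorm(50, 50, 10))
  cc1 <- data.frame(subject_id = 1:50, age_code = 3,
                    education_code = sample(1:5, 50, TRUE))
  expect_warning(z1 <- residualize_z(scores, cc1,
                                     columns = "UPPS_negative_urgency"),
                 "age_code")
  expect_lt(abs(sd(z1$UPPS_negative_urgency) - 1), 1e-8)
  cc2 <- data.frame(subject_id = 1:50, age_code = 3, education_code = 2)
  expect_warning(z2 <- residualize_z(scores, cc2,
                                     columns = "UPPS_negative_urgency"),
                 "constant covariate")
  plain <- scale(scores$UPPS_negative_urgency)[, 1]
  expect_equal(z2$UPPS_negative_urgency, plain, tolerance = 1e-10)
})

test_that("covariate coding follows band order", {
  d <- data.frame(subject_id = 1:3,
                  age_band = c("<18", "31-45", ">60"),
                  education_band = c("primary", "university_student",
                                     "university_degree"))
  cc <- covariate_codes(d)
  expect_equal(cc$age_code, c(1, 4, 6))
  expect_equal(cc$education_code, c(1, 4, 5))
  d$age_band[2] <- "33-45"
  expect_error(covariate_codes(d), "unknown age band")
})
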