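test_that("labeled selection keeps |axis| > 10 and labels by sign", {
  ids <- paste0("s", 1:5)
  axr <- structure(data.frame(subject_id = ids,
                              axis = c(-15, -5, 0, 12, 25)),
                   class = c("axis_result", "data.frame"))
  feats <- data.frame(subject_id = ids, UPPS_total_pct = 50,
                      OCDUS_total_pct = 50)
  lab <- select_labeled(axr, feats)
  expect_equal(nrow(lab), 3)
  expect_equal(as.character(lab$label),
               c("compulsive", "impulsive", "impulsive"))
  expect_equal(attr(lab, "retained_fraction"), 3 / 5)
  axr$axis <- c(-5, 5, 0, 2, -8)
  expect_error(select_labeled(axr, feats), "balance band")
})

test_that("stratified splits hit the rounded 8:2 sizes deterministically", {
  lab <- make_blobs(n = 201, seed = 41)
  sp <- split_train_test(lab, seed = 5)
  expect_length(sp$train, 161)
  expect_length(sp$test, 40)
  expect_setequal(c(sp$train, sp$test), 1:201)
  # stratification keeps class balance in both halves
  tr_tab <- table(lab$label[sp$train])
  expect_equal(unname(tr_tab), round(0.8 * unname(table(lab$label))))
  expect_identical(split_train_test(lab, seed = 5), sp)
  expect_false(identical(split_train_test(lab, seed = 6)$train, sp$train))
  small <- make_blobs(n = 10, seed = 42)
  sp10 <- split_train_test(small)
  expect_length(sp10$train, 8)
  expect_length(sp10$test, 2)
  one_class <- small; one_class$label[] <- "impulsive"
  expect_error(split_train_test(one_class), "both classes")
})

test_that("every family separates clean blobs and the winner is deterministic", {
  lab <- make_blobs(n = 200, seed = 43)
  tour <- suppressWarnings(model_tournament(lab, seed = 2))
  expect_true(all(tour$accuracy$accuracy >= 95))
  expect_true(all(tour$accuracy$accuracy <= 100))
  tour2 <- suppressWarnings(model_tournament(lab, seed = 2))
  expect_identical(tour$winner, tour2$winner)
  expect_identical(tour$split, tour2$split)
})

test_that("permuted labels give chance-level GPC accuracy", {
  set.seed(44)
  accs <- replicate(50, {
    lab <- make_blobs(n = 200, seed = sample.int(1e6, 1))
    lab$label <- sample(lab$label)
    sp <- split_train_test(lab, seed = 1)
    m <- fit_character_model(lab[sp$train, ], "gpc")
    100 * mean(predict(m, lab[sp$test, ], type = "label") ==
                 lab$label[sp$test])
  })
  expect_gt(mean(accs), 40)
  expect_lt(mean(accs), 60)
})

test_that("GPC predictions are invariant to duplication and row order", {
  lab <- make_blobs(n = 80, seed = 45)
  probe <- data.frame(UPPS_total_pct = c(10, 50, 90),
                      OCDUS_total_pct = c(15, 55, 85))
  m1 <- fit_character_model(lab, "gpc")
  m2 <- fit_character_model(lab[rev(seq_len(nrow(lab))), ], "gpc",
                            feature_cols = attr(lab, "feature_cols"))
  expect_equal(predict(m1, probe), predict(m2, probe), tolerance = 1e-6)
  dup <- rbind(lab, lab)
  attr(dup, "feature_cols") <- attr(lab, "feature_cols")
  m3 <- fit_character_model(dup, "gpc",
                            feature_cols = attr(lab, "feature_cols"))
  expect_equal(predict(m1, probe, type = "label"),
               predict(m3, probe, type = "label"))
})

test_that("GPC separates the calibrated cohort and maps sane decision regions", {
  g <- default_gpc()
  acc <- 100 * mean(predict(g$model, g$labeled[g$split$test, ],
                            type = "label") ==
                      g$labeled$label[g$split$test])
  expect_gte(acc, 75)
  grid <- g$grid
  expect_true(all(grid$p_compulsive >= 0 & grid$p_compulsive <= 1))
  # high OCDUS is never impulsive, mirroring the published reading
  high_ocdus <- grid[grid$OCDUS_total_pct > 70, ]
  expect_true(all(high_ocdus$zone != "impulsive"))
  expect_true(is.finite(attr(grid, "unconditional_compulsive_above")))
  # delta = 0 empties the uncertain zone
  g0 <- decision_region(g$model, resolution = 21, delta = 0)
  expect_false(any(g0$zone == "uncertain"))
})

test_that("p(compulsive) rises with OCDUS within the training support", {
  g <- default_gpc()
  grid <- g$grid
  max_tr <- max(g$labeled$OCDUS_total_pct[g$split$train]) # support edge
  for (u in c(20, 40, 60)) {
    col <- grid[grid$UPPS_total_pct == u &
                  grid$OCDUS_total_pct <= max_tr, ]
    p <- col$p_compulsive[order(col$OCDUS_total_pct)]
    # non-decreasing up to small GP wiggle, with a large overall rise
    expect_true(all(diff(p) > -0.01))
    expect_gt(p[length(p)] - p[1], 0.5)
  }
})

test_that("a linear decision boundary distills to near-zero curvature", {
  set.seed(46)
  n <- 400
  x1 <- runif(n, 0, 100); x2 <- runif(n, 0, 100)
  # true boundary: x2 = 60 - 0.2 x1, with logistic noise
  p <- plogis((x2 - (60 - 0.2 * x1)) / 4)
  lab <- data.frame(UPPS_total_pct = x1, OCDUS_total_pct = x2,
                    label = factor(ifelse(runif(n) < p, "compulsive",
                                          "impulsive"),
                                   c("impulsive", "compulsive")))
  m <- fit_character_model(lab, "logistic",
                           feature_cols = c("UPPS_total_pct",
                                            "OCDUS_total_pct"))
  rule <- distill_quadratic_rule(decision_region(m), m, lab)
  expect_lt(abs(rule$f1[3]), 1e-3)
  expect_lt(abs(rule$f2[3]), 1e-3)
  expect_gt(rule$agreement, 80)
})

test_that("the distilled quadratic rule tracks its GPC on the calibrated cohort", {
  g <- default_gpc()
  rule <- distill_quadratic_rule(g$grid, g$model, g$labeled)
  expect_gte(rule$agreement, 75)
  expect_lte(rule$agreement, 100)
  # f1 stays below f2 across the feature range
  xs <- seq(0, 100, 1)
  qe <- function(cf, x) cf[1] + cf[2] * x + cf[3] * x^2
  expect_true(all(qe(rule$f1, xs) <= qe(rule$f2, xs)))
  # agreement is reproducible from the persisted grid
  rule2 <- distill_quadratic_rule(g$grid, g$model, g$labeled)
  expect_identical(rule, rule2)
})

test_that("classify_subject returns labels, probabilities and zones in order", {
  g <- default_gpc()
  deep <- data.frame(UPPS_total_pct = c(25, 60), OCDUS_total_pct = c(55, 5))
  res <- classify_subject(g$model, deep)
  expect_equal(res$label, c("compulsive", "impulsive"))
  expect_gt(res$p_compulsive[1], 0.9)
  expect_lt(res$p_compulsive[2], 0.1)
  rule <- distill_quadratic_rule(g$grid, g$model, g$labeled)
  rr <- classify_subject(rule, deep)
  expect_equal(rr$zone[1], "compulsive")
  expect_equal(rr$zone[2], "impulsive")
  # a rule-uncertain pair sits between the curves
  qe <- function(cf, x) cf[1] + cf[2] * x + cf[3] * x^2
  mid <- data.frame(UPPS_total_pct = 50,
                    OCDUS_total_pct = (qe(rule$f1, 50) + qe(rule$f2, 50)) / 2)
  expect_equal(classify_subject(rule, mid)$zone, "uncertain")
  expect_error(classify_subject(g$model,
                                data.frame(UPPS_total_pct = 120,
                                           OCDUS_total_pct = 10)),
               "\\[0, 100\\]")
  # batch order preserved
  set.seed(47)
  batch <- data.frame(UPPS_total_pct = runif(10, 0, 100),
                      OCDUS_total_pct = runif(10, 0, 100))
  rb <- classify_subject(g$model, batch)
  expect_equal(nrow(rb), 10)
  expect_equal(rb$p_compulsive, predict(g$model, batch))
})
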