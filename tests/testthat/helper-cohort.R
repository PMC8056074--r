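# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# calibrated default cohort (n = 800, seed 42) and its pipeline products
default_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generate_cohort(cohort_config(n_subjects = 800,
                                                      seed = 42))
  .fixtures$cohort
}

default_products <- function() {
  if (is.null(.fixtures$products)) {
    co <- default_cohort()
    scores <- score_cohort(co$responses)
    norm <- rescale_0_100(scores)
    filt <- mahalanobis_filter(norm)
    codes <- covariate_codes(co$demographics)
    z <- residualize_z(filt$retained, codes)
    ax <- compute_axis(z)
    .fixtures$products <- list(cohort = co, scores = scores, norm = norm,
                               filt = filt, codes = codes, z = z, ax = ax,
                               feats = character_features(scores))
  }
  .fixtures$products
}

# fitted GPC on the default cohort's UPPS/OCDUS features
default_gpc <- function() {
  if (is.null(.fixtures$gpc)) {
    p <- default_products()
    lab <- select_labeled(p$ax, p$feats)
    sp <- split_train_test(lab, seed = 7)
    m <- fit_character_model(lab[sp$train, ], "gpc",
                             feature_cols = attr(lab, "feature_cols"))
    .fixtures$gpc <- list(labeled = lab, split = sp, model = m,
                          grid = decision_region(m))
  }
  .fixtures$gpc
}

# long-format response table from a named list of per-item responses
make_responses <- function(..., subject_id = "s1") {
  resp <- list(...)
  do.call(rbind, lapply(names(resp), function(inst) {
    data.frame(subject_id = subject_id, instrument = inst,
               item = seq_along(resp[[inst]]), response = resp[[inst]],
               stringsAsFactors = FALSE)
  }))
}

# exhaustive Mann-Whitney pair counting (independent oracle)
brute_force_u <- function(x, y) {
  ux <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  min(ux, length(x) * length(y) - ux)
}

# two well-separated Gaussian blobs on the feature plane
make_blobs <- function(n = 200, centers = c(20, 80), sd = 5, seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  lab <- rep(c("impulsive", "compulsive"), c(half, n - half))
  mu <- ifelse(lab == "impulsive", centers[1], centers[2])
  d <- data.frame(
    UPPS_total_pct = pmin(pmax(stats::rnorm(n, mu, sd), 0), 100),
    OCDUS_total_pct = pmin(pmax(stats::rnorm(n, mu, sd), 0), 100),
    label = factor(lab, levels = c("impulsive", "compulsive")))
  attr(d, "feature_cols") <- c("UPPS_total_pct", "OCDUS_total_pct")
  class(d) <- c("labeled_subjects", "data.frame")
  d
}
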