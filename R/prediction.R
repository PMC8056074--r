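#' Total-score features on the percent scale
#'
#' Builds the two feature pairs used by the character classifiers from a
#' raw score table: UPPS total (sum of the five scored subscales, range
#' 20-80), OCDUS total (range 12-84) and PSI total (range 0-80) expressed
#' as percent of their theoretical ranges, plus the MULTICAGE total
#' percent.
#'
#' @param scores raw-stage score table from \code{\link{score_cohort}}.
#' @return data.frame with \code{subject_id}, \code{UPPS_total_pct},
#'   \code{OCDUS_total_pct}, \code{PSI_total_pct},
#'   \code{MULTICAGE_total_pct}.
#' @export
character_features <- function(scores) {
  upps <- rowSums(scores[, upps_columns(), drop = FALSE])
  ocdus <- rowSums(scores[, ocdus_columns(), drop = FALSE])
  data.frame(
    subject_id = scores$subject_id,
    UPPS_total_pct = (upps - 20) / 60 * 100,
    OCDUS_total_pct = (ocdus - 12) / 72 * 100,
    PSI_total_pct = scores$PSI_total / 80 * 100,
    MULTICAGE_total_pct = scores$MULTICAGE_total_pct,
    stringsAsFactors = FALSE)
}

#' Select labeled (non-balance) subjects for character modelling
#'
#' Keeps subjects with |axis| > 10, labels them impulsive (axis > +10) or
#' compulsive (axis < -10) and attaches the requested feature pair;
#' balance-band subjects are excluded.
#'
#' @param axis_result output of \code{\link{compute_axis}}.
#' @param features output of \code{\link{character_features}} (or any
#'   table with \code{subject_id} and the feature columns).
#' @param feature_cols the two feature column names.
#' @return data.frame of class \code{"labeled_subjects"} with
#'   \code{subject_id}, \code{label} (factor impulsive/compulsive), the
#'   two feature columns, and attributes \code{retained_fraction} /
#'   \code{feature_cols}.
#' @export
select_labeled <- function(axis_result, features,
                           feature_cols = c("UPPS_total_pct",
                                            "OCDUS_total_pct")) {
  stopifnot(length(feature_cols) == 2L,
            all(feature_cols %in% names(features)))
  d <- merge(as.data.frame(axis_result)[c("subject_id", "axis")],
             features[, c("subject_id", feature_cols)],
             by = "subject_id", sort = FALSE)
  keep <- abs(d$axis) > 10
  if (!any(keep)) stop("no subjects outside the balance band")
  out <- d[keep, c("subject_id", feature_cols)]
  out$label <- factor(ifelse(d$axis[keep] > 10, "impulsive", "compulsive"),
                      levels = c("impulsive", "compulsive"))
  rownames(out) <- NULL
  attr(out, "retained_fraction") <- mean(keep)
  attr(out, "feature_cols") <- feature_cols
  class(out) <- c("labeled_subjects", "data.frame")
  out
}

#' Stratified train/test split
#'
#' Random partition stratified by label; the training size is
#' \code{round(ratio * n)} overall, allocated per class proportionally.
#'
#' @param labeled a \code{\link{select_labeled}} result (>= 10 rows, both
#'   classes present).
#' @param ratio training fraction (default 0.8).
#' @param seed integer seed for the partition.
#' @return list with integer row indices \code{train} and \code{test}
#'   (disjoint, exhaustive).
#' @export
split_train_test <- function(labeled, ratio = 0.8, seed = 1) {
  n <- nrow(labeled)
  if (n < 10L) stop("need at least 10 labeled subjects")
  if (nlevels(droplevels(labeled$label)) < 2L)
    stop("both classes must be present")
  n_train <- round(ratio * n)
  set.seed(as.integer(seed))
  cls <- split(seq_len(n), labeled$label)
  take <- vapply(cls, function(ix) round(ratio * length(ix)), 0)
  # proportional rounding can miss the overall target by one; fix on the
  # largest class
  while (sum(take) != n_train) {
    j <- which.max(lengths(cls) - take)
    take[j] <- take[j] + sign(n_train - sum(take))
  }
  train <- unlist(mapply(function(ix, k) sample(ix, k), cls, take,
                         SIMPLIFY = FALSE), use.names = FALSE)
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Fit a two-feature character classifier
#'
#' Supported families: \code{"gpc"} (Gaussian process classification,
#' RBF kernel, Laplace approximation via \pkg{kernlab}), \code{"logistic"}
#' (binomial GLM), \code{"knn"} (k-nearest neighbours), \code{"svm"}
#' (RBF support vector machine), \code{"tree"} (CART), and \code{"lm"}
#' (least squares on the 0/1 label, thresholded at 0.5 — a linear
#' classifier included for completeness of the tournament).
#'
#' For the GPC, \code{length_scale = NULL} (default) sets the RBF kernel
#' width from the median pairwise distance of the training features — a
#' deterministic, permutation-invariant stand-in for marginal-likelihood
#' kernel optimization; pass a number to fix the length scale exactly.
#'
#' @param train data.frame with the two feature columns and \code{label}.
#' @param family model family (see above).
#' @param feature_cols the two feature column names; default taken from
#'   the \code{labeled_subjects} attribute.
#' @param length_scale RBF length scale for the GPC (NULL = median
#'   heuristic).
#' @param k neighbours for KNN (default 5).
#' @return object of class \code{"character_model"}.
#' @export
fit_character_model <- function(train,
    family = c("gpc", "logistic", "knn", "svm", "tree", "lm"),
    feature_cols = attr(train, "feature_cols"),
    length_scale = NULL, k = 5L) {
  family <- match.arg(family)
  if (is.null(feature_cols))
    stop("feature_cols must be given (or present as attribute)")
  if (nlevels(droplevels(train$label)) < 2L)
    stop("training data must contain both classes")
  X <- as.matrix(train[, feature_cols])
  y <- factor(train$label, levels = c("impulsive", "compulsive"))
  fit <- switch(family,
    gpc = {
      ls <- if (is.null(length_scale)) median_length_scale(X) else length_scale
      kernlab::gausspr(X, y, kernel = "rbfdot", scaled = FALSE,
                       kpar = list(sigma = 1 / (2 * ls^2)))
    },
    logistic = {
      d <- data.frame(y = y, X)
      stats::glm(y ~ ., data = d, family = stats::binomial())
    },
    knn = list(X = X, y = y, k = as.integer(k)),
    svm = e1071::svm(X, y, kernel = "radial"),
    tree = {
      d <- data.frame(y = y, X)
      rpart::rpart(y ~ ., data = d, method = "class")
    },
    lm = {
      d <- data.frame(y01 = as.numeric(y == "compulsive"), X)
      stats::lm(y01 ~ ., data = d)
    })
  structure(list(family = family, fit = fit, feature_cols = feature_cols,
                 length_scale = if (family == "gpc") {
                   if (is.null(length_scale)) median_length_scale(X)
                   else length_scale
                 } else NULL,
                 n_train = nrow(train)),
            class = "character_model")
}

median_length_scale <- function(X) {
  d <- stats::dist(X)
  stats::median(d[d > 0])
}

#' @export
print.character_model <- function(x, ...) {
  cat(sprintf("Character classifier: family = %s, features = (%s), n = %d\n",
              x$family, paste(x$feature_cols, collapse = ", "), x$n_train))
  if (!is.null(x$length_scale))
    cat(sprintf("  RBF length scale: %.2f\n", x$length_scale))
  invisible(x)
}

#' Predict compulsive-class probabilities or labels
#'
#' @param object a \code{\link{fit_character_model}} result.
#' @param newdata data.frame containing the model's feature columns.
#' @param type \code{"prob"} for p(compulsive), \code{"label"} for hard
#'   labels at the 0.5 threshold.
#' @param ... unused.
#' @return numeric vector of probabilities, or a factor of labels.
#' @export
predict.character_model <- function(object, newdata,
                                    type = c("prob", "label"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  p <- switch(object$family,
    gpc = kernlab::predict(object$fit, X, type = "probabilities")[, "compulsive"],
    logistic = as.numeric(stats::predict(object$fit,
                                         as.data.frame(X), type = "response")),
    knn = {
      pr <- class::knn(object$fit$X, X, object$fit$y, k = object$fit$k,
                       prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "compulsive", win, 1 - win)
    },
    svm = {
      dv <- attr(stats::predict(object$fit, X, decision.values = TRUE),
                 "decision.values")[, 1]
      # decision values are signed margins for the first level
      # (impulsive); map to a monotone pseudo-probability
      stats::plogis(-dv)
    },
    tree = stats::predict(object$fit, as.data.frame(X))[, "compulsive"],
    lm = pmin(pmax(as.numeric(stats::predict(object$fit,
                                             as.data.frame(X))), 0), 1))
  if (type == "prob") unname(p)
  else factor(ifelse(p >= 0.5, "compulsive", "impulsive"),
              levels = c("impulsive", "compulsive"))
}

#' Model tournament over a common split
#'
#' Fits each family on the same stratified training split and scores
#' test-set accuracy (percent). Winner is the highest accuracy, ties
#' broken deterministically by family name. A family that fails to fit is
#' recorded with \code{NA} accuracy.
#'
#' @param labeled a \code{\link{select_labeled}} result.
#' @param families families to race (default all six).
#' @param seed split seed.
#' @param ratio training fraction.
#' @return list with \code{accuracy} (data.frame family/accuracy),
#'   \code{winner}, \code{split}, \code{models}.
#' @export
model_tournament <- function(labeled,
    families = c("lm", "logistic", "knn", "gpc", "svm", "tree"),
    seed = 1, ratio = 0.8) {
  sp <- split_train_test(labeled, ratio = ratio, seed = seed)
  train <- labeled[sp$train, , drop = FALSE]
  test <- labeled[sp$test, , drop = FALSE]
  fcols <- attr(labeled, "feature_cols")
  models <- list(); acc <- rep(NA_real_, length(families))
  for (i in seq_along(families)) {
    fam <- families[i]
    m <- tryCatch(fit_character_model(train, fam, feature_cols = fcols),
                  error = function(e) e)
    if (inherits(m, "error")) { models[[fam]] <- m; next }
    models[[fam]] <- m
    pred <- predict(m, test, type = "label")
    acc[i] <- 100 * mean(pred == test$label)
  }
  tab <- data.frame(family = families, accuracy = acc,
                    stringsAsFactors = FALSE)
  ok <- tab[!is.na(tab$accuracy), ]
  winner <- ok$family[order(-ok$accuracy, ok$family)][1L]
  list(accuracy = tab, winner = winner, split = sp, models = models)
}

#' Decision-region grid over the feature plane
#'
#' Evaluates p(compulsive) on a rectangular grid over the 0-100 x 0-100
#' feature plane and labels each cell impulsive
#' (p < 0.5 - delta), compulsive (p > 0.5 + delta) or uncertain.
#'
#' @param model a fitted \code{\link{fit_character_model}}.
#' @param resolution grid points per feature (default 101, i.e. unit
#'   steps).
#' @param delta half-width of the uncertain probability band
#'   (default 0.1).
#' @return data.frame of class \code{"decision_region_grid"} with the two
#'   feature columns, \code{p_compulsive} and \code{zone}; attribute
#'   \code{unconditional_compulsive_above} gives the lowest second-feature
#'   level above which no grid cell is impulsive at any first-feature
#'   value (NA when none).
#' @export
decision_region <- function(model, resolution = 101L, delta = 0.1) {
  stopifnot(delta >= 0, delta < 0.5)
  g <- seq(0, 100, length.out = resolution)
  grid <- expand.grid(x1 = g, x2 = g)
  names(grid) <- model$feature_cols
  p <- predict(model, grid, type = "prob")
  zone <- ifelse(p < 0.5 - delta, "impulsive",
                 ifelse(p > 0.5 + delta, "compulsive", "uncertain"))
  out <- cbind(grid, p_compulsive = p, zone = zone)
  # lowest level of the second feature above which impulsivity never wins
  by_level <- tapply(zone != "impulsive", grid[[2L]], all)
  lv <- as.numeric(names(by_level))
  ok <- rev(cumprod(rev(by_level))) > 0  # all levels from here up clear
  attr(out, "unconditional_compulsive_above") <-
    if (any(ok)) min(lv[ok]) else NA_real_
  attr(out, "delta") <- delta
  attr(out, "feature_cols") <- model$feature_cols
  class(out) <- c("decision_region_grid", "data.frame")
  out
}

#' Distill the GPC boundary into a quadratic decision rule
#'
#' Extracts the p = 0.5 - delta and p = 0.5 + delta probability contours
#' of a decision-region grid (first crossing in the second feature,
#' linearly interpolated, per first-feature column) and least-squares
#' fits each contour as a quadratic \code{x2 = c0 + c1 x1 + c2 x1^2}.
#' The rule: above the upper curve compulsive, below the lower curve
#' impulsive, between them abstain (uncertain). When the two fitted
#' quadratics cross, the maximum violation is split symmetrically across
#' the two intercepts so the lower curve stays below the upper one.
#'
#' @param grid a \code{\link{decision_region}} result.
#' @param model the GPC the grid came from (for the agreement figure).
#' @param labeled labeled subjects on which agreement is scored;
#'   abstentions count against agreement.
#' @return object of class \code{"quadratic_boundary"}: coefficient
#'   triples \code{f1} (lower) and \code{f2} (upper), \code{delta}, and
#'   \code{agreement} (percent, NA when \code{model}/\code{labeled} not
#'   supplied).
#' @export
distill_quadratic_rule <- function(grid, model = NULL, labeled = NULL) {
  delta <- attr(grid, "delta")
  fcols <- attr(grid, "feature_cols")
  contour_points <- function(level) {
    xs <- sort(unique(grid[[1L]]))
    pts <- lapply(xs, function(x) {
      col <- grid[grid[[1L]] == x, ]
      col <- col[order(col[[2L]]), ]
      p <- col$p_compulsive
      cross <- which(p[-1] >= level & p[-length(p)] < level)
      if (!length(cross)) return(NULL)
      i <- cross[1L]
      y <- col[[2L]][i] + (level - p[i]) / (p[i + 1] - p[i]) *
        (col[[2L]][i + 1] - col[[2L]][i])
      c(x, y)
    })
    do.call(rbind, pts)
  }
  lo <- contour_points(0.5 - delta)
  hi <- contour_points(0.5 + delta)
  if (is.null(lo) || is.null(hi) || nrow(lo) < 3L || nrow(hi) < 3L)
    stop("degenerate model: probability contours absent from the grid")
  qfit <- function(m) unname(stats::coef(
    stats::lm(m[, 2] ~ m[, 1] + I(m[, 1]^2))))
  f1 <- qfit(lo); f2 <- qfit(hi)
  xs <- seq(0, 100, by = 1)
  qeval <- function(cf, x) cf[1] + cf[2] * x + cf[3] * x^2
  viol <- max(0, max(qeval(f1, xs) - qeval(f2, xs)))
  if (viol > 0) {
    f1[1] <- f1[1] - viol / 2
    f2[1] <- f2[1] + viol / 2
  }
  agreement <- NA_real_
  if (!is.null(model) && !is.null(labeled)) {
    x1 <- labeled[[fcols[1L]]]; x2 <- labeled[[fcols[2L]]]
    rule <- ifelse(x2 > qeval(f2, x1), "compulsive",
                   ifelse(x2 < qeval(f1, x1), "impulsive", "uncertain"))
    gpc_label <- as.character(predict(model, labeled, type = "label"))
    agreement <- 100 * mean(rule == gpc_label)
  }
  structure(list(f1 = f1, f2 = f2, delta = delta, feature_cols = fcols,
                 agreement = agreement),
            class = "quadratic_boundary")
}

#' @export
print.quadratic_boundary <- function(x, ...) {
  fm <- function(cf) sprintf("%.3f %+.4f x %+.6f x^2", cf[1], cf[2], cf[3])
  cat("Quadratic boundary rule on (", paste(x$feature_cols, collapse = ", "),
      ")\n", sep = "")
  cat("  lower f1(x):", fm(x$f1), "\n  upper f2(x):", fm(x$f2), "\n")
  cat(sprintf("  rule: above f2 compulsive, below f1 impulsive, else abstain\n"))
  if (!is.na(x$agreement))
    cat(sprintf("  agreement with GPC hard labels: %.1f%%\n", x$agreement))
  invisible(x)
}

#' Classify a subject from a fitted model or distilled rule
#'
#' @param object a \code{character_model} or \code{quadratic_boundary}.
#' @param features data.frame (or named vector) with the object's feature
#'   columns, values in [0, 100].
#' @param delta uncertain-zone half width used for the zone label when
#'   \code{object} is a model (default 0.1).
#' @return data.frame with \code{label}, \code{p_compulsive} (NA for the
#'   distilled rule) and \code{zone}, one row per input row, in input
#'   order.
#' @export
classify_subject <- function(object, features, delta = 0.1) {
  if (!is.data.frame(features)) features <- as.data.frame(as.list(features))
  fcols <- object$feature_cols
  if (!all(fcols %in% names(features)))
    stop("features must contain: ", paste(fcols, collapse = ", "))
  vals <- as.matrix(features[, fcols])
  if (any(vals < 0 | vals > 100))
    stop("features must lie in [0, 100]")
  if (inherits(object, "character_model")) {
    p <- predict(object, features, type = "prob")
    zone <- ifelse(p < 0.5 - delta, "impulsive",
                   ifelse(p > 0.5 + delta, "compulsive", "uncertain"))
    data.frame(label = ifelse(p >= 0.5, "compulsive", "impulsive"),
               p_compulsive = p, zone = zone, stringsAsFactors = FALSE)
  } else if (inherits(object, "quadratic_boundary")) {
    qeval <- function(cf, x) cf[1] + cf[2] * x + cf[3] * x^2
    x1 <- vals[, 1L]; x2 <- vals[, 2L]
    zone <- ifelse(x2 > qeval(object$f2, x1), "compulsive",
                   ifelse(x2 < qeval(object$f1, x1), "impulsive",
                          "uncertain"))
    data.frame(label = ifelse(zone == "uncertain", NA_character_, zone),
               p_compulsive = NA_real_, zone = zone,
               stringsAsFactors = FALSE)
  } else stop("unsupported classifier object")
}
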