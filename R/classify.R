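#' Fit a per-feature standardizer on training data and apply it
#'
#' z-scores every feature with mean and standard deviation estimated on the
#' training rows only; the test rows are transformed with the training
#' parameters, so no test information leaks into the scaling.  Zero-variance
#' features are mapped to 0 and recorded.
#'
#' @param train,test numeric matrices (rows = sites).  `test` may be `NULL`.
#' @return list with `train`, `test`, `center`, `scale` and
#'   `constant_features` (indices scaled to zero).
#' @export
standardize_fit_apply <- function(train, test = NULL) {
  train <- as.matrix(train)
  stopifnot(nrow(train) >= 1)
  ctr <- colMeans(train)
  # population (1/n) standard deviation, the usual convention for scalers
  sd_ <- sqrt(colMeans(sweep(train, 2, ctr)^2))
  constant <- which(sd_ == 0 | is.na(sd_))
  scl <- sd_
  scl[constant] <- 1
  ztr <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  ztr[, constant] <- 0
  zte <- NULL
  if (!is.null(test)) {
    test <- as.matrix(test)
    zte <- sweep(sweep(test, 2, ctr), 2, scl, "/")
    zte[, constant] <- 0
  }
  list(
    train = ztr, test = zte, center = ctr, scale = scl,
    constant_features = constant
  )
}

#' Univariate feature selection by class separation
#'
#' Ranks features by the magnitude of the two-sample Welch t statistic
#' between the classes, computed on the training fold only, and returns the
#' top `k` indices (rank order).  Features that separate the classes
#' perfectly with zero within-class variance rank first.
#'
#' @param train feature matrix (rows = sites).
#' @param labels factor or character vector of two classes.
#' @param k number of features to keep.
#' @return integer vector of `k` feature indices, strongest first.
#' @export
select_features <- function(train, labels, k) {
  train <- as.matrix(train)
  stopifnot(k >= 1, k <= ncol(train))
  labels <- as.factor(labels)
  lv <- levels(droplevels(labels))
  stopifnot(length(lv) == 2)
  a <- train[labels == lv[1], , drop = FALSE]
  b <- train[labels == lv[2], , drop = FALSE]
  ma <- colMeans(a)
  mb <- colMeans(b)
  va <- apply(a, 2, stats::var) / nrow(a)
  vb <- apply(b, 2, stats::var) / nrow(b)
  den <- sqrt(va + vb)
  tt <- abs(ma - mb) / den
  tt[den == 0] <- ifelse(abs(ma - mb)[den == 0] > 0, Inf, 0)
  order(tt, decreasing = TRUE)[seq_len(k)]
}

#' Build a repeated stratified cross-validation plan
#'
#' For every repeat, each class's sites are shuffled and dealt round-robin
#' into the folds, so per-fold class counts differ from perfect
#' stratification by at most one site and every site is tested exactly once
#' per repeat.  With `group_by_patient = TRUE`, whole patients are dealt
#' instead of sites (no patient straddles a fold boundary).
#'
#' @param labels class label per site.
#' @param patient_ids optional patient id per site.
#' @param n_folds,n_repeats folds and repeats (defaults 5 and 5).
#' @param seed integer; the plan is deterministic given the seed.
#' @param group_by_patient fold by patient rather than by site.
#' @return object of class `cv_plan`: list with `folds` (sites x repeats
#'   integer matrix of fold ids), `n_folds`, `n_repeats`, `seed`.
#' @export
make_cv_plan <- function(labels, patient_ids = NULL, n_folds = 5,
                         n_repeats = 5, seed = 1, group_by_patient = FALSE) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (!group_by_patient && any(table(labels) < n_folds)) {
    stop("every class needs at least n_folds sites")
  }
  folds <- matrix(0L, n, n_repeats)
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      if (group_by_patient) {
        stopifnot(!is.null(patient_ids))
        pats <- unique(patient_ids)
        pf <- sample(rep_len(seq_len(n_folds), length(pats)))
        folds[, r] <- pf[match(patient_ids, pats)]
      } else {
        offset <- 0L
        for (cl in levels(labels)) {
          idx <- which(labels == cl)
          idx <- idx[sample.int(length(idx))]
          f <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
          folds[idx, r] <- f
          # rotate the dealing start so fold sizes stay balanced across classes
          offset <- (offset + length(idx)) %% n_folds
        }
      }
    }
  })
  structure(
    list(
      folds = folds, n_folds = as.integer(n_folds),
      n_repeats = as.integer(n_repeats), seed = as.integer(seed),
      group_by_patient = group_by_patient
    ),
    class = "cv_plan"
  )
}

#' Classifier specification
#'
#' Four families are available: `"xgb"` (gradient-boosted trees with the
#' exact split finder; step-size shrinkage 0.3 and maximum tree depth 6 by
#' default), `"gbt_hist"` (gradient-boosted trees with histogram split
#' finding and leaf-wise growth), `"mlp"` (single-hidden-layer perceptron)
#' and `"svm"` (RBF-kernel support vector machine with probability
#' calibration).
#'
#' @param family one of `"xgb"`, `"gbt_hist"`, `"mlp"`, `"svm"`.
#' @param ... family-specific hyperparameter overrides (validated against the
#'   family's defaults).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("xgb", "gbt_hist", "mlp", "svm"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    xgb = list(eta = 0.3, max_depth = 6, nrounds = 100),
    gbt_hist = list(eta = 0.1, max_leaves = 31, nrounds = 100),
    mlp = list(size = 32, decay = 1e-3, maxit = 200),
    svm = list(cost = 1, kernel = "radial")
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    stop("unknown hyperparameters for family '", family, "': ",
         paste(bad, collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(
    list(family = family, hyper = defaults),
    class = "classifier_spec"
  )
}

#' Fit one classifier on standardized training features
#'
#' @param x standardized feature matrix.
#' @param y factor with levels `normal`, `tumor` (tumor is the positive
#'   class).
#' @param spec a [classifier_spec()].
#' @param seed seed for stochastic fitting components.
#' @return fitted model wrapper of class `drs_model`.
#' @export
fit_classifier <- function(x, y, spec = classifier_spec("xgb"), seed = 1) {
  y <- as.factor(y)
  y01 <- as.numeric(y == "tumor")
  hp <- spec$hyper
  fit <- with_seed(seed, switch(spec$family,
    xgb = xgboost::xgb.train(
      params = list(
        objective = "binary:logistic", eta = hp$eta,
        max_depth = hp$max_depth, tree_method = "exact", nthread = 1
      ),
      data = xgboost::xgb.DMatrix(x, label = y01),
      nrounds = hp$nrounds, verbose = 0
    ),
    gbt_hist = xgboost::xgb.train(
      params = list(
        objective = "binary:logistic", eta = hp$eta,
        tree_method = "hist", grow_policy = "lossguide",
        max_leaves = hp$max_leaves, max_depth = 0, nthread = 1
      ),
      data = xgboost::xgb.DMatrix(x, label = y01),
      nrounds = hp$nrounds, verbose = 0
    ),
    mlp = nnet::nnet(
      x = x, y = y01, size = hp$size, decay = hp$decay, maxit = hp$maxit,
      entropy = TRUE, trace = FALSE, MaxNWts = 100000
    ),
    svm = e1071::svm(
      x = x, y = y, cost = hp$cost, kernel = hp$kernel, probability = TRUE
    )
  ))
  structure(list(fit = fit, spec = spec), class = "drs_model")
}

#' Tumor probability scores from a fitted model
#'
#' @param model a `drs_model`.
#' @param x standardized feature matrix.
#' @return numeric vector of tumor probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, x) {
  x <- as.matrix(x)
  switch(model$spec$family,
    xgb = ,
    gbt_hist = stats::predict(model$fit, xgboost::xgb.DMatrix(x)),
    mlp = as.vector(stats::predict(model$fit, x)),
    svm = {
      pr <- attr(
        stats::predict(model$fit, x, probability = TRUE), "probabilities"
      )
      as.vector(pr[, "tumor"])
    }
  )
}

fold_metrics <- function(truth, prob, threshold = 0.5) {
  pred <- ifelse(prob >= threshold, "tumor", "normal")
  tp <- sum(pred == "tumor" & truth == "tumor")
  tn <- sum(pred == "normal" & truth == "normal")
  fp <- sum(pred == "tumor" & truth == "normal")
  fn <- sum(pred == "normal" & truth == "tumor")
  auc <- if (length(unique(truth)) < 2) {
    NA_real_
  } else {
    as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = prob,
      levels = c("normal", "tumor"), direction = "<", quiet = TRUE
    )))
  }
  c(
    accuracy = 100 * (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    auc = 100 * auc
  )
}

#' Repeated stratified cross-validation of a classifier
#'
#' For every fold of every repeat: standardize on the training sites, select
#' the top `k_features` features on the training sites, fit, and score the
#' held-out sites.  Scaling and feature selection are refit inside each
#' training fold, so no test information leaks.  Metrics (accuracy,
#' sensitivity, specificity, AUC, all in percent, tumor = positive class)
#' are aggregated as mean and standard deviation over all
#' `n_folds * n_repeats` test folds.
#'
#' @param dataset a `spectra_dataset` (see [process_spectra()]).
#' @param spec a [classifier_spec()].
#' @param plan a [cv_plan][make_cv_plan()]; defaults to 5 folds x 5 repeats
#'   with the plan seed.
#' @param k_features features kept per fold (default 100; capped at the
#'   grid size).
#' @param seed base seed for stochastic fits.
#' @return object of class `evaluation_report`: `summary` (data frame of
#'   mean and sd per metric), `per_fold` (raw per-fold metrics) and `meta`.
#' @export
run_cv <- function(dataset, spec = classifier_spec("xgb"), plan = NULL,
                   k_features = 100, seed = 1) {
  x <- dataset$features
  y <- droplevels(dataset$labels)
  if (is.null(plan)) {
    plan <- make_cv_plan(y, dataset$patient_id, seed = seed)
  }
  k_features <- min(k_features, ncol(x))
  rows <- list()
  for (r in seq_len(plan$n_repeats)) {
    for (f in seq_len(plan$n_folds)) {
      te <- which(plan$folds[, r] == f)
      tr <- which(plan$folds[, r] != f)
      sc <- standardize_fit_apply(x[tr, , drop = FALSE], x[te, , drop = FALSE])
      sel <- select_features(sc$train, y[tr], k_features)
      model <- fit_classifier(
        sc$train[, sel, drop = FALSE], y[tr], spec,
        seed = plan$seed * 1000 + r * 10 + f
      )
      prob <- predict_prob(model, sc$test[, sel, drop = FALSE])
      m <- fold_metrics(as.character(y[te]), prob)
      if (is.na(m["auc"])) {
        warning(sprintf(
          "repeat %d fold %d has a single-class test fold; AUC undefined",
          r, f
        ))
      }
      rows[[length(rows) + 1]] <- data.frame(
        repeat_ = r, fold = f, t(m)
      )
    }
  }
  per_fold <- do.call(rbind, rows)
  metrics <- c("accuracy", "sensitivity", "specificity", "auc")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_fold[[m]], na.rm = TRUE), 0),
    sd = vapply(metrics, function(m) stats::sd(per_fold[[m]], na.rm = TRUE), 0)
  )
  rownames(summary) <- NULL
  structure(
    list(
      summary = summary,
      per_fold = per_fold,
      meta = list(
        family = spec$family, hyper = spec$hyper,
        n_folds = plan$n_folds, n_repeats = plan$n_repeats,
        k_features = k_features, seed = plan$seed,
        cv_unit = if (plan$group_by_patient) "patient" else "site"
      )
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report: %s, %d folds x %d repeats>\n",
    x$meta$family, x$meta$n_folds, x$meta$n_repeats
  ))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %6.2f +/- %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Train a classifier on a full dataset for live scoring
#'
#' Standardizer and feature selection are fit on the whole dataset; the
#' returned object scores individual spectra via [predict_site()].
#'
#' @inheritParams run_cv
#' @return object of class `trained_classifier`.
#' @export
train_classifier <- function(dataset, spec = classifier_spec("xgb"),
                             k_features = 100, seed = 1) {
  x <- dataset$features
  y <- droplevels(dataset$labels)
  k_features <- min(k_features, ncol(x))
  sc <- standardize_fit_apply(x)
  sel <- select_features(sc$train, y, k_features)
  model <- fit_classifier(sc$train[, sel, drop = FALSE], y, spec, seed = seed)
  structure(
    list(
      model = model, center = sc$center, scale = sc$scale,
      features = sel, grid = dataset$grid
    ),
    class = "trained_classifier"
  )
}

#' Tumor probability of a single site spectrum
#'
#' @param trained a [train_classifier()] result.
#' @param features reflectance values on the classifier's wavelength grid
#'   (vector or one-row matrix).
#' @return tumor probability in `[0, 1]`; values at or above 0.5 are labeled
#'   tumor on screen.
#' @export
predict_site <- function(trained, features) {
  features <- matrix(as.numeric(features), nrow = 1)
  if (ncol(features) != length(trained$grid)) {
    stop("feature grid mismatch: expected ", length(trained$grid), " values")
  }
  z <- (features - matrix(trained$center, 1)) / matrix(trained$scale, 1)
  z[!is.finite(z)] <- 0
  unname(predict_prob(trained$model, z[, trained$features, drop = FALSE]))
}
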