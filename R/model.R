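#' Classifier configuration
#'
#' Default hyperparameters of the gradient-boosted LOH classifier. They are
#' deliberately conservative (halved subsampling, raised minimum child
#' weight) to limit overfitting on cohort-scale training sets; no
#' hyperparameter search is performed.
#'
#' @param max_depth maximum tree depth (default 5).
#' @param eta learning rate (default 0.3).
#' @param subsample row subsampling per boosting round (default 0.5).
#' @param min_child_weight minimum hessian per leaf (default 2).
#' @param max_delta_step maximum delta step (default 0).
#' @param n_estimators number of boosting rounds (default 100).
#' @param probability_threshold probability at or above which a locus is
#'   called LOH, before the secondary checks (default 0.5).
#' @param as_ratio_max secondary check: the allele-specific depth ratio must
#'   be below this for an LOH call (default 0.98).
#' @param adjusted_baf_min secondary check: the adjusted BAF must exceed this
#'   (default 0.02).
#' @param biallelic_ratio,biallelic_frac bi-allelic rule: both alleles are
#'   deleted when the retained allele's per-bin normalized depth ratio is
#'   below \code{biallelic_ratio} in at least \code{biallelic_frac} of bins
#'   (defaults 0.5 and 0.25).
#' @return list of class \code{loh_config}.
#' @export
loh_config <- function(max_depth = 5, eta = 0.3, subsample = 0.5,
                       min_child_weight = 2, max_delta_step = 0,
                       n_estimators = 100, probability_threshold = 0.5,
                       as_ratio_max = 0.98, adjusted_baf_min = 0.02,
                       biallelic_ratio = 0.5, biallelic_frac = 0.25) {
  structure(list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, subsample = subsample,
                 min_child_weight = min_child_weight,
                 max_delta_step = max_delta_step,
                 n_estimators = n_estimators,
                 probability_threshold = probability_threshold,
                 as_ratio_max = as_ratio_max,
                 adjusted_baf_min = adjusted_baf_min,
                 biallelic_ratio = biallelic_ratio,
                 biallelic_frac = biallelic_frac),
            class = "loh_config")
}

model_matrix_from_formula <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (is.factor(y)) y <- as.numeric(y) - 1
  x <- as.matrix(mf[, setdiff(colnames(mf), all.vars(formula[[2]])), drop = FALSE])
  storage.mode(x) <- "double"
  list(x = x, y = y)
}

#' Fit the gradient-boosted HLA LOH classifier
#'
#' Trains an XGBoost binary-logistic model on per-locus feature vectors.
#' The standard features are the seven in \code{FEATURE_NAMES}; any numeric
#' feature set works through the formula interface.
#'
#' @param formula model formula, e.g. \code{loh ~ .}; the response must be
#'   binary (logical, 0/1 or two-level factor with the positive class last).
#' @param data data.frame of features plus the response column.
#' @param config \code{loh_config}.
#' @param seed integer seed controlling the subsampling RNG; the same seed
#'   and data reproduce the model bit for bit.
#' @return Object of class \code{loh_model} with components
#'   \code{booster_raw} (serialized trees), \code{feature_names},
#'   \code{config}, \code{seed}, \code{n}, \code{prevalence}, \code{call}.
#' @seealso [predict.loh_model()], [call_locus()], [cross_validate()]
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(fixture_params(n_loci = 120, seed = 7))
#' fit <- loh_model(loh ~ ., data = cohort$features, seed = 1)
#' print(fit)
#' }
#' @export
loh_model <- function(formula = loh ~ ., data, config = loh_config(),
                      seed = 1L) {
  mm <- model_matrix_from_formula(formula, data)
  if (length(unique(mm$y)) < 2L) {
    stop("training labels contain a single class; need both LOH and no-LOH loci")
  }
  if (anyNA(mm$x)) stop("training features contain NA; drop no-call loci first")
  dtrain <- xgboost::xgb.DMatrix(mm$x, label = mm$y)
  params <- list(objective = config$objective, max_depth = config$max_depth,
                 eta = config$eta, subsample = config$subsample,
                 min_child_weight = config$min_child_weight,
                 max_delta_step = config$max_delta_step,
                 nthread = 1, seed = as.integer(seed))
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$n_estimators, verbose = 0)
  cache <- new.env(parent = emptyenv())
  cache$booster <- booster
  structure(list(booster_raw = xgboost::xgb.save.raw(booster),
                 feature_names = colnames(mm$x),
                 config = config, seed = as.integer(seed),
                 n = nrow(mm$x), prevalence = mean(mm$y),
                 call = match.call(), cache = cache),
            class = "loh_model")
}

# The serialized raw vector is the source of truth (it survives saveRDS);
# the live handle is cached per object to avoid re-deserializing on every
# prediction.
booster_of <- function(object) {
  if (is.null(object$cache) || is.null(object$cache$booster)) {
    b <- xgboost::xgb.load.raw(object$booster_raw)
    if (!is.null(object$cache)) object$cache$booster <- b
    return(b)
  }
  object$cache$booster
}

#' @export
print.loh_model <- function(x, ...) {
  cat("Gradient-boosted HLA LOH classifier\n")
  cat(sprintf("  trained on %d loci (prevalence %.1f%%), %d features, %d rounds\n",
              x$n, 100 * x$prevalence, length(x$feature_names),
              x$config$n_estimators))
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.loh_model <- function(object, ...) {
  imp <- feature_importances(object)
  structure(list(model = object, importances = imp),
            class = "summary.loh_model")
}

#' @export
print.summary.loh_model <- function(x, ...) {
  print(x$model)
  cat("  gain-based feature importances:\n")
  for (i in seq_len(nrow(x$importances))) {
    cat(sprintf("    %-18s %.3f\n", x$importances$feature[i],
                x$importances$gain[i]))
  }
  invisible(x)
}

#' Predict LOH probabilities for feature vectors
#'
#' @param object \code{loh_model}.
#' @param newdata data.frame containing the model's feature columns.
#' @param type "prob" for raw probabilities, "class" for thresholded 0/1
#'   calls (post-hoc secondary checks are applied by [call_locus()], not
#'   here).
#' @param ... unused.
#' @return Numeric vector of probabilities or 0/1 calls.
#' @export
predict.loh_model <- function(object, newdata,
                              type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  p <- stats::predict(booster_of(object), xgboost::xgb.DMatrix(x))
  if (type == "class") as.numeric(p >= object$config$probability_threshold)
  else p
}

#' Gain-based feature importances
#' @param object \code{loh_model}.
#' @return data.frame with \code{feature} and \code{gain} (normalized to sum
#'   to 1), descending.
#' @export
feature_importances <- function(object) {
  stopifnot(inherits(object, "loh_model"))
  imp <- xgboost::xgb.importance(model = booster_of(object))
  out <- data.frame(feature = imp$Feature, gain = imp$Gain / sum(imp$Gain))
  out[order(-out$gain), , drop = FALSE]
}

#' @export
plot.loh_model <- function(x, ...) {
  imp <- feature_importances(x)
  graphics::barplot(rev(imp$gain), names.arg = rev(imp$feature), horiz = TRUE,
                    las = 1, xlab = "normalized gain",
                    main = "Feature importances", ...)
  invisible(imp)
}

#' Save / load a fitted classifier
#'
#' The archive stores the serialized tree ensemble together with the feature
#' order, configuration and seed, so a reloaded model reproduces predictions
#' bit for bit.
#'
#' @param object \code{loh_model}.
#' @param path file path (.rds archive).
#' @return \code{write_loh_model} returns the path invisibly;
#'   \code{read_loh_model} returns the model.
#' @export
write_loh_model <- function(object, path) {
  stopifnot(inherits(object, "loh_model"))
  object$cache <- NULL  # live booster handle is rebuilt from booster_raw
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_loh_model
#' @export
read_loh_model <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "loh_model"))
  obj$cache <- new.env(parent = emptyenv())
  obj
}

#' Binary classification metrics
#'
#' Sensitivity, specificity, F1, AUROC and AUPRC for probability scores
#' against binary truth. AUROC uses the trapezoidal rank statistic; AUPRC is
#' the step-function integral of precision over recall.
#'
#' @param truth 0/1 (or logical) truth labels.
#' @param prob predicted probabilities.
#' @param threshold decision threshold for sensitivity/specificity/F1.
#' @return Named numeric vector. Sensitivity (or specificity) is NA when no
#'   positive (or negative) truth is present; AUROC/AUPRC are NA for
#'   single-class truth.
#' @export
classification_metrics <- function(truth, prob, threshold = 0.5) {
  truth <- as.numeric(truth)
  pred <- as.numeric(prob >= threshold)
  tp <- sum(pred == 1 & truth == 1); fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0); fp <- sum(pred == 1 & truth == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  if (length(unique(truth)) == 2L) {
    auroc <- as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE,
                                            direction = "<")))
    auprc <- auprc(truth, prob)
  } else {
    auroc <- NA_real_
    auprc <- NA_real_
  }
  c(sensitivity = sens, specificity = spec, f1 = f1,
    auroc = auroc, auprc = auprc)
}

# Area under the precision-recall curve by step integration over descending
# score thresholds.
auprc <- function(truth, prob) {
  o <- order(prob, decreasing = TRUE)
  truth <- as.numeric(truth)[o]
  tp <- cumsum(truth)
  precision <- tp / seq_along(truth)
  recall <- tp / sum(truth)
  sum(precision * c(recall[1], diff(recall)))
}

#' k-fold cross-validation of the LOH classifier
#'
#' Partitions loci into k folds (each locus held out exactly once), trains on
#' the remaining folds and scores the held-out predictions. Metrics are
#' reported per fold and pooled over all held-out predictions.
#'
#' @param data feature data.frame including the response.
#' @param formula model formula (default \code{loh ~ .}).
#' @param k number of folds (default 10).
#' @param config \code{loh_config}.
#' @param seed master seed; fold assignment and per-fold training seeds
#'   derive from it.
#' @return Object of class \code{loh_cv}: list with \code{pooled} (named
#'   metric vector), \code{per_fold} (data.frame; folds holding a single
#'   truth class have NA for the undefined metrics), \code{fold} (fold id
#'   per row of \code{data}), \code{prob} (held-out probabilities),
#'   \code{truth}, \code{seed}.
#' @export
cross_validate <- function(data, formula = loh ~ ., k = 10,
                           config = loh_config(), seed = 1L) {
  stopifnot(k >= 2)
  n <- nrow(data)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  prob <- rep(NA_real_, n)
  response <- all.vars(formula[[2]])
  truth <- as.numeric(data[[response]])
  for (f in seq_len(k)) {
    hold <- fold == f
    fit <- loh_model(formula, data[!hold, , drop = FALSE], config,
                     seed = seed + f)
    prob[hold] <- predict(fit, data[hold, , drop = FALSE])
  }
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    m <- classification_metrics(truth[fold == f], prob[fold == f],
                                config$probability_threshold)
    data.frame(fold = f, t(m))
  }))
  pooled <- classification_metrics(truth, prob, config$probability_threshold)
  structure(list(pooled = pooled, per_fold = per_fold, fold = fold,
                 prob = prob, truth = truth, seed = seed, k = k),
            class = "loh_cv")
}

#' @export
print.loh_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation over %d loci (pooled held-out):\n",
              x$k, length(x$truth)))
  m <- x$pooled
  cat(sprintf("  sensitivity %.3f  specificity %.3f  F1 %.3f  AUROC %.3f  AUPRC %.3f\n",
              m["sensitivity"], m["specificity"], m["f1"], m["auroc"],
              m["auprc"]))
  invisible(x)
}

#' Comparator baselines for parity studies
#'
#' Cross-validated pooled metrics for simple alternatives (logistic
#' regression, and — when the optional packages are installed — a radial
#' support-vector machine and k-nearest-neighbours), plus per-feature
#' threshold classifiers swept over each single feature. These are evaluation
#' aids, not part of the calling path.
#'
#' @param data feature data.frame including the binary \code{loh} response.
#' @param k folds (default 10).
#' @param seed seed for fold assignment.
#' @return data.frame of pooled metrics, one row per method.
#' @export
evaluate_baselines <- function(data, k = 10, seed = 1L) {
  set.seed(seed)
  n <- nrow(data)
  fold <- sample(rep(seq_len(k), length.out = n))
  truth <- as.numeric(data$loh)
  feats <- setdiff(names(data), "loh")
  x <- as.matrix(data[, feats, drop = FALSE])

  cv_prob <- function(fit_fun) {
    p <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      hold <- fold == f
      p[hold] <- fit_fun(x[!hold, , drop = FALSE], truth[!hold],
                         x[hold, , drop = FALSE])
    }
    p
  }
  rows <- list()
  p_glm <- cv_prob(function(xtr, ytr, xte) {
    df <- data.frame(y = ytr, xtr)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    suppressWarnings(stats::predict(fit, data.frame(xte), type = "response"))
  })
  rows$logistic <- classification_metrics(truth, p_glm)
  if (requireNamespace("e1071", quietly = TRUE)) {
    p_svm <- cv_prob(function(xtr, ytr, xte) {
      fit <- e1071::svm(xtr, factor(ytr), probability = TRUE)
      attr(stats::predict(fit, xte, probability = TRUE),
           "probabilities")[, "1"]
    })
    rows$svm <- classification_metrics(truth, p_svm)
  }
  if (requireNamespace("class", quietly = TRUE)) {
    p_knn <- cv_prob(function(xtr, ytr, xte) {
      kn <- class::knn(xtr, xte, factor(ytr), k = 5, prob = TRUE)
      pr <- attr(kn, "prob")
      ifelse(kn == "1", pr, 1 - pr)
    })
    rows$knn <- classification_metrics(truth, p_knn)
  }
  # single-feature threshold sweeps (direction chosen by AUROC)
  for (f in feats) {
    v <- data[[f]]
    if (length(unique(v)) < 2L) next
    a <- as.numeric(pROC::auc(pROC::roc(truth, v, quiet = TRUE,
                                        direction = "<")))
    score <- if (a >= 0.5) v else -v
    thr <- stats::quantile(score, probs = seq(0.02, 0.98, by = 0.02))
    f1s <- vapply(thr, function(t0)
      classification_metrics(truth, as.numeric(score >= t0), 0.5)["f1"], 0)
    best <- thr[which.max(f1s)]
    rows[[paste0("feature:", f)]] <-
      classification_metrics(truth, as.numeric(score >= best), 0.5)
  }
  out <- data.frame(method = names(rows), do.call(rbind, rows),
                    row.names = NULL)
  out
}
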