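# Per-property supervised learning: G-mean fold metrics, leakage-safe
# stratified cross-validation (vector space, reducer and sampler are fitted
# on the training folds only), grid search ranked by median G-mean with
# dispersion/skewness tie-breaks, and final SVM model fitting.

# Stratified fold assignment: within each class, indices are shuffled (under
# the caller's RNG state) and folds assigned cyclically, so every fold
# preserves the class ratio within rounding.
make_stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) > 1L) idx <- sample(idx)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Confusion counts and G-mean of one validation fold
#'
#' Sensitivity is TP / (TP + FN), specificity TN / (TN + FP), and the
#' G-mean their geometric mean: the model-selection score under class
#' imbalance (a class that is fully missed zeroes the score even when the
#' other class is perfect).
#'
#' @param predictions Binary 0/1 vector.
#' @param truth Binary 0/1 vector of the same length, containing at least
#'   one positive and one negative.
#' @return A \code{tfsumr_fold_result}: list with \code{counts} (tp, tn,
#'   fp, fn), \code{sensitivity}, \code{specificity}, \code{gmean}.
#' @export
fold_metrics <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth differ in length", call. = FALSE)
  }
  if (!any(truth == 1) || !any(truth == 0)) {
    stop("truth must contain both classes", call. = FALSE)
  }
  tp <- sum(predictions == 1 & truth == 1)
  tn <- sum(predictions == 0 & truth == 0)
  fp <- sum(predictions == 1 & truth == 0)
  fn <- sum(predictions == 0 & truth == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(counts = list(tp = tp, tn = tn, fp = fp, fn = fn),
                 sensitivity = sens, specificity = spec,
                 gmean = sqrt(sens * spec)),
            class = "tfsumr_fold_result")
}

#' Training configuration for one property classifier
#'
#' @param representation A \code{tfsumr_repr_config}.
#' @param reducer A \code{tfsumr_reducer_config}.
#' @param sampler A \code{tfsumr_sampler_config}.
#' @param kernel SVM kernel: \code{"linear"}, \code{"rbf"} or
#'   \code{"poly"}.
#' @param C Misclassification cost (positive).
#' @param gamma Kernel coefficient for rbf/poly; \code{"auto"} means
#'   1 / n_features.
#' @param degree Polynomial degree (>= 2), required for and only used by
#'   the poly kernel.
#' @param class_weighting \code{"off"} or \code{"balanced"} (rescales the
#'   misclassification penalty of each class by the inverse class
#'   frequency).
#' @return A \code{tfsumr_train_config}.
#' @export
train_config <- function(representation = representation_config(),
                         reducer = reducer_config("NONE"),
                         sampler = sampler_config("NONE"),
                         kernel = c("linear", "rbf", "poly"),
                         C = 1, gamma = "auto", degree = NULL,
                         class_weighting = c("off", "balanced")) {
  kernel <- match.arg(kernel)
  class_weighting <- match.arg(class_weighting)
  if (!is.numeric(C) || C <= 0) stop("C must be positive", call. = FALSE)
  if (kernel == "poly") {
    if (!is_count(degree, 2L)) stop("poly kernel requires degree >= 2", call. = FALSE)
    degree <- as.integer(degree)
  } else {
    degree <- NULL
  }
  if (!identical(gamma, "auto") && !(is.numeric(gamma) && gamma > 0)) {
    stop("gamma must be positive or \"auto\"", call. = FALSE)
  }
  structure(list(representation = representation, reducer = reducer,
                 sampler = sampler, kernel = kernel, C = C, gamma = gamma,
                 degree = degree, class_weighting = class_weighting),
            class = "tfsumr_train_config")
}

# Fit the SVM stage of a configuration on a (possibly reduced, sampled)
# matrix.  Returns the e1071 fit plus everything needed to predict.
fit_svm_stage <- function(X, y, config) {
  yf <- factor(y, levels = c(0, 1))
  cw <- NULL
  if (config$class_weighting == "balanced") {
    tab <- table(yf)
    cw <- as.numeric(length(y) / (2 * tab))
    names(cw) <- names(tab)
  }
  gamma <- if (identical(config$gamma, "auto")) 1 / max(1L, ncol(X)) else config$gamma
  kern <- switch(config$kernel, linear = "linear", rbf = "radial", poly = "polynomial")
  args <- list(x = as.matrix(X), y = yf, kernel = kern, cost = config$C,
               gamma = gamma, scale = FALSE)
  if (!is.null(cw)) args$class.weights <- cw
  if (config$kernel == "poly") args$degree <- config$degree
  do.call(e1071::svm, args)
}

# Decision values oriented so that positive values favour class "1".
svm_decision <- function(fit, X) {
  pr <- stats::predict(fit, as.matrix(X), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  vals <- as.numeric(dv[, 1])
  if (identical(colnames(dv)[1], "0/1")) vals <- -vals
  vals
}

# Fit the full representation -> reduction -> sampling -> SVM chain on a
# training set of annotated sentences.  `feats` are precomputed feature
# multisets for the same config (an optimization for CV loops).
fit_chain <- function(sentences, y, config, feats = NULL) {
  if (length(unique(y)) < 2L) stop("training data has a single class", call. = FALSE)
  if (is.null(feats)) feats <- sentence_features(sentences, config$representation)
  space <- fit_vector_space(feats, config$representation)
  X <- vectorize(feats, space)
  red <- reduce_features(X, labels = y, reducer = config$reducer)
  keep <- apply_sampler(red$matrix, y, config$sampler)
  svm_fit <- fit_svm_stage(red$matrix[keep, , drop = FALSE], y[keep], config)
  list(space = space, reduction = red$transform, svm_fit = svm_fit,
       sampled_idx = keep)
}

predict_chain <- function(chain, config, sentences, feats = NULL) {
  if (is.null(feats)) feats <- sentence_features(sentences, config$representation)
  X <- vectorize(feats, chain$space)
  Xr <- apply_reduction(chain$reduction, X)
  as.integer(svm_decision(chain$svm_fit, Xr) > 0)
}

#' Leakage-safe stratified cross-validation
#'
#' Folds preserve the class ratio of the full dataset within rounding.  For
#' every iteration the whole chain — vector space, reducer, under-sampler
#' and SVM — is fitted on the training folds only and evaluated on the
#' untouched validation fold, so under-sampling never sees or alters
#' validation rows; the union of validation folds is the dataset.
#'
#' @param sentences List of annotated sentences.
#' @param y Binary 0/1 labels, one per sentence.
#' @param k Number of folds (default 10); requires at least \code{k}
#'   positives.
#' @param config A \code{tfsumr_train_config}.
#' @param seed Integer master seed for fold assignment and samplers.
#' @return List of per-fold results; each extends
#'   \code{\link{fold_metrics}} output with \code{val_idx} (validation row
#'   indices) and \code{train_idx_sampled} (training rows retained after
#'   under-sampling, as indices into the full dataset).
#' @export
stratified_cv <- function(sentences, y, k = 10L, config, seed = 1L) {
  if (!is_count(k, 2L)) stop("k must be an integer >= 2", call. = FALSE)
  if (sum(y == 1) < k) stop("fewer positives than folds", call. = FALSE)
  set.seed(seed)
  folds <- make_stratified_folds(y, k)
  feats <- sentence_features(sentences, config$representation)
  out <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f); va <- which(folds == f)
    chain <- fit_chain(sentences[tr], y[tr], config, feats = feats[tr])
    pred <- predict_chain(chain, config, sentences[va], feats = feats[va])
    res <- fold_metrics(pred, y[va])
    res$val_idx <- va
    res$train_idx_sampled <- tr[chain$sampled_idx]
    out[[f]] <- res
  }
  out
}

# Median / IQR / adjusted Fisher-Pearson skewness of fold G-means.
cv_summary <- function(fold_results) {
  g <- vapply(fold_results, `[[`, numeric(1), "gmean")
  list(median = stats::median(g),
       iqr = stats::IQR(g),
       skewness = sample_skewness(g),
       gmeans = g)
}

#' Grid search over training configurations
#'
#' Every configuration is scored by \code{\link{stratified_cv}} and ranked
#' by highest median G-mean, breaking ties by lower interquartile range,
#' then lower absolute skewness, then grid order — selecting the most
#' consistent model, not merely the best median.
#'
#' @param sentences List of annotated sentences.
#' @param y Binary 0/1 labels.
#' @param grid Non-empty list of \code{tfsumr_train_config}s.
#' @param k Folds for the inner cross-validation.
#' @param seed Master seed (same fold assignment for every configuration).
#' @return A \code{tfsumr_grid_result}: list with \code{ranking} (data
#'   frame: config index, median, iqr, skewness, rank), \code{configs},
#'   \code{cv} (per-config fold results), \code{best} (top config).
#' @export
grid_search <- function(sentences, y, grid, k = 10L, seed = 1L) {
  if (!length(grid)) stop("grid must be non-empty", call. = FALSE)
  summaries <- vector("list", length(grid))
  cvs <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cvs[[i]] <- stratified_cv(sentences, y, k = k, config = grid[[i]], seed = seed)
    summaries[[i]] <- cv_summary(cvs[[i]])
  }
  med <- vapply(summaries, `[[`, numeric(1), "median")
  iqr <- vapply(summaries, `[[`, numeric(1), "iqr")
  skw <- abs(vapply(summaries, `[[`, numeric(1), "skewness"))
  ord <- rank_configs(med, iqr, skw)
  ranking <- data.frame(config = seq_along(grid), median_gmean = med,
                        iqr = iqr, abs_skewness = skw)[ord, ]
  ranking$rank <- seq_len(nrow(ranking))
  structure(list(ranking = ranking, configs = grid, cv = cvs,
                 best = grid[[ord[1]]], best_index = ord[1]),
            class = "tfsumr_grid_result")
}

#' Model-selection ordering over cross-validation summaries
#'
#' The selection rule behind \code{\link{grid_search}}: highest median
#' G-mean first; ties broken by lower interquartile range, then lower
#' absolute skewness, then original order.
#'
#' @param median_gmean,iqr,abs_skewness Numeric vectors, one entry per
#'   configuration.
#' @return Integer permutation putting the best configuration first.
#' @export
rank_configs <- function(median_gmean, iqr, abs_skewness = rep(0, length(iqr))) {
  order(-median_gmean, iqr, abs(abs_skewness), seq_along(median_gmean))
}

#' Build a grid of training configurations
#'
#' Crosses the supplied axes into a list of \code{tfsumr_train_config}s.
#' Defaults cover the package's standard search space; any axis can be
#' overridden (or narrowed) for speed.
#'
#' @param combos,weightings,ngram_max Representation axes.
#' @param reducers List of \code{tfsumr_reducer_config}s.
#' @param samplers List of \code{tfsumr_sampler_config}s.
#' @param kernels,C,gamma,degree,class_weighting SVM axes.
#' @return List of configurations.
#' @export
make_grid <- function(combos = repr_combos,
                      weightings = repr_weightings,
                      ngram_max = 1L,
                      reducers = list(reducer_config("NONE")),
                      samplers = list(sampler_config("NONE")),
                      kernels = "linear",
                      C = c(0.1, 1, 10, 100),
                      gamma = "auto",
                      degree = 2L,
                      class_weighting = "off") {
  grid <- list()
  for (combo in combos) for (w in weightings) for (ng in ngram_max)
    for (ri in seq_along(reducers)) for (si in seq_along(samplers))
      for (kern in kernels) for (cc in C) for (cw in class_weighting) {
        gms <- if (kern %in% c("rbf", "poly")) gamma else list("auto")
        dgs <- if (kern == "poly") degree else list(NULL)
        for (gm in gms) for (dg in dgs) {
          grid[[length(grid) + 1L]] <- train_config(
            representation = representation_config(combo, ng, w),
            reducer = reducers[[ri]], sampler = samplers[[si]],
            kernel = kern, C = cc, gamma = gm, degree = dg,
            class_weighting = cw)
        }
      }
  grid
}

#' Fit the final classifier for one TF property
#'
#' Fits the full chain (representation, reduction, under-sampling, SVM) on
#' the complete dataset under one configuration.
#'
#' @param sentences List of annotated sentences.
#' @param y Binary 0/1 labels (1 = sentence describes the property).
#' @param config A \code{tfsumr_train_config}.
#' @param property The property label the model predicts.
#' @param seed Master seed (recorded in the model; drives the sampler).
#' @param cv CV summary to record (optional, e.g. from
#'   \code{\link{grid_search}}).
#' @return A \code{tfsumr_property_model}.
#' @export
fit_property_model <- function(sentences, y, config, property = NA_character_,
                               seed = 1L, cv = NULL) {
  if (!is.na(property)) check_property_labels(property)
  if (length(unique(y)) < 2L) stop("dataset has a single class", call. = FALSE)
  set.seed(seed)
  chain <- fit_chain(sentences, y, config)
  structure(list(property = property, config = config, space = chain$space,
                 reduction = chain$reduction, svm_fit = chain$svm_fit,
                 seed = as.integer(seed), cv_summary = cv),
            class = "tfsumr_property_model")
}

#' Predict property membership for annotated sentences
#'
#' A sentence is positive iff the SVM decision value exceeds 0.  Applying
#' all six property models to the same sentences yields a multi-label
#' assignment.
#'
#' @param model A fitted \code{tfsumr_property_model}.
#' @param sentences List of annotated sentences.
#' @return Integer 0/1 vector, one entry per sentence.
#' @export
predict_labels <- function(model, sentences) {
  if (!inherits(model, "tfsumr_property_model")) {
    stop("model is not a fitted property model", call. = FALSE)
  }
  if (!length(sentences)) return(integer())
  predict_chain(model, model$config, sentences)
}

#' Save / load a property model
#'
#' Serialization round-trips the fitted vector space, reduction transform,
#' SVM weights and configuration.
#'
#' @param model A \code{tfsumr_property_model}.
#' @param path File path (.rds).
#' @return \code{path} (write) or the model (read).
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)
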