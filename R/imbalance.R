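# Majority-class under-sampling.  Labels are binary with 1 = positive
# (minority) class; every sampler returns the sorted indices of rows to
# keep and never removes a positive example.  Distances are Euclidean on
# the vectorized (possibly reduced) representation; nearest-neighbor ties
# break toward the lowest row index.

# Squared Euclidean distances, sparse-friendly.
pairwise_dist2 <- function(X) {
  G <- as.matrix(Matrix::tcrossprod(X))
  rs <- diag(G)
  D2 <- outer(rs, rs, "+") - 2 * G
  D2[D2 < 0] <- 0
  D2
}

# Index of the nearest neighbor of each row (self excluded).
nearest_neighbors <- function(D2) {
  n <- nrow(D2)
  diag(D2) <- Inf
  vapply(seq_len(n), function(i) which.min(D2[i, ]), integer(1))
}

#' Random under-sampling of the negative class
#'
#' Keeps all positives and a uniform random subset of negatives of the same
#' size, so the output class ratio is exactly 1:1.
#'
#' @param X Feature matrix (rows are examples).
#' @param y Binary 0/1 labels, 1 = positive class.
#' @param seed Integer seed for the uniform draw.
#' @return Sorted integer indices of rows to keep.
#' @export
random_undersample <- function(X, y, seed) {
  pos <- which(y == 1); neg <- which(y == 0)
  if (!length(pos)) stop("no positive examples", call. = FALSE)
  if (length(neg) < length(pos)) {
    warning("fewer negatives than positives; keeping all rows", call. = FALSE)
    return(seq_along(y))
  }
  set.seed(seed)
  keep_neg <- sort(sample(neg, length(pos)))
  sort(c(pos, keep_neg))
}

#' Tomek's link removal
#'
#' A Tomek's link is a pair of opposite-class examples that are each
#' other's nearest neighbor.  The negative (majority-class) member of every
#' link is removed, cleaning the class boundary.
#'
#' @inheritParams random_undersample
#' @return Sorted integer indices of rows to keep.
#' @export
tomek_link_removal <- function(X, y) {
  if (!any(y == 1) || !any(y == 0)) stop("need both classes", call. = FALSE)
  nn <- nearest_neighbors(pairwise_dist2(X))
  n <- length(y)
  drop <- logical(n)
  for (i in seq_len(n)) {
    j <- nn[i]
    if (y[i] != y[j] && nn[j] == i) drop[if (y[i] == 0) i else j] <- TRUE
  }
  which(!drop)
}

#' One-sided selection
#'
#' Stage 1 keeps a 1NN-consistent subset of the negatives: starting from
#' all positives plus one random negative, the remaining negatives are
#' visited once in seeded random order and added whenever the current
#' subset misclassifies them by the one-nearest-neighbor rule.  Stage 2
#' removes the negative members of Tomek's links inside that subset.
#'
#' @inheritParams random_undersample
#' @param tomek_stage Run the stage-2 Tomek cleaning?  \code{FALSE} returns
#'   the 1NN-consistent subset of stage 1 unchanged.
#' @return Sorted integer indices of rows to keep.
#' @export
one_sided_selection <- function(X, y, seed, tomek_stage = TRUE) {
  pos <- which(y == 1); neg <- which(y == 0)
  if (!length(pos) || !length(neg)) stop("need both classes", call. = FALSE)
  set.seed(seed)
  first <- if (length(neg) == 1L) neg else sample(neg, 1L)
  rest <- setdiff(neg, first)
  if (length(rest) > 1L) rest <- sample(rest)
  D2 <- pairwise_dist2(X)
  keep <- sort(c(pos, first))
  for (i in rest) {
    nn_in_keep <- keep[which.min(D2[i, keep])]
    if (y[nn_in_keep] != y[i]) keep <- sort(c(keep, i))
  }
  if (!tomek_stage) return(keep)
  # Tomek stage within the retained subset
  sub <- keep
  D2s <- D2[sub, sub, drop = FALSE]
  nn <- nearest_neighbors(D2s)
  drop <- logical(length(sub))
  for (a in seq_along(sub)) {
    b <- nn[a]
    if (y[sub[a]] != y[sub[b]] && nn[b] == a) {
      drop[if (y[sub[a]] == 0) a else b] <- TRUE
    }
  }
  sub[!drop]
}

#' Default instance-hardness base learner
#'
#' An SVM whose decision values are mapped to class probabilities by a
#' logistic (Platt-style) link fitted on the training decision values.
#' Returns a closure: fitting on (X, y) yields a predictor giving
#' P(positive) for new rows.
#'
#' @param kernel,cost Passed to \code{e1071::svm}.
#' @return A learner function \code{function(X, y)} returning
#'   \code{function(X_new)}.
#' @export
iht_svm_learner <- function(kernel = "linear", cost = 1) {
  function(X, y) {
    fit <- e1071::svm(as.matrix(X), factor(y, levels = c(0, 1)),
                      kernel = kernel, cost = cost, scale = FALSE)
    dv <- as.numeric(attr(stats::predict(fit, as.matrix(X),
                                         decision.values = TRUE),
                          "decision.values"))
    platt <- suppressWarnings(
      stats::glm(y ~ dv, family = stats::binomial(),
                 data = data.frame(y = y, dv = dv))
    )
    function(X_new) {
      dvn <- as.numeric(attr(stats::predict(fit, as.matrix(X_new),
                                            decision.values = TRUE),
                             "decision.values"))
      as.numeric(stats::predict(platt, data.frame(dv = dvn), type = "response"))
    }
  }
}

#' Instance-hardness-threshold under-sampling
#'
#' Each negative receives a cross-fitted (5-fold) probability of its own
#' class from the base learner; negatives misclassified in cross-fitting
#' (own-class probability below 0.5) are the "hard" examples and are
#' removed, hardest first, but never so many that fewer negatives than
#' positives remain.  The number of kept examples is an output of the
#' procedure, not a parameter.
#'
#' @inheritParams random_undersample
#' @param base_learner Learner factory as produced by
#'   \code{\link{iht_svm_learner}}; must yield class probabilities.
#' @param n_folds Cross-fitting folds (default 5).
#' @return Sorted integer indices of rows to keep.
#' @export
instance_hardness_threshold <- function(X, y, base_learner = iht_svm_learner(),
                                        seed = 1L, n_folds = 5L) {
  pos <- which(y == 1); neg <- which(y == 0)
  if (!length(pos) || !length(neg)) stop("need both classes", call. = FALSE)
  if (!is.function(base_learner)) {
    stop("base_learner must be a learner factory producing probabilities",
         call. = FALSE)
  }
  set.seed(seed)
  folds <- make_stratified_folds(y, n_folds)
  p_pos <- rep(NA_real_, length(y))
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    if (length(unique(y[tr])) < 2L) { p_pos[te] <- mean(y[tr]); next }
    predictor <- base_learner(X[tr, , drop = FALSE], y[tr])
    p_pos[te] <- predictor(X[te, , drop = FALSE])
  }
  p_own_neg <- 1 - p_pos[neg]
  hard <- p_own_neg < 0.5
  keep_neg <- neg[!hard]
  if (length(keep_neg) < length(pos)) {
    # add back the least-hard removed negatives down to the positive count
    need <- min(length(pos), length(neg)) - length(keep_neg)
    back <- neg[hard][order(-p_own_neg[hard], neg[hard])][seq_len(need)]
    keep_neg <- c(keep_neg, back)
  }
  sort(c(pos, keep_neg))
}

#' Sampler configuration
#'
#' @param method One of \code{"NONE"}, \code{"RANDOM_US"}, \code{"TOMEK"},
#'   \code{"OSS"}, \code{"IHT"}.
#' @param seed Integer seed (required for the stochastic samplers
#'   RANDOM_US, OSS and IHT).
#' @param iht_base_learner Base learner factory for IHT.
#' @return A \code{tfsumr_sampler_config}.
#' @export
sampler_config <- function(method = c("NONE", "RANDOM_US", "TOMEK", "OSS", "IHT"),
                           seed = NULL, iht_base_learner = iht_svm_learner()) {
  method <- match.arg(method)
  if (method %in% c("RANDOM_US", "OSS", "IHT") && !is_count(seed)) {
    stop(method, " requires an integer seed", call. = FALSE)
  }
  structure(list(method = method, seed = if (is.null(seed)) NULL else as.integer(seed),
                 iht_base_learner = iht_base_learner),
            class = "tfsumr_sampler_config")
}

# Dispatch a sampler configuration on (X, y); returns kept indices.
apply_sampler <- function(X, y, sampler) {
  switch(sampler$method,
    NONE = seq_along(y),
    RANDOM_US = random_undersample(X, y, sampler$seed),
    TOMEK = tomek_link_removal(X, y),
    OSS = one_sided_selection(X, y, sampler$seed),
    IHT = instance_hardness_threshold(X, y, sampler$iht_base_learner, sampler$seed)
  )
}
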