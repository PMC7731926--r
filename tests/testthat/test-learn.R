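test_that("fold metrics implement sensitivity, specificity and G-mean", {
  perfect <- fold_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$gmean, 1.0)

  blind <- fold_metrics(rep(0, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(blind$sensitivity, 0)
  expect_equal(blind$gmean, 0)

  # sens 0.81 (81 of 100 positives), spec 1.0 -> G-mean 0.9
  truth <- c(rep(1, 100), rep(0, 50))
  preds <- c(rep(1, 81), rep(0, 19), rep(0, 50))
  m <- fold_metrics(preds, truth)
  expect_equal(m$sensitivity, 0.81)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$gmean, 0.9)
  expect_equal(with(m$counts, tp + tn + fp + fn), 150)

  expect_error(fold_metrics(c(1, 0), c(1, 1)), "both classes")
  expect_error(fold_metrics(c(1), c(1, 0)), "length")
})

test_that("G-mean is symmetric and equals accuracy at sens == spec", {
  set.seed(3)
  for (rep in 1:10) {
    truth <- c(rep(1, 40), rep(0, 40))
    preds <- rbinom(80, 1, 0.5)
    if (length(unique(preds)) < 2) next
    m <- fold_metrics(preds, truth)
    swapped <- fold_metrics(1 - preds, 1 - truth)
    expect_equal(m$gmean, sqrt(m$sensitivity * m$specificity))
    expect_equal(swapped$sensitivity, m$specificity)
  }
  # equal per-class accuracy: G-mean == overall accuracy
  truth <- c(rep(1, 10), rep(0, 10))
  preds <- c(rep(1, 8), 0, 0, rep(0, 8), 1, 1)
  m <- fold_metrics(preds, truth)
  expect_equal(m$sensitivity, m$specificity)
  expect_equal(m$gmean, mean(preds == truth))
})

test_that("stratified folds preserve the class ratio and never leak", {
  ts <- quick_training_set(n = 200, seed = 17)
  # build a 20 pos / 180 neg labeling
  y <- ts$y
  expect_equal(sum(y), 20)
  for (method in c("NONE", "RANDOM_US")) {
    cfg <- train_config(representation_config("LEMMA_NER", 1, "BINARY"),
                        sampler = sampler_config(method, seed = 5))
    res <- stratified_cv(ts$annotated, y, k = 10, config = cfg, seed = 2)
    expect_length(res, 10)
    val_all <- sort(unlist(lapply(res, `[[`, "val_idx")))
    expect_equal(val_all, seq_along(y))     # union of validation folds
    for (fold in res) {
      expect_equal(sum(y[fold$val_idx] == 1), 2)
      expect_equal(sum(y[fold$val_idx] == 0), 18)
      expect_length(intersect(fold$val_idx, fold$train_idx_sampled), 0)
    }
  }
  expect_error(stratified_cv(ts$annotated, y, k = 30,
                             config = train_config(), seed = 1),
               "fewer positives")
})

test_that("model selection ranks by median, then IQR, then skewness", {
  expect_equal(rank_configs(c(0.9, 0.7), c(0.1, 0.01))[1], 1L)
  expect_equal(rank_configs(c(0.8, 0.8), c(0.10, 0.02))[1], 2L)
  expect_equal(rank_configs(c(0.8, 0.8), c(0.05, 0.05), c(0.9, 0.1))[1], 2L)
  expect_equal(rank_configs(c(0.8, 0.8), c(0.05, 0.05), c(0.2, 0.2)), c(1L, 2L))
})

test_that("grid search scores every config and returns the most consistent", {
  ts <- quick_training_set(n = 120, seed = 23)
  grid <- list(
    train_config(representation_config("LEMMA_NER", 1, "BINARY"), C = 1),
    train_config(representation_config("LEMMA_POS_NER", 1, "TFIDF"), C = 10)
  )
  gs <- grid_search(ts$annotated, ts$y, grid, k = 6, seed = 4)
  expect_equal(nrow(gs$ranking), 2)
  expect_equal(gs$ranking$rank, 1:2)
  expect_true(all(diff(gs$ranking$median_gmean) <= 0) ||
                gs$ranking$iqr[1] <= gs$ranking$iqr[2])
  expect_identical(gs$best, gs$configs[[gs$best_index]])

  single <- grid_search(ts$annotated, ts$y, grid[1], k = 6, seed = 4)
  expect_equal(single$best_index, 1L)
  expect_error(grid_search(ts$annotated, ts$y, list(), k = 6), "non-empty")
})

test_that("a separable corpus trains to a perfect, deterministic model", {
  ts <- quick_training_set(n = 150, seed = 29)
  cfg <- train_config(representation_config("LEMMA_NER", 1, "BINARY"), C = 10)
  model <- fit_property_model(ts$annotated, ts$y, cfg, property = "ACT", seed = 6)
  preds <- predict_labels(model, ts$annotated)
  expect_equal(fold_metrics(preds, ts$y)$gmean, 1.0)

  model2 <- fit_property_model(ts$annotated, ts$y, cfg, property = "ACT", seed = 6)
  expect_identical(predict_labels(model2, ts$annotated), preds)

  expect_equal(predict_labels(model, list()), integer())
  expect_error(fit_property_model(ts$annotated, rep(0, length(ts$y)), cfg),
               "single class")
  expect_error(train_config(kernel = "poly"), "degree")
})

test_that("class weighting and kernels are honoured by the SVM stage", {
  ts <- quick_training_set(n = 120, seed = 31)
  for (cfg in list(
    train_config(representation_config("LEMMA_NER", 1, "BINARY"),
                 kernel = "rbf", C = 10, gamma = 0.5),
    train_config(representation_config("LEMMA_NER", 1, "BINARY"),
                 kernel = "poly", C = 10, degree = 2),
    train_config(representation_config("LEMMA_NER", 1, "BINARY"),
                 class_weighting = "balanced")
  )) {
    model <- fit_property_model(ts$annotated, ts$y, cfg, property = "DOM", seed = 1)
    expect_length(predict_labels(model, ts$annotated), length(ts$y))
  }
})

test_that("models serialize and round-trip their predictions", {
  ts <- quick_training_set(n = 100, seed = 37)
  cfg <- train_config(representation_config("NER_FOR_LEMMA", 1, "BINARY_TFIDF"))
  model <- fit_property_model(ts$annotated, ts$y, cfg, property = "EVO", seed = 2)
  path <- tempfile(fileext = ".rds")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(predict_labels(back, ts$annotated),
                   predict_labels(model, ts$annotated))
})
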