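test_that("the three feature combinations reproduce the worked example", {
  s <- hipab_annotated()
  lemmas <- c("HipAB", "toxin-antitoxin", "system", "appear", "to", "be",
              "regulate", "at", "level", "of", "HipB", "stability")

  lpn <- compose_features(s, "LEMMA_POS_NER")
  expect_equal(lpn[[1]], lemmas)
  expect_equal(lpn[[2]], c("ACTTF", "NN", "NN", "VBZ", "TO", "VB", "ACTREG",
                           "IN", "NN", "IN", "ACTTF", "NN"))

  ln <- compose_features(s, "LEMMA_NER")
  expect_equal(ln[[1]], lemmas)
  expect_equal(ln[[2]], c("ACTTF", "ACTREG", "ACTTF"))

  nfl <- compose_features(s, "NER_FOR_LEMMA")
  expect_equal(nfl[[1]], c("ACTTF", "toxin-antitoxin", "system", "appear",
                           "to", "be", "ACTREG", "at", "level", "of",
                           "ACTTF", "stability"))
})

test_that("a sentence without NER tags composes to its lemma sequence", {
  ann <- annotate_sentences(data.frame(pmid = "1", text = "Plain words here."),
                            lexicon(character(), character()))[[1]]
  expect_equal(compose_features(ann, "NER_FOR_LEMMA")[[1]],
               c("Plain", "word", "here"))
})

test_that("n-grams are cumulative, contiguous and block-bounded", {
  expect_setequal(extract_ngrams(c("a", "b", "c"), 2),
                  c("a", "b", "c", "a_b", "b_c"))
  expect_equal(extract_ngrams("a", 3), "a")
  grams <- extract_ngrams(list(c("a", "b"), "X"), 2)
  expect_setequal(grams, c("a", "b", "X", "a_b"))
  expect_false("b_X" %in% grams)

  # brute-force enumeration oracle on random streams
  set.seed(9)
  for (rep in 1:10) {
    stream <- sample(letters[1:5], sample(2:8, 1), replace = TRUE)
    nmax <- sample(1:3, 1)
    oracle <- character()
    for (n in 1:nmax) {
      if (n > length(stream)) next
      for (i in 1:(length(stream) - n + 1)) {
        oracle <- c(oracle, paste(stream[i:(i + n - 1)], collapse = "_"))
      }
    }
    expect_equal(sort(extract_ngrams(stream, nmax)), sort(oracle))
  }
})

test_that("idf uses add-one smoothing with the +1 floor", {
  corpus <- list(c("common", "rare"), "common", "common", "common")
  space <- fit_vector_space(corpus, representation_config(weighting = "TFIDF"))
  expect_equal(unname(space$idf["common"]), 1)               # ln(5/5) + 1
  expect_equal(unname(space$idf["rare"]), log(5 / 2) + 1)    # ln(5/2) + 1
  expect_equal(space$n_documents_fitted, 4L)
  expect_error(fit_vector_space(list(),
                                representation_config(weighting = "TFIDF")),
               "empty")
})

test_that("the three weighting schemes vectorize as defined", {
  corpus <- list(c("a", "a", "b"), c("b", "c"), c("c"))
  bin <- vectorize(corpus, fit_vector_space(corpus, representation_config(weighting = "BINARY")))
  expect_true(all(bin@x %in% c(0, 1)))
  expect_equal(as.numeric(bin[1, ]), c(1, 1, 0))

  sp_tfidf <- fit_vector_space(corpus, representation_config(weighting = "TFIDF"))
  tfidf <- vectorize(corpus, sp_tfidf)
  expect_equal(unname(tfidf[1, "a"]), 2 * unname(sp_tfidf$idf["a"]))  # count x idf
  expect_true(all(tfidf@x >= 0))

  btf <- vectorize(corpus, fit_vector_space(corpus, representation_config(weighting = "BINARY_TFIDF")))
  expect_equal(as.matrix(btf), as.matrix(bin))  # forced by the thresholding

  unseen <- vectorize(list(c("zz", "yy")), sp_tfidf)
  expect_equal(sum(unseen), 0)
})

test_that("binary TF-IDF equals binary on random corpora", {
  set.seed(31)
  for (rep in 1:5) {
    corpus <- replicate(12, sample(letters[1:8], sample(1:6, 1), replace = TRUE),
                        simplify = FALSE)
    b <- vectorize(corpus, fit_vector_space(corpus, representation_config(weighting = "BINARY")))
    bt <- vectorize(corpus, fit_vector_space(corpus, representation_config(weighting = "BINARY_TFIDF")))
    expect_equal(as.matrix(b), as.matrix(bt))
  }
})

test_that("truncated SVD is exact at full rank and improves with k", {
  set.seed(5)
  u <- matrix(rnorm(8), ncol = 1); v <- matrix(rnorm(6), ncol = 1)
  X1 <- u %*% t(v)
  colnames(X1) <- paste0("f", 1:6)
  red <- reduce_features(X1, reducer = reducer_config("SVD", 1))
  recon <- red$matrix %*% t(red$transform$v)
  expect_lt(norm(X1 - recon, "F"), 1e-8)

  X <- matrix(rnorm(20 * 8), ncol = 8, dimnames = list(NULL, paste0("f", 1:8)))
  errs <- vapply(1:6, function(k) {
    r <- reduce_features(X, reducer = reducer_config("SVD", k))
    norm(X - r$matrix %*% t(r$transform$v), "F")
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))

  # fitted transform applies consistently to new rows
  r2 <- reduce_features(X, reducer = reducer_config("SVD", 3))
  expect_equal(apply_reduction(r2$transform, X[1:4, ]), r2$matrix[1:4, ])
  expect_error(reduce_features(X, reducer = reducer_config("SVD", 99)), "k")
})

test_that("chi-squared selection favours class-predictive features", {
  X <- cbind(signal = c(1, 1, 1, 0, 0, 0, 0, 0),
             noise  = c(1, 0, 1, 0, 1, 0, 1, 0))
  y <- c(1, 1, 1, 0, 0, 0, 0, 0)
  red <- reduce_features(X, labels = y, reducer = reducer_config("CHI2", 1))
  expect_equal(red$transform$columns, "signal")

  expect_equal(reduce_features(X, labels = y,
                               reducer = reducer_config("CHI2", 2))$transform$columns,
               c("signal", "noise"))  # k = V keeps everything
  expect_error(reduce_features(X, reducer = reducer_config("CHI2", 1)), "labels")
  expect_error(reduce_features(X, labels = y, reducer = reducer_config("CHI2", 5)), "k")
})

test_that("chi-squared ranking matches the closed-form 2x2 oracle", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 40; V <- 10
    X <- matrix(rbinom(n * V, 1, 0.3), nrow = n,
                dimnames = list(NULL, sprintf("f%02d", 1:V)))
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    oracle <- vapply(seq_len(V), function(j) {
      tab <- table(factor(X[, j] > 0, c(FALSE, TRUE)), factor(y, c(0, 1)))
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(0)
      unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic)
    }, numeric(1))
    names(oracle) <- colnames(X)
    k <- 4
    want <- sort(names(oracle)[order(-oracle, names(oracle))[1:k]])
    got <- reduce_features(X, labels = y, reducer = reducer_config("CHI2", k))
    expect_equal(sort(got$transform$columns), want)
  }
})
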