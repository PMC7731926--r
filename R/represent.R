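# Sentence representation: three feature combinations over lemma/POS/NER
# annotations, cumulative n-grams that respect block boundaries, three
# vectorization schemes (binary, TF-IDF, binary TF-IDF) and two
# dimensionality treatments (truncated SVD, chi-squared feature selection).

repr_combos <- c("LEMMA_POS_NER", "LEMMA_NER", "NER_FOR_LEMMA")
repr_weightings <- c("BINARY", "TFIDF", "BINARY_TFIDF")

#' Representation configuration
#'
#' @param combo One of \code{"LEMMA_POS_NER"} (lemmas followed by the POS
#'   stream with NER tags substituted at tagged positions),
#'   \code{"LEMMA_NER"} (lemmas followed by the NER tags alone) or
#'   \code{"NER_FOR_LEMMA"} (lemmas with NER tags substituted in place).
#' @param ngram_max Largest n-gram order, in 1..3; n-grams are cumulative
#'   (all orders 1..ngram_max are generated).
#' @param weighting One of \code{"BINARY"}, \code{"TFIDF"},
#'   \code{"BINARY_TFIDF"}.
#' @return A \code{tfsumr_repr_config}.
#' @export
representation_config <- function(combo = "LEMMA_NER", ngram_max = 1L,
                                  weighting = "BINARY") {
  combo <- match.arg(combo, repr_combos)
  weighting <- match.arg(weighting, repr_weightings)
  if (!is_count(ngram_max, 1L) || ngram_max > 3L) {
    stop("ngram_max must be 1, 2 or 3", call. = FALSE)
  }
  structure(list(combo = combo, ngram_max = as.integer(ngram_max),
                 weighting = weighting),
            class = "tfsumr_repr_config")
}

#' Compose the feature stream of an annotated sentence
#'
#' Punctuation tokens carry no content and are excluded from all streams.
#' The result is a list of blocks (character vectors); n-grams are formed
#' within blocks only, never across the boundary between the lemma block and
#' an appended tag block.
#'
#' @param sentence An annotated sentence (see
#'   \code{\link{annotate_sentences}}).
#' @param combo Feature combination, see
#'   \code{\link{representation_config}}.
#' @return List of character vectors (one or two blocks).
#' @export
compose_features <- function(sentence, combo = "LEMMA_NER") {
  combo <- match.arg(combo, repr_combos)
  tok <- sentence$tokens
  keep <- !is_punct_token(tok$surface)
  lemma <- tok$lemma[keep]; pos <- tok$pos[keep]; ner <- tok$ner[keep]
  tagged <- !is.na(ner)
  switch(combo,
    LEMMA_POS_NER = list(lemma, ifelse(tagged, ner, pos)),
    LEMMA_NER = list(lemma, ner[tagged]),
    NER_FOR_LEMMA = list(ifelse(tagged, ner, lemma))
  )
}

#' Extract cumulative n-grams from a feature stream
#'
#' All contiguous n-grams for n = 1..\code{ngram_max}, joined with
#' \code{"_"}.  When \code{stream} is a list of blocks, n-grams never cross
#' a block boundary.
#'
#' @param stream Character vector, or list of character vectors (blocks).
#' @param ngram_max Largest order, in 1..3.
#' @return Character vector of features (a multiset: repeats preserved).
#' @export
extract_ngrams <- function(stream, ngram_max = 1L) {
  if (!is_count(ngram_max, 1L) || ngram_max > 3L) {
    stop("ngram_max must be 1, 2 or 3", call. = FALSE)
  }
  blocks <- if (is.list(stream)) stream else list(stream)
  out <- character()
  for (blk in blocks) {
    m <- length(blk)
    if (!m) next
    for (n in seq_len(min(ngram_max, m))) {
      if (n == 1L) {
        out <- c(out, blk)
      } else {
        idx <- seq_len(m - n + 1L)
        grams <- blk[idx]
        for (j in seq_len(n - 1L)) grams <- paste(grams, blk[idx + j], sep = "_")
        out <- c(out, grams)
      }
    }
  }
  out
}

# compose + n-grams for a list of annotated sentences, per config.
sentence_features <- function(sentences, config) {
  lapply(sentences, function(s) {
    extract_ngrams(compose_features(s, config$combo), config$ngram_max)
  })
}

#' Fit a vector space over a feature corpus
#'
#' The vocabulary is every feature seen in the fitting corpus, in
#' lexicographic order.  Inverse document frequencies use add-one smoothing
#' with a +1 floor: idf(f) = ln((1 + N) / (1 + df(f))) + 1.
#'
#' @param corpus List of feature multisets (character vectors), one per
#'   sentence.
#' @param config A \code{tfsumr_repr_config}.
#' @return A \code{tfsumr_vector_space} with fields \code{vocabulary}
#'   (named integer index), \code{idf} (present iff the weighting uses
#'   TF-IDF), \code{config} and \code{n_documents_fitted}.
#' @export
fit_vector_space <- function(corpus, config = representation_config()) {
  if (!length(corpus)) stop("cannot fit a vector space on an empty corpus", call. = FALSE)
  vocab <- sort(unique(unlist(corpus, use.names = FALSE)))
  n <- length(corpus)
  idf <- NULL
  if (config$weighting %in% c("TFIDF", "BINARY_TFIDF")) {
    df <- table(factor(unlist(lapply(corpus, unique), use.names = FALSE),
                       levels = vocab))
    idf <- log((1 + n) / (1 + as.numeric(df))) + 1
    names(idf) <- vocab
  }
  structure(list(vocabulary = stats::setNames(seq_along(vocab), vocab),
                 idf = idf, config = config, n_documents_fitted = n),
            class = "tfsumr_vector_space")
}

#' Vectorize feature multisets into a sparse matrix
#'
#' Weights per the fitted space's scheme: \code{BINARY} marks presence;
#' \code{TFIDF} multiplies the in-sentence count by the idf;
#' \code{BINARY_TFIDF} sets every strictly positive TF-IDF weight to 1
#' (hence it coincides with \code{BINARY} on any input).  Features unseen
#' at fitting time are ignored.
#'
#' @param corpus List of feature multisets, or a single character vector
#'   (treated as one sentence).
#' @param space A fitted \code{tfsumr_vector_space}.
#' @return A sparse \code{dgCMatrix}, sentences in rows, vocabulary in
#'   columns.
#' @export
vectorize <- function(corpus, space) {
  if (!inherits(space, "tfsumr_vector_space")) stop("space is not fitted", call. = FALSE)
  if (is.character(corpus)) corpus <- list(corpus)
  V <- length(space$vocabulary)
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (i in seq_along(corpus)) {
    counts <- table(corpus[[i]])
    cols <- space$vocabulary[names(counts)]
    hit <- !is.na(cols)
    if (!any(hit)) next
    cols <- cols[hit]
    cnt <- as.numeric(counts)[hit]
    w <- switch(space$config$weighting,
      BINARY = rep(1, length(cols)),
      TFIDF = cnt * space$idf[names(cols)],
      BINARY_TFIDF = as.numeric(cnt * space$idf[names(cols)] > 0)
    )
    ii <- c(ii, rep(i, length(cols))); jj <- c(jj, unname(cols)); xx <- c(xx, unname(w))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(corpus), V),
                       dimnames = list(NULL, names(space$vocabulary)))
}

#' Reducer configuration
#'
#' @param method \code{"NONE"}, \code{"SVD"} (truncated singular value
#'   decomposition; study-scale defaults are 200 and 300 dimensions) or
#'   \code{"CHI2"} (chi-squared feature selection; defaults 1000, 800, 500).
#' @param k Target dimensionality / number of selected features.
#' @return A \code{tfsumr_reducer_config}.
#' @export
reducer_config <- function(method = c("NONE", "SVD", "CHI2"), k = NULL) {
  method <- match.arg(method)
  if (method != "NONE") {
    if (!is_count(k, 1L)) stop("k must be a positive integer", call. = FALSE)
    k <- as.integer(k)
  }
  structure(list(method = method, k = k), class = "tfsumr_reducer_config")
}

#' Fit a dimensionality reduction / feature selection transform
#'
#' \code{SVD} projects onto the top-k right singular directions of the
#' weight matrix (no centering).  \code{CHI2} keeps the k columns with the
#' largest chi-squared statistic of the 2x2 feature-presence/class
#' contingency table, original weights untouched; ties break
#' lexicographically on the feature name.  The fitted transform is reusable
#' on new rows via \code{\link{apply_reduction}}.
#'
#' @param X Sentence-by-feature weight matrix (sparse or dense).
#' @param labels Binary 0/1 vector (required for CHI2, ignored for SVD).
#' @param reducer A \code{tfsumr_reducer_config}.
#' @return List with \code{matrix} (transformed rows) and \code{transform}
#'   (a \code{tfsumr_reduction} for new data).
#' @export
reduce_features <- function(X, labels = NULL, reducer = reducer_config("NONE")) {
  method <- reducer$method
  if (method == "NONE") {
    tr <- structure(list(method = "NONE"), class = "tfsumr_reduction")
    return(list(matrix = X, transform = tr))
  }
  k <- reducer$k
  if (method == "SVD") {
    if (k > min(dim(X))) stop("SVD k exceeds min(rows, features)", call. = FALSE)
    sv <- svd(as.matrix(X), nu = 0, nv = k)
    Vk <- sv$v[, seq_len(k), drop = FALSE]
    rownames(Vk) <- colnames(X)
    tr <- structure(list(method = "SVD", v = Vk), class = "tfsumr_reduction")
    return(list(matrix = as.matrix(X %*% Vk), transform = tr))
  }
  # CHI2
  if (is.null(labels)) stop("CHI2 feature selection requires labels", call. = FALSE)
  if (k > ncol(X)) stop("CHI2 k exceeds the number of features", call. = FALSE)
  stats_ <- chi2_statistics(X, labels)
  ord <- order(-stats_, colnames(X), method = "radix")
  keep <- sort(ord[seq_len(k)])
  tr <- structure(list(method = "CHI2", columns = colnames(X)[keep]),
                  class = "tfsumr_reduction")
  list(matrix = X[, keep, drop = FALSE], transform = tr)
}

# Chi-squared statistic of the 2x2 presence/class table, per feature.
# Zero when a margin is empty (feature everywhere/nowhere, or single class).
chi2_statistics <- function(X, labels) {
  labels <- as.numeric(labels)
  present <- X > 0
  n <- nrow(X)
  pos <- labels == 1
  a <- Matrix::colSums(present[pos, , drop = FALSE])   # present, positive
  b <- Matrix::colSums(present[!pos, , drop = FALSE])  # present, negative
  c_ <- sum(pos) - a
  d <- sum(!pos) - b
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stat <- ifelse(den > 0, n * (a * d - b * c_)^2 / den, 0)
  stats::setNames(as.numeric(stat), colnames(X))
}

#' Apply a fitted reduction to new rows
#'
#' @param transform A \code{tfsumr_reduction} from
#'   \code{\link{reduce_features}}.
#' @param X New sentence-by-feature matrix over the same vocabulary.
#' @return Transformed matrix.
#' @export
apply_reduction <- function(transform, X) {
  switch(transform$method,
    NONE = X,
    SVD = as.matrix(X %*% transform$v),
    CHI2 = X[, transform$columns, drop = FALSE]
  )
}
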