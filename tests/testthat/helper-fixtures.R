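# Shared fixtures and independent brute-force oracles.

# The worked representation example: sentence, lexicon and annotation.
hipab_text <- "HipAB toxin-antitoxin system appears to be regulated at level of HipB stability."

hipab_lexicon <- function() {
  lexicon(c("HipAB", "HipB", "regulated"),
          c("ACTTF", "ACTTF", "ACTREG"),
          case_sensitive = c(TRUE, TRUE, FALSE))
}

hipab_annotated <- function() {
  annotate_sentences(data.frame(pmid = "1", text = hipab_text,
                                stringsAsFactors = FALSE),
                     hipab_lexicon())[[1]]
}

# Small labeled-summary XML written to a temp file.
write_summary_fixture <- function(body) {
  path <- tempfile(fileext = ".xml")
  writeLines(c("<summaries>", body, "</summaries>"), path)
  path
}

# Brute-force Tomek-link oracle: O(n^2) scan over every opposite-class
# pair, checking mutual nearest neighborhood directly on the distance
# matrix; removes the negative member of each link.
oracle_tomek <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  drop <- logical(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (y[i] == y[j]) next
      mutual <- which.min(D[i, ]) == j && which.min(D[j, ]) == i
      if (mutual) drop[if (y[i] == 0) i else j] <- TRUE
    }
  }
  which(!drop)
}

# Brute-force leftmost-longest NER oracle: at each position try every
# lexicon entry by direct string comparison, take the longest match.
oracle_ner <- function(tokens, lex) {
  n <- length(tokens)
  tags <- rep(NA_character_, n)
  i <- 1L
  while (i <= n) {
    best_len <- 0L; best_tag <- NA_character_
    for (e in seq_len(nrow(lex))) {
      words <- strsplit(lex$term[e], " ", fixed = TRUE)[[1]]
      len <- length(words)
      if (i + len - 1L > n) next
      span <- tokens[i:(i + len - 1L)]
      hit <- if (lex$case_sensitive[e]) identical(span, words)
             else identical(tolower(span), tolower(words))
      if (hit && len > best_len) { best_len <- len; best_tag <- lex$tag[e] }
    }
    if (best_len > 0L) {
      tags[i:(i + best_len - 1L)] <- best_tag
      i <- i + best_len
    } else i <- i + 1L
  }
  tags
}

# Random point clouds with a guaranteed minority positive class.
random_imbalanced_cloud <- function(n, d = 2) {
  n_pos <- sample(seq(2, max(2, floor(n / 4))), 1)
  X <- rbind(matrix(stats::rnorm(n_pos * d, mean = 2), ncol = d),
             matrix(stats::rnorm((n - n_pos) * d), ncol = d))
  list(X = X, y = c(rep(1, n_pos), rep(0, n - n_pos)))
}

# A quick single-property training set: annotated sentences plus labels.
quick_training_set <- function(n = 200, seed = 11, noise_rate = 0,
                               property = "ACT") {
  rates <- c(ACT = 0.1, DOM = 0.1, EVO = 0.1, RP = 0.1, SITE = 0.1, TU = 0.1)
  corp <- make_corpus(corpus_spec(n_tfs = 8, n_sentences = n,
                                  positive_rate = rates,
                                  keyword_injection_rate = 1,
                                  noise_rate = noise_rate,
                                  duplicate_rate = 0, seed = seed))
  ann <- annotate_sentences(corp$summaries, corp$lexicon)
  y <- as.integer(vapply(corp$summaries$labels,
                         function(l) property %in% l, logical(1)))
  list(corpus = corp, annotated = ann, y = y)
}

label_matrix <- function(labels_list) {
  vapply(property_labels(), function(p)
    vapply(labels_list, function(l) p %in% l, logical(1)),
    logical(length(labels_list)))
}
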