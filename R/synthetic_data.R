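# Synthetic corpora with the statistical structure the pipeline assumes:
# per-property positive subsets at single-digit positive rates inside a
# few-thousand-sentence training set, planted property keyword
# vocabularies entered in the lexicons, decoy terms that share the NER tag
# but not the word form, filler-synonym paraphrase noise, and planted
# duplicates to exercise redundancy reduction.  Generation is
# template-based, so gold labels are exact by construction.

# Interchangeable filler-word groups; paraphrase noise swaps within a
# group and never touches TF names or planted keywords.
filler_groups <- list(
  c("protein", "polypeptide"), c("gene", "locus"), c("promoter", "operator"),
  c("binds", "contacts"), c("controls", "governs"), c("during", "throughout"),
  c("growth", "proliferation"), c("response", "reaction"),
  c("expression", "transcription"), c("cell", "bacterium"),
  c("strongly", "markedly"), c("encodes", "specifies"),
  c("stress", "challenge"), c("activity", "function"), c("level", "amount")
)

default_stopwords <- c("the", "a", "an", "of", "to", "in", "is", "are",
                       "and", "or", "was", "were", "by", "with", "for",
                       "on", "at", "be", "this", "that", "it", "as")

#' Built-in stop-word list
#'
#' The small closed-class English list used by the synthetic generator and
#' as a default for stop-word-free evaluation.
#'
#' @return Character vector of lowercase stop words.
#' @export
builtin_stopwords <- function() default_stopwords

property_keywords <- function() {
  out <- list()
  for (prop in property_labels()) {
    low <- tolower(prop)
    out[[prop]] <- list(
      keywords = sprintf("%skw%02d", low, 1:8),
      decoys = sprintf("%sdecoy%02d", low, 1:4),
      tag = paste0("KW", prop)
    )
  }
  out
}

#' Specification of a synthetic corpus
#'
#' Defaults mirror the structure of the real training data: 2244 sentences
#' drawn from the summaries of 177 TFs, with per-property positive rates
#' between 6\% and 15\% (ACT 12\%, DOM 15\%, EVO 7\%, RP 12\%, SITE 6\%,
#' TU 7\%).  Positive counts use the floor convention
#' (floor(rate * n_sentences)), recorded in the corpus metadata.
#'
#' @param n_tfs Number of TFs.
#' @param n_sentences Total number of training sentences.
#' @param positive_rate Named positive-class rate per property, each in
#'   [0, 1]; the six subsets are disjoint, so the rates must sum to at
#'   most 1.
#' @param keyword_injection_rate Probability that a positive sentence
#'   contains its property's planted keywords.
#' @param noise_rate Probability that a negative sentence contains a decoy
#'   term (a word sharing the property's NER tag but not its form).
#' @param duplicate_rate Fraction of article sentences duplicated or
#'   lightly paraphrased.
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @return A \code{tfsumr_corpus_spec}.
#' @export
corpus_spec <- function(n_tfs = 177L, n_sentences = 2244L,
                        positive_rate = c(ACT = 0.12, DOM = 0.15, EVO = 0.07,
                                          RP = 0.12, SITE = 0.06, TU = 0.07),
                        keyword_injection_rate = 1.0, noise_rate = 0.0,
                        duplicate_rate = 0.1, seed = 1L) {
  stopifnot(is_count(n_tfs, 1L), is_count(n_sentences, 1L), is_count(seed))
  if (!all(property_labels() %in% names(positive_rate))) {
    stop("positive_rate must name all six properties", call. = FALSE)
  }
  positive_rate <- positive_rate[property_labels()]
  rates <- c(positive_rate, keyword_injection_rate, noise_rate, duplicate_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (sum(floor(positive_rate * n_sentences)) > n_sentences) {
    stop("positive rates sum beyond the corpus size", call. = FALSE)
  }
  structure(list(n_tfs = as.integer(n_tfs), n_sentences = as.integer(n_sentences),
                 positive_rate = positive_rate,
                 keyword_injection_rate = keyword_injection_rate,
                 noise_rate = noise_rate, duplicate_rate = duplicate_rate,
                 seed = as.integer(seed)),
            class = "tfsumr_corpus_spec")
}

sample_filler <- function(k) {
  vapply(sample(length(filler_groups), k, replace = TRUE),
         function(g) sample(filler_groups[[g]], 1L), character(1))
}

# Light paraphrase: swap filler words for a synonym within their group.
paraphrase <- function(words, p_swap = 0.3) {
  for (i in seq_along(words)) {
    for (grp in filler_groups) {
      j <- match(words[i], grp)
      if (!is.na(j) && stats::runif(1) < p_swap) {
        words[i] <- sample(grp[-j], 1L)
        break
      }
    }
  }
  words
}

#' Generate a synthetic training corpus, lexicons and article collection
#'
#' Per property, a disjoint planted keyword vocabulary (and a decoy
#' vocabulary sharing its NER tag) is entered into the lexicon.  Positive
#' training sentences name a TF, planted keywords (at the injection rate)
#' and filler; negatives are filler plus decoys at the noise rate.  The
#' article collection mirrors the summary sentences with filler-synonym
#' paraphrase noise and appends exact or lightly paraphrased duplicates at
#' the duplicate rate; gold multi-labels are recorded for every article
#' sentence.
#'
#' @param spec A \code{tfsumr_corpus_spec}.
#' @return A \code{tfsumr_corpus}: list with \code{spec}, \code{lexicon},
#'   \code{stopwords}, \code{summaries} (labeled training sentences),
#'   \code{articles} (sentence collection with columns \code{pmid},
#'   \code{text}, \code{doc_index}), \code{gold} (list of label sets, one
#'   per article row) and \code{metadata} (configured positive counts and
#'   the floor convention).
#' @export
make_corpus <- function(spec = corpus_spec()) {
  if (!inherits(spec, "tfsumr_corpus_spec")) stop("spec must be a tfsumr_corpus_spec",
                                                  call. = FALSE)
  n <- spec$n_sentences
  n_pos <- floor(spec$positive_rate * n)
  if (any(spec$positive_rate > 0 & n_pos == 0)) {
    stop("corpus too small for the requested positive rate(s)", call. = FALSE)
  }
  set.seed(spec$seed)
  kw <- property_keywords()
  tf_names <- sprintf("Tf%03d", seq_len(spec$n_tfs))

  # disjoint positive subsets, remainder all-negative
  perm <- sample(n)
  labels <- rep(NA_character_, n)
  offset <- 0L
  for (prop in property_labels()) {
    take <- n_pos[[prop]]
    if (take > 0L) labels[perm[offset + seq_len(take)]] <- prop
    offset <- offset + take
  }

  tf_of <- tf_names[sample(spec$n_tfs, n, replace = TRUE)]
  pmids <- as.character(100000L + ceiling(seq_len(n) / 10L))
  texts <- character(n)
  has_kw <- logical(n)
  for (i in seq_len(n)) {
    filler <- sample_filler(4L)
    if (!is.na(labels[i])) {
      inject <- stats::runif(1) < spec$keyword_injection_rate
      has_kw[i] <- inject
      core <- if (inject) {
        paste(sample(kw[[labels[i]]]$keywords, 2L), collapse = paste0(" ", filler[3], " "))
      } else filler[3]
      texts[i] <- sprintf("%s %s the %s of %s in the %s.",
                          tf_of[i], filler[1], core, filler[2], filler[4])
    } else {
      decoy <- if (stats::runif(1) < spec$noise_rate) {
        prop <- sample(property_labels(), 1L)
        paste0(" ", sample(kw[[prop]]$decoys, 1L))
      } else ""
      texts[i] <- sprintf("%s %s the %s of %s%s in the %s.",
                          tf_of[i], filler[1], filler[3], filler[2], decoy, filler[4])
    }
  }

  summaries <- data.frame(tf_name = tf_of, pmid = pmids, text = texts,
                          stringsAsFactors = FALSE)
  summaries$labels <- lapply(labels, function(l) if (is.na(l)) character() else l)
  summaries$doc_index <- as.integer(stats::ave(seq_len(n), pmids, FUN = seq_along)) - 1L
  summaries <- summaries[, c("tf_name", "pmid", "doc_index", "text", "labels")]

  # article collection: paraphrased mirror plus planted duplicates
  art_text <- vapply(texts, function(tx) {
    words <- strsplit(sub("\\.$", "", tx), " ", fixed = TRUE)[[1]]
    paste0(paste(paraphrase(words), collapse = " "), ".")
  }, character(1), USE.NAMES = FALSE)
  gold <- summaries$labels
  n_dup <- floor(spec$duplicate_rate * n)
  if (n_dup > 0L) {
    src <- sample(n, n_dup, replace = TRUE)
    dup_text <- vapply(src, function(i) {
      if (stats::runif(1) < 0.5) art_text[i]
      else {
        words <- strsplit(sub("\\.$", "", art_text[i]), " ", fixed = TRUE)[[1]]
        paste0(paste(paraphrase(words, p_swap = 0.5), collapse = " "), ".")
      }
    }, character(1))
    art_text <- c(art_text, dup_text)
    gold <- c(gold, gold[src])
    art_pmid <- c(pmids, pmids[src])
    art_tf <- c(tf_of, tf_of[src])
  } else {
    art_pmid <- pmids
    art_tf <- tf_of
  }
  articles <- data.frame(pmid = art_pmid, text = art_text, stringsAsFactors = FALSE)
  articles$doc_index <- as.integer(stats::ave(seq_len(nrow(articles)), art_pmid,
                                              FUN = seq_along)) - 1L
  articles$tf_name <- art_tf

  terms <- tf_names; tags <- rep("ACTTF", length(tf_names))
  cs <- rep(TRUE, length(tf_names))
  for (prop in property_labels()) {
    entry <- kw[[prop]]
    words <- c(entry$keywords, entry$decoys)
    terms <- c(terms, words); tags <- c(tags, rep(entry$tag, length(words)))
    cs <- c(cs, rep(FALSE, length(words)))
  }

  structure(list(
    spec = spec,
    lexicon = lexicon(terms, tags, case_sensitive = cs),
    stopwords = default_stopwords,
    summaries = summaries,
    articles = articles,
    gold = gold,
    metadata = list(positive_counts = n_pos,
                    count_convention = "floor(rate * n_sentences)",
                    keyword_vocab = kw)
  ), class = "tfsumr_corpus")
}

#' Write a synthetic corpus in the formats the readers consume
#'
#' Writes \code{articles.jsonl}, \code{summaries.xml}, one lexicon file per
#' tag under \code{lexicons/}, and \code{stopwords.txt}.
#'
#' @param corpus A \code{tfsumr_corpus}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "lexicons"), recursive = TRUE, showWarnings = FALSE)
  write_article_collection(corpus$articles, file.path(dir, "articles.jsonl"))
  write_labeled_summaries(corpus$summaries, file.path(dir, "summaries.xml"))
  for (tag in unique(corpus$lexicon$tag)) {
    writeLines(corpus$lexicon$term[corpus$lexicon$tag == tag],
               file.path(dir, "lexicons", paste0(tag, ".txt")))
  }
  writeLines(corpus$stopwords, file.path(dir, "stopwords.txt"))
  invisible(dir)
}

#' Construct a manual/automatic summary pair with known ROUGE-1 recall
#'
#' Builds two texts whose stop-word-free clipped-overlap recall equals
#' \code{overlap_fraction} by word-count design: the manual text has
#' \code{n_manual_words} distinct content words, of which
#' round(overlap_fraction * n_manual_words) also occur in the automatic
#' text; stop words are sprinkled into both to exercise filtering.
#'
#' @param overlap_fraction Target recall in [0, 1].
#' @param n_manual_words Content words in the manual text (default 40).
#' @param seed Seed for the interleaving.
#' @return List with \code{manual}, \code{auto} and
#'   \code{expected_recall}.
#' @export
make_eval_pair <- function(overlap_fraction, n_manual_words = 40L, seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  m <- as.integer(n_manual_words)
  k <- round(overlap_fraction * m)
  manual_words <- sprintf("manualword%03d", seq_len(m))
  shared <- if (k > 0) manual_words[seq_len(k)] else character()
  auto_words <- c(shared, sprintf("autoonly%03d", seq_len(max(4L, m - k))))
  sprinkle <- function(words) {
    out <- character()
    for (w in words) {
      out <- c(out, w)
      if (stats::runif(1) < 0.3) out <- c(out, sample(default_stopwords, 1L))
    }
    paste(out, collapse = " ")
  }
  list(manual = sprinkle(sample(manual_words)),
       auto = sprinkle(sample(auto_words)),
       expected_recall = k / m)
}
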