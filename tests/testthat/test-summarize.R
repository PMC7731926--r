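# Train one small model per property once; reused across blocks.
summarize_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    corp <- make_corpus(corpus_spec(n_tfs = 10, n_sentences = 240,
                                    keyword_injection_rate = 1, noise_rate = 0,
                                    duplicate_rate = 0.15, seed = 19))
    ann <- annotate_sentences(corp$summaries, corp$lexicon)
    cfg <- train_config(representation_config("LEMMA_NER", 1, "BINARY"), C = 10)
    models <- list()
    for (p in property_labels()) {
      y <- as.integer(vapply(corp$summaries$labels, function(l) p %in% l,
                             logical(1)))
      models[[p]] <- fit_property_model(ann, y, cfg, property = p, seed = 3)
    }
    cache <<- list(corpus = corp, models = models)
    cache
  }
})

test_that("corpus classification is multi-label and drops empty sets", {
  fx <- summarize_fixture()
  arts <- fx$corpus$articles
  ann <- annotate_sentences(arts, fx$corpus$lexicon)
  classified <- classify_corpus(ann, fx$models)
  expect_true(nrow(classified) > 0)
  expect_true(all(lengths(classified$properties) >= 1))
  expect_error(classify_corpus(ann, fx$models[1:5]), "missing model")
})

test_that("TF filtering requires a whole-token mention", {
  df <- data.frame(text = c("MatA represses flhDC transcription.",
                            "The regulator represses flhDC.",
                            "Overexpression of MatA-dependent genes.",
                            "This format does not mention the factor."),
                   stringsAsFactors = FALSE)
  kept <- filter_by_tf(df, "MatA")
  expect_equal(nrow(kept), 2)           # word-boundary, hyphen is a boundary
  expect_equal(nrow(filter_by_tf(df, "mat")), 0)
  # naive substring matching would disagree on "format"
  expect_true(any(grepl("mat", df$text)))
  expect_equal(nrow(filter_by_tf(df, "matA")), 0)  # canonical name: exact case
  # aliases match case-insensitively by default, canonical names never do
  expect_equal(nrow(filter_by_tf(df, "ZZZ", aliases = "mata")), 2)
  expect_equal(nrow(filter_by_tf(df, "ZZZ", aliases = "mata",
                                 alias_case_sensitive = TRUE)), 0)
  expect_error(filter_by_tf(df, ""), "non-empty")
})

test_that("identical sentences collapse to one visible representative", {
  texts <- rep("HipAB binds the hipBA operator site.", 3)
  dd <- deduplicate(texts, 0.8)
  expect_equal(sum(dd$visible), 1)
  expect_equal(sum(!dd$visible), 2)
  expect_true(all(dd$similarity_to_kept[!dd$visible] >= 0.8))

  unrelated <- c("HipAB binds the operator.", "Glucose uptake increased.")
  dd2 <- deduplicate(unrelated, 0.8)
  expect_true(all(dd2$visible))
})

test_that("planted near-duplicate triples reduce to one visible each", {
  # two triples; within a triple only the last word differs, so every
  # within-triple binary cosine is 9/10 and every cross-triple cosine is 0
  texts <- c("RcsB activates ftsZ expression during exponential cell division growth phase",
             "OsmY transcription requires envelope stress signal relay kinase response magnitude",
             "RcsB activates ftsZ expression during exponential cell division growth stage",
             "RcsB activates ftsZ expression during exponential cell division growth period",
             "OsmY transcription requires envelope stress signal relay kinase response amplitude",
             "OsmY transcription requires envelope stress signal relay kinase response extent")
  dd <- deduplicate(texts, 0.8)
  expect_equal(nrow(dd), 6)
  expect_equal(sum(dd$visible), 2)
  # brute-force all-pairs cosine confirms the planted structure
  sets <- strsplit(texts, " ")
  cos <- function(a, b) length(intersect(a, b)) /
    sqrt(length(unique(a)) * length(unique(b)))
  triple <- c(1, 2, 1, 1, 2, 2)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(cos(sets[[i]], sets[[j]]) >= 0.8, triple[i] == triple[j])
  }
  # conservation and idempotence on the visible subset
  expect_setequal(dd$index, 1:6)
  vis <- dd$index[dd$visible]
  dd2 <- deduplicate(texts[vis], 0.8)
  expect_true(all(dd2$visible))
  expect_error(deduplicate(texts, 0), "threshold")
  expect_equal(nrow(deduplicate(character())), 0)
})

test_that("summaries assemble ordered sections with shared sentences", {
  classified <- data.frame(
    pmid = c("101", "102", "103"),
    doc_index = 0:2,
    text = c("MngR represses mngA transcription.",
             "MngR controls sugar catabolism genes.",
             "The mngR gene forms an operon."),
    stringsAsFactors = FALSE)
  classified$properties <- list(c("ACT", "RP"), "RP", "TU")
  summ <- build_summary("MngR", classified)
  expect_equal(names(summ$sections), c("ACT", "RP", "TU"))
  expect_equal(nrow(summ$sections$RP), 2)   # the ACT sentence reappears
  expect_equal(summ$n_articles, 3)
})

test_that("rendered HTML links PMIDs, hides redundancy and parses back", {
  classified <- data.frame(
    pmid = c("123", "124", "125"),
    doc_index = 0:2,
    text = c("MngR binds <mngA> operator region tightly.",
             "MngR binds the mngA operator region tightly.",
             "MngR also regulates mngB here."),
    stringsAsFactors = FALSE)
  classified$properties <- list("ACT", "ACT", "ACT")
  summ <- build_summary("MngR", classified, threshold = 0.6)
  html <- render_html(summ)
  expect_match(html, "href=\"https://pubmed.ncbi.nlm.nih.gov/123/\"", fixed = TRUE)
  expect_match(html, "&lt;mngA&gt;", fixed = TRUE)
  expect_false(grepl("<mngA>", html, fixed = TRUE))

  parsed <- parse_summary_html(html)
  expect_setequal(parsed$pmid, c("123", "124", "125"))
  sec <- summ$sections$ACT
  expect_equal(sum(parsed$visible), sum(sec$visible))
  expect_equal(parsed$visible[match(sec$pmid, parsed$pmid)], sec$visible)
  # empty sections never render a heading
  expect_false(grepl("Structural domains", html))
})

test_that("every sentence of an end-to-end summary mentions the TF", {
  fx <- summarize_fixture()
  tf <- fx$corpus$articles$tf_name[1]
  summ <- summarize_collection(fx$corpus$articles[, c("pmid", "text", "doc_index")],
                               fx$models, tf, fx$corpus$lexicon,
                               stopwords = fx$corpus$stopwords)
  for (sec in summ$sections) {
    expect_true(all(grepl(tf, sec$text, fixed = TRUE)))
    expect_equal(sum(sec$visible) + sum(!sec$visible), nrow(sec))
  }
  parsed <- parse_summary_html(render_html(summ))
  expect_equal(nrow(parsed), sum(vapply(summ$sections, nrow, integer(1))))
})
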