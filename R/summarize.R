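# Automatic summarization: apply the six property classifiers to an article
# collection, keep only sentences mentioning the TF, reduce redundancy per
# property section by average-linkage clustering of cosine similarities, and
# render an HTML summary in which redundant sentences are hidden but
# recoverable and every sentence links to its PubMed record.

#' Classify every sentence of a corpus with the six property models
#'
#' @param sentences List of annotated sentences.
#' @param models Named list of fitted \code{tfsumr_property_model}s covering
#'   all six property labels.
#' @return Data frame with columns \code{pmid}, \code{doc_index},
#'   \code{text} and \code{properties} (list column); sentences predicted
#'   by no model are dropped, the rest carry every predicted property.
#' @export
classify_corpus <- function(sentences, models) {
  missing <- setdiff(property_labels(), names(models))
  if (length(missing)) {
    stop("missing model(s) for propert", if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- length(sentences)
  hits <- matrix(0L, nrow = n, ncol = length(property_labels()),
                 dimnames = list(NULL, property_labels()))
  for (prop in property_labels()) {
    hits[, prop] <- predict_labels(models[[prop]], sentences)
  }
  keep <- which(rowSums(hits) > 0)
  out <- data.frame(
    pmid = vapply(sentences[keep], `[[`, character(1), "pmid"),
    doc_index = vapply(sentences[keep], function(s) as.integer(s$doc_index), integer(1)),
    text = vapply(sentences[keep], `[[`, character(1), "text"),
    stringsAsFactors = FALSE
  )
  out$properties <- lapply(keep, function(i) property_labels()[hits[i, ] == 1L])
  out
}

#' Keep only sentences mentioning the TF
#'
#' A sentence survives iff the TF name or one of its aliases occurs as a
#' whole token (word-boundary match, so TF "mat" does not match "format").
#' The canonical name is matched with exact case; alias case-sensitivity is
#' configurable.
#'
#' @param classified Data frame from \code{\link{classify_corpus}} (any data
#'   frame with a \code{text} column works).
#' @param tf_name Canonical TF name (non-empty).
#' @param aliases Additional names to accept.
#' @param alias_case_sensitive Match aliases with exact case? Default
#'   \code{FALSE}.
#' @return The filtered data frame.
#' @export
filter_by_tf <- function(classified, tf_name, aliases = character(),
                         alias_case_sensitive = FALSE) {
  if (!is_string(tf_name) || !nzchar(tf_name)) {
    stop("tf_name must be a non-empty string", call. = FALSE)
  }
  bound <- function(name) {
    sprintf("(^|[^[:alnum:]])%s([^[:alnum:]]|$)", regex_escape(name))
  }
  hit <- grepl(bound(tf_name), classified$text)
  for (al in aliases) {
    hit <- hit | grepl(bound(al), classified$text,
                       ignore.case = !alias_case_sensitive)
  }
  classified[hit, , drop = FALSE]
}

# Stop-word-free lowercase content tokens of a sentence, for dedup vectors
# and for ROUGE.
content_tokens <- function(text, stopwords = character()) {
  toks <- tolower(tokenize(text))
  toks <- toks[!is_punct_token(toks)]
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks <- toks[nzchar(toks)]
  toks[!(toks %in% tolower(stopwords))]
}

#' Redundancy reduction within one property section
#'
#' Sentences are represented as binary TF-IDF vectors over their
#' stop-word-free words, compared by cosine similarity, and ordered by the
#' leaf order of an average-linkage hierarchical clustering (so similar
#' sentences sit together).  Walking that order, the first sentence is
#' kept; each following sentence is hidden iff its cosine similarity to
#' the most recently kept sentence reaches the threshold, and kept
#' otherwise.  Every input sentence appears exactly once, visible or
#' hidden.
#'
#' @param texts Character vector of sentence texts (section order).
#' @param threshold Redundancy threshold in (0, 1]; default 0.8.  A
#'   sentence is redundant iff similarity >= threshold (the complement of
#'   "dissimilar: cosine similarity < 0.8").
#' @param stopwords Stop-word set excluded from the vectors.
#' @return Data frame in dendrogram leaf order with columns \code{index}
#'   (position in \code{texts}), \code{visible}, \code{cluster_id} and
#'   \code{similarity_to_kept} (NA for visible sentences).
#' @export
deduplicate <- function(texts, threshold = 0.8, stopwords = character()) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  n <- length(texts)
  empty <- data.frame(index = integer(), visible = logical(),
                      cluster_id = integer(), similarity_to_kept = numeric())
  if (!n) return(empty)
  if (n == 1L) {
    return(data.frame(index = 1L, visible = TRUE, cluster_id = 1L,
                      similarity_to_kept = NA_real_))
  }
  feats <- lapply(texts, content_tokens, stopwords = stopwords)
  if (all(!lengths(feats))) {
    return(data.frame(index = seq_len(n), visible = TRUE,
                      cluster_id = seq_len(n), similarity_to_kept = NA_real_))
  }
  space <- fit_vector_space(feats[lengths(feats) > 0],
                            representation_config(weighting = "BINARY_TFIDF"))
  X <- as.matrix(vectorize(feats, space))
  norms <- sqrt(rowSums(X^2))
  sim <- tcrossprod(X) / outer(pmax(norms, 1e-300), pmax(norms, 1e-300))
  sim[norms == 0, ] <- 0; sim[, norms == 0] <- 0
  diag(sim) <- 1
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  leaf <- hc$order
  clusters <- stats::cutree(hc, h = 1 - threshold)
  visible <- logical(n); sim_kept <- rep(NA_real_, n)
  last_kept <- NA_integer_
  for (pos in seq_along(leaf)) {
    i <- leaf[pos]
    if (is.na(last_kept) || sim[i, last_kept] < threshold) {
      visible[i] <- TRUE
      last_kept <- i
    } else {
      sim_kept[i] <- sim[i, last_kept]
    }
  }
  data.frame(index = leaf, visible = visible[leaf],
             cluster_id = as.integer(clusters[leaf]),
             similarity_to_kept = sim_kept[leaf])
}

#' Assemble a per-TF summary from classified sentences
#'
#' Sections follow the canonical property order; a sentence predicted with
#' several properties appears in every corresponding section.  Redundancy
#' reduction runs independently per section.
#'
#' @param tf_name TF the summary describes.
#' @param classified Data frame from \code{\link{classify_corpus}} (after
#'   \code{\link{filter_by_tf}}).
#' @param threshold Redundancy threshold, see \code{\link{deduplicate}}.
#' @param stopwords Stop-word set for the dedup vectors.
#' @return A \code{tfsumr_summary}: list with \code{tf_name},
#'   \code{sections} (named list of data frames in dendrogram order with
#'   columns \code{pmid}, \code{text}, \code{properties}, \code{visible},
#'   \code{cluster_id}, \code{similarity_to_kept}) and \code{n_articles}.
#' @export
build_summary <- function(tf_name, classified, threshold = 0.8,
                          stopwords = character()) {
  sections <- list()
  for (prop in property_labels()) {
    in_prop <- vapply(classified$properties, function(p) prop %in% p, logical(1))
    sub <- classified[in_prop, , drop = FALSE]
    if (!nrow(sub)) next
    dd <- deduplicate(sub$text, threshold, stopwords)
    sec <- sub[dd$index, , drop = FALSE]
    sec$visible <- dd$visible
    sec$cluster_id <- dd$cluster_id
    sec$similarity_to_kept <- dd$similarity_to_kept
    rownames(sec) <- NULL
    sections[[prop]] <- sec
  }
  structure(list(tf_name = tf_name, sections = sections,
                 n_articles = length(unique(classified$pmid))),
            class = "tfsumr_summary")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Render a summary as an HTML document
#'
#' One section per property with a human-readable heading (empty sections
#' are omitted); visible sentences are listed in dendrogram order; hidden
#' (redundant) sentences are present in the markup, collapsed under a
#' "similar sentences" disclosure the curator can expand.  Every sentence
#' is followed by its PubMed ID rendered as a hyperlink to the article.
#'
#' @param summary A \code{tfsumr_summary}.
#' @param pubmed_url_template \code{sprintf} template with one \code{\%s}
#'   slot for the PMID.
#' @return A single well-formed HTML document string.
#' @export
render_html <- function(summary,
                        pubmed_url_template = "https://pubmed.ncbi.nlm.nih.gov/%s/") {
  li <- function(row, cls) {
    sprintf('<li class="sentence %s">%s <a class="pmid" href="%s">%s</a></li>',
            cls, html_escape(row$text),
            html_escape(sprintf(pubmed_url_template, row$pmid)), row$pmid)
  }
  out <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>Automatic summary of %s</title>", html_escape(summary$tf_name)),
    "<style>li.hidden{color:#777;} details{margin-left:1.5em;}</style>",
    "</head><body>",
    sprintf("<h1>Automatic summary of %s</h1>", html_escape(summary$tf_name)),
    sprintf("<p class=\"meta\">Extracted from %d article%s.</p>",
            summary$n_articles, if (summary$n_articles == 1) "" else "s")
  )
  for (prop in names(summary$sections)) {
    sec <- summary$sections[[prop]]
    out <- c(out,
             sprintf('<section id="%s"><h2>%s</h2>', prop, property_headings[[prop]]),
             "<ul>")
    i <- 1L
    while (i <= nrow(sec)) {
      out <- c(out, li(sec[i, ], "visible"))
      j <- i + 1L
      hidden <- character()
      while (j <= nrow(sec) && !sec$visible[j]) {
        hidden <- c(hidden, li(sec[j, ], "hidden"))
        j <- j + 1L
      }
      if (length(hidden)) {
        out <- c(out,
                 sprintf("<details><summary>%d similar sentence%s</summary><ul>",
                         length(hidden), if (length(hidden) == 1) "" else "s"),
                 hidden, "</ul></details>")
      }
      i <- j
    }
    out <- c(out, "</ul></section>")
  }
  paste(c(out, "</body></html>"), collapse = "\n")
}

#' Parse a rendered summary back into a table
#'
#' Recovers the visible/hidden partition, section membership and PMIDs from
#' the HTML produced by \code{\link{render_html}}.
#'
#' @param html HTML document string.
#' @return Data frame with columns \code{property}, \code{text},
#'   \code{pmid}, \code{visible}.
#' @export
parse_summary_html <- function(html) {
  doc <- xml2::read_html(html)
  rows <- list()
  for (sec in xml2::xml_find_all(doc, "//section")) {
    prop <- xml2::xml_attr(sec, "id")
    for (node in xml2::xml_find_all(sec, ".//li")) {
      a <- xml2::xml_find_first(node, "./a[@class='pmid']")
      pmid <- xml2::xml_text(a)
      text <- trimws(sub(paste0(regex_escape(pmid), "\\s*$"), "",
                         xml2::xml_text(node)))
      cls <- xml2::xml_attr(node, "class")
      rows[[length(rows) + 1L]] <- data.frame(
        property = prop, text = text, pmid = pmid,
        visible = grepl("\\bvisible\\b", cls), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(property = character(), text = character(),
                      pmid = character(), visible = logical()))
  }
  do.call(rbind, rows)
}

#' End-to-end summarization of an article collection
#'
#' Annotates, classifies, filters by TF mention, assembles and (optionally)
#' renders the summary for one TF.
#'
#' @param articles Data frame of article sentences (\code{pmid},
#'   \code{text}, \code{doc_index}).
#' @param models Named list of the six fitted property models.
#' @param tf_name Canonical TF name.
#' @param lex Lexicon used for annotation (must match the one the models
#'   were trained with).
#' @param aliases Alternative TF names.
#' @param threshold Redundancy threshold.
#' @param stopwords Stop words for the dedup vectors.
#' @param tagger Lemma/POS tagger.
#' @return A \code{tfsumr_summary}.
#' @export
summarize_collection <- function(articles, models, tf_name, lex,
                                 aliases = character(), threshold = 0.8,
                                 stopwords = character(),
                                 tagger = fallback_tagger) {
  ann <- annotate_sentences(articles, lex, tagger)
  classified <- classify_corpus(ann, models)
  classified <- filter_by_tf(classified, tf_name, aliases)
  build_summary(tf_name, classified, threshold, stopwords)
}
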