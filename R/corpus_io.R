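# On-disk artifacts: article sentence collections (JSONL/TSV), property-tagged
# manual summaries (XML), lexicons and stop-word lists (one term per line).
# All files are read and written as UTF-8.

#' Read an article sentence collection
#'
#' An article collection is a flat file of sentences, each carrying the
#' PubMed identifier of the article it came from.  Two dialects are
#' supported: JSON-lines (one object per line with fields \code{pmid} and
#' \code{text}) and tab-separated (\code{pmid<TAB>text}, no header).
#'
#' @param path Path to the collection file.
#' @param format Either \code{"jsonl"} (default) or \code{"tsv"}.
#' @return A data frame with columns \code{pmid} (character), \code{text}
#'   (character) and \code{doc_index} (integer, ordinal position of the
#'   sentence within its article, starting at 0), in file order.
#' @export
read_article_collection <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(pmid = character(), text = character(),
                      doc_index = integer(), stringsAsFactors = FALSE))
  }
  recs <- lapply(seq_along(lines), function(i) {
    ln <- lines[[i]]
    if (format == "jsonl") {
      rec <- tryCatch(jsonlite::fromJSON(ln),
                      error = function(e) stop("malformed JSON record at line ", i,
                                               ": ", conditionMessage(e), call. = FALSE))
      if (is.null(rec$pmid)) stop("missing pmid at line ", i, call. = FALSE)
      if (is.null(rec$text)) stop("missing text at line ", i, call. = FALSE)
      pmid <- as.character(rec$pmid)
      text <- as.character(rec$text)
    } else {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L) {
        stop("malformed TSV record at line ", i, ": expected pmid<TAB>text",
             call. = FALSE)
      }
      pmid <- parts[[1]]
      text <- paste(parts[-1L], collapse = "\t")
    }
    if (!nzchar(trimws(text))) stop("blank sentence text at line ", i, call. = FALSE)
    if (!grepl("^[0-9]{1,9}$", pmid)) {
      stop("invalid pmid '", pmid, "' at line ", i, call. = FALSE)
    }
    data.frame(pmid = pmid, text = trimws(text), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$doc_index <- as.integer(stats::ave(seq_len(nrow(out)), out$pmid,
                                         FUN = seq_along)) - 1L
  out
}

#' Write an article sentence collection
#'
#' @param sentences Data frame with columns \code{pmid} and \code{text}.
#' @param path Output path.
#' @param format \code{"jsonl"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_article_collection <- function(sentences, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  check_pmid(sentences$pmid)
  lines <- if (format == "jsonl") {
    vapply(seq_len(nrow(sentences)), function(i) {
      jsonlite::toJSON(list(pmid = sentences$pmid[i], text = sentences$text[i]),
                       auto_unbox = TRUE)
    }, character(1))
  } else {
    paste(sentences$pmid, sentences$text, sep = "\t")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read property-tagged manual summaries
#'
#' Manual TF summaries are stored as one XML document: a \code{<summaries>}
#' root holding one \code{<summary tf="...">} element per TF, each containing
#' \code{<s pmid="...">} sentence elements.  Inside a sentence, spans relevant
#' to a property are wrapped in a tag named after the property
#' (\code{<ACT>...</ACT>} etc.; tags may nest or cover the whole sentence).
#' A sentence receives the union of all property tags enclosing any part of
#' it; untagged sentences are negative examples for all six properties.
#'
#' @param path Path to the tagged-summary XML file.
#' @return A data frame with columns \code{tf_name}, \code{pmid},
#'   \code{doc_index}, \code{text} and \code{labels} (a list column of
#'   character vectors, possibly empty).
#' @export
read_labeled_summaries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path, encoding = "UTF-8"),
                  error = function(e) stop("malformed tagged-summary file (",
                                           conditionMessage(e), ")", call. = FALSE))
  rows <- list()
  for (summ in xml2::xml_find_all(doc, "./summary")) {
    tf <- xml2::xml_attr(summ, "tf")
    if (is.na(tf) || !nzchar(tf)) stop("summary element without tf attribute", call. = FALSE)
    sents <- xml2::xml_find_all(summ, "./s")
    for (i in seq_along(sents)) {
      s <- sents[[i]]
      pmid <- xml2::xml_attr(s, "pmid")
      if (is.na(pmid)) stop("sentence without pmid in summary for ", tf, call. = FALSE)
      check_pmid(pmid)
      inner <- xml2::xml_name(xml2::xml_find_all(s, ".//*"))
      check_property_labels(inner)
      labels <- sort(unique(inner))
      text <- trimws(xml2::xml_text(s))
      if (!nzchar(text)) stop("empty sentence in summary for ", tf, call. = FALSE)
      rows[[length(rows) + 1L]] <- list(tf_name = tf, pmid = pmid,
                                        text = text, labels = labels)
    }
  }
  out <- data.frame(
    tf_name = vapply(rows, `[[`, character(1), "tf_name"),
    pmid    = vapply(rows, `[[`, character(1), "pmid"),
    text    = vapply(rows, `[[`, character(1), "text"),
    stringsAsFactors = FALSE
  )
  out$labels <- lapply(rows, `[[`, "labels")
  out$doc_index <- if (nrow(out)) {
    as.integer(stats::ave(seq_len(nrow(out)), out$pmid, FUN = seq_along)) - 1L
  } else integer()
  out[, c("tf_name", "pmid", "doc_index", "text", "labels")]
}

#' Write property-tagged manual summaries
#'
#' Inverse of \code{\link{read_labeled_summaries}}: sentences with labels are
#' wrapped in nested property tags (outermost first in canonical order), so a
#' round trip preserves the label set of every sentence.
#'
#' @param summaries Data frame as returned by \code{read_labeled_summaries}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_labeled_summaries <- function(summaries, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c("<summaries>")
  for (tf in unique(summaries$tf_name)) {
    lines <- c(lines, sprintf("  <summary tf=\"%s\">", esc(tf)))
    sub <- summaries[summaries$tf_name == tf, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      labels <- intersect(property_labels(), sub$labels[[i]])
      body <- esc(sub$text[i])
      for (lab in rev(labels)) body <- sprintf("<%s>%s</%s>", lab, body, lab)
      lines <- c(lines, sprintf("    <s pmid=\"%s\">%s</s>", sub$pmid[i], body))
    }
    lines <- c(lines, "  </summary>")
  }
  lines <- c(lines, "</summaries>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Build a lexicon from term/tag pairs
#'
#' A lexicon maps terms (single words or multiword phrases) to NER tag
#' symbols such as \code{ACTTF} (transcription factor name) or \code{ACTREG}
#' (verb of regulation).  Entity-name tags are typically matched
#' case-sensitively (protecting short gene symbols), ordinary term tags
#' case-insensitively.
#'
#' @param terms Character vector of terms.
#' @param tags Character vector of tag symbols, recycled if length 1.
#' @param case_sensitive Logical, per entry (recycled): match exact case?
#' @return An object of class \code{tfsumr_lexicon}.
#' @export
lexicon <- function(terms, tags, case_sensitive = FALSE) {
  if (!length(terms)) {
    out <- data.frame(term = character(), tag = character(),
                      case_sensitive = logical(), stringsAsFactors = FALSE)
    class(out) <- c("tfsumr_lexicon", "data.frame")
    return(out)
  }
  terms <- trimws(terms)
  if (any(!nzchar(terms))) stop("lexicon terms must be non-empty", call. = FALSE)
  out <- data.frame(term = terms,
                    tag = rep_len(tags, length(terms)),
                    case_sensitive = rep_len(case_sensitive, length(terms)),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  dup <- duplicated(out$term)
  if (any(dup)) {
    stop("term(s) mapped to more than one tag: ",
         paste(unique(out$term[dup]), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("tfsumr_lexicon", "data.frame")
  out
}

#' Read lexicon files into a merged lexicon
#'
#' @param spec Named list mapping a tag symbol to one or more file paths;
#'   each file holds one term per line.
#' @param case_sensitive_tags Character vector of tags whose entries are
#'   matched with exact case (entity-name lexicons: TF, gene, TU names).
#'   All other tags are matched case-insensitively.
#' @return A \code{tfsumr_lexicon}.  Duplicate terms with the same tag are
#'   deduplicated; a term mapped to two different tags is an error.
#' @export
read_lexicons <- function(spec, case_sensitive_tags = character()) {
  terms <- character(); tags <- character()
  for (tag in names(spec)) {
    for (path in spec[[tag]]) {
      if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
      tm <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
      tm <- tm[nzchar(tm)]
      terms <- c(terms, tm)
      tags <- c(tags, rep(tag, length(tm)))
    }
  }
  lexicon(terms, tags, case_sensitive = tags %in% case_sensitive_tags)
}

#' Read a stop-word list
#'
#' @param path Path to a file with one lowercase term per line.
#' @return Character vector (a set; duplicates removed).  Lookups downstream
#'   are case-insensitive.
#' @export
read_stopwords <- function(path) {
  if (!file.exists(path)) stop("stop-word file not found: ", path, call. = FALSE)
  words <- tolower(trimws(readLines(path, encoding = "UTF-8", warn = FALSE)))
  words <- unique(words[nzchar(words)])
  if (!length(words)) warning("stop-word file is empty: ", path, call. = FALSE)
  words
}
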