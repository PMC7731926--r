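# Linguistic preprocessing: sentence segmentation, whitespace tokenization
# with punctuation detachment, a pluggable lemma/POS tagger with a naive
# deterministic fallback, dictionary NER (leftmost-longest) and DNA-motif
# tagging.

abbreviations <- c("e.g", "i.e", "et al", "al", "fig", "figs", "dr", "vs",
                   "cf", "sp", "subsp", "spp", "no", "approx", "ca", "st")

#' Segment a document into sentences
#'
#' Splits at sentence-final punctuation followed by whitespace and an
#' upper-case letter or digit, guarding common abbreviations and single
#' capital initials (so "E. coli grows." stays one sentence).  Terminal
#' punctuation is kept with its sentence.
#'
#' @param text A document string.
#' @return Character vector of non-empty sentences (empty input gives an
#'   empty vector).
#' @export
segment <- function(text) {
  if (is.null(text) || !nzchar(trimws(text))) return(character())
  m <- gregexpr("[.?!]+(?=\\s+[A-Z0-9(])", text, perl = TRUE)[[1]]
  cuts <- integer()
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in ends) {
      head <- substr(text, 1, e)
      word <- regmatches(head, regexpr("[^[:space:]]+$", head))
      stem <- sub("[.?!]+$", "", word)
      if (grepl("^\\(?[A-Z]$", stem)) next              # single-initial abbreviation
      two <- regmatches(head, regexpr("[^[:space:]]+ [^[:space:]]+$", head))
      two_stem <- if (length(two)) tolower(sub("[.?!]+$", "", two)) else ""
      if (tolower(stem) %in% abbreviations || two_stem %in% abbreviations) next
      cuts <- c(cuts, e)
    }
  }
  starts <- c(1L, cuts + 1L)
  stops <- c(cuts, nchar(text))
  out <- trimws(substring(text, starts, stops))
  out[nzchar(out)]
}

#' Tokenize a sentence
#'
#' Splits on whitespace, then detaches leading and trailing punctuation into
#' their own tokens.  Internal hyphens are preserved, so biomedical compounds
#' such as "toxin-antitoxin" remain single tokens.
#'
#' @param text A sentence string.
#' @return Character vector of tokens whose concatenation reconstructs the
#'   sentence up to whitespace.
#' @export
tokenize <- function(text) {
  raw <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  raw <- raw[nzchar(raw)]
  out <- character()
  for (tok in raw) {
    lead <- regmatches(tok, regexpr("^[\"'([{]+", tok))
    core <- sub("^[\"'([{]+", "", tok)
    trail <- regmatches(core, regexpr("[.,;:!?\"')\\]}]+$", core, perl = TRUE))
    core <- sub("[.,;:!?\"')\\]}]+$", "", core, perl = TRUE)
    pieces <- c(
      if (length(lead)) strsplit(lead, "")[[1]],
      if (nzchar(core)) core,
      if (length(trail)) strsplit(trail, "")[[1]]
    )
    out <- c(out, pieces)
  }
  out
}

is_punct_token <- function(tokens) grepl("^[[:punct:]]+$", tokens) &
  !grepl("[[:alnum:]]", tokens)

# Closed-class POS/lemma table for the fallback tagger.
closed_class <- data.frame(
  surface = c("the", "a", "an", "this", "that", "these", "those",
              "in", "of", "at", "on", "by", "for", "with", "from", "as",
              "into", "within", "under", "between", "during", "through",
              "to", "and", "or", "but", "nor",
              "be", "is", "are", "am", "was", "were", "been", "being",
              "it", "they", "we", "he", "she", "i", "you",
              "can", "may", "must", "will", "should", "could", "would",
              "not"),
  pos = c(rep("DT", 7), rep("IN", 15), "TO", rep("CC", 4),
          "VB", "VBZ", "VBP", "VBP", "VBD", "VBD", "VBN", "VBG",
          rep("PRP", 7), rep("MD", 7), "RB"),
  lemma = c("the", "a", "an", "this", "that", "these", "those",
            "in", "of", "at", "on", "by", "for", "with", "from", "as",
            "into", "within", "under", "between", "during", "through",
            "to", "and", "or", "but", "nor",
            rep("be", 8),
            "it", "they", "we", "he", "she", "i", "you",
            "can", "may", "must", "will", "should", "could", "would",
            "not"),
  stringsAsFactors = FALSE
)

#' Naive fallback lemma/POS tagger
#'
#' A deterministic stand-in for a full lemmatizer/POS engine, adequate for
#' the regular vocabulary of synthetic corpora and for smoke use: lemmas are
#' lowercased surfaces with plural/verbal suffixes stripped
#' (-ies/-ied to -y, -ing/-ed/-es to -e, bare -s dropped), POS comes from a
#' small closed-class table, suffix heuristics (-ing VBG, -ed VBN, -s VBZ)
#' or NN.  Punctuation tokens tag as themselves.  Any tagger honouring the
#' same contract (deterministic, one (lemma, pos) pair per token) can replace
#' it via the \code{tagger} argument of \code{\link{annotate_linguistic}}.
#'
#' @param tokens Character vector of surface tokens.
#' @return Data frame with columns \code{lemma} and \code{pos}, one row per
#'   token.
#' @export
fallback_tagger <- function(tokens) {
  n <- length(tokens)
  lemma <- character(n); pos <- character(n)
  for (i in seq_len(n)) {
    tok <- tokens[i]
    low <- tolower(tok)
    if (is_punct_token(tok)) {
      lemma[i] <- tok; pos[i] <- tok
      next
    }
    hit <- match(low, closed_class$surface)
    if (!is.na(hit)) {
      lemma[i] <- closed_class$lemma[hit]; pos[i] <- closed_class$pos[hit]
      next
    }
    lm <- low
    if (grepl("ies$", lm) && nchar(lm) > 4) lm <- sub("ies$", "y", lm)
    else if (grepl("ied$", lm) && nchar(lm) > 4) lm <- sub("ied$", "y", lm)
    else if (grepl("ing$", lm) && nchar(lm) > 5) lm <- sub("ing$", "e", lm)
    else if (grepl("ed$", lm) && nchar(lm) > 4) lm <- sub("ed$", "e", lm)
    else if (grepl("es$", lm) && nchar(lm) > 3) lm <- sub("es$", "e", lm)
    else if (grepl("[^su]s$", lm) && nchar(lm) > 3) lm <- sub("s$", "", lm)
    # no suffix stripped: keep the surface form (entity names keep case)
    lemma[i] <- if (identical(lm, low)) tok else lm
    pos[i] <- if (grepl("ing$", low) && nchar(low) > 5) "VBG"
      else if (grepl("ed$", low) && nchar(low) > 4) "VBN"
      else if (grepl("[^su]s$", low) && nchar(low) > 3) "VBZ"
      else "NN"
  }
  data.frame(lemma = lemma, pos = pos, stringsAsFactors = FALSE)
}

#' Annotate tokens with lemma and POS
#'
#' @param tokens Character vector of surface tokens.
#' @param tagger A function from a token vector to a data frame (or list)
#'   with one \code{lemma} and one \code{pos} per token; must be
#'   deterministic.  Defaults to \code{\link{fallback_tagger}}.
#' @return Data frame with columns \code{lemma} and \code{pos}.
#' @export
annotate_linguistic <- function(tokens, tagger = fallback_tagger) {
  if (!length(tokens)) {
    return(data.frame(lemma = character(), pos = character(),
                      stringsAsFactors = FALSE))
  }
  out <- tagger(tokens)
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (!all(c("lemma", "pos") %in% names(out)) || nrow(out) != length(tokens)) {
    stop("tagger must return one (lemma, pos) pair per token", call. = FALSE)
  }
  if (any(!nzchar(out$lemma))) stop("tagger produced an empty lemma", call. = FALSE)
  out[, c("lemma", "pos")]
}

#' Dictionary NER tagging (leftmost-longest)
#'
#' Scans tokens left to right; at each position the longest lexicon entry
#' (in tokens) that matches is taken and all its tokens receive that entry's
#' tag, so tagged spans never overlap.  Case sensitivity is honoured per
#' lexicon entry.
#'
#' @param tokens Character vector of surface tokens.
#' @param lex A \code{tfsumr_lexicon}.
#' @return Character vector of tags, \code{NA} where untagged; same length
#'   as \code{tokens}.
#' @export
annotate_ner <- function(tokens, lex) {
  n <- length(tokens)
  tags <- rep(NA_character_, n)
  if (!n || !nrow(lex)) return(tags)
  entry_len <- lengths(strsplit(lex$term, " ", fixed = TRUE))
  max_len <- max(entry_len)
  cs <- lex$case_sensitive
  cs_map <- stats::setNames(lex$tag[cs], lex$term[cs])
  ci_map <- stats::setNames(lex$tag[!cs], tolower(lex$term[!cs]))
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      span <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      tag <- cs_map[span]
      if (is.na(tag)) tag <- ci_map[tolower(span)]
      if (!is.na(tag)) {
        tags[i:(i + len - 1L)] <- tag
        matched <- len
        break
      }
    }
    i <- i + max(matched, 1L)
  }
  tags
}

#' Flag DNA-motif tokens
#'
#' A token is flagged as a DNA motif iff it is a run of at least six
#' characters over the uppercase alphabet A, C, G, T, N, the IUPAC
#' degeneracy letters W, S, R, Y, and the gap character '-'.  Both the
#' alphabet and the length threshold are configurable.
#'
#' @param tokens Character vector of surface tokens.
#' @param min_len Minimum motif length (default 6).
#' @param alphabet Characters allowed in a motif.
#' @return Logical vector, one flag per token.
#' @export
tag_dna_motifs <- function(tokens, min_len = 6L,
                           alphabet = c("A", "C", "G", "T", "N", "-",
                                        "W", "S", "R", "Y")) {
  if (!length(tokens)) return(logical())
  # literal '-' must sit at the end of the class, not form a range
  chars <- c(setdiff(alphabet, "-"), if ("-" %in% alphabet) "-")
  pat <- sprintf("^[%s]{%d,}$", paste(chars, collapse = ""), min_len)
  grepl(pat, tokens)
}

#' Fully annotate a sentence collection
#'
#' Runs tokenization, the lemma/POS tagger, dictionary NER and DNA-motif
#' tagging over a data frame of sentences, producing the annotated objects
#' that all classification and summarization functions consume.  Motif
#' tokens not already tagged by the lexicon receive the tag
#' \code{DNAMOTIF}.
#'
#' @param sentences Data frame with columns \code{pmid}, \code{text} and
#'   optionally \code{doc_index}.
#' @param lex A \code{tfsumr_lexicon} (may be empty).
#' @param tagger Lemma/POS tagger, see \code{\link{annotate_linguistic}}.
#' @return List of annotated sentences; each element is a list with fields
#'   \code{pmid}, \code{doc_index}, \code{text} and \code{tokens} (a data
#'   frame with columns \code{surface}, \code{lemma}, \code{pos},
#'   \code{ner}).
#' @export
annotate_sentences <- function(sentences, lex = lexicon(character(), character()),
                               tagger = fallback_tagger) {
  lapply(seq_len(nrow(sentences)), function(i) {
    toks <- tokenize(sentences$text[i])
    lp <- annotate_linguistic(toks, tagger)
    ner <- annotate_ner(toks, lex)
    motif <- tag_dna_motifs(toks)
    ner[is.na(ner) & motif] <- "DNAMOTIF"
    structure(list(
      pmid = sentences$pmid[i],
      doc_index = if ("doc_index" %in% names(sentences)) sentences$doc_index[i] else 0L,
      text = sentences$text[i],
      tokens = data.frame(surface = toks, lemma = lp$lemma, pos = lp$pos,
                          ner = ner, stringsAsFactors = FALSE)
    ), class = "tfsumr_annotated")
  })
}
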