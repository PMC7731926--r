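# Evaluation of knowledge extraction: stop-word-free ROUGE-1 recall and
# precision between a manual and an automatic summary, per-TF property
# coverage (properties gained and missed by the automatic summary), and
# aggregation of curator relevance judgements.

#' ROUGE-1 between a manual and an automatic summary
#'
#' Both texts are lowercased, punctuation-stripped and stop-word-filtered.
#' The default overlap is the standard clipped multiset count: for every
#' word type, min(count in manual, count in automatic), summed.  Recall
#' divides the overlap by the manual summary's word count (how much of the
#' curated knowledge was recovered); precision divides by the automatic
#' summary's word count.  \code{mode = "types"} counts each overlapping
#' word type once instead.
#'
#' @param manual_text,auto_text Summary texts (non-empty after stop-word
#'   removal).
#' @param stopwords Stop-word set (case-insensitive).
#' @param mode \code{"clipped"} (default) or \code{"types"}.
#' @return A \code{tfsumr_rouge} list: \code{overlap_count},
#'   \code{manual_word_count}, \code{auto_word_count}, \code{recall},
#'   \code{precision}.
#' @export
rouge1 <- function(manual_text, auto_text, stopwords = character(),
                   mode = c("clipped", "types")) {
  mode <- match.arg(mode)
  man <- content_tokens(paste(manual_text, collapse = " "), stopwords)
  aut <- content_tokens(paste(auto_text, collapse = " "), stopwords)
  if (!length(man)) stop("manual summary is empty after stop-word removal",
                         call. = FALSE)
  if (!length(aut)) stop("automatic summary is empty after stop-word removal",
                         call. = FALSE)
  if (mode == "types") { man <- unique(man); aut <- unique(aut) }
  mc <- table(man); ac <- table(aut)
  shared <- intersect(names(mc), names(ac))
  overlap <- sum(pmin(as.numeric(mc[shared]), as.numeric(ac[shared])))
  structure(list(overlap_count = overlap,
                 manual_word_count = length(man),
                 auto_word_count = length(aut),
                 recall = overlap / length(man),
                 precision = overlap / length(aut)),
            class = "tfsumr_rouge")
}

#' Property coverage of an automatic summary against a manual one
#'
#' The manual property set is the union of the labels of the TF's manual
#' sentences; the automatic property set contains the sections with at
#' least one visible sentence.  "Additional" properties appear only in the
#' automatic summary, "missing" ones only in the manual summary.
#'
#' @param manual Data frame of labeled manual sentences for one TF
#'   (columns \code{tf_name} and \code{labels}).
#' @param auto A \code{tfsumr_summary} for the same TF.
#' @return A one-row data frame: \code{tf_name}, \code{manual_properties}
#'   and \code{auto_properties} (list columns), \code{shared},
#'   \code{additional}, \code{missing}.
#' @export
property_coverage <- function(manual, auto) {
  tfs <- unique(manual$tf_name)
  if (length(tfs) != 1L || !identical(tfs, auto$tf_name)) {
    stop("manual and automatic summaries describe different TFs", call. = FALSE)
  }
  manual_props <- sort(unique(unlist(manual$labels)))
  auto_props <- names(auto$sections)[vapply(auto$sections,
                                            function(s) any(s$visible), logical(1))]
  auto_props <- intersect(property_labels(), auto_props)
  out <- data.frame(tf_name = tfs,
                    shared = length(intersect(manual_props, auto_props)),
                    additional = length(setdiff(auto_props, manual_props)),
                    missing = length(setdiff(manual_props, auto_props)),
                    stringsAsFactors = FALSE)
  out$manual_properties <- list(manual_props)
  out$auto_properties <- list(auto_props)
  out
}

#' Distribution of additional properties over a TF collection
#'
#' @param entries Data frame with one row per TF and an \code{additional}
#'   column (e.g. stacked \code{\link{property_coverage}} rows).
#' @return List with \code{histogram} (TF counts for 0..6 additional
#'   properties) and \code{percent_with_additional} (percentage of TFs that
#'   gained at least one property, rounded half away from zero to an
#'   integer).
#' @export
coverage_distribution <- function(entries) {
  if (!nrow(entries)) stop("no coverage entries", call. = FALSE)
  add <- entries$additional
  hist <- table(factor(add, levels = 0:6))
  list(histogram = stats::setNames(as.integer(hist), names(hist)),
       percent_with_additional = round_half_away(100 * sum(add >= 1) / length(add)))
}

#' Aggregate curator relevance judgements
#'
#' Curators judge each automatic-summary sentence twice: is it relevant for
#' its assigned property (which also scores the property assignment), and
#' is it relevant for describing the TF at all.  Percentages are computed
#' per evaluator and averaged; the macro average is the unweighted mean of
#' the per-property percentages, rounded half away from zero.
#'
#' @param evaluations Data frame with columns \code{sentence_id},
#'   \code{property}, \code{relevant_for_property} (logical),
#'   \code{relevant_for_tf} (logical) and \code{evaluator}.
#' @return List with \code{per_property} (named vector of
#'   correctly-classified percentages), \code{macro_average} (integer),
#'   \code{percent_relevant} (percentage of sentences relevant for the TF).
#' @export
curator_report <- function(evaluations) {
  check_property_labels(evaluations$property)
  rates <- numeric()
  for (prop in property_labels()) {
    sub <- evaluations[evaluations$property == prop, , drop = FALSE]
    if (!nrow(sub)) {
      warning("no evaluated sentences for property ", prop, "; omitted",
              call. = FALSE)
      next
    }
    by_eval <- tapply(sub$relevant_for_property, sub$evaluator,
                      function(v) 100 * mean(v))
    rates[prop] <- mean(by_eval)
  }
  rel_by_eval <- tapply(evaluations$relevant_for_tf, evaluations$evaluator,
                        function(v) 100 * mean(v))
  list(per_property = rates,
       macro_average = round_half_away(mean(rates)),
       percent_relevant = round_half_away(mean(rel_by_eval)))
}
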