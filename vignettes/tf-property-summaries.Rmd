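---
title: "Extracting transcription-factor property sentences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting transcription-factor property sentences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfsumr)
```

## The curation problem

Curated databases of bacterial transcriptional regulation describe each
transcription factor (TF) in a short prose summary covering a recurring set
of properties: its transcriptional activity and effectors (ACT), structural
domains (DOM), evolutionary family (EVO), the biological processes of its
regulated genes (RP), its DNA binding sites (SITE) and the organization of
the transcription unit encoding it (TU).  Writing such summaries by hand
means reading dozens of papers per TF.  `tfsumr` assists that work with
extractive multi-document summarization: six independent binary classifiers
decide, sentence by sentence, whether a sentence from an article collection
describes each property, and the positive sentences are assembled into an
HTML draft a curator can prune.

Because a sentence may describe several properties at once, the problem is
multi-label by construction, and it is solved as six separate binary
decisions rather than one multi-class decision.

## Training data and class imbalance

Training examples are sentences of existing manual summaries, tagged at the
sentence level with the properties they describe (`<ACT>...</ACT>` and so
on, read by `read_labeled_summaries()`; a sentence takes the union of all
tags that enclose any part of it, and untagged sentences are negatives for
all six properties).  In a realistic training set each property's positive
class is a small minority — on the order of 6–15% of a few thousand
sentences — so every design choice downstream is made under class
imbalance:

* **Score.** Plain accuracy is useless at a 6% positive rate.  Model
  quality is measured by the G-mean, the geometric mean of sensitivity
  (TP/(TP+FN)) and specificity (TN/(TN+FP)).  Either class fully missed
  zeroes the score.
* **Under-sampling.** Four majority-class under-samplers are implemented
  from scratch: random under-sampling to exact 1:1 balance; Tomek-link
  removal (drop the negative of every mutual-nearest-neighbor
  opposite-class pair); one-sided selection (a 1NN-consistent negative
  subset, then Tomek cleaning); and an instance-hardness threshold
  (drop negatives whose cross-fitted own-class probability is low).  No
  sampler ever touches a positive example.
* **Class weighting.** Alternatively, the SVM's misclassification penalty
  can be rescaled per class (`class_weighting = "balanced"`).

## Sentence representation

Tokens are annotated with a lemma, a POS tag and, where a dictionary
matches, a NER tag (`ACTTF` for TF names, `ACTREG` for verbs of regulation,
and so on).  Dictionary matching is leftmost-longest over possibly
multiword entries; entity-name dictionaries match exact case (protecting
short gene symbols such as `mat` from matching inside "format"), term
dictionaries match case-insensitively.  A configurable regular expression
flags DNA motifs: by default a token of six or more characters over
`A C G T N W S R Y -` (the IUPAC degeneracy letters and the gap character).

Three feature combinations are available per sentence:

* `LEMMA_POS_NER` — the lemma sequence, followed by the POS sequence in
  which every NER-tagged position shows its NER tag instead of the POS tag;
* `LEMMA_NER` — the lemma sequence followed by the NER tags alone;
* `NER_FOR_LEMMA` — the lemma sequence with NER tags substituted in place.

Punctuation tokens carry no content and are excluded from feature streams.
N-grams are cumulative (all orders 1..`ngram_max`, `ngram_max` ≤ 3) and
never cross the boundary between the lemma block and an appended tag block
— a bigram gluing the last lemma to the first tag would be a linguistically
meaningless concatenation.

Three vectorizations are supported: binary presence, TF-IDF
(count × idf with idf(f) = ln((1+N)/(1+df(f))) + 1, i.e. add-one smoothing
with a +1 floor and no length normalization), and binary TF-IDF, in which
every strictly positive TF-IDF weight becomes 1.  The last scheme therefore
coincides with binary presence on any input; it is kept as a distinct
configuration because the weighting is part of a model's declared
configuration.  Dimensionality is treated either by truncated SVD (no
centering; study-scale defaults 200 and 300 dimensions) or by chi-squared
feature selection on the 2×2 feature-presence/class table (defaults 1000,
800, 500 features; ties broken lexicographically so selection is
deterministic).

## Model selection

`stratified_cv()` runs 10-fold stratified cross-validation in which the
*entire* chain — vocabulary, idf, reducer, under-sampler and SVM — is
fitted on the nine training folds only.  Validation folds keep the original
imbalance, under-sampling never sees a validation row, and the union of
validation folds is the dataset.  `grid_search()` ranks configurations by
highest median fold G-mean, breaking ties by lower interquartile range,
then lower absolute skewness (adjusted Fisher–Pearson over fold scores),
then grid order: the most consistent model wins, not merely the best
median.  The SVM decision threshold is fixed at 0; no probability
calibration is applied.

## Summarization and redundancy reduction

At prediction time the six models classify every article sentence; a
sentence with no positive decision is dropped, and the rest are kept only
if they mention the target TF as a whole token (exact case for the
canonical name, configurable for aliases).  Sentences are grouped into the
six property sections; a multi-label sentence appears in every section it
was predicted for.

Within each section, redundancy is reduced independently: sentences become
binary TF-IDF vectors over their stop-word-free words, the cosine
similarity matrix feeds average-linkage hierarchical clustering, and
sentences are reordered by dendrogram leaf order so near-duplicates sit
together.  Walking that order, the first sentence is kept and each
subsequent sentence is hidden iff its similarity to the most recently kept
sentence is at least the threshold (default 0.8).  The boundary is
resolved as *redundant iff similarity ≥ 0.8*, the strict complement of
"dissimilar" meaning similarity < 0.8.  Hidden sentences are not discarded:
the HTML rendering keeps them collapsed under a disclosure element, with
every sentence linking to its PubMed record.  De-duplication is within
sections only; the same fact stated under two properties is deliberately
retained in both.

## Evaluation

`rouge1()` computes ROUGE-1 recall and precision without stop words:
texts are lowercased, punctuation-stripped and stop-word-filtered, and the
overlap is the clipped multiset count (per word type,
min(count in manual, count in automatic)); a word-type variant is available
via `mode = "types"`.  No stemming is applied in evaluation — lemmatization
belongs to training, not scoring.  Recall normalizes by the manual summary,
which is the score of interest for assisted curation (the goal is to miss
little, not to be short).  `property_coverage()` and
`coverage_distribution()` report, per TF, the properties an automatic
summary adds to and misses from the manual one; `curator_report()` averages
per-evaluator relevance judgements per property and macro-averages across
properties.  All printed percentages round half away from zero, so a macro
average of 64.5 reports as 65.

## The synthetic corpus generator

Real training corpora are proprietary database exports, so
`make_corpus()` generates corpora with the same statistical structure:
`corpus_spec()` defaults to 2244 sentences over 177 TFs with per-property
positive rates ACT 12%, DOM 15%, EVO 7%, RP 12%, SITE 6%, TU 7% (positive
counts use floor(rate × n), recorded in the corpus metadata).  Each
property gets a disjoint planted keyword vocabulary entered into the
lexicon, plus decoy terms that share the property's NER tag but not its
word form — so tag-only representations are ambiguous and lemma features
are needed to separate decoys from keywords.  Positive sentences name a
TF, planted keywords (with probability `keyword_injection_rate`) and
filler; negatives are filler with decoys at `noise_rate`.  The article
collection mirrors the training sentences with synonym swaps confined to
the filler vocabulary (never keywords or TF names) and appends duplicates
at `duplicate_rate`, with gold labels recorded throughout.  Generation is
template-based so gold labels are exact by construction, and a fixed seed
reproduces a corpus bit for bit.

What the generator does *not* emulate: real biomedical prose, vocabulary
burstiness, label noise in curator tagging, and sentences whose property
is expressed without any characteristic keyword.  Green tests on synthetic
corpora therefore demonstrate that the machinery is correct and that the
protocol recovers plantable signal at study-scale imbalance; they do not
certify real-corpus G-means.

## Numerical and design choices

* Segmentation guards single-capital initials ("E. coli") and a short
  abbreviation list; tokenization splits on whitespace and detaches
  terminal punctuation, keeping hyphenated compounds whole.
* The built-in lemma/POS tagger is a deliberately naive, deterministic
  fallback (suffix stripping plus a closed-class table); any engine
  honouring the pluggable contract — one deterministic (lemma, pos) pair
  per token — can replace it without code changes.
* Distances for all samplers are Euclidean on the vectorized (possibly
  reduced) representation; nearest-neighbor ties break to the lowest row
  index.
* The instance-hardness learner is an SVM with a logistic link fitted on
  its decision values; cross-fitting is 5-fold.  A negative is removable
  when its cross-fitted own-class probability falls below 0.5, and
  removal stops before the negatives would drop below the positive count
  — so separable data loses nothing and the kept count is an output, not
  a parameter.
* Dendrogram leaf order and `hclust` tie handling are deterministic given
  the input order, which is the corpus order.
* Test suites and the acceptance script run the protocol at reduced
  problem sizes (hundreds of sentences, compact grids); these sizes are
  the package's own choice of desk-scale defaults and are stated where
  used.

## Known limitations

* TF filtering is a token match; sentences referring to the TF only by
  anaphora ("this regulator…") are lost, and no coreference resolution is
  attempted.
* The TU property is intrinsically hard: sentences about regulation *of*
  transcription units by the TF are easily confused with sentences about
  the unit *encoding* the TF.
* Abstractive compression of the final summary is out of scope; the
  output is a curator's draft, not publishable prose.
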