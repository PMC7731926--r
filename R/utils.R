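#' The six transcription-factor property labels
#'
#' Canonical, ordered vector of the property classes used throughout the
#' package: transcriptional activity (ACT), structural domains (DOM),
#' evolutionary properties (EVO), regulated processes (RP), binding sites
#' (SITE) and transcription-unit organization (TU).
#'
#' @return Character vector of length six, in canonical section order.
#' @export
property_labels <- function() {
  c("ACT", "DOM", "EVO", "RP", "SITE", "TU")
}

# Human-readable section headings for HTML summaries.
property_headings <- c(
  ACT  = "Transcriptional activity",
  DOM  = "Structural domains",
  EVO  = "Evolutionary properties",
  RP   = "Processes regulated",
  SITE = "Binding sites",
  TU   = "Transcription unit"
)

# Round half away from zero to `digits` decimals (printed percentages in
# reports use digits = 0).  base::round() rounds half to even, which would
# turn 64.5 into 64.
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

check_pmid <- function(pmid) {
  ok <- grepl("^[0-9]{1,9}$", pmid)
  if (!all(ok)) {
    stop("invalid PubMed id(s): ", paste(unique(pmid[!ok]), collapse = ", "),
         " (expected 1-9 decimal digits)", call. = FALSE)
  }
  invisible(pmid)
}

check_property_labels <- function(labels) {
  bad <- setdiff(labels, property_labels())
  if (length(bad)) {
    stop("unknown property label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(labels)
}

# Escape a string for literal use inside a regular expression.
regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Adjusted Fisher-Pearson skewness coefficient; 0 for constant samples and
# for n < 3 (no third moment to estimate).
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(0)
  s <- stats::sd(x)
  if (s == 0) return(0)
  g1 <- mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}
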