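# Text primitives shared by the detector and quality metrics.

.ABBREVIATIONS <- c(
  "dr", "mr", "mrs", "ms", "prof", "st", "e.g", "i.e", "vs", "etc",
  "approx", "no", "rev", "jr", "sr", "a.m", "p.m"
)

#' Tokenize text into lower-case alphanumeric tokens
#'
#' The fixed tokenization behind ROUGE-1 and the toy embedder: lower-case,
#' split on non-alphanumeric characters, numerals kept.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_words <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# Tokens keeping internal hyphens/apostrophes, with character offsets,
# for span extraction on the original sentence.
.tokenize_spans <- function(sentence) {
  m <- gregexpr("[A-Za-z][A-Za-z'-]*", sentence)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(0), start = integer(0), end = integer(0)))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(
    token = substring(sentence, starts, starts + lens - 1L),
    start = starts,
    end = starts + lens - 1L,
    stringsAsFactors = FALSE
  )
}

#' Segment text into sentences
#'
#' Newline-aware, abbreviation-safe rule-based segmentation: lines are
#' hard boundaries; within a line, splits occur after `.`, `!` or `?`
#' followed by whitespace, except after common abbreviations ("Dr.",
#' "e.g."), single initials, decimals, and numbered-list markers.
#' Concatenating the result recovers the input up to whitespace.
#'
#' @param text Character scalar; empty or all-whitespace text yields an
#'   empty character vector.
#' @return Character vector of sentences.
#' @export
#' @examples
#' segment_sentences("Dr. Smith saw the patient. Plan: rest.")
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  out <- unlist(lapply(lines, .segment_line), use.names = FALSE)
  out[nzchar(out)]
}

.segment_line <- function(line) {
  protected <- line
  # shield abbreviation periods, initials, decimals and list markers
  for (ab in .ABBREVIATIONS) {
    pat <- paste0("(?i)(?<![A-Za-z])(", gsub(".", "\\.", ab, fixed = TRUE), ")\\.")
    protected <- gsub(pat, "\\1\x01", protected, perl = TRUE)
  }
  protected <- gsub("\\b([A-Z])\\.", "\\1\x01", protected, perl = TRUE)       # initials
  protected <- gsub("(\\d)\\.(\\d)", "\\1\x01\\2", protected, perl = TRUE)    # decimals
  protected <- gsub("(^|\\s)(\\d+)\\.", "\\1\\2\x01", protected, perl = TRUE) # "1. item"
  pieces <- strsplit(protected, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  trimws(gsub("\x01", ".", pieces, fixed = TRUE))
}

# cosine similarity; zero vectors compare as 0 by convention
.cosine <- function(a, b) {
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# normalized form used by the containment entailment backend
.normalize_text <- function(text) {
  trimws(gsub("[^a-z0-9]+", " ", tolower(text)))
}
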