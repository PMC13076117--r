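# Reference-based note quality: ROUGE-1 recall and claim-level
# completeness/conciseness via decompose-then-verify.

#' ROUGE-1 recall of a reference note by a generated note
#'
#' Proportion of reference unigrams recalled by the generated note, with
#' clipped counts:
#' sum_u min(Count_gen(u), Count_ref(u)) / sum_u Count_ref(u).
#' Tokenization is fixed (lower-case, split on non-alphanumerics, numerals
#' kept) so scores are bit-reproducible.
#'
#' @param generated,reference Note texts.
#' @return Score in `[0, 1]`.
#' @export
#' @examples
#' rouge1("patient reports chest pain", "patient denies chest pain") # 0.75
rouge1 <- function(generated, reference) {
  ref_toks <- tokenize_words(reference)
  if (length(ref_toks) == 0L) {
    stop("reference note has no tokens after normalization", call. = FALSE)
  }
  gen_toks <- tokenize_words(generated)
  ref_counts <- table(ref_toks)
  gen_counts <- table(gen_toks)
  shared <- intersect(names(ref_counts), names(gen_counts))
  overlap <- sum(pmin(as.integer(ref_counts[shared]), as.integer(gen_counts[shared])))
  overlap / sum(ref_counts)
}

#' Sentence-level claim decomposition backend
#'
#' Bundled deterministic decomposer: one claim per sentence. Stands behind
#' the decomposition contract so model-based decomposers can be swapped
#' in.
#'
#' @return A decomposition function `text -> character vector`.
#' @export
claims_by_sentence <- function() {
  function(text) segment_sentences(text)
}

#' Decompose a note into an ordered, de-duplicated claim set
#'
#' @param note Note text.
#' @param backend Decomposition function `text -> character vector`
#'   (default: one claim per sentence).
#' @return Character vector of claims (possibly empty for an empty note).
#' @export
decompose_claims <- function(note, backend = claims_by_sentence()) {
  stopifnot(is.function(backend))
  claims <- backend(note)
  if (!is.character(claims)) stop("decomposition backend must return character", call. = FALSE)
  claims <- claims[nzchar(trimws(claims))]
  claims[!duplicated(claims)]
}

#' Normalized-substring containment entailment backend
#'
#' Bundled deterministic verifier: a text entails a claim when the
#' normalized claim occurs as a substring of the normalized text.
#' Paraphrases are not recognized (a documented backend limitation);
#' model-based entailment backends can be swapped in.
#'
#' @return An entailment function `(text, claim) -> 0/1`.
#' @export
containment_entailer <- function() {
  function(text, claim) {
    as.integer(grepl(.normalize_text(claim), .normalize_text(text), fixed = TRUE))
  }
}

#' Verify whether a document entails a claim
#'
#' @param text Document text.
#' @param claim Non-empty claim text.
#' @param backend Entailment function `(text, claim) -> 0/1`.
#' @return 0 or 1.
#' @export
verify_entailment <- function(text, claim, backend = containment_entailer()) {
  stopifnot(is.character(claim), length(claim) == 1L, nzchar(trimws(claim)))
  v <- backend(text, claim)
  if (!v %in% c(0L, 1L)) stop("entailment backend must return 0 or 1", call. = FALSE)
  as.integer(v)
}

#' Completeness: reference claims supported by the generated note
#'
#' (1/|C_ref|) * sum over reference claims of V(N_gen, c).
#'
#' @param generated,reference Note texts.
#' @param decomposer Claim decomposition backend.
#' @param entailer Entailment backend.
#' @return Score in `[0, 1]`.
#' @export
completeness <- function(generated, reference,
                         decomposer = claims_by_sentence(),
                         entailer = containment_entailer()) {
  c_ref <- decompose_claims(reference, decomposer)
  if (length(c_ref) == 0L) stop("reference note decomposes to no claims", call. = FALSE)
  mean(vapply(c_ref, function(cl) verify_entailment(generated, cl, entailer),
              integer(1)))
}

#' Conciseness: generated claims supported by the reference note
#'
#' (1/|C_gen|) * sum over generated claims of V(N_ref, c).
#'
#' @param generated,reference Note texts.
#' @param decomposer Claim decomposition backend.
#' @param entailer Entailment backend.
#' @return Score in `[0, 1]`.
#' @export
conciseness <- function(generated, reference,
                        decomposer = claims_by_sentence(),
                        entailer = containment_entailer()) {
  c_gen <- decompose_claims(generated, decomposer)
  if (length(c_gen) == 0L) stop("generated note decomposes to no claims", call. = FALSE)
  mean(vapply(c_gen, function(cl) verify_entailment(reference, cl, entailer),
              integer(1)))
}

#' Full quality report for a (generated, reference) note pair
#'
#' @param generated,reference Note texts.
#' @param decomposer,entailer Backends, as above.
#' @return One-row tibble: `rouge1`, `completeness`, `conciseness`,
#'   `n_claims_ref`, `n_claims_gen`. Scores are unrounded; round only at
#'   reporting.
#' @export
note_quality <- function(generated, reference,
                         decomposer = claims_by_sentence(),
                         entailer = containment_entailer()) {
  tibble::tibble(
    rouge1 = rouge1(generated, reference),
    completeness = completeness(generated, reference, decomposer, entailer),
    conciseness = conciseness(generated, reference, decomposer, entailer),
    n_claims_ref = length(decompose_claims(reference, decomposer)),
    n_claims_gen = length(decompose_claims(generated, decomposer))
  )
}
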