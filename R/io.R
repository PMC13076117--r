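# JSON-lines I/O for corpora, benchmarks, notes and reports.

#' Read a JSON-lines file
#'
#' @param path File path; one JSON object per line.
#' @return List with one element per line.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}

#' Write a list of records to a JSON-lines file
#'
#' Serialization is deterministic: identical inputs produce byte-identical
#' files.
#'
#' @param records List of records (each serializable by jsonlite).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(
    records,
    function(r) as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null")),
    character(1)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an encounter corpus from JSON lines
#'
#' Each line holds one patient profile: `patient_id`, `full_name`, `age`,
#' `encounter_id`, and `transcript` (array of `{speaker, text}`).
#'
#' @param path File path.
#' @return List of patient profiles (see [patient_profile()]).
#' @export
read_corpus_jsonl <- function(path) {
  lapply(read_jsonl(path), function(r) {
    patient_profile(
      patient_id = r$patient_id,
      full_name = r$full_name,
      age = r$age,
      encounter_id = r$encounter_id,
      transcript = as.data.frame(r$transcript),
      validate = FALSE
    )
  })
}

#' Write an injection benchmark to JSON lines
#'
#' One scenario per line with full ground truth; byte-stable given
#' identical scenarios.
#'
#' @param scenarios List of `injection_scenario` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_jsonl <- function(scenarios, path) {
  write_jsonl(lapply(scenarios, function(s) {
    list(
      scenario_id = s$scenario_id,
      patient_id = s$patient_id,
      encounter_id = s$encounter_id,
      relationship = s$relationship,
      topic = s$topic,
      subject_name = s$subject_name,
      relationship_term = s$relationship_term,
      injected_fact = s$injected_fact,
      inserted_turns = s$inserted_turns,
      modified_transcript = s$modified_transcript
    )
  }), path)
}

#' Read an injection benchmark from JSON lines
#'
#' @param path File path written by [write_benchmark_jsonl()].
#' @return List of `injection_scenario` objects.
#' @export
read_benchmark_jsonl <- function(path) {
  lapply(read_jsonl(path), function(r) {
    structure(
      list(
        scenario_id = r$scenario_id,
        patient_id = r$patient_id,
        encounter_id = r$encounter_id,
        relationship = r$relationship,
        topic = r$topic,
        subject_name = r$subject_name,
        relationship_term = r$relationship_term,
        injected_fact = r$injected_fact,
        inserted_turns = as.integer(r$inserted_turns),
        modified_transcript = as.data.frame(r$modified_transcript)
      ),
      class = "injection_scenario"
    )
  })
}

#' Write note documents to JSON lines
#'
#' @param notes List of `note_document` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_notes_jsonl <- function(notes, path) {
  write_jsonl(lapply(notes, function(n) {
    list(
      note_id = n$note_id,
      scenario_id = n$scenario_id,
      condition = if (!is.null(n$condition)) unclass(n$condition),
      text = n$text
    )
  }), path)
}

#' Read note documents from JSON lines
#'
#' @param path File path written by [write_notes_jsonl()].
#' @return List of `note_document` objects (sentences and sections are
#'   re-derived from the stored text).
#' @export
read_notes_jsonl <- function(path) {
  lapply(read_jsonl(path), function(r) {
    cond <- if (!is.null(r$condition)) {
      prompt_condition(
        privacy = isTRUE(r$condition$privacy),
        soap = isTRUE(r$condition$soap),
        other_section = isTRUE(r$condition$other_section),
        edit_preset = r$condition$edit_preset %||% "none"
      )
    }
    note_document(r$text, note_id = r$note_id, scenario_id = r$scenario_id,
                  condition = cond)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
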