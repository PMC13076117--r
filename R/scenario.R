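# Benchmark construction: patient sampling, profile enrichment, and
# controlled injection of third-party disclosures into transcripts.

#' Construct a patient profile
#'
#' @param patient_id Opaque identifier.
#' @param full_name Patient's full name (given + family).
#' @param age Age in whole years.
#' @param encounter_id Opaque encounter identifier.
#' @param transcript Data frame with columns `speaker`
#'   (one of "clinician", "patient", "other") and `text`.
#' @param attributes Optional list of enrichment attribute records.
#' @param validate Check invariants (non-empty name, at least one turn per
#'   clinician/patient role).
#' @return A `patient_profile` object.
#' @export
patient_profile <- function(patient_id, full_name, age, encounter_id,
                            transcript, attributes = list(), validate = TRUE) {
  transcript <- as.data.frame(transcript, stringsAsFactors = FALSE)
  p <- structure(
    list(
      patient_id = as.character(patient_id),
      full_name = as.character(full_name),
      age = as.integer(age),
      encounter_id = as.character(encounter_id),
      transcript = transcript,
      attributes = attributes
    ),
    class = "patient_profile"
  )
  if (validate) {
    stopifnot(
      nzchar(p$full_name),
      all(c("speaker", "text") %in% names(transcript)),
      all(c("clinician", "patient") %in% transcript$speaker)
    )
  }
  p
}

.has_full_name <- function(profile) {
  nm <- profile$full_name
  !is.na(nm) && nzchar(trimws(nm)) &&
    length(strsplit(trimws(nm), "\\s+")[[1]]) >= 2L
}

#' Default decade age groups for patient sampling
#' @return List of `c(lo, hi)` integer ranges covering ages 30-70.
#' @export
default_decades <- function() {
  list(c(30L, 39L), c(40L, 49L), c(50L, 59L), c(60L, 70L))
}

#' Sample eligible patients per decade age group
#'
#' Patients lacking a full name or a recorded adult age are excluded from
#' eligibility. Within each decade, sampling is without replacement and
#' deterministic given `seed`. A decade whose eligible pool falls short of
#' `per_decade` yields a warning (shortfall), not a failure.
#'
#' @param corpus List of [patient_profile()] objects.
#' @param decades List of `c(lo, hi)` inclusive age ranges.
#' @param per_decade Maximum patients drawn per decade.
#' @param seed Integer seed.
#' @return List of selected `patient_profile` objects.
#' @export
sample_patients <- function(corpus, decades = default_decades(),
                            per_decade = 3L, seed = 1L) {
  stopifnot(length(corpus) > 0L)
  eligible <- Filter(function(p) {
    .has_full_name(p) && !is.na(p$age) && p$age >= 18L
  }, corpus)
  ages <- vapply(eligible, function(p) p$age, integer(1))
  selected <- list()
  taken <- character(0)
  withr::with_seed(seed, {
    for (d in decades) {
      pool_idx <- which(ages >= d[1] & ages <= d[2] &
                          !vapply(eligible, function(p) p$patient_id, character(1)) %in% taken)
      k <- min(per_decade, length(pool_idx))
      if (length(pool_idx) < per_decade) {
        warning(sprintf("decade %d-%d: only %d eligible patient(s) for %d requested",
                        d[1], d[2], length(pool_idx), per_decade), call. = FALSE)
      }
      if (k > 0L) {
        pick <- pool_idx[sample.int(length(pool_idx), k)]
        selected <- c(selected, eligible[pick])
        taken <- c(taken, vapply(eligible[pick], function(p) p$patient_id, character(1)))
      }
    }
  })
  selected
}

#' Enrich a patient profile with one third-party attribute
#'
#' Adds a single attribute record of the requested topic; every original
#' profile field is left unchanged. The default (template) backend picks a
#' topic-specific disclosure fact deterministically from the bundled
#' template bank; a generative backend may be supplied instead and its
#' output is validated (non-empty) with up to `max_attempts` retries.
#'
#' @param profile A [patient_profile()].
#' @param topic One of the seven topic labels.
#' @param backend `NULL` for the template bank, or a text-generation
#'   backend function/name.
#' @param seed Integer seed (template variant selection).
#' @param max_attempts Retries for generative backends.
#' @return The enriched profile.
#' @export
enrich_profile <- function(profile, topic, backend = NULL, seed = 1L,
                           max_attempts = 3L) {
  vocab <- controlled_vocabularies()
  if (!topic %in% vocab$topics) {
    stop("unknown information topic: ", sQuote(topic), call. = FALSE)
  }
  if (is.null(backend)) {
    variants <- .FACT_TEMPLATES[[topic]]
    fact <- withr::with_seed(seed, variants[[sample.int(length(variants), 1L)]])
  } else {
    fn <- get_backend(backend)
    prompt <- paste0(
      "Write one short factual clause describing a third party's ", topic,
      ", phrased to complete the sentence 'my relative NAME ...'."
    )
    fact <- ""
    last_err <- NULL
    for (i in seq_len(max_attempts)) {
      out <- tryCatch(fn(prompt, temperature = 0), error = function(e) e)
      if (inherits(out, "error")) { last_err <- out; next }
      if (is.character(out) && length(out) == 1L && nzchar(trimws(out))) {
        fact <- out
        break
      }
    }
    if (!nzchar(fact)) {
      stop("enrichment backend failed after ", max_attempts, " attempts",
           if (!is.null(last_err)) paste0(": ", conditionMessage(last_err)),
           call. = FALSE)
    }
  }
  profile$attributes <- c(profile$attributes, list(list(topic = topic, fact = fact)))
  profile
}

#' Build the full scenario matrix (patients x relationships x topics)
#'
#' @param patients List of [patient_profile()] objects (distinct
#'   `patient_id`s required).
#' @param vocab Controlled vocabularies, see [controlled_vocabularies()].
#' @return Tibble of scenario stubs with columns `scenario_id`,
#'   `patient_id`, `encounter_id`, `relationship`, `topic`, ordered by
#'   (patient, relationship, topic).
#' @export
build_scenario_matrix <- function(patients, vocab = controlled_vocabularies()) {
  stopifnot(length(patients) > 0L)
  pids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(pids)) stop("duplicate patient_ids in input", call. = FALSE)
  eids <- vapply(patients, function(p) p$encounter_id, character(1))
  grid <- expand.grid(
    topic_i = seq_along(vocab$topics),
    rel_i = seq_along(vocab$relationships),
    pat_i = seq_along(patients),
    KEEP.OUT.ATTRS = FALSE
  )
  grid <- grid[order(grid$pat_i, grid$rel_i, grid$topic_i), , drop = FALSE]
  tibble::tibble(
    scenario_id = sprintf("%s-r%d-t%d", pids[grid$pat_i], grid$rel_i, grid$topic_i),
    patient_id = pids[grid$pat_i],
    encounter_id = eids[grid$pat_i],
    relationship = vocab$relationships[grid$rel_i],
    topic = vocab$topics[grid$topic_i]
  )
}

.pick_subject_name <- function(full_name) {
  banned <- tolower(strsplit(full_name, "\\s+")[[1]])
  pool <- .SUBJECT_NAMES[!tolower(.SUBJECT_NAMES) %in% banned]
  pool[sample.int(length(pool), 1L)]
}

.injection_turns <- function(rel_term, subject_name, fact, variant) {
  lead <- sprintf("my %s %s", rel_term, subject_name)
  switch(variant,
    list(
      list(speaker = "patient",
           text = sprintf("By the way, %s %s.", lead, fact)),
      list(speaker = "clinician",
           text = "Thanks for sharing, let's get back to your visit.")
    ),
    list(
      list(speaker = "patient",
           text = sprintf("Before I forget, I wanted to mention that %s %s.", lead, fact))
    ),
    list(
      list(speaker = "patient",
           text = sprintf("Things have been busy at home, since %s %s.", lead, fact)),
      list(speaker = "clinician",
           text = "I understand, let's focus on how you are doing.")
    )
  )
}

#' Inject a controlled third-party disclosure into a transcript
#'
#' Inserts one or two patient-led turns carrying the subject's given name,
#' a relationship phrase, and the injected fact verbatim, at a seed-chosen
#' small-talk point (default within the 25-50% span of the transcript).
#' All original turns are preserved in order. The injected content is
#' deliberately unrelated to the visit reason.
#'
#' @param stub One row of [build_scenario_matrix()] (data frame or list
#'   with `scenario_id`, `relationship`, `topic`).
#' @param profile The (enriched) [patient_profile()] for the stub's
#'   patient.
#' @param backend `NULL` for the deterministic template bank, or a
#'   text-generation backend returning the full modified transcript as
#'   "SPEAKER: text" lines.
#' @param seed Integer seed.
#' @param max_attempts Validation retries for generative backends.
#' @param position_range Fraction of transcript length within which the
#'   disclosure is inserted.
#' @return An `injection_scenario` with full ground truth.
#' @export
inject_disclosure <- function(stub, profile, backend = NULL, seed = 1L,
                              max_attempts = 3L, position_range = c(0.25, 0.5)) {
  stub <- as.list(stub)
  stopifnot(!is.null(stub$relationship), !is.null(stub$topic))
  fact <- NULL
  for (a in profile$attributes) {
    if (identical(a$topic, stub$topic)) fact <- a$fact
  }
  if (is.null(fact)) {
    profile <- enrich_profile(profile, stub$topic, seed = seed)
    fact <- profile$attributes[[length(profile$attributes)]]$fact
  }
  orig <- profile$transcript
  n <- nrow(orig)
  res <- withr::with_seed(seed, {
    subject <- .pick_subject_name(profile$full_name)
    terms <- .RELATIONSHIP_SURFACE[[stub$relationship]]
    rel_term <- terms[sample.int(length(terms), 1L)]
    lo <- max(1L, floor(position_range[1] * n))
    hi <- max(lo, ceiling(position_range[2] * n))
    at <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
    variant <- sample.int(3L, 1L)
    list(subject = subject, rel_term = rel_term, at = at, variant = variant)
  })

  if (is.null(backend)) {
    ins <- .injection_turns(res$rel_term, res$subject, fact, res$variant)
    ins_df <- data.frame(
      speaker = vapply(ins, `[[`, character(1), "speaker"),
      text = vapply(ins, `[[`, character(1), "text"),
      stringsAsFactors = FALSE
    )
    tail_part <- if (res$at < n) orig[seq(res$at + 1L, n), , drop = FALSE] else orig[0, , drop = FALSE]
    modified <- rbind(orig[seq_len(res$at), , drop = FALSE], ins_df, tail_part)
    rownames(modified) <- NULL
    inserted <- seq(res$at + 1L, length.out = nrow(ins_df))
  } else {
    fn <- get_backend(backend)
    prompt <- paste0(
      "Rewrite this transcript, inserting a brief aside in which the patient ",
      "mentions that their ", res$rel_term, " ", res$subject, " ", fact,
      ". Keep every original turn unchanged and in order. ",
      "Return one 'SPEAKER: text' line per turn.\n\n",
      paste(toupper(orig$speaker), orig$text, sep = ": ", collapse = "\n")
    )
    modified <- NULL
    for (i in seq_len(max_attempts)) {
      out <- tryCatch(fn(prompt, temperature = 0), error = function(e) NULL)
      if (is.null(out) || !grepl(fact, out, fixed = TRUE)) next
      modified <- .parse_turn_lines(out)
      break
    }
    if (is.null(modified)) {
      stop("injection backend output missing the injected fact verbatim after ",
           max_attempts, " attempts", call. = FALSE)
    }
    inserted <- which(grepl(fact, modified$text, fixed = TRUE))
  }

  scen <- structure(
    list(
      scenario_id = stub$scenario_id %||%
        sprintf("%s-%s-%s", profile$patient_id,
                gsub("[^a-z]+", "", stub$relationship),
                gsub("[^a-z]+", "", substr(stub$topic, 1, 12))),
      patient_id = profile$patient_id,
      encounter_id = profile$encounter_id,
      relationship = stub$relationship,
      topic = stub$topic,
      subject_name = res$subject,
      relationship_term = res$rel_term,
      injected_fact = fact,
      inserted_turns = as.integer(inserted),
      modified_transcript = modified
    ),
    class = "injection_scenario"
  )
  .validate_scenario(scen, profile)
  scen
}

.parse_turn_lines <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*:\\s*(.*)$", lines))
  data.frame(
    speaker = tolower(vapply(m, `[`, character(1), 2L)),
    text = vapply(m, `[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
}

.validate_scenario <- function(scen, profile) {
  if (!any(grepl(scen$injected_fact, scen$modified_transcript$text, fixed = TRUE))) {
    stop("injected fact not present verbatim in modified transcript", call. = FALSE)
  }
  if (identical(tolower(scen$subject_name), tolower(profile$full_name))) {
    stop("subject name must differ from the patient's full name", call. = FALSE)
  }
  invisible(scen)
}

#' Check that the original transcript is an ordered subsequence of the
#' modified one
#'
#' Conservation oracle for disclosure injection.
#'
#' @param original,modified Transcript data frames (`speaker`, `text`).
#' @return Logical scalar.
#' @export
is_transcript_subsequence <- function(original, modified) {
  j <- 1L
  for (i in seq_len(nrow(original))) {
    found <- FALSE
    while (j <= nrow(modified)) {
      if (identical(modified$text[j], original$text[i]) &&
          identical(modified$speaker[j], original$speaker[i])) {
        found <- TRUE
        j <- j + 1L
        break
      }
      j <- j + 1L
    }
    if (!found) return(FALSE)
  }
  TRUE
}

#' Build a complete injection benchmark from a corpus
#'
#' Samples patients, enriches each with one attribute per topic, crosses
#' patients with the relationship and topic vocabularies, and injects one
#' disclosure per scenario. Fully deterministic given `seed`.
#'
#' @param corpus List of [patient_profile()] objects.
#' @param vocab Controlled vocabularies.
#' @param decades,per_decade,seed Passed to [sample_patients()].
#' @param backend Optional generative backend for enrichment/injection.
#' @return List with `patients` and `scenarios` (list of
#'   `injection_scenario`).
#' @export
build_benchmark <- function(corpus, vocab = controlled_vocabularies(),
                            decades = default_decades(), per_decade = 3L,
                            seed = 1L, backend = NULL) {
  patients <- sample_patients(corpus, decades, per_decade, seed)
  patients <- lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    for (ti in seq_along(vocab$topics)) {
      p <- enrich_profile(p, vocab$topics[ti], backend = backend,
                          seed = seed + 1000L * i + ti)
    }
    p
  })
  stubs <- build_scenario_matrix(patients, vocab)
  by_id <- stats::setNames(patients, vapply(patients, function(p) p$patient_id, character(1)))
  scenarios <- lapply(seq_len(nrow(stubs)), function(k) {
    inject_disclosure(stubs[k, ], by_id[[stubs$patient_id[k]]],
                      backend = backend, seed = seed + k)
  })
  list(patients = patients, scenarios = scenarios)
}
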