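# Shared fixtures, built once per test run.

# small fixture suite: 2 patients x 42 scenarios, leak modes cycling
small_suite <- generate_fixture_suite(n_patients = 2L, seed = 42L)

# a tiny corpus with known decade structure for sampling tests
make_corpus <- function(ages, full_names = NULL) {
  lapply(seq_along(ages), function(i) {
    patient_profile(
      patient_id = sprintf("p%02d", i),
      full_name = if (is.null(full_names)) sprintf("Test Person%02d", i) else full_names[i],
      age = ages[i],
      encounter_id = sprintf("e%02d", i),
      transcript = data.frame(
        speaker = c("clinician", "patient"),
        text = c("How are you today?", "Doing fine, thanks."),
        stringsAsFactors = FALSE
      ),
      validate = FALSE
    )
  })
}

# embedder with hand-constructed geometry: maps exact strings to fixed
# vectors (anything else to zero)
lookup_embedder <- function(vectors) {
  dim <- length(vectors[[1]])
  function(text) {
    if (text %in% names(vectors)) vectors[[text]] else numeric(dim)
  }
}

expect_leak_labels <- function(scored, modes) {
  expected <- data.frame(
    generic = modes != "none",
    specific = modes == "specific",
    knowing = modes == "knowing"
  )
  expect_equal(scored$generic, expected$generic)
  expect_equal(scored$specific, expected$specific)
  expect_equal(scored$knowing, expected$knowing)
}
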