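test_that("patient sampling honours eligibility, determinism, and forced selection", {
  # exactly one eligible patient per decade: forced selection under any seed
  corpus <- make_corpus(c(35, 45, 55, 65))
  for (seed in c(1L, 99L)) {
    sel <- sample_patients(corpus, per_decade = 1L, seed = seed)
    expect_setequal(vapply(sel, `[[`, character(1), "patient_id"),
                    c("p01", "p02", "p03", "p04"))
  }

  # a patient lacking a full name is excluded from eligibility
  corpus2 <- make_corpus(c(35, 36), full_names = c("Mononym", "Ada Lovelace"))
  sel2 <- suppressWarnings(sample_patients(corpus2, per_decade = 2L, seed = 1L))
  expect_equal(vapply(sel2, `[[`, character(1), "full_name"), "Ada Lovelace")

  # minors are never sampled
  corpus3 <- make_corpus(c(15, 35))
  sel3 <- suppressWarnings(sample_patients(corpus3, per_decade = 1L, seed = 1L))
  expect_true(all(vapply(sel3, `[[`, integer(1), "age") >= 18L))

  # same corpus and seed twice: identical selection; shortfall warns
  corpus4 <- make_corpus(c(31, 33, 35, 44, 47, 52, 58, 61, 66, 68))
  a <- sample_patients(corpus4, per_decade = 2L, seed = 7L)
  b <- sample_patients(corpus4, per_decade = 2L, seed = 7L)
  expect_identical(a, b)
  expect_warning(
    sample_patients(make_corpus(c(35, 45, 55, 65)),
                    decades = list(c(30L, 39L)), per_decade = 2L, seed = 1L),
    "eligible"
  )
})

test_that("profile enrichment adds exactly one attribute and nothing else", {
  p <- make_corpus(30)[[1]]
  e <- enrich_profile(p, "political views", seed = 7L)
  expect_length(e$attributes, 1L)
  expect_identical(e$attributes[[1]]$topic, "political views")
  expect_true(nzchar(e$attributes[[1]]$fact))

  # determinism
  expect_identical(e, enrich_profile(p, "political views", seed = 7L))

  # field-by-field diff: only the attribute list changes
  for (field in setdiff(names(p), "attributes")) {
    expect_identical(e[[field]], p[[field]])
  }

  # unknown (removed) topic is an error; backend failure surfaces diagnostics
  expect_error(enrich_profile(p, "purchasing habits"), "unknown information topic")
  failing <- function(prompt, temperature = 0, meta = NULL) stop("backend down")
  expect_error(enrich_profile(p, "political views", backend = failing),
               "failed after 3 attempts.*backend down")
})

test_that("scenario matrix has full cardinality, distinct triples, stable order", {
  vocab <- controlled_vocabularies()
  corpus10 <- make_corpus(30 + seq_len(10))
  m <- build_scenario_matrix(corpus10, vocab)
  expect_equal(nrow(m), 10L * 6L * 7L)
  expect_equal(nrow(m), 420L)
  expect_false(any(duplicated(m[, c("patient_id", "relationship", "topic")])))

  # stable (patient, relationship, topic) ordering
  expect_equal(m$patient_id, rep(sprintf("p%02d", 1:10), each = 42L))
  expect_equal(m$relationship[1:14], rep(vocab$relationships[1:2], each = 7L))

  # restricted vocabularies
  v1 <- list(relationships = vocab$relationships[1], topics = vocab$topics[1])
  expect_equal(nrow(build_scenario_matrix(corpus10[1], v1)), 1L)

  # brute-force triple enumeration oracle at 2 x 3 x 2
  v2 <- list(relationships = vocab$relationships[1:3], topics = vocab$topics[1:2])
  m2 <- build_scenario_matrix(corpus10[1:2], v2)
  oracle <- expand.grid(p = c("p01", "p02"), r = v2$relationships, t = v2$topics,
                        stringsAsFactors = FALSE)
  expect_equal(nrow(m2), 12L)
  expect_setequal(
    paste(m2$patient_id, m2$relationship, m2$topic),
    paste(oracle$p, oracle$r, oracle$t)
  )

  # duplicated patient ids are rejected
  expect_error(build_scenario_matrix(c(corpus10[1], corpus10[1])), "duplicate")
})

test_that("matrix cardinality law holds across random design sizes", {
  vocab <- controlled_vocabularies()
  withr::with_seed(11, {
    for (rep in 1:8) {
      np <- sample.int(10L, 1L)
      nr <- sample.int(6L, 1L)
      nt <- sample.int(7L, 1L)
      v <- list(relationships = vocab$relationships[seq_len(nr)],
                topics = vocab$topics[seq_len(nt)])
      m <- build_scenario_matrix(make_corpus(30 + seq_len(np)), v)
      expect_equal(nrow(m), np * nr * nt)
      expect_false(any(duplicated(m$scenario_id)))
    }
  })
})

test_that("disclosure injection preserves the transcript and plants the fact", {
  corpus <- fixture_corpus(3, seed = 5)
  stubs <- build_scenario_matrix(corpus)
  for (k in c(1L, 20L, 84L)) {
    p <- corpus[[match(stubs$patient_id[k], vapply(corpus, `[[`, character(1), "patient_id"))]]
    scen <- inject_disclosure(stubs[k, ], p, seed = 100L + k)
    # subsequence conservation oracle
    expect_true(is_transcript_subsequence(p$transcript, scen$modified_transcript))
    # fact verbatim; patient-voiced; name + relationship phrase present
    hit <- grepl(scen$injected_fact, scen$modified_transcript$text, fixed = TRUE)
    expect_true(any(hit))
    expect_true(any(scen$modified_transcript$speaker[hit] == "patient"))
    expect_true(any(grepl(scen$subject_name, scen$modified_transcript$text[hit], fixed = TRUE)))
    expect_true(any(grepl(paste0("my ", scen$relationship_term),
                          scen$modified_transcript$text[hit], fixed = TRUE)))
    expect_false(identical(tolower(scen$subject_name), tolower(p$full_name)))
  }

  # ground truth carries vocabulary labels verbatim
  stub <- stubs[stubs$relationship == "child" &
                  stubs$topic == "stigmatizing mental health status and medication", ][1, ]
  p <- corpus[[match(stub$patient_id, vapply(corpus, `[[`, character(1), "patient_id"))]]
  scen <- inject_disclosure(stub, p, seed = 2L)
  expect_identical(scen$relationship, "child")
  expect_identical(scen$topic, "stigmatizing mental health status and medication")

  # generative backend whose output never contains the fact: validation error
  bad <- function(prompt, temperature = 0, meta = NULL) "CLINICIAN: hello\nPATIENT: hi"
  expect_error(inject_disclosure(stubs[1, ], corpus[[1]], backend = bad, seed = 1L),
               "missing the injected fact")
})

test_that("benchmark JSONL serialization is byte-identical given a seed and round-trips", {
  suite <- generate_fixture_suite(1, seed = 9)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_benchmark_jsonl(suite$scenarios, f1)
  write_benchmark_jsonl(generate_fixture_suite(1, seed = 9)$scenarios, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))

  back <- read_benchmark_jsonl(f1)
  expect_length(back, length(suite$scenarios))
  expect_identical(back[[5]]$injected_fact, suite$scenarios[[5]]$injected_fact)
  expect_identical(back[[5]]$modified_transcript$text,
                   suite$scenarios[[5]]$modified_transcript$text)

  # exact-string ground-truth oracle finds every disclosure
  for (s in back) {
    expect_true(any(grepl(s$injected_fact, s$modified_transcript$text, fixed = TRUE)))
  }
})
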