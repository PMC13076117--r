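#' Controlled vocabularies for the benchmark design
#'
#' The benchmark crosses six third-party relationship types with seven
#' personal-information topics. The topic list derives from public
#' privacy-perception categories, restricted to those applicable in a
#' clinical conversation (e.g. "purchasing habits" is deliberately absent).
#'
#' @return A list with components `relationships` (character, length 6)
#'   and `topics` (character, length 7).
#' @export
#' @examples
#' v <- controlled_vocabularies()
#' length(v$relationships) * length(v$topics)
controlled_vocabularies <- function() {
  list(
    relationships = c(
      "child",
      "parent",
      "sibling/cousin",
      "spouse/partner",
      "friend",
      "boss/co-worker/classmate"
    ),
    topics = c(
      "stigmatizing health status and medication",
      "stigmatizing mental health status and medication",
      "relationship history",
      "religious and spiritual views",
      "political views",
      "sexuality and sex life",
      "lifestyle, habits, and recreational activities"
    )
  )
}

#' Relationship lexicon used to identify specific leakages
#'
#' Seven categories of relationship head terms. Matching against the
#' lexicon is case-insensitive and lemma-aware (simple plural stripping,
#' hyphen/space variants of multiword terms).
#'
#' @return Named list of character vectors, terms lower-cased and unique
#'   within category.
#' @export
relationship_lexicon <- function() {
  lex <- list(
    "immediate family" = c(
      "family", "relative", "sister", "brother", "mother", "father",
      "parent", "daughter", "son", "child", "children", "sibling",
      "siblings", "stepmother", "stepfather", "stepparent", "stepdaughter",
      "stepson", "stepchild", "stepchildren", "stepsister", "stepbrother",
      "stepsibling"
    ),
    "extended family" = c(
      "cousin", "aunt", "uncle", "niece", "nephew", "grandmother",
      "grandfather", "grandparent", "grandson", "granddaughter",
      "grandchild", "grandchildren", "great-grandmother",
      "great-grandfather", "great-grandparent", "great-aunt",
      "great-uncle", "mother-in-law", "father-in-law", "sister-in-law",
      "brother-in-law", "daughter-in-law", "son-in-law"
    ),
    "work" = c(
      "colleague", "coworker", "co-worker", "boss", "employee",
      "supervisor", "manager", "subordinate", "intern", "trainee",
      "apprentice", "mentor", "mentee", "consultant", "contractor",
      "associate", "assistant", "secretary", "coordinator", "director",
      "administrator", "staff", "teammate", "partner"
    ),
    "educational" = c(
      "student", "teacher", "professor", "instructor", "tutor",
      "classmate", "schoolmate", "peer", "pupil", "advisor", "advisee",
      "counselor", "principal", "dean", "supervisor"
    ),
    "social/community" = c(
      "friend", "acquaintance", "neighbor", "neighbour", "roommate",
      "housemate", "tenant", "landlord", "landlady", "pastor", "priest",
      "rabbi", "imam", "minister", "clergy", "parishioner"
    ),
    "care" = c(
      "caretaker", "nurse", "aide", "assistant", "helper", "companion",
      "babysitter", "nanny", "guardian", "ward", "dependent", "charge",
      "protege", "sponsor", "supporter"
    ),
    "professional service" = c(
      "lawyer", "attorney", "accountant", "agent", "broker",
      "representative", "advisor", "consultant", "counselor",
      "specialist", "professional", "provider", "vendor"
    )
  )
  lapply(lex, function(x) unique(tolower(x)))
}

#' Natural-language retrieval queries per information topic
#'
#' One high-level "What ... ?" question per topic, used as the semantic
#' search query against note sentences. Wordings are package defaults
#' (the pattern, not the exact strings, is prescribed by the method) and
#' can be overridden.
#'
#' @return Named character vector, names are the seven topic labels.
#' @export
topic_queries <- function() {
  c(
    "stigmatizing health status and medication" =
      "What infection or treatment, such as HIV, hepatitis, or methadone, is someone managing?",
    "stigmatizing mental health status and medication" =
      "What psychiatric condition or antidepressant, such as anxiety or depression, is someone managing?",
    "relationship history" =
      "What relationship history, such as a divorce, breakup, or affair, has someone been through?",
    "religious and spiritual views" =
      "What religious or spiritual views, such as church worship or prayer, does someone hold?",
    "political views" =
      "What political views, such as an election campaign or vote, does someone hold?",
    "sexuality and sex life" =
      "What is someone's sexuality, sexual orientation, or intimacy like?",
    "lifestyle, habits, and recreational activities" =
      "What lifestyle or recreational habits, such as gardening, hiking, yoga, or gambling, does someone have?"
  )
}

#' Map an information topic to its retrieval query
#'
#' Deterministic and injective over the seven topics; unknown topics
#' (including categories dropped from the design, such as "purchasing
#' habits") are an error.
#'
#' @param topic One of the seven topic labels.
#' @param queries Named character vector of query texts (defaults to
#'   [topic_queries()]).
#' @return A list with `topic` and `query_text`.
#' @export
map_topic_to_query <- function(topic, queries = topic_queries()) {
  stopifnot(is.character(topic), length(topic) == 1L)
  if (!topic %in% names(queries)) {
    stop("unknown information topic: ", sQuote(topic), call. = FALSE)
  }
  list(topic = topic, query_text = unname(queries[[topic]]))
}
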