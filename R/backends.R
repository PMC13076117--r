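# Text-generation backend contract and registry.
#
# A backend is a function(prompt, temperature = 0, meta = NULL) returning a
# single character string. `meta` is optional structured context (scenario,
# condition) that scripted mock backends use to look up their programmed
# output; adapters for real model APIs are free to ignore it.

.backend_registry <- new.env(parent = emptyenv())

#' Register a text-generation backend under a name
#'
#' @param name Backend name.
#' @param fn Function implementing the backend contract
#'   `function(prompt, temperature = 0, meta = NULL) -> character(1)`.
#' @return `name`, invisibly.
#' @export
register_backend <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .backend_registry)
  invisible(name)
}

#' Resolve a backend by name or pass a function through
#'
#' @param backend Backend name (registered) or a backend function.
#' @return A backend function.
#' @export
get_backend <- function(backend) {
  if (is.function(backend)) return(backend)
  stopifnot(is.character(backend), length(backend) == 1L)
  if (!exists(backend, envir = .backend_registry, inherits = FALSE)) {
    stop("no backend registered under name ", sQuote(backend), call. = FALSE)
  }
  get(backend, envir = .backend_registry, inherits = FALSE)
}

#' List registered backend names
#' @return Character vector.
#' @export
list_backends <- function() sort(ls(envir = .backend_registry))

#' Echo mock backend
#'
#' Returns its prompt unchanged; useful for testing plumbing.
#' @return A backend function.
#' @export
mock_echo_backend <- function() {
  function(prompt, temperature = 0, meta = NULL) prompt
}

#' Fixed-script mock backend
#'
#' Always returns `text`, regardless of the prompt.
#' @param text The scripted completion.
#' @return A backend function.
#' @export
mock_fixed_backend <- function(text) {
  force(text)
  function(prompt, temperature = 0, meta = NULL) text
}

#' Identity edit backend
#'
#' For edit prompts of the form instruction + note, returns the note part
#' unchanged (everything after the first blank line); otherwise echoes.
#' @return A backend function.
#' @export
mock_identity_edit_backend <- function() {
  function(prompt, temperature = 0, meta = NULL) {
    parts <- strsplit(prompt, "\n\n", fixed = TRUE)[[1]]
    if (length(parts) > 1L) paste(parts[-1L], collapse = "\n\n") else prompt
  }
}

# record of the last invocation, for tests asserting the temperature contract
.last_call <- new.env(parent = emptyenv())

.log_backend_call <- function(temperature) {
  assign("temperature", temperature, envir = .last_call)
  n <- tryCatch(get("n", envir = .last_call), error = function(e) 0L)
  assign("n", n + 1L, envir = .last_call)
}

#' Inspect the most recent backend invocation
#'
#' The generation harness logs the decoding temperature of every backend
#' call it makes; this accessor exposes the last logged value.
#' @return List with `temperature` and cumulative call count `n` (or
#'   `NULL` if nothing has been logged).
#' @export
last_backend_call <- function() {
  if (!exists("temperature", envir = .last_call)) return(NULL)
  list(temperature = get("temperature", envir = .last_call),
       n = get("n", envir = .last_call))
}
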