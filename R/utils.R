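# Internal condition helpers. Two error classes are distinguished so the
# command-line layer can map them onto exit codes: usage errors (bad
# arguments, unknown formats) versus data errors (malformed files, empty
# results, inconsistent inputs).

abort_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("contactr_usage_error", "contactr_error")))
}

abort_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("contactr_data_error", "contactr_error")))
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
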