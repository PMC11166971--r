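# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Locale-independent lexicographic sort
#'
#' Radix sort so that vocabulary order is identical across platforms and
#' locales; vocabularies index parameter matrices, so order must be stable.
#' @noRd
sort_c <- function(x) sort(unique(x), method = "radix")

#' Canonical symptom / disease identifier
#'
#' Lowercase with internal whitespace collapsed; names act as discrete slots.
#' @noRd
normalize_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

#' Numerically stable softmax
#' @noRd
softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
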