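#' Normalize a label for indexing and matching
#'
#' Case-folds, trims leading/trailing whitespace and collapses internal
#' whitespace runs to a single space. All label/synonym indexing and
#' free-text matching goes through this, so matching is deterministic.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @keywords internal
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' @keywords internal
#' @noRd
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' @keywords internal
#' @noRd
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

#' @keywords internal
#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

# stop() without the call, used everywhere for user-facing errors
abort <- function(..., class = "crtool_error") {
  cond <- structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = NULL)
  )
  stop(cond)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tokenize free text into lowercase word tokens
#' @keywords internal
#' @noRd
tokenize_text <- function(x) {
  x <- tolower(as.character(x))
  toks <- unlist(strsplit(x, "[^a-z0-9]+"))
  toks[nzchar(toks)]
}
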