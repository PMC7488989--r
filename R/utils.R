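## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_ <- function(...) stop(..., call. = FALSE)

#' Escape a string for use inside a regular expression
#' @noRd
regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Token-boundary regex for a literal phrase
#'
#' Boundaries are defined by alphanumeric runs: the phrase must not be
#' preceded or followed by an alphanumeric character. Hyphens and other
#' punctuation inside the phrase are matched literally.
#' @noRd
boundary_pattern <- function(phrase) {
  paste0("(?<![[:alnum:]])", regex_escape(phrase), "(?![[:alnum:]])")
}

## canonical unordered pair key
pair_key <- function(a, b) {
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "\r")
}

split_pair_key <- function(key) {
  parts <- strsplit(key, "\r", fixed = TRUE)
  list(a = vapply(parts, `[[`, "", 1L), b = vapply(parts, `[[`, "", 2L))
}

## seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
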