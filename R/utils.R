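# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Canonical gene-symbol form: uppercase, surrounding whitespace stripped.
canonical_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

# The closed evidence-channel vocabulary.
EVIDENCE_CHANNELS <- c("experimental", "database", "textmining", "coexpression")

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_format("'%s' must be a single positive number", name)
  invisible(x)
}
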