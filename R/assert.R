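# Internal validation helpers. All user-facing configuration errors are
# signalled with class "rapidsc_validation_error" and name the offending
# field and the violated constraint, so a CLI wrapper can map them to a
# clean exit status.

rsc_abort <- function(field, constraint, ...) {
  abort(
    message = sprintf("`%s`: %s", field, sprintf(constraint, ...)),
    class = "rapidsc_validation_error",
    field = field
  )
}

assert_number <- function(x, field, min = -Inf, max = Inf,
                          strict_min = FALSE, strict_max = FALSE,
                          allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    rsc_abort(field, "is required")
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    rsc_abort(field, "must be a single number")
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    rsc_abort(field, "must be in %s%s, %s%s (got %g)",
              if (strict_min) "(" else "[", format(min),
              format(max), if (strict_max) ")" else "]", x)
  }
  invisible(x)
}

assert_count <- function(x, field, min = 0L, allow_null = FALSE) {
  if (is.null(x) && allow_null) return(invisible(NULL))
  assert_number(x, field, min = min)
  if (x != as.integer(x)) rsc_abort(field, "must be an integer (got %g)", x)
  invisible(as.integer(x))
}

assert_string <- function(x, field, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    rsc_abort(field, "is required")
  }
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    rsc_abort(field, "must be a non-empty string")
  }
  invisible(x)
}

assert_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    rsc_abort(field, "must be TRUE or FALSE")
  }
  invisible(x)
}

assert_choice <- function(x, field, choices) {
  assert_string(x, field)
  if (!x %in% choices) {
    rsc_abort(field, "must be one of %s (got \"%s\")",
              paste(sprintf('"%s"', choices), collapse = ", "), x)
  }
  invisible(x)
}
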