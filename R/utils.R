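`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

# Genotype call vocabulary shared across modules.
CALL_LEVELS <- c("AA", "AB", "BB", "NC")
ABH_CODES <- c("A", "H", "B", "-")

assert_calls <- function(x, what = "calls") {
  bad <- !(x %in% CALL_LEVELS) & !is.na(x)
  if (any(bad))
    stop_fmt("invalid %s: %s", what, paste(unique(x[bad]), collapse = ", "))
  invisible(x)
}
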