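# Structured error conditions. Every error the package raises carries a
# specific condition class (plus "cmomoError") so callers and tests can
# discriminate failure modes without matching message text.

cmomoStop <- function(class, message, ...) {
  stop(structure(
    class = c(class, "cmomoError", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    cmomoStop("badParams", sprintf("'%s' must be a finite scalar", name))
  invisible(x)
}

assertSameLength <- function(a, b, what = "vectors") {
  if (length(a) != length(b))
    cmomoStop("dimensionMismatch",
              sprintf("%s have lengths %d and %d", what, length(a), length(b)))
  invisible(TRUE)
}
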