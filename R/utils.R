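#' @keywords internal
"_PACKAGE"

# Internal assertion/helper utilities shared across modules.

stop_moesurv <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_moesurv("'%s' must be a single finite number", name)
  if (positive && x <= 0) stop_moesurv("'%s' must be > 0", name)
  if (integer && x != round(x)) stop_moesurv("'%s' must be an integer", name)
  invisible(x)
}

check_fraction <- function(x, name) {
  check_number(x, name)
  if (x < 0 || x > 1) stop_moesurv("'%s' must lie in [0, 1]", name)
  invisible(x)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Row-wise softmax of a matrix.
softmax_rows <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

relu <- function(x) pmax(x, 0)

# Deterministic seed fan-out: derives a stage seed from a base seed and a
# stage tag, staying within 32-bit integer range.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
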