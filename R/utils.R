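# Internal helpers: structured errors and seed-stream derivation.

ms_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "metspectrum_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ms_stop_missing <- function(field) {
  ms_stop(sprintf("required field '%s' is missing or NA", field),
          "ms_missing_data_error", field = field)
}

#' @keywords internal
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Deterministic child seed for a named random stream, derived from one root
# seed. Keeps every stream independent of the order and number of draws made
# by other streams, so adding a variable never perturbs existing ones.
child_seed <- function(root_seed, name) {
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% 1984061L
  as.integer((as.numeric(root_seed) * 1021 + h) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
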