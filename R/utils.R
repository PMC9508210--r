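# Internal helpers shared across modules.

abort_config <- function(msg, field = NULL) {
  rlang::abort(msg, class = "txp_config_error", field = field)
}

abort_data <- function(msg, ...) {
  rlang::abort(msg, class = "txp_data_error", ...)
}

abort_parse <- function(msg, file = NULL, line = NULL) {
  rlang::abort(msg, class = "txp_parse_error", file = file, line = line)
}

abort_integrity <- function(msg, ...) {
  rlang::abort(msg, class = "txp_integrity_error", ...)
}

as_date_scalar <- function(x, field) {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(d) != 1L || is.na(d)) {
    abort_config(sprintf("`%s` must be a single parseable date, got %s",
                         field, deparse(x)), field = field)
  }
  d
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort_config(sprintf("`%s` must contain probabilities in [0, 1]", field),
                 field = field)
  }
  invisible(x)
}

# Integer sample that avoids sample()'s scalar surprise.
sample_int_range <- function(n, lo, hi) {
  lo + floor(stats::runif(n) * (hi - lo + 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
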