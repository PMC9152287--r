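# Internal helpers shared across modules.

# Identifiers are matched case-insensitively after trimming whitespace;
# original spellings are preserved for reporting.
id_key <- function(x) tolower(trimws(x))

abort_format <- function(msg) abort(msg, class = "mirdap_format_error")
abort_value <- function(msg) abort(msg, class = "mirdap_value_error")
abort_config <- function(msg) abort(msg, class = "mirdap_config_error")
abort_shape <- function(msg) abort(msg, class = "mirdap_shape_error")
abort_metric <- function(msg) abort(msg, class = "mirdap_metric_error")

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never perturb user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  force(code)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    abort_config(sprintf("`%s` must be > %s", name, lower))
  }
  if (!strict_lower && x < lower) {
    abort_config(sprintf("`%s` must be >= %s", name, lower))
  }
  if (x > upper) {
    abort_config(sprintf("`%s` must be <= %s", name, upper))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name, lower = min)
  if (x != as.integer(x)) abort_config(sprintf("`%s` must be an integer", name))
  as.integer(x)
}

# binary labels in any of logical / numeric 0-1 / factor form -> integer 0/1
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) labels <- as.numeric(labels)
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) {
    abort_value("labels must be binary (0/1, logical, or a 0/1 factor)")
  }
  as.integer(labels)
}
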