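# internal helpers shared across modules

# Run `fn()` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs on the current stream.
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

# Collect all validation failures, then fail once naming every offending field.
check_config <- function(checks, context) {
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad))
    stop(sprintf("invalid %s configuration: %s", context,
                 paste(bad, collapse = "; ")), call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_pos <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
is_nonneg <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
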