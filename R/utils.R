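# small internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. seed = NULL runs expr as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    rlang::abort("`seed` must be a single finite number.", class = "hr_error_domain")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

stop_domain <- function(msg) rlang::abort(msg, class = "hr_error_domain")
stop_schema <- function(msg) rlang::abort(msg, class = "hr_error_schema")
stop_geometry <- function(msg) rlang::abort(msg, class = "hr_error_geometry")
stop_unsupported <- function(msg) rlang::abort(msg, class = "hr_error_unsupported")

check_levels <- function(levels, allow_one = TRUE) {
  if (!is.numeric(levels) || length(levels) == 0L || anyNA(levels)) {
    stop_domain("`levels` must be a non-empty numeric vector of fractions.")
  }
  hi <- if (allow_one) 1 else 1 - 1e-12
  if (any(levels <= 0 | levels > hi)) {
    stop_domain(sprintf(
      "`levels` must lie in (0, %s]; got: %s",
      if (allow_one) "1" else "1)", paste(levels, collapse = ", ")
    ))
  }
  lv <- sort(unique(levels))
  if (length(lv) != length(levels)) {
    rlang::warn("Duplicate `levels` dropped.")
  }
  lv
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
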