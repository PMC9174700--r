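# Internal helpers shared across modules.

# Classed conditions so callers can distinguish bad arguments (domain),
# bad configuration objects, and fit failures.
.fo_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "flashodh_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

stop_domain <- function(msg) .fo_stop(msg, "flashodh_domain_error")
stop_config <- function(msg) .fo_stop(msg, "flashodh_config_error")
stop_fit <- function(msg) .fo_stop(msg, "flashodh_fit_error")

.assert_scalar_number <- function(x, name, lower = -Inf, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop_domain(sprintf("'%s' must be a single finite number", name))
  }
  if (x < lower) {
    stop_domain(sprintf("'%s' must be >= %g (got %g)", name, lower, x))
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
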