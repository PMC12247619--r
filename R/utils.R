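# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    stopf("`%s` = %g is outside %s%g, %g%s", name, x,
          if (closed_lower) "[" else "(", lower, upper,
          if (closed_upper) "]" else ")")
  invisible(x)
}

deg2rad <- function(x) x * pi / 180

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps generator outputs a pure function of (inputs, seed).
with_seed <- function(seed, code) {
  assert_number(seed, "seed")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# near-integer check for segment/TR arithmetic
is_whole <- function(x, tol = 1e-8) abs(x - round(x)) < tol
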