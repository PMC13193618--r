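# Internal helpers: classed conditions, seed scoping, small numerics.

# All package errors carry class "reliefstl_error" plus a specific subclass,
# so the CLI can map condition classes onto exit codes.
rs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "reliefstl_error")))
}

rs_param_error <- function(msg) rs_error(msg, "reliefstl_param_error")
rs_io_error <- function(msg) rs_error(msg, "reliefstl_io_error")
rs_validation_error <- function(msg) rs_error(msg, "reliefstl_validation_error")

stopifnot_param <- function(ok, msg) if (!isTRUE(ok)) rs_param_error(msg)

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
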