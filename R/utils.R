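# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
    set.seed(as.integer(seed))
  }
  force(code)
}

# column-major vectorisation of a p x 2 configuration: (x1..xp, y1..yp)
vec_config <- function(m) as.numeric(m)

mat_config <- function(v) matrix(v, ncol = 2L)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fm <- function(...) stop(..., call. = FALSE)

warn_fm <- function(...) warning(..., call. = FALSE)
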