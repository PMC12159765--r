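#' @keywords internal
"_PACKAGE"

## Internal numeric helpers shared across modules.

# Smallest highly-composite FFT length >= n (stats::nextn with factors 2,3,5).
next_fast_len <- function(n) stats::nextn(n, factors = c(2L, 3L, 5L))

# Periodic Hann window (matches FFT-analysis convention).
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
}

# Deterministic sub-seed derivation: one master seed fans out to named,
# independent streams. Values kept below .Machine$integer.max.
derive_seed <- function(seed, ...) {
  tokens <- c(seed, unlist(list(...)))
  h <- 0
  for (tok in tokens) {
    for (ch in utf8ToInt(paste0(tok, "|"))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

# Run an expression under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

stop_tinnpac <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
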