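# Internal helpers: named RNG sub-streams and small numeric utilities.

# One integer master seed drives independent named streams so that e.g. the
# harmonic coefficients of a phantom do not change when the noise realisation
# does. The sub-seed is a deterministic 31-bit hash of (seed, stream name).
substream_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(name)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
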