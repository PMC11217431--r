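
# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date_strict <- function(x, what = "date") {
  d <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
  d
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(abs(x - round(x)) < tol)
}

# stable per-stream seed derivation; keeps results < 2^31
derive_seed <- function(seed, stream, index = 0L) {
  base <- as.double(seed) %% 2147480000
  off <- switch(stream,
    temperature = 7919,
    cohort      = 104729,
    mc          = 611953,
    stop("unknown seed stream: ", stream)
  )
  as.integer((base + off + 131 * as.double(index)) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
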