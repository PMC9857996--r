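# Internal helpers: seeded substreams and a config checksum.

# Substream indices keep the noise drawn by different generator families
# decoupled, so calling order never changes results.
.STREAMS <- c(titration = 1L, spectra = 2L, kinetics = 3L, calibration = 4L)

.substreamSeed <- function(seed, stream) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be coercible to integer")
  ((abs(seed) %% 1000003L) * 1009L + .STREAMS[[stream]] * 101L) %% 2147483647L
}

# Evaluate expr under set.seed(seed) and restore the caller's RNG state,
# so generators are pure functions of their arguments.
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

# Cheap deterministic fingerprint of a character scalar (config logging).
.checksum <- function(txt) {
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
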