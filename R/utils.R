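# internal helpers: seed fan-out, clamping, config hashing

# One user-facing seed fans out to independent per-stage seeds so that
# changing e.g. the number of epochs never perturbs the data split.
# Kept strictly below 2^31 (R integers are 32-bit).
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# md5 of an R object via a serialized temp file (stable across sessions
# thanks to serialize version 2 without header randomness is not an
# issue for plain lists of atomic vectors)
configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
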