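# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage substream seed from a global seed; kept below 2^31.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 2011L + match(
    stage,
    c("genotypes", "covariates", "traits", "null_panel", "power", "misc")
  )
}

# 31-bit polynomial string hash, as a hex string. Used only to stamp
# output headers so reruns with the same configuration are traceable.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_ap <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "assocpower_error")))
}
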