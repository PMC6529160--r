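# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code with a temporarily fixed RNG seed
#'
#' Sets the seed, evaluates `code`, then restores the previous RNG state so
#' that seeded generators do not perturb the caller's random stream. A `NULL`
#' seed evaluates `code` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("seed must be a single number or NULL")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a root seed; kept below 2^31-1.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

# Total length covered by the union of 0-based half-open intervals
# intersected with [lo, hi).
union_cover <- function(starts, ends, lo, hi) {
  if (length(starts) == 0L) return(0L)
  s <- pmax(as.numeric(starts), lo)
  e <- pmin(as.numeric(ends), hi)
  keep <- s < e
  if (!any(keep)) return(0L)
  s <- s[keep]; e <- e[keep]
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  tot <- 0
  cs <- s[1L]; ce <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= ce) ce <- max(ce, e[i]) else { tot <- tot + (ce - cs); cs <- s[i]; ce <- e[i] }
  }
  as.integer(tot + (ce - cs))
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits. Used to stamp
# output files with a config fingerprint without external dependencies.
# Arithmetic is split into 16-bit halves so every intermediate stays exactly
# representable in a double.
fnv1a_hex <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  prime <- 16777619
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

config_hash <- function(config) {
  fnv1a_hex(paste(deparse(config[order(names(config))]), collapse = ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
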