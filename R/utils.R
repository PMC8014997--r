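#' Geometric mean
#'
#' Geometric mean of strictly positive values, the aggregation used
#' throughout reporter-ion quantification (peptide roll-up, condition
#' summaries, fold changes).
#'
#' @param x numeric vector, strictly positive.
#' @param na.rm drop missing values first.
#' @return the geometric mean as a scalar.
#' @export
geomean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(is.na(x))) return(NA_real_)
  if (any(x <= 0)) stop("geomean() requires strictly positive values", call. = FALSE)
  exp(mean(log(x)))
}

# FNV-1a over a character serialization; stable content fingerprint for
# design/manifest hashing without external digest dependencies.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(as.character(unlist(x)), collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit overflow-safe multiply by FNV prime 16777619
    h <- (h * 403 %% 4294967296 + h * 16777216 %% 4294967296) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Deterministic per-stage seed substream: keeps every derived seed a valid
# 32-bit integer regardless of the user's base seed.
stage_seed <- function(seed, stage) {
  offset <- c(simulate = 1L, quantify = 2L, integrate = 3L,
              distances = 4L, cluster = 5L, diffexp = 6L)[stage]
  if (is.na(offset)) offset <- 7L
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
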