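#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clamp values into a closed interval
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Per-column min-max scaling onto the unit interval
#'
#' A constant column scales to all zeros (its range is zero).  Returns the
#' scaled matrix plus the column minima and ranges so the gradient of a
#' training step can reuse them.
#' @noRd
minmax_scale <- function(M) {
  lo <- apply(M, 2L, min)
  hi <- apply(M, 2L, max)
  rng <- hi - lo
  out <- sweep(M, 2L, lo, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, rng[nz], "/")
  out[, !nz] <- 0
  list(scaled = out, min = lo, range = rng)
}

#' Polynomial rolling hash of a character scalar, as 8 hex digits
#'
#' Used only as a lightweight config fingerprint embedded in artifacts; not
#' cryptographic.  Arithmetic stays exact in doubles (< 2^53).
#' @noRd
str_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 4294967291
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Canonical JSON fingerprint of a config list
#' @noRd
config_fingerprint <- function(cfg) {
  str_hash(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)))
}

#' Derive a per-stage seed from the run seed
#'
#' Fixed offsets keep stages independently re-runnable; the result stays
#' below 2^31 - 1 so it is always a valid R integer seed.
#' @noRd
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
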