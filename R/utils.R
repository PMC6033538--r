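#' @keywords internal
"_PACKAGE"

## Coordinate convention used everywhere in this package: 0-based, half-open
## [start, end), BED-native.  GTF input is converted on read.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive a child seed from a global seed
#'
#' Fans a single global seed out to per-stage / per-artifact seeds by a fixed
#' integer mixing rule, so enabling or disabling one stage never perturbs the
#' random stream of another.  Result is always in `[0, 2^31 - 1)`.
#'
#' @param seed integer global seed.
#' @param offset integer artifact offset (each artifact has a fixed one).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483647)
}

## overlap length of [s1,e1) with [s2,e2), vectorised
.ov_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

## does [s,e) overlap any row of the 2-column matrix m (start,end)?
.ov_any <- function(s, e, m) {
  if (is.null(m) || nrow(m) == 0L) return(FALSE)
  any(pmin(e, m[, 2L]) > pmax(s, m[, 1L]))
}

.mat <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  m[order(m[, 1L]), , drop = FALSE]
}

## checksum of an in-memory object (via temp file); md5, see pipeline docs
.checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  ## version = 2 for stable serialization across R minor versions
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
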