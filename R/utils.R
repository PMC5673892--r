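#' @keywords internal
"_PACKAGE"

# Intervals are 0-based half-open [start, end) throughout the package
# (BED convention); a probe at position p lies in [start, end) iff
# start <= p < end.

# x first so pmin/pmax keep x's dim attributes
clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a reproducible sub-seed from a root seed
#'
#' All randomness in the package flows from a single root seed; each stage
#' draws from a named substream so that re-running one stage in isolation
#' reproduces the full-run output. Sub-seeds stay below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param stream character stream name (e.g. "betas", "cna").
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

# TRUE where position p falls inside [start, end)
pos_in_interval <- function(pos, start, end) pos >= start & pos < end

# length of overlap of [s1,e1) with [s2,e2)
interval_overlap <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)
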