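# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# bp overlap between two 1-based inclusive intervals (0 when disjoint)
interval_overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

# start/end index pairs of maximal runs of TRUE with length >= k
runs_of_true <- function(x, k = 1L) {
  if (!length(x)) return(list(start = integer(0), end = integer(0)))
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= k
  list(start = starts[keep], end = ends[keep])
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# significant-digit formatting used by all text writers so that
# write -> read round-trips are lossless to 12 significant digits
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.12g", v)
  }, character(1))
  out
}
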