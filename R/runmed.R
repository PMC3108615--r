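#' Running median with symmetric shrinking end windows
#'
#' Smooths an ordered series with a centred running median of odd width `w`.
#' At position `i` of an `n`-vector the half-width is
#' `h_i = min(i - 1, n - i, (w - 1) / 2)` (1-based), i.e. interior positions
#' use the full window while windows shrink symmetrically towards either end,
#' down to the raw value at the first and last position. Output length equals
#' input length. Interior positions are computed by `stats::runmed` (the
#' robust scatter-plot smoother the transcriptome maps are built on); the end
#' windows are medians of the raw values, so the whole output is the plain
#' window-median definition above. (This differs from
#' `runmed(endrule = "median")`, whose end rule re-smooths the already
#' smoothed series.)
#'
#' @param x Numeric vector (all finite). An empty input gives an empty output.
#' @param w Odd integer window width, `w >= 1`. `w = 1` returns `x` unchanged.
#'   Windows wider than the series shrink to the series.
#' @return Numeric vector of smoothed values, same length as `x`.
#' @export
#' @examples
#' running_median(c(1, 9, 2, 8, 3), 3)  # 1 2 8 3 3
running_median <- function(x, w) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 1 || w %% 2 == 0)
    stopf("`w` must be an odd integer >= 1")
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (any(!is.finite(x))) stopf("`x` must contain only finite values")
  k <- min(w, n - (1L - n %% 2L))  # largest odd width <= n, capped at w
  if (k <= 1L) return(x)
  out <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  h <- (k - 1L) / 2L
  for (i in seq_len(h)) {         # symmetric shrinking windows on raw values
    out[i] <- stats::median(x[1:(2L * i - 1L)])
    out[n - i + 1L] <- stats::median(x[(n - 2L * i + 2L):n])
  }
  out
}
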