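#' Template match counts for sample entropy
#'
#' Counts ordered template pairs whose Chebyshev distance is within the
#' tolerance `r`, at pattern lengths `m` and `m - 1`.  Both lengths use the
#' same `N - m` template starting positions, so `c_m <= c_{m-1}` and the
#' entropy of the regular branch is non-negative.
#'
#' @param y numeric series (already standardized by [sample_entropy()]; this
#'   function applies `r` to the values as given).
#' @param m pattern length, at least 1.
#' @param r Chebyshev tolerance, positive.
#' @return Named numeric vector `c_m`, `c_m_minus_1`, plus attribute `N`.
#' @export
count_matches <- function(y, m = 3L, r = 0.15) {
  if (m < 1L) stop("m must be at least 1")
  if (r <= 0) stop("r must be positive")
  N <- length(y)
  if (N <= m + 1L)
    stop("series length (", N, ") must exceed m + 1 = ", m + 1L)
  counts <- cpp_count_matches(as.numeric(y), as.integer(m), r)
  attr(counts, "N") <- N
  counts
}

#' Sample entropy of a signal segment
#'
#' Regularity statistic `-log(c_m / c_{m-1})` over Chebyshev-matched
#' templates; low values indicate a periodic underlying mechanism (e.g. the
#' maternal cardiac component in band B1), high values its absence.  The
#' segment is standardized to zero mean and unit variance before matching,
#' so the tolerance `r` is in standard-deviation units and the statistic is
#' invariant to offset and scale.  When either count is zero the fallback
#' value `-log((N - m)/(N - m - 1))` is returned; note this quantity is
#' slightly negative, as its argument exceeds 1.  A zero-variance segment is
#' the all-match case and yields exactly 0.
#'
#' @param y numeric series with more than `m + 1` samples.
#' @param m pattern length (default 3).
#' @param r tolerance in SD units (default 0.15).
#' @return Sample entropy in nats.
#' @export
sample_entropy <- function(y, m = 3L, r = 0.15) {
  N <- length(y)
  if (N <= m + 1L)
    stop("series length (", N, ") must exceed m + 1 = ", m + 1L)
  s <- sd(y)
  if (s == 0) return(0)
  y <- (y - mean(y)) / s
  counts <- cpp_count_matches(y, as.integer(m), r)
  if (counts[[1L]] > 0 && counts[[2L]] > 0) {
    -log(counts[[1L]] / counts[[2L]])
  } else {
    -log((N - m) / (N - m - 1))
  }
}
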