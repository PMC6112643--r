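#' One-sided Hanning-windowed power spectrum
#'
#' Computes the squared-magnitude discrete Fourier spectrum of the
#' Hanning-windowed input over `k = 0..floor(M/2)` with `M = length(x)` (no
#' zero-padding), scaled so that the one-sided spectral sum equals the
#' windowed time-domain energy (Parseval).  The signal mean is not removed;
#' inputs are expected to come from the wide-band (0.08--5.0 Hz) filter,
#' which has already rejected DC.
#'
#' @param x numeric sample vector, length at least 16.
#' @param fs sampling frequency in Hz.
#' @return An object of class `power_spectrum`: list with `P` (values),
#'   `freq` (Hz), `M`, `fs`, `df` (bin width), and state flags `smoothed`,
#'   `normalized`, `P_max`.
#' @export
power_spectrum <- function(x, fs) {
  if (length(x) < 16L) stop("need at least 16 samples for a power spectrum")
  M <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(M - 1)) / (M - 1))  # Hanning window
  X <- fft(x * w)
  half <- floor(M / 2)
  P <- Mod(X[1:(half + 1L)])^2 / M
  # double interior bins so sum(P) equals the windowed energy
  dbl <- 2:(half + if (M %% 2 == 0) 0L else 1L)
  P[dbl] <- 2 * P[dbl]
  structure(
    list(P = P, freq = (0:half) * fs / M, M = M, fs = fs, df = fs / M,
         smoothed = FALSE, normalized = FALSE, P_max = NULL),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> M=%d, df=%.4g Hz, 0..%.3g Hz%s%s\n",
              x$M, x$df, max(x$freq),
              if (x$smoothed) ", smoothed" else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Moving-average smoothing of a power spectrum
#'
#' Centered moving average spanning `width` Hz (default 0.1 Hz, i.e. 1% of
#' the 0--10 Hz half-spectrum at 20 Hz sampling).  The window covers
#' `max(1, round(width/df))` bins, forced odd; at the spectrum edges the
#' window shrinks to the available bins.
#'
#' @param ps a `power_spectrum`.
#' @param width smoothing span in Hz.
#' @return The smoothed `power_spectrum`.
#' @export
smooth_spectrum <- function(ps, width = 0.1) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (!is.numeric(width) || width <= 0) stop("width must be positive")
  w <- max(1L, round(width / ps$df))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > 1L) {
    half <- (w - 1L) %/% 2L
    n <- length(ps$P)
    cs <- cumsum(c(0, ps$P))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    ps$P <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  ps$smoothed <- TRUE
  ps
}

#' Normalize a power spectrum by its global peak
#'
#' Divides every bin by `P_max`, the maximum spectral component over the
#' full 0 to fs/2 interval, so the peak of the normalized spectrum is
#' exactly 1.  Smoothing precedes normalization in the feature pipeline.
#'
#' @param ps a smoothed `power_spectrum`.
#' @return The normalized `power_spectrum`, with `P_max` recorded.
#' @export
normalize_spectrum <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (!ps$smoothed)
    stop("normalize_spectrum expects a smoothed spectrum (smooth first)")
  pmaxv <- max(ps$P)
  if (pmaxv <= 0) stop("cannot normalize an all-zero spectrum")
  ps$P <- ps$P / pmaxv
  ps$P_max <- pmaxv
  ps$normalized <- TRUE
  ps
}

# 0-based bin indices of a band: the shared edge belongs to the lower band,
# so the in-band range is (k_low, k_high].
band_bin_range <- function(ps, f_low, f_high) {
  k_low <- round(f_low * ps$M / ps$fs)
  k_high <- min(round(f_high * ps$M / ps$fs), floor(ps$M / 2))
  if (k_high <= k_low)
    stop("band [", f_low, ", ", f_high, "] Hz spans no spectral bins at df = ",
         signif(ps$df, 3))
  (k_low + 1L):k_high
}

#' Median frequency of a power spectrum in a band
#'
#' The frequency of the first bin at which the cumulative in-band power
#' reaches half of the total in-band power, i.e. the frequency splitting the
#' in-band spectral mass into (approximately) equal halves.
#'
#' @param ps a `power_spectrum` (the feature pipeline uses the smoothed,
#'   normalized spectrum; the statistic is scale-invariant).
#' @param band band name or numeric `c(f_low, f_high)`.
#' @return Median frequency in Hz.
#' @export
median_frequency <- function(ps, band) {
  stopifnot(inherits(ps, "power_spectrum"))
  edges <- band_edges(band, ps$fs)
  ks <- band_bin_range(ps, edges[1L], edges[2L])
  p <- ps$P[ks + 1L]
  total <- sum(p)
  if (total <= 0) stop("zero in-band power in [", edges[1L], ", ", edges[2L], "] Hz")
  kj <- ks[which(cumsum(p) >= total / 2)[1L]]
  kj * ps$fs / ps$M
}

#' Peak amplitude of the normalized power spectrum in a band
#'
#' The maximum normalized spectral component inside the band.  Equals 1
#' exactly when the global spectral peak lies in the band; values well below
#' 1 in band B1 indicate a weak maternal cardiac component relative to the
#' dominant low-frequency (respiration/contraction) content.
#'
#' @param ps a normalized `power_spectrum`.
#' @param band band name or numeric `c(f_low, f_high)`.
#' @return Peak amplitude in (0, 1].
#' @export
peak_amplitude <- function(ps, band) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (!ps$normalized)
    stop("peak_amplitude requires a normalized spectrum")
  edges <- band_edges(band, ps$fs)
  ks <- band_bin_range(ps, edges[1L], edges[2L])
  max(ps$P[ks + 1L])
}

#' Short-time Fourier spectrogram
#'
#' Sliding Hanning-window power spectra; the default 256-sample window spans
#' 12.8 s at 20 Hz, for a frequency resolution of fs/256 = 0.078 Hz.
#' Signals should be wide-band (0.08--5.0 Hz) filtered first.
#'
#' @param x numeric sample vector.
#' @param fs sampling frequency in Hz.
#' @param window_samples window length in samples.
#' @param hop hop between consecutive windows in samples (default 64, i.e.
#'   75% overlap).
#' @return List of class `ehg_spectrogram`: `power` (frequency x time
#'   matrix), `freq` (Hz), `time` (window-center seconds).
#' @export
spectrogram <- function(x, fs, window_samples = 256L, hop = 64L) {
  if (length(x) < window_samples)
    stop("signal shorter than one spectrogram window (", window_samples, " samples)")
  starts <- seq(1L, length(x) - window_samples + 1L, by = hop)
  cols <- lapply(starts, function(s) {
    power_spectrum(x[s:(s + window_samples - 1L)], fs)$P
  })
  structure(
    list(power = do.call(cbind, cols),
         freq = (0:(window_samples %/% 2)) * fs / window_samples,
         time = (starts - 1L + window_samples / 2) / fs),
    class = "ehg_spectrogram"
  )
}
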