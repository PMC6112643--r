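#' Canonical analysis bands
#'
#' The four strictly separated analysis bands plus the wide preprocessing
#' band.  B0 (0.08--1.0 Hz) carries contraction bursts and maternal
#' respiration; B1 (1.0--2.2 Hz) the maternal heart rate; B2 (2.2--3.5 Hz)
#' and B3 (3.5--5.0 Hz) its second and third harmonics.  WIDE (0.08--5.0 Hz)
#' rejects baseline wander and content above 5 Hz.
#'
#' @param fs sampling frequency in Hz; band edges must fit below `fs/2`.
#' @return Data frame with columns `name`, `f_low`, `f_high`.
#' @export
ehg_bands <- function(fs = 20) {
  bands <- data.frame(
    name = c("B0", "B1", "B2", "B3", "WIDE"),
    f_low = c(0.08, 1.0, 2.2, 3.5, 0.08),
    f_high = c(1.0, 2.2, 3.5, 5.0, 5.0),
    stringsAsFactors = FALSE
  )
  if (any(bands$f_high > fs / 2))
    stop("band edges exceed the Nyquist frequency fs/2 = ", fs / 2)
  bands
}

band_edges <- function(band, fs = 20) {
  if (is.numeric(band) && length(band) == 2L) return(band)
  bands <- ehg_bands(fs)
  i <- match(band, bands$name)
  if (is.na(i)) stop("unknown band: ", band)
  c(bands$f_low[i], bands$f_high[i])
}

.filter_cache <- new.env(parent = emptyenv())

#' Design a Butterworth band-pass filter for one analysis band
#'
#' Designs the digital Butterworth band-pass of the stated design order
#' (default 4, i.e. a roll-off of -80 dB per decade per pass, -160 dB after
#' bidirectional use).  Coefficients are computed at run time and cached per
#' `(band, fs, order)`.
#'
#' @param band band name (see [ehg_bands()]) or numeric `c(f_low, f_high)`.
#' @param fs sampling frequency in Hz.
#' @param order design order before bidirectional application.
#' @return An object of class `ehg_filter` with elements `b`, `a` (transfer
#'   function coefficients), `band`, `f_low`, `f_high`, `fs`, `order`.
#' @export
design_bandpass <- function(band, fs = 20, order = 4) {
  edges <- band_edges(band, fs)
  f_low <- edges[1L]; f_high <- edges[2L]
  if (!(f_low > 0) || !(f_low < f_high))
    stop("band must satisfy 0 < f_low < f_high")
  if (f_high > fs / 2)
    stop("f_high = ", f_high, " exceeds Nyquist fs/2 = ", fs / 2)
  key <- sprintf("%.10g_%.10g_%.10g_%d", f_low, f_high, fs, order)
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  bt <- signal::butter(order, c(f_low, f_high) / (fs / 2), type = "pass")
  if (max(Mod(polyroot(rev(bt$a)))) >= 1)
    stop("designed filter is unstable for band [", f_low, ", ", f_high, "] Hz")
  # transient length from the slowest pole: samples until an impulse decays
  # below 1e-10, which sets the reflection padding for zero-phase use
  rho <- max(Mod(polyroot(rev(bt$a))))
  transient <- ceiling(log(1e-10) / log(rho))
  spec <- structure(
    list(b = bt$b, a = bt$a,
         band = if (is.character(band)) band else sprintf("[%g,%g]", f_low, f_high),
         f_low = f_low, f_high = f_high, fs = fs, order = order,
         transient = transient),
    class = "ehg_filter"
  )
  .filter_cache[[key]] <- spec
  spec
}

#' Frequency response magnitude of a designed filter
#'
#' Evaluates the analytic transfer function on the unit circle.  With
#' `bidirectional = TRUE` (the way the filters are applied) the returned
#' magnitude is `|H(f)|^2`, the zero-phase amplitude gain of
#' forward-plus-backward filtering.
#'
#' @param spec an `ehg_filter` from [design_bandpass()].
#' @param f frequencies in Hz.
#' @param bidirectional square the single-pass magnitude?
#' @return Numeric vector of amplitude gains at `f`.
#' @export
filter_gain <- function(spec, f, bidirectional = TRUE) {
  stopifnot(inherits(spec, "ehg_filter"))
  w <- 2 * pi * f / spec$fs
  k <- seq_along(spec$b) - 1
  H <- vapply(w, function(wi) {
    e <- exp(-1i * wi * k)
    Mod(sum(spec$b * e) / sum(spec$a * e))
  }, numeric(1L))
  if (bidirectional) H^2 else H
}

#' Zero-phase (bidirectional) filtering
#'
#' Applies the filter forward and backward so the effective phase response is
#' zero and the amplitude response is the squared single-pass magnitude.
#' Edge transients are suppressed by odd-reflection padding sized to the
#' filter's transient length (the samples an impulse needs to decay below
#' 1e-10, from the slowest pole), removed before returning; this keeps the
#' operation time-reversal symmetric to high precision even for the
#' narrow low-frequency bands whose transients are thousands of samples.
#'
#' @param x numeric sample vector.
#' @param spec an `ehg_filter` from [design_bandpass()].
#' @return Filtered vector of the same length as `x`.
#' @export
zero_phase_filter <- function(x, spec) {
  stopifnot(inherits(spec, "ehg_filter"))
  pad <- spec$transient
  if (length(x) <= pad)
    stop("input too short for zero-phase filtering: need more than ",
         pad, " samples, got ", length(x))
  # odd reflection about the end points
  front <- 2 * x[1L] - x[(pad + 1L):2L]
  back <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - pad)]
  xp <- c(front, x, back)
  y <- signal::filter(spec$b, spec$a, xp)
  y <- rev(signal::filter(spec$b, spec$a, rev(y)))
  as.numeric(y[(pad + 1L):(pad + length(x))])
}

#' Decompose a record into the wide band and the four analysis subbands
#'
#' Every channel (EHG and TOCO alike) is filtered with the zero-phase
#' Butterworth band-pass of each band, yielding the wide-band record and
#' subrecords for B0..B3.
#'
#' @param record a [uterine_record()].
#' @param order filter design order.
#' @return Named list of `uterine_record`s: `WIDE`, `B0`, `B1`, `B2`, `B3`.
#' @export
decompose_record <- function(record, order = 4) {
  stopifnot(inherits(record, "uterine_record"))
  bands <- ehg_bands(record$fs)
  out <- lapply(seq_len(nrow(bands)), function(i) {
    spec <- design_bandpass(c(bands$f_low[i], bands$f_high[i]),
                            record$fs, order)
    filt <- record
    filt$signals <- apply(record$signals, 2L, zero_phase_filter, spec = spec)
    colnames(filt$signals) <- record$channel_names
    filt
  })
  names(out) <- bands$name
  out[c("WIDE", "B0", "B1", "B2", "B3")]
}
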