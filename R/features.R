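se_bands <- c("B0", "B1", "B2", "B3")
mf_bands <- c("B0", "B1", "B2", "B3")
pa_bands <- c("B1", "B2", "B3")  # B0 omitted: P_max almost always lies there

#' Feature names for a set of signals
#'
#' Eleven features per signal in a fixed order: bands B0 to B3, within each
#' band sample entropy (SE), median frequency (MF) and, outside B0, peak
#' amplitude (PA).  Names follow `<signal>.<band>.<feature>`, e.g.
#' `S2.B1.PA`.
#'
#' @param signals character vector of channel names.
#' @return Character vector of feature names (11 per signal).
#' @export
feature_names <- function(signals) {
  per_signal <- unlist(lapply(se_bands, function(b) {
    c(paste0(b, ".SE"), paste0(b, ".MF"),
      if (b %in% pa_bands) paste0(b, ".PA"))
  }))
  as.character(unlist(lapply(signals, function(s) paste(s, per_signal, sep = "."))))
}

#' Extract SE/MF/PA features for one interval or a whole record
#'
#' Implements the two data paths of the feature pipeline: sample entropy is
#' computed on the time-domain subband signals (B0..B3) sliced to the
#' interval, while median frequency and peak amplitude are read per band
#' from the single Hanning power spectrum of the interval's wide-band
#' (0.08--5.0 Hz) signal after 0.1 Hz moving-average smoothing and
#' normalization by the global peak.
#'
#' @param record a [uterine_record()].
#' @param onset,offset half-open sample interval; omit both (`NULL`) for
#'   whole-record mode.
#' @param signals channel subset to extract from.
#' @param m,r sample-entropy pattern length and tolerance.
#' @param smooth_width spectral smoothing span in Hz.
#' @param decomposed optional precomputed [decompose_record()] result, to
#'   avoid re-filtering when extracting many intervals of one record.
#' @return Named numeric vector of `11 * length(signals)` features with
#'   attributes `record_id` and `interval_label`.
#' @export
extract_interval_features <- function(record, onset = NULL, offset = NULL,
                                      signals = record$channel_names,
                                      m = 3L, r = 0.15, smooth_width = 0.1,
                                      decomposed = NULL) {
  stopifnot(inherits(record, "uterine_record"))
  missing_ch <- setdiff(signals, record$channel_names)
  if (length(missing_ch))
    stop("record ", record$record_id, " lacks channel(s): ",
         paste(missing_ch, collapse = ", "))
  whole <- is.null(onset) && is.null(offset)
  if (whole) { onset <- 0L; offset <- n_samples(record) }
  len <- offset - onset
  if (len < 16L || len <= m + 1L)
    stop("interval too short for feature extraction: ", len, " samples")
  if (is.null(decomposed)) decomposed <- decompose_record(record)

  idx <- (onset + 1L):offset
  vals <- numeric(0)
  for (sig in signals) {
    wide <- decomposed$WIDE$signals[idx, sig]
    ps <- normalize_spectrum(smooth_spectrum(power_spectrum(wide, record$fs),
                                             smooth_width))
    for (b in se_bands) {
      se <- sample_entropy(decomposed[[b]]$signals[idx, sig], m = m, r = r)
      mf <- median_frequency(ps, b)
      v <- c(se, mf, if (b %in% pa_bands) peak_amplitude(ps, b))
      vals <- c(vals, v)
    }
  }
  names(vals) <- feature_names(signals)
  attr(vals, "record_id") <- record$record_id
  attr(vals, "interval_label") <- if (whole) "whole_record" else NA_character_
  vals
}

task_label <- function(record, task, labor_boundary_weeks = 3) {
  meta <- record$meta
  switch(task,
    preterm_vs_term = {
      if (!meta$group %in% c("preterm", "term")) NA_character_ else meta$group
    },
    labor_vs_nonlabor = {
      if (is.null(meta$gestation_at_delivery) ||
          is.null(meta$gestation_at_recording)) NA_character_
      else if (meta$gestation_at_delivery - meta$gestation_at_recording <=
               labor_boundary_weeks) "labor" else "nonlabor"
    },
    nonpregnant_vs_pregnant = {
      if (meta$group == "nonpregnant") "nonpregnant"
      else if (meta$group %in% c("preterm", "term")) "pregnant"
      else NA_character_
    },
    stop("unknown task: ", task)
  )
}

#' Build a feature matrix over a dataset of records
#'
#' One row per selected interval (or per record in whole-record mode) with
#' the 11-per-signal SE/MF/PA features and a class label derived from the
#' record metadata.  The labor/nonlabor boundary is intentionally early:
#' a recording within `labor_boundary_weeks` (default 3) of delivery counts
#' as labor.
#'
#' @param records list of [uterine_record()]s.
#' @param annotations data frame of annotations covering the records
#'   (ignored in whole-record mode).
#' @param task one of `"preterm_vs_term"`, `"labor_vs_nonlabor"`,
#'   `"nonpregnant_vs_pregnant"`.
#' @param interval_kind `"contraction"`, `"dummy"`, or `"whole_record"`.
#' @param signals channel subset used for every record.
#' @param labor_boundary_weeks weeks-to-delivery boundary for the labor task.
#' @inheritParams extract_interval_features
#' @return Data frame with columns `record_id`, `interval_label`, `class`
#'   and one column per feature.  Rows skipped for missing metadata are
#'   reported in the `skipped` attribute.
#' @export
build_feature_matrix <- function(records, annotations = NULL,
                                 task = "preterm_vs_term",
                                 interval_kind = c("contraction", "dummy",
                                                   "whole_record"),
                                 signals, m = 3L, r = 0.15,
                                 smooth_width = 0.1,
                                 labor_boundary_weeks = 3) {
  interval_kind <- match.arg(interval_kind)
  rows <- list(); skipped <- character(0)
  for (rec in records) {
    cls <- task_label(rec, task, labor_boundary_weeks)
    if (is.na(cls)) {
      skipped <- c(skipped,
                   sprintf("%s: metadata missing for task %s", rec$record_id, task))
      next
    }
    dec <- decompose_record(rec)
    if (interval_kind == "whole_record") {
      fv <- extract_interval_features(rec, signals = signals, m = m, r = r,
                                      smooth_width = smooth_width,
                                      decomposed = dec)
      rows[[length(rows) + 1L]] <-
        c(list(record_id = rec$record_id, interval_label = "whole_record",
               class = cls), as.list(fv))
    } else {
      ann <- annotations[annotations$record_id == rec$record_id &
                         annotations$label == interval_kind, , drop = FALSE]
      for (i in seq_len(nrow(ann))) {
        fv <- extract_interval_features(rec, ann$onset[i], ann$offset[i],
                                        signals = signals, m = m, r = r,
                                        smooth_width = smooth_width,
                                        decomposed = dec)
        rows[[length(rows) + 1L]] <-
          c(list(record_id = rec$record_id, interval_label = interval_kind,
                 class = cls), as.list(fv))
      }
    }
  }
  if (!length(rows)) stop("no usable rows for task ", task)
  fm <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  rownames(fm) <- NULL
  attr(fm, "skipped") <- skipped
  fm
}

#' Split a feature matrix into features and labels
#'
#' @param fm a data frame from [build_feature_matrix()] (or a CSV re-import
#'   with the same columns).
#' @return List with `x` (numeric feature matrix) and `y` (factor of class
#'   labels).
#' @export
fm_xy <- function(fm) {
  meta_cols <- intersect(c("record_id", "interval_label", "class"), names(fm))
  if (!"class" %in% meta_cols) stop("feature matrix lacks a 'class' column")
  x <- as.matrix(fm[, setdiff(names(fm), meta_cols), drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("feature matrix contains missing values")
  list(x = x, y = factor(fm$class))
}
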