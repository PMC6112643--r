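#' Construct a uterine record
#'
#' A uterine record bundles the simultaneously recorded signals of one
#' session: up to three bipolar EHG channels (S1, S2, S3) and optionally the
#' external tocogram (TOCO), all sampled at the same rate.  EHG samples are
#' in microvolts; TOCO samples are in raw tocograph units (150 uV per Pa at
#' acquisition).
#'
#' @param record_id character scalar identifying the record.
#' @param signals numeric matrix, one column per channel (rows are samples).
#' @param channel_names character vector naming the columns; subset of
#'   `c("S1","S2","S3","TOCO")`, unique.
#' @param fs sampling frequency in Hz (20 for the referenced databases).
#' @param meta list with optional elements `gestation_at_recording`,
#'   `gestation_at_delivery` (weeks) and `group` (one of `"preterm"`,
#'   `"term"`, `"nonpregnant"`, `"unknown"`).
#' @return An object of class `uterine_record`.
#' @export
uterine_record <- function(record_id, signals, channel_names, fs = 20,
                           meta = list()) {
  signals <- as.matrix(signals)
  if (nrow(signals) < 1L) stop("record must contain at least one sample")
  if (ncol(signals) != length(channel_names))
    stop("number of signal columns must match channel_names")
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique")
  if (!all(channel_names %in% c("S1", "S2", "S3", "TOCO")))
    stop("channel_names must be drawn from S1, S2, S3, TOCO")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  meta$group <- if (is.null(meta$group)) "unknown" else
    match.arg(meta$group, c("preterm", "term", "nonpregnant", "unknown"))
  colnames(signals) <- channel_names
  structure(
    list(record_id = as.character(record_id), signals = signals,
         channel_names = channel_names, fs = fs, meta = meta),
    class = "uterine_record"
  )
}

#' @export
print.uterine_record <- function(x, ...) {
  cat(sprintf("<uterine_record> %s: %d channels (%s), %d samples @ %g Hz (%.1f min)\n",
              x$record_id, length(x$channel_names),
              paste(x$channel_names, collapse = ","),
              nrow(x$signals), x$fs, nrow(x$signals) / x$fs / 60))
  cat(sprintf("  group: %s, recording week: %s, delivery week: %s\n",
              x$meta$group,
              if (is.null(x$meta$gestation_at_recording)) "?" else x$meta$gestation_at_recording,
              if (is.null(x$meta$gestation_at_delivery)) "?" else x$meta$gestation_at_delivery))
  invisible(x)
}

n_samples <- function(record) nrow(record$signals)

# Fixed-point gain used by the writer: 1 LSB = 0.005 uV, int16 range +-163 uV.
.WFDB_GAIN <- 200

#' Read a uterine record from WFDB-style header and signal files
#'
#' Reads a `.hea` header plus interleaved 16-bit little-endian `.dat` signal
#' file in the PhysioNet WFDB dialect used by the term/preterm EHG databases.
#' The header's first line gives `record nsig fs nsamp`; one line per signal
#' gives the dat file, format (16), `gain(baseline)/units` and, as the final
#' field, the channel name.  Comment lines (`#`) may carry obstetric
#' metadata: `# Group`, `# RecWeeks`, `# DeliveryWeeks`.
#'
#' @param path path to the header file, with or without the `.hea` suffix.
#' @return A [uterine_record()] with gains applied (physical units).
#' @export
read_record <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("header file not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  comments <- lines[grepl("^\\s*#", lines)]
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("malformed header (need record line and signal lines): ", hea)

  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(top) < 4L) stop("malformed record line in ", hea)
  record_id <- top[1L]
  nsig <- as.integer(top[2L])
  fs <- as.numeric(top[3L])
  nsamp <- as.integer(top[4L])
  if (is.na(fs) || fs <= 0) stop("invalid sampling frequency in ", hea)
  if (is.na(nsig) || nsig < 1L) stop("invalid signal count in ", hea)
  if (length(lines) - 1L != nsig)
    stop("header declares ", nsig, " signals but has ", length(lines) - 1L,
         " signal lines: ", hea)

  sig <- lapply(lines[-1L], function(ln) strsplit(trimws(ln), "\\s+")[[1L]])
  dat_file <- vapply(sig, `[`, "", 1L)
  fmt <- vapply(sig, `[`, "", 2L)
  if (!all(fmt == "16")) stop("only format 16 signal files are supported")
  if (length(unique(dat_file)) != 1L)
    stop("all signals must share one interleaved .dat file")
  gain_spec <- vapply(sig, `[`, "", 3L)
  gain <- as.numeric(sub("\\(.*$|/.*$", "", gain_spec))
  baseline <- ifelse(grepl("\\(", gain_spec),
                     as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", gain_spec)), 0)
  gain[is.na(gain) | gain == 0] <- 1
  chan <- vapply(sig, function(f) f[length(f)], "")

  dat_path <- file.path(dirname(hea), dat_file[1L])
  if (!file.exists(dat_path)) stop("signal file not found: ", dat_path)
  raw_n <- file.size(dat_path) / 2L
  if (raw_n != nsig * nsamp)
    stop(sprintf("signal file %s holds %d samples but header declares %d x %d",
                 dat_path, raw_n, nsig, nsamp))
  adc <- readBin(dat_path, "integer", n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  digital <- matrix(adc, ncol = nsig, byrow = TRUE)
  phys <- sweep(sweep(digital, 2L, baseline, "-"), 2L, gain, "/")

  meta <- list()
  for (cm in comments) {
    body <- trimws(sub("^\\s*#", "", cm))
    kv <- strsplit(body, "\\s+")[[1L]]
    if (length(kv) < 2L) next
    key <- tolower(kv[1L])
    if (key == "group") meta$group <- kv[2L]
    if (key == "recweeks") meta$gestation_at_recording <- as.numeric(kv[2L])
    if (key == "deliveryweeks") meta$gestation_at_delivery <- as.numeric(kv[2L])
  }
  uterine_record(record_id, phys, chan, fs, meta)
}

#' Write a uterine record as WFDB-style header and signal files
#'
#' Counterpart to [read_record()]; quantizes samples to 16-bit integers at a
#' fixed gain of 200 ADC units per physical unit.  Reading a written record
#' back reproduces the quantized samples exactly, and re-writing the result
#' reproduces the files byte for byte.
#'
#' @param record a [uterine_record()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the path of the written header file.
#' @export
write_record <- function(record, dir) {
  stopifnot(inherits(record, "uterine_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- record$record_id
  hea <- file.path(dir, paste0(id, ".hea"))
  datf <- paste0(id, ".dat")

  adc <- round(record$signals * .WFDB_GAIN)
  if (any(abs(adc) > 32767))
    stop("sample amplitude exceeds the int16 range at gain ", .WFDB_GAIN)
  units <- ifelse(record$channel_names == "TOCO", "raw", "uV")
  sig_lines <- sprintf("%s 16 %d(0)/%s 16 0 0 0 0 %s",
                       datf, .WFDB_GAIN, units, record$channel_names)
  meta <- record$meta
  cmt <- c(sprintf("# Group %s", meta$group),
           if (!is.null(meta$gestation_at_recording))
             sprintf("# RecWeeks %g", meta$gestation_at_recording),
           if (!is.null(meta$gestation_at_delivery))
             sprintf("# DeliveryWeeks %g", meta$gestation_at_delivery))
  writeLines(c(sprintf("%s %d %g %d", id, length(record$channel_names),
                       record$fs, n_samples(record)),
               sig_lines, cmt), hea)
  con <- file(file.path(dir, datf), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  invisible(hea)
}

#' Read interval annotations for a record
#'
#' Annotations mark `contraction` and `dummy` (non-contraction) intervals as
#' half-open sample ranges `[onset, offset)` with 0-based onsets.  The
#' canonical format is a TSV with columns `onset`, `offset`, `label`; a
#' header row is optional.
#'
#' @param path path to the annotation TSV.
#' @param record the [uterine_record()] the annotations refer to; used to
#'   validate interval bounds.
#' @return A data frame with columns `record_id`, `onset`, `offset`, `label`,
#'   sorted by onset.
#' @export
read_annotations <- function(path, record) {
  stopifnot(inherits(record, "uterine_record"))
  if (!file.exists(path)) stop("annotation file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("onset", first, ignore.case = TRUE)
  df <- read.table(path, header = has_header, sep = "\t",
                   col.names = c("onset", "offset", "label"),
                   colClasses = c("integer", "integer", "character"))
  validate_annotations(df, record)
}

validate_annotations <- function(df, record) {
  if (!all(df$label %in% c("contraction", "dummy")))
    stop("unknown annotation label(s): ",
         paste(setdiff(unique(df$label), c("contraction", "dummy")), collapse = ", "))
  if (any(df$onset < 0L) || any(df$offset <= df$onset))
    stop("annotations must satisfy 0 <= onset < offset")
  if (any(df$offset > n_samples(record)))
    stop("annotation offset beyond record end (", n_samples(record), " samples)")
  df <- df[order(df$onset), , drop = FALSE]
  if (nrow(df) > 1L && any(df$onset[-1L] < df$offset[-nrow(df)]))
    stop("annotated intervals overlap")
  data.frame(record_id = record$record_id, onset = df$onset,
             offset = df$offset, label = df$label,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write interval annotations as TSV
#'
#' @param annotations data frame as returned by [read_annotations()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotations[, c("onset", "offset", "label")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Slice an annotated segment out of a record
#'
#' @param record a [uterine_record()].
#' @param onset,offset half-open sample interval `[onset, offset)`, 0-based.
#' @param channels channel names to keep (default: all).
#' @param label provenance label stored on the segment.
#' @return A list of class `ehg_segment` with elements `samples` (matrix,
#'   one column per channel), `fs`, `record_id`, `label`.
#' @export
extract_segment <- function(record, onset, offset,
                            channels = record$channel_names,
                            label = NA_character_) {
  stopifnot(inherits(record, "uterine_record"))
  if (length(channels) == 0L) stop("channel subset must not be empty")
  missing <- setdiff(channels, record$channel_names)
  if (length(missing))
    stop("record ", record$record_id, " lacks channel(s): ",
         paste(missing, collapse = ", "))
  if (onset < 0L || offset <= onset || offset > n_samples(record))
    stop("invalid interval [", onset, ", ", offset, ") for record of length ",
         n_samples(record))
  structure(
    list(samples = record$signals[(onset + 1L):offset, channels, drop = FALSE],
         fs = record$fs, record_id = record$record_id, label = label),
    class = "ehg_segment"
  )
}
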