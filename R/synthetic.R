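#' Configuration for a synthetic uterine record
#'
#' Builds the parameter set for [synth_record()].  The defaults emulate a
#' 30-min, 20 Hz, four-channel recording: wideband instrumentation noise on
#' every channel, a maternal respiration sinusoid in 0.2--0.34 Hz, a
#' maternal cardiac component with fundamental in 1.2--1.5 Hz plus second
#' and third harmonics on the EHG channels (the tocogram shows the rate but
#' not sharp harmonics, so TOCO receives the fundamental only), and
#' amplitude-modulated 0.1--1.0 Hz noise bursts during scheduled contraction
#' intervals, mirrored into TOCO as a smooth pressure deflection.
#'
#' Archetypes encode the study contrast: `term_nonlabor` has a strong
#' cardiac component on all channels; `preterm_like` a weak one;
#' `nonpregnant_like` has a weak electrical cardiac component, essentially
#' none on TOCO, and no contractions.
#'
#' @param archetype `"term_nonlabor"`, `"preterm_like"` or
#'   `"nonpregnant_like"`.
#' @param duration_s record length in seconds.
#' @param fs sampling frequency in Hz.
#' @param f_hr cardiac fundamental in Hz (1.0--2.2).
#' @param cardiac_amp named per-channel fundamental amplitudes (uV); `NULL`
#'   takes the archetype default.
#' @param harmonic_decay amplitude ratio of successive cardiac harmonics.
#' @param f_resp respiration frequency in Hz (0.2--0.34).
#' @param resp_amp respiration amplitude (uV).
#' @param schedule matrix-like list of contraction `c(onset_s, offset_s)`
#'   intervals; `NULL` gives the archetype default (three contractions, none
#'   for `nonpregnant_like`).
#' @param burst_amp contraction burst amplitude on EHG channels (uV).
#' @param noise_sd white-noise standard deviation per channel (uV).
#' @param seed integer seed.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(archetype = c("term_nonlabor", "preterm_like",
                                       "nonpregnant_like"),
                         duration_s = 1800, fs = 20, f_hr = 1.35,
                         cardiac_amp = NULL, harmonic_decay = 0.5,
                         f_resp = 0.27, resp_amp = 1.5,
                         schedule = NULL, burst_amp = 8, noise_sd = 1,
                         seed = 1L) {
  archetype <- match.arg(archetype)
  if (f_hr < 1.0 || f_hr > 2.2)
    stop("f_hr must lie inside band B1 (1.0-2.2 Hz)")
  if (f_resp < 0.2 || f_resp > 0.34)
    stop("f_resp must lie in the respiration band 0.2-0.34 Hz")
  if (is.null(cardiac_amp)) {
    cardiac_amp <- switch(archetype,
      term_nonlabor = c(S1 = 0.75, S2 = 0.50, S3 = 0.60, TOCO = 0.60),
      preterm_like = c(S1 = 0.25, S2 = 0.12, S3 = 0.18, TOCO = 0.08),
      nonpregnant_like = c(S1 = 0.25, S2 = 0.12, S3 = 0.18, TOCO = 0.0))
  }
  if (any(cardiac_amp < 0) || noise_sd < 0 || burst_amp < 0 || resp_amp < 0)
    stop("amplitudes must be non-negative")
  if (is.null(schedule)) {
    schedule <- if (archetype == "nonpregnant_like") {
      matrix(numeric(0), ncol = 2L)
    } else {
      n_con <- max(1L, floor(duration_s / 600))
      onsets <- seq(0.15, by = 0.3, length.out = n_con) * duration_s
      cbind(onsets, onsets + 80)
    }
  }
  schedule <- matrix(as.numeric(schedule), ncol = 2L)
  if (nrow(schedule)) {
    schedule <- schedule[order(schedule[, 1L]), , drop = FALSE]
    if (any(schedule[, 1L] < 0) || any(schedule[, 2L] > duration_s) ||
        any(schedule[, 2L] <= schedule[, 1L]))
      stop("contraction schedule must lie inside [0, duration_s]")
    if (nrow(schedule) > 1L &&
        any(schedule[-1L, 1L] < schedule[-nrow(schedule), 2L]))
      stop("contraction schedule intervals overlap")
  }
  structure(list(archetype = archetype, duration_s = duration_s, fs = fs,
                 f_hr = f_hr, cardiac_amp = cardiac_amp,
                 harmonic_decay = harmonic_decay, f_resp = f_resp,
                 resp_amp = resp_amp, schedule = schedule,
                 burst_amp = burst_amp, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# band-limited (0.1-1.0 Hz) unit-variance noise for contraction bursts
burst_noise <- function(n, fs) {
  spec <- design_bandpass(c(0.1, 1.0), fs)
  z <- zero_phase_filter(rnorm(n + 400L), spec)[201L:(200L + n)]
  z / max(sd(z), .Machine$double.eps)
}

#' Generate one synthetic uterine record with annotations
#'
#' See [synth_config()] for the signal model.  Contraction annotations match
#' the schedule; a dummy interval of approximately the same length as its
#' neighboring contraction is placed in each inter-contraction gap (for
#' `nonpregnant_like`, evenly spaced dummy intervals only).
#'
#' @param config a `synth_config`.
#' @return List with `record` (a [uterine_record()]) and `annotations`.
#' @export
synth_record <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  t <- (0:(n - 1)) / fs
  channels <- c("S1", "S2", "S3", "TOCO")

  # cardiac phase with slow sinusoidal FM (+-0.05 Hz over a 60 s cycle)
  f_inst <- config$f_hr + 0.05 * sin(2 * pi * t / 60)
  phase <- 2 * pi * cumsum(f_inst) / fs
  resp_phase <- 2 * pi * config$f_resp * t + runif(1L, 0, 2 * pi)

  env <- numeric(n)
  toco_defl <- numeric(n)
  sched <- config$schedule
  for (i in seq_len(nrow(sched))) {
    on_s <- sched[i, 1L]; off_s <- sched[i, 2L]
    mid <- (on_s + off_s) / 2; w <- (off_s - on_s) / 4
    g <- exp(-0.5 * ((t - mid) / w)^2)
    g[t < on_s | t >= off_s] <- 0
    env <- pmax(env, g)
  }
  burst <- if (nrow(sched)) burst_noise(n, fs) * env else numeric(n)
  toco_defl <- 2 * config$burst_amp * env

  sig <- sapply(channels, function(ch) {
    amp <- config$cardiac_amp[[ch]]
    cardiac <- if (ch == "TOCO") {
      amp * sin(phase)
    } else {
      amp * (sin(phase) + config$harmonic_decay * sin(2 * phase) +
               config$harmonic_decay^2 * sin(3 * phase))
    }
    base <- cardiac + config$resp_amp * sin(resp_phase + which(channels == ch)) +
      rnorm(n, sd = config$noise_sd)
    if (ch == "TOCO") base + toco_defl else base + config$burst_amp * burst
  })

  group <- switch(config$archetype, term_nonlabor = "term",
                  preterm_like = "preterm", nonpregnant_like = "nonpregnant")
  meta <- switch(config$archetype,
    term_nonlabor = list(group = group, gestation_at_recording = 29,
                         gestation_at_delivery = 39),
    preterm_like = list(group = group, gestation_at_recording = 28,
                        gestation_at_delivery = 33),
    nonpregnant_like = list(group = group))
  rec <- uterine_record(sprintf("synth_%s_%d", substr(config$archetype, 1, 4),
                                config$seed),
                        sig, channels, fs, meta)

  ann <- make_annotations(sched, config, n, fs)
  ann$record_id <- rec$record_id
  list(record = rec, annotations = validate_annotations(ann, rec))
}

make_annotations <- function(sched, config, n, fs) {
  if (nrow(sched) == 0L) {
    # nonpregnant: evenly spaced dummy intervals of a typical length
    len_s <- 90
    k <- max(1L, floor(config$duration_s / 300))
    starts <- seq(0.1, by = 0.8 / max(k, 1L), length.out = k) * config$duration_s
    return(data.frame(record_id = "", onset = as.integer(round(starts * fs)),
                      offset = as.integer(round((starts + len_s) * fs)),
                      label = "dummy", stringsAsFactors = FALSE))
  }
  con <- data.frame(onset = as.integer(round(sched[, 1L] * fs)),
                    offset = as.integer(round(sched[, 2L] * fs)),
                    label = "contraction", stringsAsFactors = FALSE)
  # one dummy per contraction, centered in the following (or preceding) gap
  gaps_lo <- c(sched[, 2L], config$duration_s)
  gaps_hi <- c(sched[-1L, 1L], config$duration_s)
  dum <- lapply(seq_len(nrow(sched)), function(i) {
    len <- sched[i, 2L] - sched[i, 1L]
    lo <- gaps_lo[i] + 10; hi <- gaps_hi[min(i, length(gaps_hi))] - 10
    if (hi - lo < len) { # fall back to the gap before the first contraction
      lo <- 10; hi <- sched[1L, 1L] - 10
    }
    mid <- (lo + hi) / 2
    c(round((mid - len / 2) * fs), round((mid + len / 2) * fs))
  })
  dum <- do.call(rbind, dum)
  ann <- rbind(con, data.frame(onset = as.integer(dum[, 1L]),
                               offset = as.integer(dum[, 2L]),
                               label = "dummy", stringsAsFactors = FALSE))
  ann$record_id <- ""
  ann[, c("record_id", "onset", "offset", "label")]
}

#' Generate a synthetic cohort of labeled uterine records
#'
#' Draws `n_per_class` records per archetype with per-record jitter of the
#' cardiac fundamental, channel amplitudes and contraction schedule, all
#' derived deterministically from one seed.  Optionally writes the records
#' and annotations in the WFDB-style dialect of [write_record()].
#'
#' @param n_per_class records per class, at least 2.
#' @param archetypes character vector of two archetype names (see
#'   [synth_config()]); the first is the positive-like class.
#' @param seed master seed.
#' @param duration_s record length in seconds.
#' @param dir optional output directory for record and annotation files.
#' @return List with `records`, `annotations` (one data frame), `labels`
#'   (factor of archetype group names, one per record).
#' @export
synth_cohort <- function(n_per_class, archetypes = c("preterm_like",
                                                     "term_nonlabor"),
                         seed = 1L, duration_s = 1800, dir = NULL) {
  if (n_per_class < 2L) stop("n_per_class must be at least 2")
  archetypes <- match.arg(archetypes,
                          c("term_nonlabor", "preterm_like", "nonpregnant_like"),
                          several.ok = TRUE)
  if (length(archetypes) != 2L) stop("archetypes must name two classes")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  records <- list(); anns <- list(); labels <- character(0)
  counter <- 0L
  for (arch in archetypes) {
    for (i in seq_len(n_per_class)) {
      counter <- counter + 1L
      rec_seed <- (as.integer(seed) + counter * 10007L) %% .Machine$integer.max
      set.seed(rec_seed)
      base <- synth_config(arch, duration_s = duration_s, seed = rec_seed)
      jit <- synth_config(
        arch, duration_s = duration_s, seed = rec_seed,
        f_hr = min(1.5, max(1.2, 1.35 + rnorm(1L, sd = 0.06))),
        f_resp = min(0.34, max(0.2, 0.27 + rnorm(1L, sd = 0.03))),
        cardiac_amp = pmax(base$cardiac_amp * exp(rnorm(4L, sd = 0.15)), 0),
        schedule = if (nrow(base$schedule))
          base$schedule + round(runif(1L, -30, 30)) else base$schedule
      )
      sr <- synth_record(jit)
      sr$record$record_id <- sprintf("synth_%s_%03d", substr(arch, 1L, 4L), counter)
      sr$annotations$record_id <- sr$record$record_id
      records[[length(records) + 1L]] <- sr$record
      anns[[length(anns) + 1L]] <- sr$annotations
      labels <- c(labels, sr$record$meta$group)
    }
  }
  annotations <- do.call(rbind, anns)
  if (!is.null(dir)) {
    for (j in seq_along(records)) {
      write_record(records[[j]], dir)
      write_annotations(anns[[j]],
                        file.path(dir, paste0(records[[j]]$record_id, ".ann.tsv")))
    }
  }
  list(records = records, annotations = annotations, labels = factor(labels))
}
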