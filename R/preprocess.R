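#' Continuous multi-channel recording
#'
#' Lightweight container for an unsegmented recording: a channels x samples
#' signal matrix, its sampling rate, channel names, and cue events.
#'
#' @param signals Numeric matrix, channels x samples.
#' @param rate Sampling rate in Hz.
#' @param channel_names Character vector, one name per channel.
#' @param events Data frame with columns \code{sample} (1-based cue sample
#'   index) and \code{label} (class label), or NULL.
#' @return An object of class \code{continuous_recording}.
#' @export
continuous_recording <- function(signals, rate,
                                 channel_names = rownames(signals),
                                 events = NULL) {
  signals <- as.matrix(signals)
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(signals)))
  stopifnot(rate > 0, length(channel_names) == nrow(signals))
  if (!is.null(events)) {
    stopifnot(all(c("sample", "label") %in% names(events)))
    if (any(events$sample < 1L | events$sample > ncol(signals)))
      stop("event sample indices out of bounds")
  }
  structure(list(signals = signals, rate = rate,
                 channel_names = channel_names, events = events,
                 provenance = character()),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$signals), ncol(x$signals), x$rate,
              if (is.null(x$events)) 0L else nrow(x$events)))
  if (length(x$provenance))
    cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

note_step <- function(rec, step) {
  rec$provenance <- c(rec$provenance, step)
  rec
}

#' Signal-conditioning configuration
#'
#' Defaults follow the standard motor-imagery pipeline: 4--40 Hz zero-phase
#' fourth-order Butterworth band-pass, optional 50 Hz notch, epochs cut
#' relative to the cue, a +/-100 microvolt amplitude rejection threshold, a
#' 3-SD joint-probability rejection limit, and per-trial z-scoring.
#'
#' @param band Band-pass corners (low, high) in Hz.
#' @param filter_order Butterworth order of the one-directional prototype.
#' @param zero_phase Apply the filter forward-backward (always recommended).
#' @param notch_hz Notch center frequency in Hz, or NULL to skip.
#' @param notch_halfwidth_hz Half-width of the notch stop band in Hz.
#' @param amp_threshold_uV Amplitude rejection threshold in microvolts.
#' @param jointprob_sd Joint-probability rejection limit in SD units.
#' @param epoch_window_s Epoch window (start, end) in seconds relative to cue.
#' @param target_rate_hz Resampling target rate in Hz.
#' @param baseline Baseline-correction rule: \code{"precue"} uses the mean of
#'   the pre-cue segment when the window starts before 0, otherwise the whole
#'   trial mean (\code{"whole"} forces the latter).
#' @return An object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(band = c(4, 40),
                              filter_order = 4L,
                              zero_phase = TRUE,
                              notch_hz = 50,
                              notch_halfwidth_hz = 2,
                              amp_threshold_uV = 100,
                              jointprob_sd = 3,
                              epoch_window_s = c(-0.5, 4.5),
                              target_rate_hz = 250,
                              baseline = c("precue", "whole")) {
  stopifnot(length(band) == 2L, band[1] > 0, band[1] < band[2],
            filter_order >= 1L, amp_threshold_uV > 0, jointprob_sd > 0,
            epoch_window_s[1] < epoch_window_s[2], target_rate_hz > 0)
  structure(list(band = band, filter_order = as.integer(filter_order),
                 zero_phase = isTRUE(zero_phase), notch_hz = notch_hz,
                 notch_halfwidth_hz = notch_halfwidth_hz,
                 amp_threshold_uV = amp_threshold_uV,
                 jointprob_sd = jointprob_sd,
                 epoch_window_s = epoch_window_s,
                 target_rate_hz = target_rate_hz,
                 baseline = match.arg(baseline)),
            class = "preprocess_config")
}

apply_filtfilt <- function(signals, filt) {
  t(apply(signals, 1, function(x) signal::filtfilt(filt, x)))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the configured order and applies it
#' forward-backward per channel (zero phase shift in the passband; magnitude
#' response squared).
#'
#' @param rec A [continuous_recording()].
#' @param cfg A [preprocess_config()].
#' @return The filtered recording (input is not modified).
#' @export
bandpass_filter <- function(rec, cfg = preprocess_config()) {
  nyq <- rec$rate / 2
  if (cfg$band[2] >= nyq)
    stop(sprintf("band upper corner %g Hz is not below Nyquist (%g Hz)",
                 cfg$band[2], nyq))
  bf <- signal::butter(cfg$filter_order, cfg$band / nyq, type = "pass")
  rec$signals <- apply_filtfilt(rec$signals, bf)
  note_step(rec, sprintf("bandpass %g-%g Hz (order %d, zero-phase)",
                         cfg$band[1], cfg$band[2], cfg$filter_order))
}

#' Zero-phase notch filter
#'
#' Second-order Butterworth band-stop around \code{notch_hz}, applied
#' forward-backward per channel. Attenuates the line frequency by well over
#' 20 dB while leaving the 8--30 Hz sensorimotor band essentially untouched.
#'
#' @inheritParams bandpass_filter
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, cfg = preprocess_config()) {
  nyq <- rec$rate / 2
  lo <- cfg$notch_hz - cfg$notch_halfwidth_hz
  hi <- cfg$notch_hz + cfg$notch_halfwidth_hz
  if (hi >= nyq) stop("notch band must lie below Nyquist")
  bf <- signal::butter(2, c(lo, hi) / nyq, type = "stop")
  rec$signals <- apply_filtfilt(rec$signals, bf)
  note_step(rec, sprintf("notch %g Hz", cfg$notch_hz))
}

# FFT-domain resampling of one signal to exactly n_out samples.
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  keep <- min(n, n_out)
  half <- (keep + 1L) %/% 2L
  Y[seq_len(half)] <- X[seq_len(half)]
  if (half > 1L)
    Y[(n_out - half + 2L):n_out] <- X[(n - half + 2L):n]
  if (keep %% 2L == 0L) {
    # split the Nyquist bin symmetrically
    nyq <- X[half + 1L]
    if (n_out > n) {
      Y[half + 1L] <- nyq / 2
      Y[n_out - half + 1L] <- Conj(nyq) / 2
    } else {
      Y[half + 1L] <- nyq
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample a recording
#'
#' FFT-domain resampling per channel to \code{round(n * target/rate)} samples;
#' event indices are rescaled accordingly and the rate field updated.
#'
#' @param rec A [continuous_recording()].
#' @param target_rate Target rate in Hz.
#' @return The resampled recording.
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(target_rate > 0)
  if (target_rate == rec$rate) return(rec)
  n <- ncol(rec$signals)
  n_out <- round(n * target_rate / rec$rate)
  rec$signals <- t(apply(rec$signals, 1, fft_resample, n_out = n_out))
  if (!is.null(rec$events))
    rec$events$sample <- pmax(1L, round(rec$events$sample *
                                          target_rate / rec$rate))
  old <- rec$rate
  rec$rate <- target_rate
  note_step(rec, sprintf("resample %g -> %g Hz", old, target_rate))
}

#' Cut cue-locked epochs from a continuous recording
#'
#' Extracts \code{round((end - start) * rate)} samples per event. Baseline
#' correction subtracts the per-channel mean of the pre-cue segment when the
#' window starts before the cue, and the whole-trial mean otherwise. Events
#' whose window leaves the recording are skipped with a warning and counted in
#' the \code{n_skipped} field.
#'
#' @param rec A [continuous_recording()] with events.
#' @param events Optional events data frame overriding \code{rec$events}.
#' @param window_s Window (start, end) in seconds relative to cue onset.
#' @param subject_id Subject identifier attached to every trial.
#' @param baseline \code{"precue"} or \code{"whole"}; see
#'   [preprocess_config()].
#' @return A [trial_set()].
#' @export
epoch_trials <- function(rec, events = rec$events,
                         window_s = c(-0.5, 4.5),
                         subject_id = "S01",
                         baseline = "precue") {
  if (is.null(events) || nrow(events) == 0L) stop("no events to epoch")
  rate <- rec$rate
  n_samp <- round((window_s[2] - window_s[1]) * rate)
  offset <- round(window_s[1] * rate)
  n_pre <- max(0L, -offset)
  total <- ncol(rec$signals)
  kept <- list(); labels <- character(); skipped <- 0L
  for (e in seq_len(nrow(events))) {
    start <- events$sample[e] + offset
    stop_ <- start + n_samp - 1L
    if (start < 1L || stop_ > total) {
      skipped <- skipped + 1L
      next
    }
    seg <- rec$signals[, start:stop_, drop = FALSE]
    base <- if (baseline == "precue" && n_pre > 0L) {
      rowMeans(seg[, seq_len(n_pre), drop = FALSE])
    } else {
      rowMeans(seg)
    }
    kept[[length(kept) + 1L]] <- seg - base
    labels <- c(labels, as.character(events$label[e]))
  }
  if (skipped > 0L)
    warning(sprintf("%d event(s) skipped: epoch window out of bounds", skipped))
  if (length(kept) == 0L) stop("all events fell outside the recording")
  trials <- array(0, dim = c(length(kept), nrow(rec$signals), n_samp))
  for (i in seq_along(kept)) trials[i, , ] <- kept[[i]]
  ts <- trial_set(trials, labels, rep(subject_id, length(kept)), rate,
                  window = window_s,
                  channel_names = rec$channel_names)
  ts$n_skipped <- skipped
  ts
}

#' Amplitude-threshold artifact rejection
#'
#' Removes every trial whose absolute amplitude strictly exceeds the
#' threshold in any channel at any sample.
#'
#' @param trials A [trial_set()].
#' @param threshold_uV Threshold in the units of the data (microvolts).
#' @return List with the cleaned \code{trial_set} and the integer
#'   \code{rejected} indices (relative to the input).
#' @export
reject_amplitude <- function(trials, threshold_uV = 100) {
  stopifnot(threshold_uV > 0)
  peak <- apply(abs(trials$trials), 1, max)
  rejected <- which(peak > threshold_uV)
  keep <- setdiff(seq_len(n_trials(trials)), rejected)
  list(trials = subset_trials(trials, keep), rejected = rejected)
}

#' Joint-probability artifact rejection
#'
#' Scores each trial by the improbability of its samples under per-channel
#' empirical densities estimated from all trials pooled (histogram with
#' Freedman-Diaconis bins): statistic = -mean log p-hat over channels and
#' samples. Trials whose statistic exceeds mean + sd_limit * SD (across
#' trials, single pass) are rejected.
#'
#' @param trials A [trial_set()] with at least 5 trials.
#' @param sd_limit Rejection limit in SD units (default 3); \code{Inf}
#'   rejects nothing.
#' @return List with the cleaned \code{trial_set}, \code{rejected} indices,
#'   and the per-trial \code{statistic}.
#' @export
reject_joint_probability <- function(trials, sd_limit = 3) {
  n <- n_trials(trials)
  if (n < 5L) stop("joint-probability rejection needs at least 5 trials")
  C <- dim(trials$trials)[2]
  stat <- numeric(n)
  logp <- array(0, dim = dim(trials$trials))
  for (ch in seq_len(C)) {
    vals <- as.vector(trials$trials[, ch, ])
    br <- tryCatch(graphics::hist(vals, breaks = "FD", plot = FALSE),
                   error = function(e) graphics::hist(vals,
                                                      breaks = "Sturges",
                                                      plot = FALSE))
    dens <- br$counts / sum(br$counts)
    bin <- findInterval(trials$trials[, ch, ], br$breaks,
                        rightmost.closed = TRUE, all.inside = TRUE)
    p <- dens[bin]
    p[p <= 0] <- 1 / (2 * sum(br$counts))
    logp[, ch, ] <- log(array(p, dim = c(n, dim(trials$trials)[3])))
  }
  stat <- -apply(logp, 1, mean)
  if (is.infinite(sd_limit)) {
    rejected <- integer()
  } else {
    rejected <- which(stat > mean(stat) + sd_limit * stats::sd(stat))
  }
  keep <- setdiff(seq_len(n), rejected)
  list(trials = subset_trials(trials, keep), rejected = rejected,
       statistic = stat)
}

#' Per-trial, per-channel z-score normalization
#'
#' Subtracts the mean and divides by the SD of every channel within every
#' trial. Idempotent up to floating-point error.
#'
#' @param trials A [trial_set()].
#' @return The normalized \code{trial_set}.
#' @export
zscore_trials <- function(trials) {
  arr <- trials$trials
  n <- dim(arr)[1]; C <- dim(arr)[2]
  for (i in seq_len(n)) {
    x <- arr[i, , , drop = TRUE]
    mu <- rowMeans(x)
    sdv <- sqrt(rowMeans((x - mu)^2))
    if (any(sdv == 0)) {
      ch <- which(sdv == 0)[1]
      stop(sprintf("zero-variance channel %d in trial %d", ch, i))
    }
    arr[i, , ] <- (x - mu) / sdv
  }
  trials$trials <- arr
  trials
}

#' Select (and reorder) channels
#'
#' Works on both [continuous_recording()] and [trial_set()] objects; output
#' channels follow the requested order.
#'
#' @param x A recording or trial set with channel names.
#' @param names Character vector of channel names to keep.
#' @return Object of the same class with only the requested channels.
#' @export
select_channels <- function(x, names) {
  have <- if (inherits(x, "continuous_recording")) x$channel_names
          else x$channel_names
  missing <- setdiff(names, have)
  if (length(missing))
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  idx <- match(names, have)
  if (inherits(x, "continuous_recording")) {
    x$signals <- x$signals[idx, , drop = FALSE]
    x$channel_names <- names
  } else {
    x$trials <- x$trials[, idx, , drop = FALSE]
    x$channel_names <- names
  }
  x
}
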