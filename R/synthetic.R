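# Synthetic multi-subject motor-imagery EEG with class-specific contralateral
# event-related desynchronization (ERD), so every other module is testable
# without external recordings.

#' Standard 22-channel motor-cortex montage
#'
#' 10-20-style channel names matching the common 22-electrode motor-imagery
#' layout, with the four source groups used by the generator: left-central,
#' right-central, midline-central, and fronto-central.
#'
#' @return Named list with \code{channels} and \code{groups}.
#' @export
mi_montage <- function() {
  channels <- c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4",
                "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
                "CP3", "CP1", "CPz", "CP2", "CP4",
                "P1", "Pz", "P2", "POz")
  groups <- list(
    left_central = c("C5", "C3", "C1", "CP3", "CP1"),
    right_central = c("C2", "C4", "C6", "CP2", "CP4"),
    midline_central = c("Cz", "CPz", "Pz"),
    fronto_central = c("Fz", "FCz", "FC1", "FC2")
  )
  list(channels = channels, groups = groups)
}

#' Synthetic-data configuration
#'
#' Defaults emulate the structure of the standard four-class benchmark
#' recordings: 22 channels at 250 Hz, 4-s trials whose first 0.5 s is pre-cue
#' rest, classes left hand / right hand / feet / tongue, mu (8-13 Hz) and
#' beta (14-30 Hz) sensorimotor rhythms, contralateral ERD of depth 0.4 in
#' amplitude, multiplicative inter-subject gain variability (SD 0.15),
#' topography jitter (SD 0.1), spatially correlated 1/f background noise, and
#' 0 dB rhythm-to-noise ratio.
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_class Trials per class per subject.
#' @param n_channels Channel count (montage currently fixes 22).
#' @param rate_hz Sampling rate.
#' @param trial_s Trial duration in seconds.
#' @param precue_s Pre-cue rest at the start of each trial, in seconds.
#' @param classes Class labels.
#' @param mu_band,beta_band Rhythm bands in Hz.
#' @param erd_depth Amplitude attenuation fraction in (0, 1); post-cue rhythm
#'   amplitude at the targeted source is multiplied by (1 - erd_depth), i.e.
#'   band power drops by roughly (1 - erd_depth)^2.
#' @param subject_gain_sd SD of the per-subject multiplicative rhythm gain.
#' @param topography_jitter_sd SD of per-subject topography perturbations.
#' @param noise_exponent Slope of the 1/f^exponent background spectrum.
#' @param snr_db Rhythm-to-noise power ratio in dB.
#' @param master_seed Master seed; all randomness derives from it.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_subjects = 5L,
                       trials_per_class = 20L,
                       n_channels = 22L,
                       rate_hz = 250,
                       trial_s = 4,
                       precue_s = 0.5,
                       classes = c("left_hand", "right_hand", "feet", "tongue"),
                       mu_band = c(8, 13),
                       beta_band = c(14, 30),
                       erd_depth = 0.4,
                       subject_gain_sd = 0.15,
                       topography_jitter_sd = 0.1,
                       noise_exponent = 1.0,
                       snr_db = 0,
                       master_seed = 1L) {
  stopifnot(erd_depth >= 0, erd_depth < 1,
            mu_band[2] < rate_hz / 2, beta_band[2] < rate_hz / 2,
            n_channels == 22L)
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_class = as.integer(trials_per_class),
                 n_channels = as.integer(n_channels), rate_hz = rate_hz,
                 trial_s = trial_s, precue_s = precue_s, classes = classes,
                 mu_band = mu_band, beta_band = beta_band,
                 erd_depth = erd_depth, subject_gain_sd = subject_gain_sd,
                 topography_jitter_sd = topography_jitter_sd,
                 noise_exponent = noise_exponent, snr_db = snr_db,
                 master_seed = as.integer(master_seed)),
            class = "sim_config")
}

# Class -> attenuated source group: motor imagery desynchronizes the
# CONTRALATERAL sensorimotor rhythm (left hand -> right-central cortex).
class_source_map <- function() {
  c(left_hand = "right_central", right_hand = "left_central",
    feet = "midline_central", tongue = "fronto_central")
}

#' Generate one subject's generative model
#'
#' Deterministic in (master_seed, subject_index). Builds unit-normalized
#' source topographies over the montage (group channels weighted 1, all
#' channels jittered), the class x source ERD-depth matrix with the fixed
#' contralateral assignment, per-subject rhythm gain, and the subject's seed.
#'
#' @param cfg A [sim_config()].
#' @param subject_index Integer subject index (1-based).
#' @return An object of class \code{subject_model}.
#' @export
generate_subject_model <- function(cfg, subject_index) {
  mont <- mi_montage()
  seed <- derive_seed(cfg$master_seed, "subject", subject_index)
  with_seed(seed, {
    topo <- lapply(mont$groups, function(chs) {
      v <- as.numeric(mont$channels %in% chs)
      v <- v + stats::rnorm(length(v), 0, cfg$topography_jitter_sd)
      v <- pmax(v, 0)
      v / sqrt(sum(v^2))
    })
    gain <- max(0.2, 1 + stats::rnorm(1, 0, cfg$subject_gain_sd))
    erd <- matrix(0, length(cfg$classes), length(mont$groups),
                  dimnames = list(cfg$classes, names(mont$groups)))
    target <- class_source_map()[cfg$classes]
    for (cl in cfg$classes) erd[cl, target[[cl]]] <- cfg$erd_depth
    # individual rhythm peaks: the mu (alpha-range) peak frequency varies by
    # roughly +/- 1 Hz across people, the beta peak more; each subject gets
    # its own band-limited rhythm support inside the configured bands
    mu_mid <- mean(cfg$mu_band); mu_hw <- diff(cfg$mu_band) / 2
    mu_c <- min(max(stats::rnorm(1, mu_mid, 1.2),
                    cfg$mu_band[1] + 1), cfg$mu_band[2] - 1)
    beta_mid <- mean(cfg$beta_band)
    beta_c <- min(max(stats::rnorm(1, beta_mid, 2.5),
                      cfg$beta_band[1] + 2), cfg$beta_band[2] - 2)
    structure(list(subject_id = sprintf("S%02d", subject_index),
                   topographies = topo, erd = erd, gain = gain,
                   mu_band = c(mu_c - mu_hw, mu_c + mu_hw),
                   beta_band = c(beta_c - 6, beta_c + 6),
                   base_amplitude = c(mu = 1, beta = 0.5),
                   noise_rho = 0.3, seed = seed, cfg = cfg),
              class = "subject_model")
  })
}

# Band-limited rhythm: white noise filtered to the band (zero-phase).
band_noise <- function(n, rate, band) {
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 200))
  x <- x[101:(100 + n)]
  x / stats::sd(x)
}

# 1/f^alpha noise via FFT spectral shaping, unit variance.
pink_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  shape <- 1 / f^(alpha / 2)
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate one trial
#'
#' trial = sum over sources of topography x amplitude-modulated band-limited
#' rhythm (mu + beta), plus spatially correlated 1/f noise scaled to the
#' configured SNR. During the post-cue interval the class-targeted source's
#' rhythm amplitude is multiplied by (1 - erd_depth). Deterministic in
#' \code{trial_seed}.
#'
#' @param model A [generate_subject_model()] output.
#' @param class_label One of the configured classes.
#' @param trial_seed Integer seed for this trial.
#' @return Numeric matrix channels x samples.
#' @export
simulate_trial <- function(model, class_label, trial_seed) {
  cfg <- model$cfg
  if (!class_label %in% cfg$classes) stop("unknown class: ", class_label)
  n <- round(cfg$trial_s * cfg$rate_hz)
  n_pre <- round(cfg$precue_s * cfg$rate_hz)
  C <- cfg$n_channels
  with_seed(trial_seed, {
    X <- matrix(0, C, n)
    envelope_base <- c(rep(1, n_pre), rep(1, n - n_pre))
    for (src in names(model$topographies)) {
      depth <- model$erd[class_label, src]
      env <- envelope_base
      if (depth > 0) env[(n_pre + 1L):n] <- 1 - depth
      rhythm <- model$base_amplitude["mu"] *
        band_noise(n, cfg$rate_hz, model$mu_band) +
        model$base_amplitude["beta"] *
          band_noise(n, cfg$rate_hz, model$beta_band)
      X <- X + model$gain * model$topographies[[src]] %o% (env * rhythm)
    }
    sig_power <- mean(X^2)
    common <- pink_noise(n, cfg$noise_exponent)
    noise <- matrix(0, C, n)
    rho <- model$noise_rho
    for (ch in seq_len(C)) {
      noise[ch, ] <- sqrt(1 - rho) * pink_noise(n, cfg$noise_exponent) +
        sqrt(rho) * common
    }
    noise_power <- mean(noise^2)
    scale <- sqrt(sig_power / (noise_power * 10^(cfg$snr_db / 10)))
    X + scale * noise
  })
}

#' Generate a full multi-subject dataset
#'
#' Balanced labels, one subject model per subject, trials at the configured
#' rate and duration. Bit-identical for identical \code{master_seed}.
#'
#' @param cfg A [sim_config()].
#' @return A [trial_set()] whose window marks the first \code{precue_s}
#'   seconds as pre-cue rest.
#' @export
generate_dataset <- function(cfg = sim_config()) {
  n_per_subj <- cfg$trials_per_class * length(cfg$classes)
  total <- cfg$n_subjects * n_per_subj
  n <- round(cfg$trial_s * cfg$rate_hz)
  arr <- array(0, dim = c(total, cfg$n_channels, n))
  labels <- character(total); subjects <- character(total)
  i <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    model <- generate_subject_model(cfg, s)
    for (cl in cfg$classes) {
      for (r in seq_len(cfg$trials_per_class)) {
        i <- i + 1L
        seed <- derive_seed(cfg$master_seed, "trial", s, cl, r)
        arr[i, , ] <- simulate_trial(model, cl, seed)
        labels[i] <- cl
        subjects[i] <- model$subject_id
      }
    }
  }
  trial_set(arr, labels, subjects, cfg$rate_hz,
            window = c(-cfg$precue_s, cfg$trial_s - cfg$precue_s),
            channel_names = mi_montage()$channels, classes = cfg$classes)
}

#' Split a dataset into per-subject support/query meta-tasks
#'
#' One task per subject: \code{k_shot} trials per class sampled without
#' replacement form the support set, all remaining trials the query set.
#'
#' @param ts A [trial_set()].
#' @param k_shot Support trials per class.
#' @param seed Integer seed for the support sampling.
#' @return List of \code{meta_task} objects (fields \code{support},
#'   \code{query}, \code{subject_id}).
#' @export
make_meta_tasks <- function(ts, k_shot, seed = 1L) {
  with_seed(seed, {
    lapply(unique(ts$subject_ids), function(s) {
      sup <- integer()
      for (cl in levels(ts$labels)) {
        idx <- which(ts$subject_ids == s & ts$labels == cl)
        if (length(idx) <= k_shot)
          stop(sprintf(
            "subject %s has only %d trials of class %s (need > %d)",
            s, length(idx), cl, k_shot))
        sup <- c(sup, sample(idx, k_shot))
      }
      qry <- setdiff(which(ts$subject_ids == s), sup)
      structure(list(support = subset_trials(ts, sort(sup)),
                     query = subset_trials(ts, qry),
                     subject_id = s),
                class = "meta_task")
    })
  })
}

#' Post/pre-cue band-power ratio (ERD index)
#'
#' Band-pass filters each trial (zero-phase), accumulates post-cue and
#' pre-cue variance at the requested channels across all trials, and returns
#' the ratio of the pooled powers (averaging power before taking the ratio
#' avoids the small-sample bias of per-trial ratios on short pre-cue
#' windows). For a rhythm attenuated in amplitude by (1 - erd_depth) after
#' the cue the noise-free ratio is (1 - erd_depth)^2; in-band background
#' noise pulls the measured ratio toward 1.
#'
#' @param ts A [trial_set()] whose window starts before the cue.
#' @param channels Channel names (or indices) to average over.
#' @param band Frequency band in Hz (default mu, 8-13).
#' @return Mean post/pre power ratio across the selected trials.
#' @export
erd_ratio <- function(ts, channels, band = c(8, 13)) {
  if (is.character(channels)) channels <- match(channels, ts$channel_names)
  n_pre <- round(-ts$window[1] * ts$rate)
  stopifnot(n_pre >= 8)
  bf <- signal::butter(4, band / (ts$rate / 2), type = "pass")
  Tn <- dim(ts$trials)[3]
  pad <- min(200L, Tn - 1L)
  num <- 0; den <- 0
  for (i in seq_len(n_trials(ts))) {
    for (ch in channels) {
      x <- ts$trials[i, ch, ]
      # mirror-pad so filter edge transients fall outside the windows
      xp <- signal::filtfilt(bf, c(rev(x[1:pad]), x, rev(x[(Tn - pad + 1):Tn])))
      x <- xp[(pad + 1):(pad + Tn)]
      num <- num + stats::var(x[(n_pre + 1):Tn])
      den <- den + stats::var(x[1:n_pre])
    }
  }
  num / den
}

#' Log band-power features
#'
#' Per trial and channel, the log mean spectral power inside each requested
#' band (periodogram). The classical baseline feature for motor-imagery
#' classification, used in separability checks.
#'
#' @param ts A [trial_set()].
#' @param bands Named list of (low, high) Hz bands.
#' @param window_idx Optional sample indices to restrict to (e.g. post-cue).
#' @return Numeric matrix n_trials x (channels * bands).
#' @export
bandpower_features <- function(ts, bands = list(mu = c(8, 13),
                                                beta = c(14, 30)),
                               window_idx = NULL) {
  n <- n_trials(ts); C <- dim(ts$trials)[2]; Tn <- dim(ts$trials)[3]
  if (is.null(window_idx)) window_idx <- seq_len(Tn)
  m <- length(window_idx)
  freqs <- (seq_len(m %/% 2)) * ts$rate / m
  sel <- lapply(bands, function(b) which(freqs >= b[1] & freqs <= b[2]))
  out <- matrix(0, n, C * length(bands))
  for (i in seq_len(n)) {
    for (ch in seq_len(C)) {
      x <- ts$trials[i, ch, window_idx]
      P <- abs(stats::fft(x - mean(x))[2:(m %/% 2 + 1)])^2 / m
      for (bi in seq_along(bands)) {
        out[i, (bi - 1L) * C + ch] <- log(mean(P[sel[[bi]]]) + 1e-12)
      }
    }
  }
  colnames(out) <- as.vector(t(outer(names(bands), ts$channel_names, paste,
                                     sep = "_")))
  out
}
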