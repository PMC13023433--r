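#' Labeled epoched EEG trials
#'
#' The universal data carrier of the package: an n_trials x channels x samples
#' array with class labels, subject identifiers, the sampling rate, and the
#' epoch window relative to the cue.
#'
#' @param trials Numeric array n_trials x channels x samples.
#' @param labels Class label per trial (factor or character).
#' @param subject_ids Subject identifier per trial.
#' @param rate Sampling rate in Hz.
#' @param window Epoch window (start, end) in seconds relative to cue.
#' @param channel_names Optional channel names.
#' @param classes Optional explicit class set (factor levels).
#' @return An object of class \code{trial_set}.
#' @export
trial_set <- function(trials, labels, subject_ids, rate = 250,
                      window = c(0, dim(trials)[3] / rate),
                      channel_names = NULL, classes = NULL) {
  stopifnot(length(dim(trials)) == 3L)
  n <- dim(trials)[1]
  stopifnot(length(labels) == n, length(subject_ids) == n, rate > 0)
  labels <- if (is.null(classes)) factor(labels) else
    factor(labels, levels = classes)
  if (anyNA(labels)) stop("labels outside the configured class set")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(dim(trials)[2]))
  structure(list(trials = trials, labels = labels,
                 subject_ids = as.character(subject_ids), rate = rate,
                 window = window, channel_names = channel_names),
            class = "trial_set")
}

#' Number of trials in a trial set
#' @param ts A [trial_set()].
#' @return Integer count.
#' @export
n_trials <- function(ts) dim(ts$trials)[1]

#' Subset a trial set by trial index
#' @param ts A [trial_set()].
#' @param idx Integer indices of trials to keep.
#' @return A \code{trial_set} with the selected trials.
#' @export
subset_trials <- function(ts, idx) {
  ts$trials <- ts$trials[idx, , , drop = FALSE]
  ts$labels <- ts$labels[idx]
  ts$subject_ids <- ts$subject_ids[idx]
  ts
}

#' Concatenate trial sets
#' @param ... \code{trial_set} objects with identical geometry.
#' @return One combined \code{trial_set}.
#' @export
combine_trials <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "trial_set")) parts <- parts[[1]]
  base <- parts[[1]]
  dims <- dim(base$trials)
  total <- sum(vapply(parts, n_trials, integer(1)))
  arr <- array(0, dim = c(total, dims[2], dims[3]))
  labels <- character(); subjects <- character()
  at <- 0L
  for (p in parts) {
    stopifnot(all(dim(p$trials)[2:3] == dims[2:3]), p$rate == base$rate)
    k <- n_trials(p)
    if (k > 0L) arr[(at + 1L):(at + k), , ] <- p$trials
    labels <- c(labels, as.character(p$labels))
    subjects <- c(subjects, p$subject_ids)
    at <- at + k
  }
  trial_set(arr, labels, subjects, base$rate, base$window,
            base$channel_names, classes = levels(base$labels))
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz\n",
              n_trials(x), dim(x$trials)[2], dim(x$trials)[3], x$rate))
  cat(sprintf("  window: [%g, %g] s; subjects: %s\n", x$window[1], x$window[2],
              paste(unique(x$subject_ids), collapse = ", ")))
  print(table(x$labels))
  invisible(x)
}

# Stratified index split: per (subject, class) cell, assign `fraction` of the
# trials (rounded down, at least 1 when the cell has >= 2) to the first part.
stratified_split <- function(ts, fraction, seed) {
  with_seed(seed, {
    first <- integer()
    for (s in unique(ts$subject_ids)) {
      for (cl in levels(ts$labels)) {
        idx <- which(ts$subject_ids == s & ts$labels == cl)
        if (length(idx) < 2L)
          stop(sprintf("subject %s has fewer than 2 trials of class %s", s, cl))
        k <- max(1L, floor(length(idx) * fraction))
        first <- c(first, sample(idx, k))
      }
    }
    list(first = sort(first),
         second = setdiff(seq_len(n_trials(ts)), first))
  })
}

#' Write a trial set to disk
#'
#' Serializes the trial array as an RDS container next to a structured-text
#' (JSON) sidecar holding labels, subjects, rate, window, and channel names,
#' so the metadata stays auditable without loading R.
#'
#' @param ts A [trial_set()].
#' @param path Base path; writes \code{<path>.rds} and \code{<path>.json}.
#' @return Invisibly, the base path.
#' @export
write_trial_set <- function(ts, path) {
  saveRDS(ts$trials, paste0(path, ".rds"), compress = "gzip")
  meta <- list(labels = as.character(ts$labels),
               classes = levels(ts$labels),
               subject_ids = ts$subject_ids, rate = ts$rate,
               window = ts$window, channel_names = ts$channel_names)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trial set written by [write_trial_set()]
#' @param path Base path used when writing.
#' @return A [trial_set()].
#' @export
read_trial_set <- function(path) {
  arr <- readRDS(paste0(path, ".rds"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  trial_set(arr, meta$labels, meta$subject_ids, meta$rate,
            window = meta$window, channel_names = meta$channel_names,
            classes = meta$classes)
}
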