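# Declarative run configuration (YAML, no code execution) and run manifests.

run_config_sections <- function() {
  list(model = model_config, preprocess = preprocess_config,
       sim = sim_config, train = train_config, meta = meta_config,
       nas = nas_config)
}

#' Load a run configuration
#'
#' Reads a YAML file with optional sections \code{model}, \code{preprocess},
#' \code{sim}, \code{train}, \code{meta}, \code{nas} plus top-level
#' \code{master_seed} and \code{output_dir}. Every omitted value takes the
#' package default; unknown sections or keys are rejected by name. An empty
#' file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return An object of class \code{run_config}: list of resolved section
#'   objects plus \code{master_seed} and \code{output_dir}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  sections <- run_config_sections()
  known_top <- c(names(sections), "master_seed", "output_dir")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- list()
  for (sec in names(sections)) {
    ctor <- sections[[sec]]
    args <- raw[[sec]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
    out[[sec]] <- do.call(ctor, args)
  }
  out$master_seed <- if (is.null(raw$master_seed)) 1L
                     else as.integer(raw$master_seed)
  out$output_dir <- if (is.null(raw$output_dir)) "." else raw$output_dir
  class(out) <- "run_config"
  out
}

#' Serialize a run configuration back to YAML
#'
#' Writes the fully resolved configuration (every default made explicit), so
#' \code{load_config(dump_config(x))} round-trips.
#'
#' @param cfg A \code{run_config}.
#' @param path Output YAML path.
#' @return Invisibly, \code{path}.
#' @export
dump_config <- function(cfg, path) {
  plain <- lapply(cfg[names(run_config_sections())], function(sec) {
    sec <- unclass(sec)
    sec[!vapply(sec, is.function, logical(1))]
  })
  plain$master_seed <- cfg$master_seed
  plain$output_dir <- cfg$output_dir
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the resolved configuration, master seed, R and package versions,
#' and timestamp of a run as JSON — sufficient to reproduce it.
#'
#' @param cfg A \code{run_config}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(cfg, dir = cfg$output_dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(fileext = ".yaml")
  dump_config(cfg, tmp)
  manifest <- list(
    config = yaml::read_yaml(tmp),
    master_seed = cfg$master_seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("midecode")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EDF continuous recording
#'
#' Thin adapter for European Data Format files (16-bit little-endian
#' samples, per-record channel blocks), returning a
#' [continuous_recording()]. Annotation channels are dropped. Only
#' uniform-rate signals are supported.
#'
#' @param path Path to an EDF file.
#' @return A [continuous_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr(8)                      # version
  hdr(80); hdr(80)            # patient, recording ids
  hdr(8); hdr(8)              # start date, time
  header_bytes <- as.integer(hdr(8))
  hdr(44)                     # reserved
  n_records <- as.integer(hdr(8))
  record_s <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  labels <- vapply(seq_len(ns), function(i) hdr(16), character(1))
  for (i in seq_len(ns)) hdr(80)   # transducer
  for (i in seq_len(ns)) hdr(8)    # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), character(1)))
  for (i in seq_len(ns)) hdr(80)   # prefiltering
  nsamp <- as.integer(vapply(seq_len(ns), function(i) hdr(8), character(1)))
  for (i in seq_len(ns)) hdr(32)   # reserved
  seek(con, header_bytes)
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  sig <- vector("list", ns)
  for (i in seq_len(ns)) sig[[i]] <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      x <- readBin(con, "integer", nsamp[i], size = 2, endian = "little",
                   signed = TRUE)
      sig[[i]][[r]] <- x
    }
  }
  rates <- nsamp / record_s
  if (length(unique(rates[keep])) != 1L)
    stop("mixed sampling rates are not supported")
  mat <- do.call(rbind, lapply(which(keep), function(i) {
    d <- unlist(sig[[i]], use.names = FALSE)
    pmin[i] + (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
  }))
  continuous_recording(mat, rates[keep][1],
                       channel_names = labels[keep])
}
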