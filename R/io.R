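#' Write a recording to a plain-text directory container
#'
#' Three CSV files plus a small YAML header: `signals.csv` (one column per
#' site, header = site ids, one row per 1 kHz sample), `events.csv` (the
#' stimulus schedule), `sites.csv` (the site table) and `recording.yaml`
#' (sampling rate and dimensions). Ground truth, if present, is written to
#' `ground_truth_edges.csv` / `ground_truth_effects.csv`.
#'
#' @param recording A `narr_recording`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "narr_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- as.data.frame(t(recording$signals))
  names(sig) <- rownames(recording$signals)
  utils::write.csv(sig, file.path(dir, "signals.csv"), row.names = FALSE)
  utils::write.csv(recording$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(recording$sites, file.path(dir, "sites.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(sampling_rate = recording$fs,
                        n_sites = nrow(recording$sites),
                        n_samples = ncol(recording$signals)),
                   file.path(dir, "recording.yaml"))
  if (!is.null(recording$ground_truth)) {
    utils::write.csv(recording$ground_truth$edges,
                     file.path(dir, "ground_truth_edges.csv"),
                     row.names = FALSE)
    utils::write.csv(recording$ground_truth$effects,
                     file.path(dir, "ground_truth_effects.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Container directory.
#' @return A `narr_recording` (without ground truth unless present on disk).
#' @export
read_recording <- function(dir) {
  hdr <- yaml::read_yaml(file.path(dir, "recording.yaml"))
  sig <- utils::read.csv(file.path(dir, "signals.csv"), check.names = FALSE,
                         colClasses = rep("numeric", hdr$n_sites))
  signals <- t(as.matrix(sig))
  dimnames(signals) <- list(colnames(sig), NULL)
  events <- tibble::as_tibble(utils::read.csv(file.path(dir, "events.csv")))
  sites <- tibble::as_tibble(utils::read.csv(file.path(dir, "sites.csv")))
  gt <- NULL
  ep <- file.path(dir, "ground_truth_edges.csv")
  if (file.exists(ep)) {
    gt <- list(
      edges = tibble::as_tibble(utils::read.csv(ep)),
      effects = tibble::as_tibble(
        utils::read.csv(file.path(dir, "ground_truth_effects.csv"))))
  }
  structure(list(signals = signals, sites = sites,
                 fs = hdr$sampling_rate, events = events,
                 ground_truth = gt),
            class = "narr_recording")
}
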