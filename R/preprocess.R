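#' Common-average re-referencing
#'
#' Re-references every included site to the global mean signal of its subject
#' by subtracting, at each time point, the average across that subject's
#' included sites. Excluded sites are left untouched and do not enter the mean.
#'
#' @param recording A `narr_recording`.
#' @return The recording with re-referenced signals.
#' @export
common_average_reference <- function(recording) {
  stopifnot(inherits(recording, "narr_recording"))
  sites <- recording$sites
  for (sj in unique(sites$subject_id)) {
    inc <- sites$subject_id == sj & !sites$excluded
    if (sum(inc) < 2)
      stop("subject ", sj, " has fewer than 2 included sites; ",
           "common average reference undefined")
    idx <- which(inc)
    avg <- colMeans(recording$signals[idx, , drop = FALSE])
    recording$signals[idx, ] <-
      sweep(recording$signals[idx, , drop = FALSE], 2, avg)
  }
  recording
}

#' Flag sites for exclusion
#'
#' @param recording A `narr_recording`.
#' @param site_ids Character vector of site ids to exclude. Unknown ids are an
#'   error; excluding all sites of the recording is an error.
#' @param quiet Suppress the bookkeeping message.
#' @return The recording with `sites$excluded` updated.
#' @export
exclude_sites <- function(recording, site_ids, quiet = FALSE) {
  stopifnot(inherits(recording, "narr_recording"))
  if (length(site_ids) == 0) return(recording)
  unknown <- setdiff(site_ids, recording$sites$site_id)
  if (length(unknown))
    stop("unknown site id(s): ", paste(unknown, collapse = ", "))
  recording$sites$excluded <- recording$sites$excluded |
    recording$sites$site_id %in% site_ids
  n_inc <- sum(!recording$sites$excluded)
  if (n_inc == 0) stop("exclusion leaves zero analyzable sites")
  if (!quiet)
    message(sum(recording$sites$excluded), " sites excluded; ",
            n_inc, " analyzed")
  recording
}

#' Included-site view of a site table
#' @param sites Site table.
#' @return Rows with `excluded == FALSE`.
#' @export
included_sites <- function(sites) sites[!sites$excluded, , drop = FALSE]

# stimulus-indexed trial id shared across subjects (all subjects saw the
# identical sequence), so cross-subject pattern vectors are well-defined
trial_id_of <- function(events) {
  pos <- ifelse(is.na(events$position_in_series), "gray",
                as.character(events$position_in_series))
  paste(events$condition, events$series_index, pos, sep = "_")
}

#' Cut peri-transition epochs
#'
#' Extracts, for every included site and every selected event, the window
#' `[-100, +500)` ms around event onset (600 samples at 1 kHz; onset at
#' sample index 100, 0-based). Image events are selected by their transition
#' class; requesting the `image_to_isi` class selects gray-screen onsets (ISI
#' controls).
#'
#' @param recording A `narr_recording`.
#' @param events Event table; defaults to the recording's own schedule.
#' @param window Length-2 ms window relative to onset, half-open.
#' @param classes Transition classes to keep. Default `image_to_image`:
#'   within-series transitions, the trial universe of the encoding analysis.
#' @return A `narr_epochs`: list with `data` (epochs x samples matrix) and
#'   `meta` (tibble: subject/site/region/hemisphere/condition/class/onset/
#'   trial_id).
#' @export
epoch_transitions <- function(recording, events = recording$events,
                              window = c(-100, 500),
                              classes = "image_to_image") {
  stopifnot(inherits(recording, "narr_recording"), length(window) == 2)
  wlen <- as.integer(window[2] - window[1])
  sel <- events[events$transition_class %in% classes, , drop = FALSE]
  sites <- included_sites(recording$sites)
  if (nrow(sel) == 0 || length(classes) == 0) {
    return(structure(list(
      data = matrix(numeric(), 0, wlen),
      meta = tibble::tibble(subject_id = character(), site_id = character(),
                            region = character(), hemisphere = character(),
                            condition = character(),
                            transition_class = character(),
                            onset_ms = numeric(), trial_id = character()),
      window = window, fs = recording$fs), class = "narr_epochs"))
  }
  n_samp <- ncol(recording$signals)
  first_idx <- sel$onset_ms + window[1] + 1
  last_idx <- sel$onset_ms + window[2]
  bad <- first_idx < 1 | last_idx > n_samp
  if (any(bad))
    stop("event at onset ", sel$onset_ms[which(bad)[1]],
         " ms falls within ", window[1], "/", window[2],
         " ms of the recording edge")

  n_ep <- nrow(sel) * nrow(sites)
  data <- matrix(NA_real_, n_ep, wlen)
  meta <- vector("list", nrow(sites))
  row <- 0L
  tid <- trial_id_of(sel)
  for (i in seq_len(nrow(sites))) {
    sig <- recording$signals[sites$site_id[i], ]
    for (e in seq_len(nrow(sel))) {
      row <- row + 1L
      data[row, ] <- sig[first_idx[e]:last_idx[e]]
    }
    meta[[i]] <- tibble::tibble(
      subject_id = sites$subject_id[i], site_id = sites$site_id[i],
      region = sites$region[i], hemisphere = sites$hemisphere[i],
      condition = sel$condition, transition_class = sel$transition_class,
      onset_ms = sel$onset_ms, trial_id = tid)
  }
  structure(list(data = data, meta = dplyr::bind_rows(meta),
                 window = window, fs = recording$fs),
            class = "narr_epochs")
}

#' Baseline (DC-offset) correction
#'
#' Subtracts from each epoch its mean amplitude over a baseline window. Two
#' windows are used in practice: `c(-100, 50)` ms for time-domain display and
#' `c(-100, 100)` ms for the connectivity path.
#'
#' @param epochs A `narr_epochs` (or a single numeric epoch vector).
#' @param baseline_window ms range, half-open, relative to onset; must
#'   intersect the epoch window.
#' @param epoch_window Epoch window in ms (used when `epochs` is a bare
#'   vector).
#' @return Same type as input, baseline-corrected.
#' @export
baseline_correct <- function(epochs, baseline_window = c(-100, 50),
                             epoch_window = c(-100, 500)) {
  win <- if (inherits(epochs, "narr_epochs")) epochs$window else epoch_window
  t_ms <- seq(win[1], win[2] - 1)
  sel <- t_ms >= baseline_window[1] & t_ms < baseline_window[2]
  if (!any(sel)) stop("baseline window does not intersect the epoch window")
  if (inherits(epochs, "narr_epochs")) {
    epochs$data <- epochs$data -
      rowMeans(epochs$data[, sel, drop = FALSE])
    epochs
  } else {
    epochs - mean(epochs[sel])
  }
}

#' @export
print.narr_epochs <- function(x, ...) {
  cat(sprintf("<narr_epochs> %d epochs x %d samples, window [%d, %d) ms\n",
              nrow(x$data), ncol(x$data), x$window[1], x$window[2]))
  invisible(x)
}
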