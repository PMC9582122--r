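#' Stimulus schedule configuration
#'
#' Describes the block design of the visual-narrative experiment: two
#' condition blocks (scrambled then sequential), each consisting of
#' `n_series` image series of `images_per_series` images shown back to back,
#' with a gray inter-series screen between series.
#'
#' @param n_series Number of image series (stories) per condition block.
#' @param images_per_series Images per series.
#' @param image_duration Image display duration in ms.
#' @param isi_duration Gray-screen (inter-series interval) duration in ms.
#' @param condition_order Character vector of the two condition labels in
#'   presentation order; the first block is shown first.
#' @return A `schedule_config` list.
#' @export
schedule_config <- function(n_series = 7L,
                            images_per_series = 5L,
                            image_duration = 2000,
                            isi_duration = 6000,
                            condition_order = c("Scr", "Seq")) {
  if (n_series < 0 || images_per_series < 1)
    stop("counts must be >= 1 (n_series may be 0 for an empty schedule)")
  if (image_duration <= 0 || isi_duration <= 0)
    stop("durations must be > 0")
  if (length(condition_order) != 2 || anyDuplicated(condition_order))
    stop("condition_order must be two distinct labels")
  structure(
    list(n_series = as.integer(n_series),
         images_per_series = as.integer(images_per_series),
         image_duration = image_duration,
         isi_duration = isi_duration,
         condition_order = condition_order),
    class = "schedule_config")
}

#' Generate the full two-block stimulus schedule
#'
#' Lays out image and gray-screen events for both condition blocks in
#' presentation order. Every image event is tagged with a transition class:
#' the very first image of a block is `first_of_experiment`, the first image
#' of each later series is `isi_to_image` (the preceding event is the gray
#' screen), all other images are `image_to_image`, and each gray-screen onset
#' is `image_to_isi`.
#'
#' @param config A [schedule_config()].
#' @param start_ms Onset of the first event, in ms from recording start
#'   (lead-in so that peri-onset windows fit within the recording).
#' @return A tibble of events ordered by onset with columns `onset_ms`,
#'   `kind` ("image"/"gray"), `condition`, `series_index` (0-based),
#'   `position_in_series` (0-based; NA for gray) and `transition_class`.
#' @export
generate_schedule <- function(config = schedule_config(), start_ms = 1000) {
  stopifnot(inherits(config, "schedule_config"))
  n_s <- config$n_series
  n_i <- config$images_per_series
  dur <- config$image_duration
  isi <- config$isi_duration
  series_len <- n_i * dur + isi
  block_len <- n_s * series_len

  one_block <- function(condition, block_start) {
    if (n_s == 0L) return(NULL)
    rows <- vector("list", n_s)
    for (k in seq_len(n_s) - 1L) {
      s0 <- block_start + k * series_len
      img_on <- s0 + (seq_len(n_i) - 1L) * dur
      cls <- rep("image_to_image", n_i)
      cls[1] <- if (k == 0L) "first_of_experiment" else "isi_to_image"
      rows[[k + 1L]] <- tibble::tibble(
        onset_ms = c(img_on, s0 + n_i * dur),
        kind = c(rep("image", n_i), "gray"),
        condition = condition,
        series_index = k,
        position_in_series = c(seq_len(n_i) - 1L, NA_integer_),
        transition_class = c(cls, "image_to_isi"))
    }
    dplyr::bind_rows(rows)
  }

  ev <- dplyr::bind_rows(
    one_block(config$condition_order[1], start_ms),
    one_block(config$condition_order[2], start_ms + block_len))
  if (is.null(ev) || ncol(ev) == 0) {
    ev <- tibble::tibble(onset_ms = numeric(), kind = character(),
                         condition = character(), series_index = integer(),
                         position_in_series = integer(),
                         transition_class = character())
  }
  stopifnot(!is.unsorted(ev$onset_ms, strictly = TRUE))
  ev
}

#' Total schedule span in ms (end of the last event), for sizing recordings.
#' @param config A [schedule_config()].
#' @param start_ms Lead-in before the first onset.
#' @param tail_ms Padding after the last event.
#' @return Duration in ms.
#' @export
schedule_duration <- function(config = schedule_config(), start_ms = 1000,
                              tail_ms = 1000) {
  series_len <- config$images_per_series * config$image_duration +
    config$isi_duration
  start_ms + 2 * config$n_series * series_len + tail_ms
}
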