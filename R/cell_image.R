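#' Multi-channel time-lapse image of a single cell
#'
#' Container for one cell's pixel data: a 4-D array indexed
#' `[row, col, channel, frame]`, the whole-cell region of interest (ROI)
#' mask, channel labels, and acquisition metadata. All analysis functions in
#' the package consume this container; the ROI is always supplied, never
#' inferred, so that cell segmentation cannot contaminate downstream
#' measurements.
#'
#' @param data Numeric 4-D array, `dim = c(H, W, n_channels, n_frames)`.
#'   A plain `H x W` matrix is promoted to a single-channel, single-frame
#'   stack.
#' @param channels Character vector of unique channel labels, one per
#'   channel slice.
#' @param roi Logical `H x W` matrix marking the whole-cell ROI.
#' @param frame_interval Time between frames, in minutes (metadata only;
#'   no computation depends on physical units).
#' @param event_frame Frame index (1-based) at which a perturbation such as
#'   drug addition occurs, or `NA` if none.
#' @param cell_id Identifier used in output tables.
#' @return An object of class `cell_image`.
#' @export
cell_image <- function(data, channels, roi, frame_interval = 1,
                       event_frame = NA_integer_, cell_id = "cell1") {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) != 4L)
    stop("data must be a 4-D array [row, col, channel, frame]")
  if (length(channels) != dim(data)[3L])
    stop("length(channels) must equal the number of channel slices")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  check_roi(roi, dim(data)[1:2])
  structure(
    list(data = data, channels = as.character(channels), roi = roi,
         frame_interval = frame_interval,
         event_frame = as.integer(event_frame), cell_id = cell_id),
    class = "cell_image")
}

#' @export
print.cell_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cell_image '%s'> %d x %d px, %d channel(s) [%s], %d frame(s)\n",
              x$cell_id, d[1], d[2], d[3],
              paste(x$channels, collapse = ", "), d[4]))
  cat(sprintf("  ROI: %d px (%.1f%% of frame); frame interval %g min\n",
              sum(x$roi), 100 * mean(x$roi), x$frame_interval))
  invisible(x)
}

#' @export
dim.cell_image <- function(x) dim(x$data)

#' Extract one channel's image at one frame
#'
#' @param x A [cell_image].
#' @param channel Channel label or index.
#' @param frame Frame index (default 1).
#' @return Numeric `H x W` matrix.
#' @export
get_frame <- function(x, channel, frame = 1L) {
  stopifnot(inherits(x, "cell_image"))
  ci <- channel_index(x, channel)
  if (frame < 1L || frame > dim(x$data)[4L])
    stop("frame index out of range")
  x$data[, , ci, frame]
}

channel_index <- function(x, channel) {
  if (is.numeric(channel)) {
    if (channel < 1 || channel > length(x$channels))
      stop("channel index out of range")
    return(as.integer(channel))
  }
  i <- match(channel, x$channels)
  if (is.na(i))
    stop("unknown channel label '", channel, "' (have: ",
         paste(x$channels, collapse = ", "), ")")
  i
}
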