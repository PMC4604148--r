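# TIFF stack I/O. Pixel data are written as plain multi-page TIFF with
# pages ordered frame-major, channel-minor (page = (frame-1)*C + channel);
# a JSON sidecar (<path>.json) records the dimension order, image size,
# channel labels and acquisition metadata so the layout is never guessed.

#' Write a cell image stack to a multi-page TIFF with JSON sidecar
#'
#' Counts are stored as 16-bit unsigned samples; integer-valued data in
#' `[0, 65535]` (the renderer's output range) round-trip bitwise.
#'
#' @param stack A [cell_image].
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#' @param sidecar Write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "cell_image"))
  d <- dim(stack$data)
  pages <- vector("list", d[3] * d[4])
  i <- 0L
  for (t in seq_len(d[4])) for (c in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- stack$data[, , c, t] / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (sidecar) {
    meta <- list(dimension_order = "page = (frame-1)*n_channels + channel",
                 height = d[1], width = d[2],
                 n_channels = d[3], n_frames = d[4],
                 channels = stack$channels,
                 frame_interval = stack$frame_interval,
                 event_frame = stack$event_frame,
                 cell_id = stack$cell_id,
                 scale = 65535)
    if (is.na(meta$event_frame)) meta$event_frame <- NULL
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a multi-page TIFF stack as a cell image
#'
#' Reads the JSON sidecar written by [write_stack()] when present;
#' otherwise an explicit `layout` (list with `n_frames`, `n_channels` and
#' optionally `channels`) must disambiguate the page order. Integer sample
#' data are widened to double without value change.
#'
#' @param path TIFF path.
#' @param roi Logical ROI matrix; when reading a sidecar-less file the ROI
#'   must be supplied separately (e.g. via [read_roi()]).
#' @param layout Optional explicit layout spec overriding/replacing the
#'   sidecar.
#' @return A [cell_image] (ROI defaults to all-`TRUE` if none given).
#' @export
read_stack <- function(path, roi = NULL, layout = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  meta <- NULL
  side <- paste0(path, ".json")
  if (is.null(layout) && file.exists(side))
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!is.null(layout)) meta <- layout
  if (is.null(meta)) {
    if (n_pages == 1L) {
      meta <- list(n_frames = 1L, n_channels = 1L)
    } else {
      stop("ambiguous stack layout for ", n_pages, " pages: supply a ",
           "`layout` list(n_frames=, n_channels=) or a JSON sidecar")
    }
  }
  Tn <- as.integer(meta$n_frames); Cn <- as.integer(meta$n_channels)
  if (Tn * Cn != n_pages)
    stop("layout (", Tn, " frames x ", Cn, " channels) does not match ",
         n_pages, " TIFF pages")
  scale <- if (!is.null(meta$scale)) meta$scale else 65535
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  arr <- array(0, dim = c(H, W, Cn, Tn))
  i <- 0L
  for (t in seq_len(Tn)) for (c in seq_len(Cn)) {
    i <- i + 1L
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # tolerate grayscale-as-RGB
    arr[, , c, t] <- round(pg * scale)
  }
  channels <- if (!is.null(meta$channels)) unlist(meta$channels)
              else paste0("ch", seq_len(Cn))
  if (is.null(roi)) roi <- matrix(TRUE, H, W)
  cell_image(arr, channels = channels, roi = roi,
             frame_interval = if (!is.null(meta$frame_interval))
               meta$frame_interval else 1,
             event_frame = if (is.null(meta$event_frame)) NA_integer_
               else suppressWarnings(as.integer(meta$event_frame)),
             cell_id = if (!is.null(meta$cell_id)) meta$cell_id else "cell1")
}

#' Write / read a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask Logical matrix (or `compartment_mask`).
#' @param path TIFF path.
#' @return `write_roi()`: `path`, invisibly. `read_roi()`: logical matrix.
#' @export
write_roi <- function(mask, path) {
  if (inherits(mask, "compartment_mask")) mask <- mask$mask
  tiff::writeTIFF((mask * 1), path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
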