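#' Whole-cell normalized intensity image
#'
#' Divides every ROI pixel by the mean intensity over the whole-cell ROI,
#' so the cell-average brightness maps to exactly 1 at every frame. Because
#' the normalization is recomputed per frame and per cell, expression-level
#' differences between cells and slow intensity drifts (photobleaching,
#' focus) cancel. Pixels outside the ROI are set to 0 and excluded from all
#' statistics.
#'
#' @param raw Numeric intensity matrix.
#' @param roi Logical whole-cell mask; must be non-empty with positive mean.
#' @return Numeric matrix; mean over the ROI is exactly 1.
#' @export
normalized_intensity_image <- function(raw, roi) {
  stopifnot_image(raw, "raw")
  check_roi(roi, dim(raw))
  m <- mean(raw[roi])
  if (m <= 0) stop("ROI mean intensity must be > 0")
  out <- raw / m
  out[!roi] <- 0
  out
}

#' Mean normalized intensity over a compartment mask
#'
#' Arithmetic mean of a whole-cell-normalized probe image over the pixels
#' of a compartment mask (intersected with the ROI when given). Values
#' above 1 indicate enrichment of the probe at the compartment relative to
#' the cell average; 1 means no enrichment.
#'
#' An empty mask yields `NA` with a warning rather than an error, so a
#' single bad frame does not abort a time-lapse analysis.
#'
#' @param norm Normalized intensity image ([normalized_intensity_image()]).
#' @param mask A `compartment_mask` or logical matrix.
#' @param roi Optional logical ROI to intersect with.
#' @return Numeric scalar, or `NA_real_` for an empty mask.
#' @export
compartment_mean <- function(norm, mask, roi = NULL) {
  if (inherits(mask, "compartment_mask")) mask <- mask$mask
  px <- if (is.null(roi)) mask else mask & roi
  if (!any(px)) {
    warning("empty compartment mask; reporting NA")
    return(NA_real_)
  }
  mean(norm[px])
}

#' Compartment intensity time-course for one cell
#'
#' For each frame: builds the marker compartment mask
#' ([mask_timelapse()]), normalizes each probe channel to its whole-cell
#' mean for that frame, and records the mean normalized probe intensity
#' over the masked compartments. This is the per-cell readout used to ask
#' whether a membrane-binding probe dissociates (trace falls towards 1) or
#' persists (trace flat or drifting) after a perturbation.
#'
#' @param stack A [cell_image].
#' @param probe_channels Labels/indices of the probe channels to quantify.
#' @param marker_channel Label/index of the compartment marker channel.
#' @param mask_params List of arguments for [compartment_mask()].
#' @return Data frame with columns `cell_id`, `frame_index`, `time`
#'   (minutes, `(frame_index - 1) * frame_interval`), `probe_channel`,
#'   `compartment`, `normalized_intensity`, `n_mask_pixels`. Frames whose
#'   mask is empty carry `NA` intensity.
#' @export
timecourse <- function(stack, probe_channels, marker_channel,
                       mask_params = list()) {
  stopifnot(inherits(stack, "cell_image"))
  n_frames <- dim(stack$data)[4L]
  probes <- vapply(probe_channels, function(ch)
    stack$channels[channel_index(stack, ch)], character(1))
  marker <- stack$channels[channel_index(stack, marker_channel)]
  masks <- do.call(mask_timelapse,
                   c(list(stack = stack, marker_channel = marker), mask_params))
  rows <- vector("list", n_frames * length(probes))
  r <- 0L
  for (t in seq_len(n_frames)) {
    mk <- masks[[t]]
    npx <- sum(mk$mask)
    for (p in probes) {
      norm <- normalized_intensity_image(get_frame(stack, p, t), stack$roi)
      val <- if (npx > 0) mean(norm[mk$mask]) else NA_real_
      r <- r + 1L
      rows[[r]] <- data.frame(
        cell_id = stack$cell_id, frame_index = t,
        time = (t - 1) * stack$frame_interval,
        probe_channel = p, compartment = marker,
        normalized_intensity = val, n_mask_pixels = npx)
    }
  }
  do.call(rbind, rows)
}

#' Cohort aggregate of per-cell time-courses
#'
#' Combines per-cell [timecourse()] tables and summarizes each
#' (frame, probe) point as mean +/- s.e.m. across cells, using only cells
#' with a non-missing value at that point. `sem = sd / sqrt(n_cells)`.
#'
#' @param tables A single time-course data frame or a list of them.
#' @return Data frame with `frame_index`, `time`, `probe_channel`,
#'   `compartment`, `mean`, `sem`, `n_cells`.
#' @export
aggregate_timecourse <- function(tables) {
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  tab <- tab[!is.na(tab$normalized_intensity), , drop = FALSE]
  key <- interaction(tab$frame_index, tab$probe_channel, drop = TRUE)
  agg <- lapply(split(tab, key), function(d) {
    v <- d$normalized_intensity
    data.frame(frame_index = d$frame_index[1], time = d$time[1],
               probe_channel = d$probe_channel[1],
               compartment = d$compartment[1],
               mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n_cells = length(unique(d$cell_id)))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$probe_channel, out$frame_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent change from pre-event baseline to final plateau
#'
#' Convenience summary of a time-course around a perturbation: baseline is
#' the mean normalized compartment intensity over all pre-event frames,
#' plateau is the mean over the last `plateau_frames` frames, and the change
#' is `100 * (plateau - baseline) / baseline` (negative = dissociation).
#'
#' @param table A [timecourse()] or [aggregate_timecourse()] table (uses
#'   column `normalized_intensity` if present, else `mean`).
#' @param event_frame Frame index of the perturbation.
#' @param plateau_frames Number of trailing frames averaged as the plateau.
#' @return Data frame per probe: `probe_channel`, `baseline`, `plateau`,
#'   `percent_change`.
#' @export
percent_change <- function(table, event_frame, plateau_frames = 3L) {
  val_col <- if ("normalized_intensity" %in% names(table))
    "normalized_intensity" else "mean"
  out <- lapply(split(table, table$probe_channel), function(d) {
    d <- d[order(d$frame_index), ]
    v <- d[[val_col]]
    pre <- v[d$frame_index < event_frame]
    post <- utils::tail(v[!is.na(v)], plateau_frames)
    baseline <- mean(pre, na.rm = TRUE)
    plateau <- mean(post, na.rm = TRUE)
    data.frame(probe_channel = d$probe_channel[1], baseline = baseline,
               plateau = plateau,
               percent_change = 100 * (plateau - baseline) / baseline)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Select the representative cell of a cohort
#'
#' Returns the cell whose score lies nearest the cohort median — the
#' standard unbiased choice when picking an example image to display. The
#' selected score always falls within the 25th-75th percentile range of the
#' cohort (asserted, with order-statistic percentiles: for those the
#' nearest-to-median value provably lies inside the interquartile range).
#' Ties go to the smallest `cell_id`.
#'
#' @param cells Data frame with columns `cell_id` and `score` (per-cell
#'   metric, e.g. nMDP score or compartment intensity).
#' @return The selected `cell_id`.
#' @export
select_representative <- function(cells) {
  if (!is.data.frame(cells) || !all(c("cell_id", "score") %in% names(cells)))
    stop("cells must be a data frame with columns cell_id and score")
  if (nrow(cells) == 0L) stop("empty cohort")
  med <- stats::median(cells$score)
  d <- abs(cells$score - med)
  cand <- cells[d == min(d), , drop = FALSE]
  cand <- cand[order(cand$cell_id), , drop = FALSE]
  sel <- cand[1L, ]
  q <- stats::quantile(cells$score, c(0.25, 0.75), names = FALSE, type = 2)
  if (sel$score < q[1] || sel$score > q[2])
    stop("internal error: selected score outside the interquartile range")
  sel$cell_id
}
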