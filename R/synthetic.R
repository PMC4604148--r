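#' Synthetic punctate-cell scenes with known ground truth
#'
#' `make_scene()` builds a complete description of a simulated cell: an
#' irregular whole-cell ROI, diffraction-limited punctate compartments
#' (isotropic 2-D Gaussian spots) shared between channels according to a
#' programmed overlap fraction, a diffuse cytosolic background, a kinetic
#' program describing how each channel's spot enrichment evolves over
#' frames, and a confocal-style noise model (Poisson shot noise, detector
#' gain and offset, additive Gaussian read noise). The scene is a pure
#' description; [render_frame()] and [render_timelapse()] turn it into
#' pixels. Everything is deterministic given `seed`.
#'
#' Overlap semantics: with `N = n_spots` and overlap fraction `f`,
#' `round(f * N)` spots carry nonzero amplitude in both of the first two
#' channels; the remainder carry amplitude in exactly one of them
#' (alternating). Channels beyond the second (e.g. a compartment marker
#' imaged alongside two probes) carry amplitude at every spot.
#'
#' @param shape Integer `c(H, W)` image size in pixels.
#' @param channels Character vector of 1-4 unique channel labels.
#' @param n_spots Number of punctate compartments (>= 0).
#' @param overlap_fraction Fraction in `[0, 1]` of spots shared between the
#'   first two channels.
#' @param amplitude Mean integrated spot intensity in photons; scalar or one
#'   value per channel. Individual spots jitter uniformly within +/- 50%.
#' @param sigma Gaussian spot width (s.d.) in pixels.
#' @param background Diffuse photon level per pixel inside the cell; scalar
#'   or per channel.
#' @param kinetics Per-channel enrichment multiplier per frame: a numeric
#'   `n_frames x n_channels` matrix (see [kinetic_constant()],
#'   [kinetic_decay()], [kinetic_drift()]), or `NULL` for a single constant
#'   frame.
#' @param noise List with elements `poisson` (logical; apply shot noise) and
#'   `read_sd` (Gaussian read noise s.d. in detector counts).
#' @param gain Detector counts per photon. `NULL` picks a gain placing the
#'   brightest expected pixel near a quarter of the 16-bit range, leaving
#'   headroom against clipping.
#' @param offset Baseline detector counts added to every pixel.
#' @param min_separation Minimum center-to-center spot distance in pixels
#'   (0 = spots may overlap freely, the realistic default).
#' @param edge_clearance Minimum distance in pixels from a spot center to
#'   the ROI boundary (default 10). Cells are optically thin at their
#'   margins and organelles sit in the cytoplasmic interior, so puncta
#'   right at the cell edge are not realistic; set 0 to allow them.
#' @param conserve_probe Logical, scalar or per channel. When `TRUE`, spot
#'   flux lost as a channel's kinetic multiplier falls below its first-frame
#'   value is redistributed uniformly into that channel's cytosolic
#'   background (a dissociating probe relocates to the cytosol rather than
#'   vanishing). Off by default, so the expectation image is exactly
#'   `background + multiplier * spots`.
#' @param frame_interval Minutes between frames (metadata only).
#' @param event_frame Frame index of the perturbation, or `NA`.
#' @param seed Integer seed; required.
#' @return An object of class `synthetic_scene`.
#' @seealso [render_frame()], [render_timelapse()], [scene_expectation()],
#'   [amplitude_for_snr()]
#' @examples
#' sc <- make_scene(shape = c(64, 64), n_spots = 20,
#'                  overlap_fraction = 0.5, seed = 1)
#' img <- render_frame(sc, 1)
#' @export
make_scene <- function(shape = c(128L, 128L),
                       channels = c("probe", "marker"),
                       n_spots = 50L,
                       overlap_fraction = 1.0,
                       amplitude = 2000,
                       sigma = 1.5,
                       background = 100,
                       kinetics = NULL,
                       noise = list(poisson = TRUE, read_sd = 2),
                       gain = NULL,
                       offset = 100,
                       min_separation = 0,
                       edge_clearance = 10,
                       conserve_probe = FALSE,
                       frame_interval = 1,
                       event_frame = NA_integer_,
                       seed) {
  if (missing(seed)) stop("make_scene() requires an explicit seed")
  n_channels <- length(channels)
  if (n_channels < 1L || n_channels > 4L || anyDuplicated(channels))
    stop("channels must be 1-4 unique labels")
  if (!is.numeric(overlap_fraction) || length(overlap_fraction) != 1L ||
      is.na(overlap_fraction) || overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]")
  if (n_spots < 0) stop("n_spots must be >= 0")
  amplitude <- rep_len(amplitude, n_channels)
  background <- rep_len(background, n_channels)
  names(background) <- channels
  if (!all(is.finite(amplitude)) || any(amplitude < 0))
    stop("amplitude must be finite and nonnegative")
  if (!all(is.finite(background)) || any(background < 0))
    stop("background must be finite and nonnegative")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")

  if (is.null(kinetics)) kinetics <- kinetic_constant(1L, n_channels = n_channels)
  kinetics <- as.matrix(kinetics)
  if (ncol(kinetics) == 1L && n_channels > 1L)
    kinetics <- kinetics[, rep(1L, n_channels), drop = FALSE]
  if (ncol(kinetics) != n_channels)
    stop("kinetics must have one column per channel")
  if (!all(is.finite(kinetics)) || any(kinetics < 0))
    stop("kinetic multipliers must be finite and nonnegative")
  colnames(kinetics) <- channels
  n_frames <- nrow(kinetics)

  noise <- utils::modifyList(list(poisson = TRUE, read_sd = 2), as.list(noise))
  if (noise$read_sd < 0) stop("read_sd must be >= 0")
  conserve_probe <- rep_len(as.logical(conserve_probe), n_channels)

  sc <- with_seed(derive_seed(seed, 1L), {
    cell_mask <- random_cell_mask(shape)
    interior <- erode_mask(cell_mask, edge_clearance)
    if (!any(interior)) interior <- cell_mask
    spots <- place_spots(interior, n_spots, min_separation, sigma)
    amp <- assign_amplitudes(n_spots, n_channels, overlap_fraction, amplitude)
    colnames(amp) <- paste0("amp_", channels)
    list(cell_mask = cell_mask, spots = cbind(spots, as.data.frame(amp)))
  })

  scene <- structure(
    list(shape = as.integer(shape), channels = as.character(channels),
         n_frames = n_frames, cell_mask = sc$cell_mask, spots = sc$spots,
         overlap_fraction = overlap_fraction, background = background,
         sigma = sigma, kinetics = kinetics, noise = noise,
         gain = gain, offset = offset, conserve_probe = conserve_probe,
         frame_interval = frame_interval,
         event_frame = as.integer(event_frame), seed = as.integer(seed)),
    class = "synthetic_scene")

  if (is.null(gain)) {
    peak <- 0
    for (t in seq_len(n_frames))
      peak <- max(peak, max(scene_expectation(scene, t)))
    scene$gain <- if (peak > 0) (65535 / 4 - offset) / peak else 1
  }
  scene
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d channel(s), %d frame(s), %d spot(s)\n",
              x$shape[1], x$shape[2], length(x$channels), x$n_frames,
              nrow(x$spots)))
  cat(sprintf("  overlap %.2f | background %s photons | gain %.3g | seed %d\n",
              x$overlap_fraction, paste(signif(x$background, 3), collapse = "/"),
              x$gain, x$seed))
  invisible(x)
}

# Irregular star-convex blob occupying roughly 20-60% of the frame.
# Radius is a low-order Fourier perturbation of a disc; uses the current RNG.
random_cell_mask <- function(shape) {
  H <- shape[1]; W <- shape[2]
  cy <- H / 2 + stats::runif(1, -0.05, 0.05) * H
  cx <- W / 2 + stats::runif(1, -0.05, 0.05) * W
  r0 <- 0.36 * min(H, W)
  kmax <- 4L
  a <- stats::runif(kmax, 0, 0.12)
  phi <- stats::runif(kmax, 0, 2 * pi)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  theta <- atan2(dy, dx)
  r <- r0
  for (k in seq_len(kmax)) r <- r + r0 * a[k] * cos(k * theta + phi[k])
  r <- pmin(r, min(H, W) / 2 - 2)
  sqrt(dy^2 + dx^2) <= r
}

# Sample spot centers uniformly over ROI pixels, with sub-pixel jitter that
# keeps each center inside its (in-mask) pixel. Greedy rejection enforces a
# minimum separation when requested.
place_spots <- function(region, n_spots, min_separation, sigma) {
  if (n_spots == 0L)
    return(data.frame(spot = integer(), row = numeric(), col = numeric(),
                      sigma = numeric()))
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cell mask is empty; cannot place spots")
  rows <- numeric(n_spots); cols <- numeric(n_spots)
  placed <- 0L; tries <- 0L
  while (placed < n_spots) {
    tries <- tries + 1L
    if (tries > 200L * n_spots + 10000L)
      stop("could not place ", n_spots, " spots at min_separation = ",
           min_separation)
    i <- idx[sample.int(nrow(idx), 1L), ]
    r <- i[1] + stats::runif(1, -0.49, 0.49)
    c <- i[2] + stats::runif(1, -0.49, 0.49)
    if (min_separation > 0 && placed > 0L) {
      d2 <- (rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2
      if (min(d2) < min_separation^2) next
    }
    placed <- placed + 1L
    rows[placed] <- r; cols[placed] <- c
  }
  data.frame(spot = seq_len(n_spots), row = rows, col = cols, sigma = sigma)
}

# Per-spot, per-channel integrated amplitudes honouring the pairwise overlap
# contract between channels 1 and 2; channels 3+ label every spot.
assign_amplitudes <- function(n_spots, n_channels, overlap_fraction, amplitude) {
  amp <- matrix(0, n_spots, n_channels)
  if (n_spots == 0L) return(amp)
  jitter <- matrix(stats::runif(n_spots * n_channels, 0.5, 1.5), n_spots)
  base <- sweep(jitter, 2L, amplitude, `*`)
  if (n_channels == 1L) return(base)
  n_both <- round(overlap_fraction * n_spots)
  ord <- sample.int(n_spots)
  both <- ord[seq_len(n_both)]
  singles <- if (n_both < n_spots) ord[(n_both + 1L):n_spots] else integer()
  in1 <- logical(n_spots); in2 <- logical(n_spots)
  in1[both] <- TRUE; in2[both] <- TRUE
  if (length(singles)) {
    odd <- singles[seq_along(singles) %% 2L == 1L]
    even <- setdiff(singles, odd)
    in1[odd] <- TRUE; in2[even] <- TRUE
  }
  amp[, 1] <- base[, 1] * in1
  amp[, 2] <- base[, 2] * in2
  if (n_channels > 2L) amp[, 3:n_channels] <- base[, 3:n_channels]
  amp
}

#' Kinetic programs: per-frame enrichment multipliers
#'
#' A kinetic program is an `n_frames x n_channels` matrix of nonnegative
#' multipliers applied to every spot's amplitude in that channel at that
#' frame. These helpers build the common single-channel columns; combine
#' columns for multi-channel scenes with `cbind()`.
#'
#' `kinetic_constant()` holds the multiplier fixed. `kinetic_decay()` holds
#' `from` until `event_frame`, then relaxes exponentially towards `to` with
#' time constant `tau` frames (a biosensor dissociating after drug
#' addition). `kinetic_drift()` holds `value` until `event_frame`, then
#' ramps linearly to `value * (1 + drift)` by the final frame (a probe that
#' persists, with a slight secular trend).
#'
#' @param n_frames Number of frames.
#' @param value,from,to Multiplier levels (unitless enrichment factors).
#' @param n_channels Replicate the column this many times.
#' @param event_frame Frame index at which the perturbation takes effect.
#' @param tau Exponential time constant, in frames.
#' @param drift Fractional change by the last frame (e.g. `0.05` = +5%).
#' @return Numeric matrix `n_frames x n_channels`.
#' @export
kinetic_constant <- function(n_frames, value = 1, n_channels = 1L) {
  matrix(value, nrow = n_frames, ncol = n_channels)
}

#' @rdname kinetic_constant
#' @export
kinetic_decay <- function(n_frames, event_frame, from = 3, to = 1, tau = 2.5) {
  t <- seq_len(n_frames)
  m <- ifelse(t < event_frame, from,
              to + (from - to) * exp(-(t - event_frame) / tau))
  matrix(m, ncol = 1L)
}

#' @rdname kinetic_constant
#' @export
kinetic_drift <- function(n_frames, event_frame, value = 3, drift = 0.05) {
  t <- seq_len(n_frames)
  post <- pmax(t - event_frame, 0) / max(n_frames - event_frame, 1L)
  matrix(value * (1 + drift * post), ncol = 1L)
}

#' Noiseless expectation image of a scene at one frame
#'
#' Returns the expected photon image per channel before any noise, gain or
#' offset: `background * cell_mask + sum of Gaussian spots scaled by the
#' channel's kinetic multiplier at this frame` (plus the conservation
#' correction to the background when `conserve_probe` is set for a channel).
#'
#' @param scene A [make_scene()] scene.
#' @param frame_index Frame (1-based) within the kinetic program.
#' @return Numeric `H x W x n_channels` array of expected photons.
#' @export
scene_expectation <- function(scene, frame_index) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (frame_index < 1L || frame_index > scene$n_frames)
    stop("frame_index out of range (1..", scene$n_frames, ")")
  H <- scene$shape[1]; W <- scene$shape[2]
  C <- length(scene$channels)
  out <- array(0, dim = c(H, W, C))
  n_roi <- sum(scene$cell_mask)
  for (ci in seq_len(C)) {
    mult <- scene$kinetics[frame_index, ci]
    amps <- scene$spots[[paste0("amp_", scene$channels[ci])]]
    bg <- scene$background[ci]
    if (scene$conserve_probe[ci] && length(amps) && n_roi > 0) {
      released <- (scene$kinetics[1L, ci] - mult) * sum(amps) / n_roi
      bg <- max(bg + released, 0)
    }
    img <- bg * scene$cell_mask
    if (length(amps))
      img <- add_gaussian_spots(img, scene$spots$row, scene$spots$col,
                                amps * mult, scene$spots$sigma)
    out[, , ci] <- img
  }
  out
}

# Accumulate isotropic 2-D Gaussians (integrated amplitude = amp photons)
# into img, evaluated on a +/- 5 sigma pixel window around each center.
add_gaussian_spots <- function(img, rows, cols, amps, sigmas) {
  H <- nrow(img); W <- ncol(img)
  for (i in seq_along(rows)) {
    if (amps[i] == 0) next
    s <- sigmas[i]
    w <- ceiling(5 * s)
    r0 <- max(1L, floor(rows[i] - w)); r1 <- min(H, ceiling(rows[i] + w))
    c0 <- max(1L, floor(cols[i] - w)); c1 <- min(W, ceiling(cols[i] + w))
    if (r0 > r1 || c0 > c1) next
    gy <- exp(-((r0:r1) - rows[i])^2 / (2 * s^2))
    gx <- exp(-((c0:c1) - cols[i])^2 / (2 * s^2))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
      (amps[i] / (2 * pi * s^2)) * outer(gy, gx)
  }
  img
}

#' Render one frame of a scene as detector counts
#'
#' Applies the forward imaging model to the noiseless expectation: Poisson
#' shot noise on photons (if enabled), multiplication by the detector gain,
#' addition of the offset and Gaussian read noise, then quantization to
#' integer counts clipped to the 16-bit range `[0, 65535]`. Deterministic
#' for a fixed scene: the RNG substream is derived from the scene seed and
#' the frame index.
#'
#' @param scene A [make_scene()] scene.
#' @param frame_index Frame (1-based).
#' @param noise Apply the scene's noise model (`TRUE`, default) or render
#'   the quantized noiseless image (`FALSE`).
#' @return Numeric `H x W x n_channels` array of integer-valued counts.
#' @export
render_frame <- function(scene, frame_index, noise = TRUE) {
  expect <- scene_expectation(scene, frame_index)
  C <- dim(expect)[3]
  out <- with_seed(derive_seed(scene$seed, 1000L + frame_index), {
    res <- array(0, dim = dim(expect))
    for (ci in seq_len(C)) {
      e <- expect[, , ci]
      photons <- if (noise && isTRUE(scene$noise$poisson))
        matrix(stats::rpois(length(e), e), nrow(e)) else e
      counts <- scene$gain * photons + scene$offset
      if (noise && scene$noise$read_sd > 0)
        counts <- counts + stats::rnorm(length(counts), sd = scene$noise$read_sd)
      res[, , ci] <- counts
    }
    res
  })
  out <- round(out)
  out[out < 0] <- 0
  out[out > 65535] <- 65535
  out
}

#' Render a full time-lapse and its ground-truth tables
#'
#' Stacks [render_frame()] over every frame of the kinetic program and wraps
#' the result as a [cell_image]. The returned object additionally carries a
#' `$truth` element: the spot table (centers, per-channel integrated
#' amplitudes) and the kinetic multiplier matrix, sufficient to recompute
#' the programmed overlap fraction and per-frame enrichment exactly.
#'
#' @inheritParams render_frame
#' @param cell_id Identifier stored in the result.
#' @return A [cell_image] with ground truth in `$truth`.
#' @export
render_timelapse <- function(scene, noise = TRUE, cell_id = "cell1") {
  H <- scene$shape[1]; W <- scene$shape[2]
  C <- length(scene$channels)
  arr <- array(0, dim = c(H, W, C, scene$n_frames))
  for (t in seq_len(scene$n_frames))
    arr[, , , t] <- render_frame(scene, t, noise = noise)
  img <- cell_image(arr, channels = scene$channels, roi = scene$cell_mask,
                    frame_interval = scene$frame_interval,
                    event_frame = scene$event_frame, cell_id = cell_id)
  img$truth <- list(spots = scene$spots, kinetics = scene$kinetics,
                    overlap_fraction = true_overlap(scene))
  img
}

#' Realized spot overlap fraction between two channels
#'
#' Fraction of ground-truth spots carrying nonzero amplitude in both named
#' channels; round-trips the configured `overlap_fraction` as
#' `round(f * n_spots) / n_spots`.
#'
#' @param scene A scene.
#' @param channels Two channel labels or indices (default: first two).
#' @return Numeric scalar in `[0, 1]` (`NaN` for a spotless scene).
#' @export
true_overlap <- function(scene, channels = c(1L, 2L)) {
  labs <- scene$channels
  pick <- vapply(channels, function(ch)
    if (is.numeric(ch)) labs[ch] else ch, character(1))
  a <- scene$spots[[paste0("amp_", pick[1])]]
  b <- scene$spots[[paste0("amp_", pick[2])]]
  mean(a > 0 & b > 0)
}

#' Spot amplitude achieving a target peak signal-to-noise ratio
#'
#' Converts a peak SNR into an integrated Gaussian amplitude. SNR here is
#' the spot's peak expected photon signal above background divided by the
#' background noise s.d. (`sqrt(background + (read_sd/gain)^2)`), the usual
#' convention in spot-detection benchmarks.
#'
#' @param snr Target peak SNR.
#' @param sigma Spot width in pixels.
#' @param background Background photons per pixel.
#' @param read_sd Read noise s.d. in counts.
#' @param gain Counts per photon.
#' @return Integrated amplitude in photons.
#' @export
amplitude_for_snr <- function(snr, sigma = 1.5, background = 100,
                              read_sd = 2, gain = 1) {
  noise_sd <- sqrt(background + (read_sd / gain)^2)
  snr * noise_sd * 2 * pi * sigma^2
}
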