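#' Mean-deviation normalization of a channel within a whole-cell ROI
#'
#' Rescales pixel intensities inside the ROI so that the ROI mean maps to 0,
#' the brightest ROI pixel to 1 and the dimmest to -1. The map is two-sided:
#' with ROI mean `m`, maximum `M` and minimum `L`, a pixel of intensity `I`
#' becomes `(I - m) / (M - m)` when `I >= m` and `(I - m) / (m - L)` when
#' `I < m`. It is order-preserving and invariant under positive affine
#' rescaling of the raw intensities, so detector gain and offset cancel.
#' Pixels outside the ROI are set to 0 and excluded from every statistic.
#'
#' A channel that is constant on the ROI carries no contrast; it normalizes
#' to all zeros (the "no information" value) rather than erroring.
#'
#' The classical one-sided variant, which divides both sides by `M - m`, is
#' available via `method = "one.sided"` for comparison; the two-sided form
#' is the default and the one used throughout the package.
#'
#' @param raw Numeric matrix of raw intensities.
#' @param roi Logical matrix, the whole-cell ROI; must be non-empty.
#' @param method `"two.sided"` (default) or `"one.sided"`.
#' @return An object of class `normalized_image`: list with `values` (float
#'   matrix in `[-1, 1]` on the ROI, 0 outside), `roi`, `source_stats`
#'   (named mean/min/max of the raw ROI intensities) and `method`.
#' @export
normalize_channel <- function(raw, roi, method = c("two.sided", "one.sided")) {
  method <- match.arg(method)
  stopifnot_image(raw, "raw")
  check_roi(roi, dim(raw))
  v <- raw[roi]
  m <- mean(v); M <- max(v); L <- min(v)
  values <- matrix(0, nrow(raw), ncol(raw))
  if (M > L) {
    if (method == "two.sided") {
      hi <- roi & raw >= m
      lo <- roi & raw < m
      if (M > m) values[hi] <- (raw[hi] - m) / (M - m)
      if (m > L) values[lo] <- (raw[lo] - m) / (m - L)
    } else {
      values[roi] <- (raw[roi] - m) / (M - m)
    }
  }
  structure(list(values = values, roi = roi,
                 source_stats = c(mean = m, min = L, max = M),
                 method = method),
            class = "normalized_image")
}

#' @export
print.normalized_image <- function(x, ...) {
  cat(sprintf("<normalized_image> %d x %d px, %d ROI px, %s; raw mean %.4g [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), sum(x$roi), x$method,
              x$source_stats["mean"], x$source_stats["min"],
              x$source_stats["max"]))
  invisible(x)
}

#' Normalized mean deviation product (nMDP) image and score
#'
#' Multiplies two mean-deviation-normalized channels pixelwise over their
#' shared ROI. Pixels whose intensities co-vary (both above or both below
#' their channel means) yield positive products; pixels that anti-vary
#' yield negative products. The scalar nMDP score is the arithmetic mean of
#' the product image over ROI pixels — a per-cell colocalization index that
#' is symmetric in its arguments, bounded in `[-1, 1]`, and comparable
#' across cells of different sizes. The score is computed over all ROI
#' pixels with their signs; the display convention that blacks out
#' mutually-dim pixels (see [render_nmdp_display()]) never affects it.
#'
#' @param a,b `normalized_image` objects sharing the same ROI (see
#'   [normalize_channel()]).
#' @param channel_pair Optional character vector of two labels for reporting.
#' @return An object of class `nmdp_result`: `product_image` (float matrix,
#'   0 outside the ROI), `score`, `roi`, `n_roi_pixels`, `channel_pair`.
#' @export
nmdp_image <- function(a, b, channel_pair = c("A", "B")) {
  stopifnot(inherits(a, "normalized_image"), inherits(b, "normalized_image"))
  if (!identical(dim(a$values), dim(b$values)) || !identical(a$roi, b$roi))
    stop("the two normalized images must share the same ROI and shape")
  prod <- a$values * b$values
  prod[!a$roi] <- 0
  structure(list(product_image = prod,
                 score = mean(prod[a$roi]),
                 roi = a$roi,
                 n_roi_pixels = sum(a$roi),
                 channel_pair = channel_pair),
            class = "nmdp_result")
}

#' @export
print.nmdp_result <- function(x, ...) {
  cat(sprintf("<nmdp_result> %s vs %s: score %.6g over %d ROI px\n",
              x$channel_pair[1], x$channel_pair[2], x$score, x$n_roi_pixels))
  invisible(x)
}

#' nMDP score between two raw channels
#'
#' Convenience wrapper: normalizes both channels within the ROI and returns
#' the scalar nMDP score.
#'
#' @inheritParams normalize_channel
#' @param raw_a,raw_b Raw intensity matrices.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
nmdp_score <- function(raw_a, raw_b, roi, method = "two.sided") {
  nmdp_image(normalize_channel(raw_a, roi, method),
             normalize_channel(raw_b, roi, method))$score
}

#' Render the nMDP display image
#'
#' Produces the conventional RGB rendering of an nMDP product image:
#' positive products (correlating bright pixels) ramp linearly from black to
#' gold (RGB 255, 215, 0 at product +1), negative products (anti-correlating
#' pixels) ramp from black to green (0, 255, 0 at product -1), and pixels
#' that are dim in both channels (both normalized values below 0, hence a
#' positive product) are blacked out for clarity. The blanking is purely
#' cosmetic: the scalar score in `result` was computed before it and is
#' unchanged by rendering.
#'
#' @param result An [nmdp_image()] result.
#' @param a,b The `normalized_image` inputs `result` was computed from
#'   (needed to identify mutually-dim pixels).
#' @return Numeric `H x W x 3` RGB array in `[0, 1]`.
#' @export
render_nmdp_display <- function(result, a, b) {
  stopifnot(inherits(result, "nmdp_result"))
  if (!identical(dim(a$values), dim(result$product_image)) ||
      !identical(dim(b$values), dim(result$product_image)))
    stop("normalized images do not match the nMDP result's shape")
  p <- result$product_image
  H <- nrow(p); W <- ncol(p)
  rgb <- array(0, dim = c(H, W, 3))
  gold <- c(255, 215, 0) / 255
  pos <- result$roi & p > 0 & !(a$values < 0 & b$values < 0)
  neg <- result$roi & p < 0
  for (k in 1:3) {
    ch <- matrix(0, H, W)
    ch[pos] <- p[pos] * gold[k]
    if (k == 2) ch[neg] <- -p[neg]
    rgb[, , k] <- ch
  }
  rgb
}

#' Write an RGB display image to a PNG file
#'
#' @param rgb `H x W x 3` array in `[0, 1]` (e.g. from
#'   [render_nmdp_display()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_display_png <- function(rgb, path) {
  png::writePNG(rgb, target = path)
  invisible(path)
}
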