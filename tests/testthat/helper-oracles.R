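# Shared oracles and fixture builders. Everything is generated in code at
# test time; no binary fixtures.

# Brute-force oracle for one a-trous smoothing pass: dense 2-D convolution
# with the explicitly spaced (dilated) B3-spline kernel, written
# independently of the package's separable implementation.
dense_atrous_smooth <- function(img, step, boundary = "mirror") {
  k1 <- c(1, 4, 6, 4, 1) / 16
  n_r <- nrow(img); n_c <- ncol(img)
  wrap <- function(idx, n) {
    if (boundary == "periodic") return(((idx - 1L) %% n) + 1L)
    period <- 2L * n - 2L
    x <- (idx - 1L) %% period
    ifelse(x >= n, period - x, x) + 1L
  }
  out <- matrix(0, n_r, n_c)
  for (a in -2:2) for (b in -2:2) {
    w <- k1[a + 3L] * k1[b + 3L]
    ridx <- wrap(seq_len(n_r) + a * step, n_r)
    cidx <- wrap(seq_len(n_c) + b * step, n_c)
    out <- out + w * img[ridx, cidx]
  }
  out
}

dense_atrous_decompose <- function(img, n_scales, boundary = "mirror") {
  planes <- vector("list", n_scales)
  a_prev <- img
  for (j in seq_len(n_scales)) {
    a_cur <- dense_atrous_smooth(a_prev, 2L^(j - 1L), boundary)
    planes[[j]] <- a_prev - a_cur
    a_prev <- a_cur
  }
  list(planes = planes, residual = a_prev)
}

# Object-level detection metrics against ground-truth spot centers:
# a spot is recalled if its (rounded) center pixel lies inside a mask
# object; an object is a true positive if it contains >= 1 center.
detection_metrics <- function(mask, spots) {
  if (inherits(mask, "compartment_mask")) mask <- mask$mask
  lab <- punctacoloc::mask_objects(mask)
  labm <- matrix(0L, nrow(mask), ncol(mask))
  if (nrow(lab) > 0) {
    full <- EBImage::bwlabel(EBImage::Image(mask * 1))
    labm <- matrix(as.integer(EBImage::imageData(full)), nrow(mask))
  }
  ctr <- cbind(round(spots$row), round(spots$col))
  hits <- labm[ctr] > 0L
  recall <- mean(hits)
  n_obj <- max(labm)
  precision <- if (n_obj > 0) length(unique(labm[ctr][hits])) / n_obj else NA_real_
  f1 <- if (!is.na(precision) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(recall = recall, precision = precision, f1 = f1, n_objects = n_obj)
}

# Quick non-constant test image with a pixel exactly at the ROI mean.
fixture_with_mean_pixel <- function() {
  raw <- matrix(c(2, 5, 9, 4, 11, 5, 3, 8, 7), 3, 3)
  roi <- matrix(TRUE, 3, 3)
  raw[2, 2] <- mean(raw[-5])  # overwrite center pixel with the mean of the rest
  list(raw = raw, roi = roi)
}
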