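test_that("normalization maps mean to 0, extremes to +/-1, in order", {
  roi <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  raw <- matrix(c(2, 4, 9, 0), 2, 2)
  n <- normalize_channel(raw, roi)
  expect_equal(n$values[roi], c(-1, -1 / 3, 1))
  expect_equal(n$values[!roi], 0)  # outside ROI carries no value
  expect_equal(unname(n$source_stats), c(5, 2, 9))

  # a pixel exactly at the ROI mean maps to 0; extremes to +/-1
  fx <- fixture_with_mean_pixel()
  nf <- normalize_channel(fx$raw, fx$roi)
  expect_equal(nf$values[2, 2], 0)
  expect_equal(max(nf$values[fx$roi]), 1)
  expect_equal(min(nf$values[fx$roi]), -1)

  # order-preserving on random images
  set.seed(21)
  for (i in 1:5) {
    raw <- matrix(stats::rgamma(400, 2, 0.01), 20, 20)
    roi <- matrix(stats::runif(400) < 0.8, 20, 20)
    v <- normalize_channel(raw, roi)$values[roi]
    expect_equal(order(v), order(raw[roi]))
    expect_equal(max(v), 1)
    expect_equal(min(v), -1)
    expect_lt(abs(v[which.min(abs(raw[roi] - mean(raw[roi])))]), 0.05)
  }
})

test_that("degenerate and invalid normalization inputs are handled", {
  roi <- matrix(TRUE, 2, 2)
  expect_equal(normalize_channel(matrix(7, 2, 2), roi)$values,
               matrix(0, 2, 2))
  expect_error(normalize_channel(matrix(1:4, 2, 2), matrix(FALSE, 2, 2)),
               "empty")
  expect_error(normalize_channel(matrix(c(1, NA, 3, 4), 2, 2), roi),
               "finite")
  expect_error(normalize_channel(matrix(1:4, 2, 2), matrix(TRUE, 4, 1)),
               "dimensions")
})

test_that("one-sided variant divides both sides by the upper range", {
  roi <- matrix(TRUE, 1, 3)
  raw <- matrix(c(2, 4, 9), 1, 3)
  n <- normalize_channel(raw, roi, method = "one.sided")
  expect_equal(n$values[roi], (c(2, 4, 9) - 5) / 4)
})

test_that("normalization is invariant under positive affine rescaling", {
  set.seed(33)
  raw <- matrix(stats::rpois(900, 40), 30, 30)
  roi <- matrix(stats::runif(900) < 0.7, 30, 30)
  n0 <- normalize_channel(raw, roi)
  for (tf in list(c(3.7, 0), c(1, 120), c(0.25, -5))) {
    nt <- normalize_channel(tf[1] * raw + tf[2], roi)
    expect_equal(nt$values, n0$values, tolerance = 1e-9)
  }
})

test_that("nMDP product image and score follow the hand-worked example", {
  roi <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  raw <- matrix(c(2, 4, 9, 0), 2, 2)
  a <- normalize_channel(raw, roi)
  res <- nmdp_image(a, a)
  expect_equal(sort(res$product_image[roi]), sort(c(1, 1 / 9, 1)))
  expect_equal(res$score, 19 / 27)
  expect_true(all(res$product_image[roi] >= 0))  # self-product nonnegative
  expect_equal(res$n_roi_pixels, 3L)
})

test_that("nMDP score is symmetric, bounded, and positive against itself", {
  set.seed(77)
  for (i in 1:5) {
    raw_a <- matrix(stats::rpois(1024, 30), 32, 32)
    raw_b <- matrix(stats::rpois(1024, 30), 32, 32)
    roi <- matrix(stats::runif(1024) < 0.75, 32, 32)
    a <- normalize_channel(raw_a, roi)
    b <- normalize_channel(raw_b, roi)
    ab <- nmdp_image(a, b)
    ba <- nmdp_image(b, a)
    expect_identical(ab$score, ba$score)
    expect_true(all(abs(ab$product_image) <= 1))
    expect_true(abs(ab$score) <= 1)
    expect_gt(nmdp_image(a, a)$score, 0)
  }
})

test_that("mismatched ROIs are refused", {
  roi1 <- matrix(TRUE, 4, 4); roi2 <- roi1; roi2[1, 1] <- FALSE
  img <- matrix(1:16, 4, 4)
  a <- normalize_channel(img, roi1)
  b <- normalize_channel(img, roi2)
  expect_error(nmdp_image(a, b), "ROI")
})

test_that("higher programmed overlap yields higher scores, every seed", {
  for (s in 1:10) {
    imgs <- lapply(c(0, 1), function(f) {
      sc <- scenario_coloc(seed = 500 + s, overlap_fraction = f)
      list(img = render_frame(sc, 1), roi = sc$cell_mask)
    })
    s0 <- nmdp_score(imgs[[1]]$img[, , 1], imgs[[1]]$img[, , 2], imgs[[1]]$roi)
    s1 <- nmdp_score(imgs[[2]]$img[, , 1], imgs[[2]]$img[, , 2], imgs[[2]]$roi)
    expect_gt(s1, s0)
  }
})

test_that("display blanks mutually-dim pixels without touching the score", {
  roi <- matrix(TRUE, 1, 4)
  a <- normalize_channel(matrix(c(1, 2, 6, 11), 1, 4), roi)   # mean 5
  b <- normalize_channel(matrix(c(2, 3, 12, 5), 1, 4), roi)   # mean 5.5
  res <- nmdp_image(a, b)
  score_before <- res$score
  rgb <- render_nmdp_display(res, a, b)
  # pixel 1: dim in both (a,b < 0), positive product -> rendered black
  expect_true(res$product_image[1, 1] > 0)
  expect_equal(rgb[1, 1, ], c(0, 0, 0))
  # pixel 3: bright in both -> gold family (red & green, no blue, red>green)
  expect_gt(rgb[1, 3, 1], 0)
  expect_gt(rgb[1, 3, 2], 0)
  expect_equal(rgb[1, 3, 3], 0)
  expect_gt(rgb[1, 3, 1], rgb[1, 3, 2])
  # pixel 4: bright in a, dim in b -> green family
  expect_lt(res$product_image[1, 4], 0)
  expect_equal(rgb[1, 4, 1], 0)
  expect_gt(rgb[1, 4, 2], 0)
  # the score is untouched by rendering
  expect_identical(res$score, score_before)
  # mutually-dim pixels still contribute their positive product to the score
  expect_equal(res$score, mean(res$product_image[roi]))
})
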