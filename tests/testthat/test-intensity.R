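test_that("whole-cell normalization divides by the ROI mean", {
  roi <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  raw <- matrix(c(2, 4, 9, 50), 2, 2)
  norm <- normalized_intensity_image(raw, roi)
  expect_equal(norm[roi], c(0.4, 0.8, 1.8))
  expect_equal(norm[!roi], 0)
  expect_equal(normalized_intensity_image(matrix(7, 3, 3),
                                          matrix(TRUE, 3, 3)),
               matrix(1, 3, 3))
  # ROI-mean identity holds for arbitrary input
  set.seed(51)
  for (i in 1:3) {
    raw <- matrix(stats::rgamma(400, 2, 0.01), 20, 20)
    roi <- matrix(stats::runif(400) < 0.7, 20, 20)
    expect_equal(mean(normalized_intensity_image(raw, roi)[roi]), 1)
  }
  expect_error(normalized_intensity_image(matrix(0, 2, 2), matrix(TRUE, 2, 2)),
               "mean")
})

test_that("compartment means read enrichment off the normalized image", {
  norm <- matrix(1, 4, 4)
  expect_equal(compartment_mean(norm, matrix(TRUE, 4, 4)), 1)
  # a mask built from the probe's own bright spots selects > 1 values
  sc <- make_scene(shape = c(96, 96), channels = "probe", n_spots = 15,
                   amplitude = amplitude_for_snr(10), background = 100,
                   min_separation = 6, seed = 61)
  img <- render_frame(sc, 1)[, , 1]
  cm <- compartment_mask(img, roi = sc$cell_mask)
  norm <- normalized_intensity_image(img, sc$cell_mask)
  expect_gt(compartment_mean(norm, cm, roi = sc$cell_mask), 1)
  # empty mask: NA plus a warning, not an error
  expect_warning(v <- compartment_mean(norm, matrix(FALSE, 96, 96)), "empty")
  expect_true(is.na(v))
})

test_that("noiseless compartment means match the scene's expectation images", {
  kin <- cbind(kinetic_constant(1, 3), kinetic_constant(1, 1))
  # gain 1 / offset 0 so rendered counts sit in the same units as the
  # ground-truth photon expectation (a detector offset deliberately biases
  # normalized intensities and is not part of this recovery check)
  sc <- make_scene(shape = c(128, 128), n_spots = 12, kinetics = kin,
                   amplitude = c(30000, 2500), background = 100,
                   gain = 1, offset = 0,
                   min_separation = 6, seed = 62)
  tl <- render_timelapse(sc, noise = FALSE)
  cm <- compartment_mask(get_frame(tl, "marker", 1), roi = tl$roi)
  measured <- compartment_mean(
    normalized_intensity_image(get_frame(tl, "probe", 1), tl$roi), cm)
  e <- scene_expectation(sc, 1)[, , 1]
  truth <- mean((e / mean(e[sc$cell_mask]))[cm$mask])
  expect_equal(measured, truth, tolerance = 0.02)
})

test_that("compartment means are invariant to probe gain", {
  sc <- make_scene(shape = c(96, 96), n_spots = 15,
                   amplitude = c(20000, 2500), background = 100,
                   min_separation = 6, seed = 63)
  tl <- render_timelapse(sc)
  cm <- compartment_mask(get_frame(tl, "marker", 1), roi = tl$roi)
  probe <- get_frame(tl, "probe", 1)
  v1 <- compartment_mean(normalized_intensity_image(probe, tl$roi), cm)
  v2 <- compartment_mean(normalized_intensity_image(3.17 * probe, tl$roi), cm)
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("time-course tables carry per-frame normalized enrichment", {
  sc <- scenario_dissociation(seed = 64, n_frames = 8, event_frame = 3)
  tl <- render_timelapse(sc)
  tc <- timecourse(tl, "probe", "marker")
  expect_equal(nrow(tc), 8L)
  expect_equal(tc$time, (0:7) * sc$frame_interval)
  expect_true(all(tc$n_mask_pixels > 0))
  expect_true(all(!is.na(tc$normalized_intensity)))
  # enrichment is high pre-event and falls after
  expect_gt(tc$normalized_intensity[1], 2)
  expect_lt(tc$normalized_intensity[8], tc$normalized_intensity[1])

  # single-frame stack degenerates to one row per probe
  sc1 <- scenario_coloc(seed = 65)
  tl1 <- render_timelapse(sc1)
  tc1 <- timecourse(tl1, "probe", "marker")
  expect_equal(nrow(tc1), 1L)
})

test_that("cohort aggregation computes mean, s.e.m. and n per point", {
  tabs <- lapply(1:4, function(i) {
    sc <- scenario_dissociation(seed = 70 + i, n_frames = 5, event_frame = 2)
    tl <- render_timelapse(sc, cell_id = sprintf("cell%02d", i))
    timecourse(tl, "probe", "marker")
  })
  agg <- aggregate_timecourse(tabs)
  expect_equal(nrow(agg), 5L)
  expect_true(all(agg$n_cells == 4L))
  # hand-check one point
  f3 <- vapply(tabs, function(t)
    t$normalized_intensity[t$frame_index == 3], numeric(1))
  a3 <- agg[agg$frame_index == 3, ]
  expect_equal(a3$mean, mean(f3))
  expect_equal(a3$sem, stats::sd(f3) / 2)

  # missing values drop out of the aggregate with reduced n
  tabs[[1]]$normalized_intensity[3] <- NA
  agg2 <- aggregate_timecourse(tabs)
  expect_equal(agg2$n_cells[agg2$frame_index == 3], 3L)
  expect_equal(agg2$mean[agg2$frame_index == 3], mean(f3[-1]))
})

test_that("percent change compares pre-event baseline to the plateau", {
  tab <- data.frame(cell_id = "c", frame_index = 1:6, time = 0:5,
                    probe_channel = "p", compartment = "m",
                    normalized_intensity = c(2, 2, 2, 1.5, 1, 1),
                    n_mask_pixels = 10)
  pc <- percent_change(tab, event_frame = 4, plateau_frames = 2)
  expect_equal(pc$baseline, 2)
  expect_equal(pc$plateau, 1)
  expect_equal(pc$percent_change, -50)
})

test_that("the representative cell is the one nearest the cohort median", {
  expect_equal(select_representative(
    data.frame(cell_id = c("A", "B", "C"), score = c(1, 2, 3))), "B")
  # median 2.5: B and C tie at distance 0.5; tie-break to smaller id
  expect_equal(select_representative(
    data.frame(cell_id = c("A", "B", "C", "D"), score = c(1, 2, 3, 10))), "B")
  expect_error(select_representative(
    data.frame(cell_id = character(), score = numeric())), "empty")
  # selected score always falls in the interquartile range
  set.seed(81)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    cells <- data.frame(cell_id = sprintf("c%02d", seq_len(n)),
                        score = stats::rlnorm(n))
    id <- select_representative(cells)
    sc <- cells$score[cells$cell_id == id]
    q <- stats::quantile(cells$score, c(0.25, 0.75), names = FALSE, type = 2)
    expect_gte(sc, q[1]); expect_lte(sc, q[2])
  }
})
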