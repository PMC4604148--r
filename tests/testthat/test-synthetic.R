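test_that("scenes are deterministic and honour the overlap contract", {
  sc1 <- make_scene(shape = c(64, 64), n_spots = 50, overlap_fraction = 0.5,
                    seed = 42)
  sc2 <- make_scene(shape = c(64, 64), n_spots = 50, overlap_fraction = 0.5,
                    seed = 42)
  expect_identical(sc1$spots, sc2$spots)
  expect_identical(sc1$cell_mask, sc2$cell_mask)
  expect_identical(render_frame(sc1, 1), render_frame(sc2, 1))

  sc3 <- make_scene(shape = c(64, 64), n_spots = 50, overlap_fraction = 0.5,
                    seed = 43)
  expect_false(identical(sc1$spots, sc3$spots))

  both <- function(sc) sc$spots$amp_probe > 0 & sc$spots$amp_marker > 0
  full <- make_scene(shape = c(64, 64), n_spots = 50, overlap_fraction = 1,
                     seed = 1)
  none <- make_scene(shape = c(64, 64), n_spots = 50, overlap_fraction = 0,
                     seed = 1)
  expect_true(all(both(full)))
  expect_false(any(both(none)))
  # every spot still lives in exactly one channel at overlap 0
  expect_true(all(xor(none$spots$amp_probe > 0, none$spots$amp_marker > 0)))
  expect_equal(true_overlap(full), 1)
  expect_equal(true_overlap(none), 0)

  half <- make_scene(shape = c(64, 64), n_spots = 41, overlap_fraction = 0.5,
                     seed = 9)
  expect_equal(sum(both(half)), round(0.5 * 41))
  expect_equal(true_overlap(half), round(0.5 * 41) / 41)
})

test_that("scene invariants hold: geometry, positivity, cell area", {
  for (seed in c(3, 17, 101)) {
    sc <- make_scene(shape = c(96, 96), n_spots = 30, overlap_fraction = 0.6,
                     seed = seed)
    ctr <- cbind(round(sc$spots$row), round(sc$spots$col))
    expect_true(all(sc$cell_mask[ctr]))
    expect_true(all(sc$spots$sigma > 0))
    expect_true(all(sc$spots$amp_probe >= 0 & sc$spots$amp_marker >= 0))
    expect_gt(mean(sc$cell_mask), 0.2)
    expect_lt(mean(sc$cell_mask), 0.6)
  }
})

test_that("invalid scene configurations are rejected", {
  expect_error(make_scene(overlap_fraction = 1.2, seed = 1), "overlap")
  expect_error(make_scene(overlap_fraction = -0.1, seed = 1), "overlap")
  expect_error(make_scene(amplitude = -5, seed = 1), "amplitude")
  expect_error(make_scene(background = Inf, seed = 1), "background")
  expect_error(make_scene(sigma = 0, seed = 1), "sigma")
  expect_error(make_scene(n_spots = -1, seed = 1), "n_spots")
  expect_error(make_scene(), "seed")
  sc <- make_scene(shape = c(64, 64), n_spots = 5, seed = 1)
  expect_error(render_frame(sc, 0), "frame_index")
  expect_error(render_frame(sc, 2), "frame_index")
  expect_error(scene_expectation(sc, 99), "frame_index")
})

test_that("rendered frames follow the forward model in degenerate cases", {
  # no spots, no background, noise off: offset only
  sc <- make_scene(shape = c(64, 64), n_spots = 0, background = 0,
                   noise = list(poisson = FALSE, read_sd = 0),
                   gain = 1, offset = 100, seed = 2)
  fr <- render_frame(sc, 1)
  expect_true(all(fr == 100))

  # kinetic multiplier 0: background only in that channel
  kin <- cbind(c(1, 0), c(1, 1))
  sc0 <- make_scene(shape = c(64, 64), n_spots = 10, background = 50,
                    kinetics = kin, noise = list(poisson = FALSE, read_sd = 0),
                    gain = 1, offset = 0, seed = 5)
  e <- scene_expectation(sc0, 2)
  expect_equal(e[, , 1], 50 * sc0$cell_mask * 1)
  expect_gt(max(e[, , 2]), 50)
})

test_that("a rendered spot integrates to its configured amplitude", {
  sc <- make_scene(shape = c(65, 65), channels = "probe", n_spots = 1,
                   amplitude = 1000, background = 0,
                   noise = list(poisson = FALSE, read_sd = 0),
                   gain = 1, offset = 0, seed = 3)
  e <- scene_expectation(sc, 1)[, , 1]
  # independent oracle: direct dense evaluation of the Gaussian over the grid
  s <- sc$spots
  g <- outer(seq_len(65), seq_len(65), function(r, c)
    exp(-((r - s$row)^2 + (c - s$col)^2) / (2 * s$sigma^2)))
  oracle <- s$amp_probe / (2 * pi * s$sigma^2) * sum(g)
  expect_lt(abs(sum(e) - oracle), 1e-5)  # only the +/- 5 sigma truncation
  expect_lt(abs(sum(e) - s$amp_probe) / s$amp_probe, 0.01)
})

test_that("noiseless rendering is linear in spot amplitude", {
  base <- list(shape = c(64, 64), n_spots = 15, overlap_fraction = 1,
               background = 20, noise = list(poisson = FALSE, read_sd = 0),
               gain = 1, offset = 0, seed = 8)
  sc1 <- do.call(make_scene, c(base, list(amplitude = 500)))
  sc2 <- do.call(make_scene, c(base, list(amplitude = 1000)))
  e1 <- scene_expectation(sc1, 1)
  e2 <- scene_expectation(sc2, 1)
  bg <- 20 * sc1$cell_mask
  expect_equal(e2[, , 1] - bg, 2 * (e1[, , 1] - bg), tolerance = 1e-12)
})

test_that("time-lapse stacking and kinetic programs behave as programmed", {
  kin <- cbind(kinetic_constant(4, 2), kinetic_constant(4, 2))
  sc <- make_scene(shape = c(64, 64), n_spots = 8, kinetics = kin,
                   noise = list(poisson = FALSE, read_sd = 0), seed = 4)
  tl <- render_timelapse(sc, noise = FALSE)
  expect_s3_class(tl, "cell_image")
  expect_equal(dim(tl$data), c(64, 64, 2, 4))
  for (t in 2:4) expect_identical(tl$data[, , , t], tl$data[, , , 1])
  expect_identical(tl$truth$spots, sc$spots)
  expect_equal(tl$truth$overlap_fraction, 1)

  # dissociation program: mean expectation at spot pixels falls monotonically
  kin2 <- cbind(kinetic_decay(10, 3, from = 3, to = 1, tau = 2),
                kinetic_constant(10, 1))
  sc2 <- make_scene(shape = c(96, 96), n_spots = 10, kinetics = kin2,
                    noise = list(poisson = FALSE, read_sd = 0), seed = 6)
  ctr <- cbind(round(sc2$spots$row), round(sc2$spots$col))
  means <- vapply(3:10, function(t) mean(scene_expectation(sc2, t)[, , 1][ctr]),
                  numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("Poisson shot noise matches the counting-statistics prediction", {
  # one spot, constant program: every frame is an independent realization
  kin <- kinetic_constant(100, 1)
  sc <- make_scene(shape = c(48, 48), channels = "probe", n_spots = 1,
                   amplitude = 1000, background = 0, kinetics = kin,
                   noise = list(poisson = TRUE, read_sd = 0),
                   gain = 1, offset = 100, seed = 12)
  tl <- render_timelapse(sc)
  totals <- vapply(seq_len(100), function(t)
    sum(tl$data[, , 1, t] - 100), numeric(1))
  cv <- stats::sd(totals) / mean(totals)
  cv_pred <- 1 / sqrt(sc$spots$amp_probe)  # Poisson: CV = 1/sqrt(N)
  expect_lt(abs(cv - cv_pred) / cv_pred, 0.2)
})

test_that("probe-flux conservation redistributes lost enrichment to cytosol", {
  kin <- cbind(kinetic_decay(6, 2, from = 3, to = 1, tau = 1),
               kinetic_constant(6, 1))
  sc <- make_scene(shape = c(96, 96), n_spots = 10, kinetics = kin,
                   conserve_probe = c(TRUE, FALSE),
                   noise = list(poisson = FALSE, read_sd = 0), seed = 7)
  tot <- vapply(1:6, function(t) sum(scene_expectation(sc, t)[, , 1]),
                numeric(1))
  # total probe flux is conserved over the dissociation (up to clipped tails)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 0.01)
})
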