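test_that("the single-frame MSD matches its hand-computed and naive forms", {
  tr <- spt_tracks(data.frame(track_id = 1, frame = 1:3,
                              x = c(0, 3, 3), y = c(0, 4, 4)))
  ms <- msd_series(tr)
  expect_equal(nrow(ms), 1)
  expect_equal(ms$R2, 12.5)          # (25 + 0) / 2
  expect_equal(ms$frame, 2L)

  still <- spt_tracks(data.frame(track_id = 1, frame = 1:10, x = 1, y = -2))
  expect_true(all(msd_series(still)$R2 == 0))

  short <- spt_tracks(data.frame(track_id = 1, frame = 1:2, x = 0:1, y = 0:1))
  expect_equal(nrow(msd_series(short)), 0)
})

test_that("msd_series agrees with the naive double-loop reference", {
  for (k in 1:100) {
    tr <- make_walk(30, D = runif(1, 0.05, 5), seed = 1000 + k,
                    gaps = if (k %% 3 == 0) sample(5:25, 3) else integer(0))
    ms <- msd_series(tr)
    ref <- msd_naive(tr$frame, tr$x, tr$y)
    if (is.null(ref)) {
      expect_equal(nrow(ms), 0)
    } else {
      expect_equal(ms$frame, ref$frame)
      expect_equal(ms$R2, ref$R2, tolerance = 1e-14)
    }
  }
})

test_that("frames adjacent to gaps are skipped, all others kept", {
  tr <- make_walk(20, seed = 5, gaps = c(8, 14))
  ms <- msd_series(tr)
  expect_false(any(ms$frame %in% c(7, 8, 9, 13, 14, 15)))
  expect_true(all(setdiff(2:19, c(7, 8, 9, 13, 14, 15)) %in% ms$frame))
})

test_that("MSD and V are invariant under rigid motions; V is scale-free", {
  tr <- make_walk(120, seed = 6)
  ms <- msd_series(tr)
  rot <- msd_series(rotate_tracks(tr, 1.1))
  expect_equal(ms$R2, rot$R2, tolerance = 1e-12)
  shift <- tr; shift$x <- tr$x + 5; shift$y <- tr$y - 3
  expect_equal(msd_series(shift)$R2, ms$R2, tolerance = 1e-12)

  v <- normalized_variance(ms$R2)
  expect_equal(normalized_variance(ms$R2 * 7.3), v, tolerance = 1e-12)
  expect_equal(normalized_variance(rev(ms$R2)), v, tolerance = 1e-12)
})

test_that("normalized variance handles constants, short input and zero mean", {
  expect_equal(normalized_variance(rep(0.4, 25)), 0)
  expect_error(normalized_variance(c(1, 2, 3)), "at least 4")
  expect_error(normalized_variance(rep(0, 10)), "undefined")
  # calibration factor: >= 1 always, decreasing in n, -> 1 asymptotically
  expect_true(all(diff(v_calibration_factor(c(5, 10, 38, 100, 1000))) < 0))
  expect_lt(v_calibration_factor(5000), 1.001)
})

test_that("D = R2 / (4 tau) conversion", {
  expect_equal(diffusion_coefficient(0.8, 0.025), 8)
  expect_equal(diffusion_coefficient(0.012, 0.025), 0.12)
  expect_equal(diffusion_coefficient(0, 0.025), 0)
  expect_error(diffusion_coefficient(0.8, 0), "tau")
})

test_that("segment_stats windows respect gaps, length limits and identities", {
  tr <- make_walk(30, seed = 8)
  expect_equal(nrow(segment_stats(tr, window = 40, step = 20)), 0)
  expect_error(segment_stats(tr, window = 10), "min_window")

  tr2 <- make_walk(200, D = 0.5, seed = 9)
  st <- segment_stats(tr2, window = 40, step = 20)
  expect_gt(nrow(st), 5)
  expect_equal(st$D, st$mean_R2 / (4 * 0.025), tolerance = 1e-12)
  expect_true(all(st$mean_R2 > 0) && all(st$V > 0))

  # windows never span a gap
  trg <- make_walk(200, seed = 10, gaps = 100)
  stg <- segment_stats(trg, window = 40, step = 20)
  expect_false(any(stg$start_frame <= 100 & stg$start_frame + 40 > 100))
})

test_that("windows of a homogeneous free track share one V distribution", {
  tr <- simulate_free(membrane_params("free", D_free = 1, n_frames = 2000,
                                      seed = 30), 30)
  st <- segment_stats(tr, window = 40, step = 40)
  first <- st$V[st$start_frame < 900]
  second <- st$V[st$start_frame >= 900]
  expect_gt(t.test(first, second)$p.value, 0.01)
})
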