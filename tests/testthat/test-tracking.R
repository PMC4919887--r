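test_that("consecutive nearby detections form one track", {
  det <- data.frame(frame = 1:20, x = cumsum(rnorm(20, 0, 0.02)),
                    y = cumsum(rnorm(20, 0, 0.02)), intensity = 1)
  tr <- link_nearest(det, max_disp = 0.5)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 20)
})

test_that("two parallel walkers keep their identities", {
  withr::local_seed(91)
  steps <- matrix(rnorm(10, 0, 0.02), 5, 2)
  a <- cbind(cumsum(c(0, steps[1:4, 1])), cumsum(c(0, steps[1:4, 2])))
  b <- sweep(a, 2, c(0, 1), `+`)        # same shape, offset 1 um in y
  det <- data.frame(frame = rep(1:5, each = 2),
                    x = as.vector(rbind(a[, 1], b[, 1])),
                    y = as.vector(rbind(a[, 2], b[, 2])))
  tr <- link_nearest(det, max_disp = 0.3)
  expect_equal(length(unique(tr$track_id)), 2)
  for (id in unique(tr$track_id)) {
    t1 <- tr[tr$track_id == id, ]
    expect_lt(max(abs(diff(t1$y))), 0.3)  # never jumps to the other lane
  }
})

test_that("displacements beyond the gate terminate the track", {
  det <- data.frame(frame = 1:6, x = c(0, 0.01, 0.02, 5, 5.01, 5.02), y = 0)
  tr <- link_nearest(det, max_disp = 0.5)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_equal(as.vector(table(tr$track_id)), c(3, 3))
})

test_that("gap bridging keeps a track alive across missed frames", {
  det <- data.frame(frame = c(1, 2, 4, 5), x = c(0, 0.01, 0.03, 0.04), y = 0)
  tr1 <- link_nearest(det, max_disp = 0.5, max_gap = 1)
  expect_equal(length(unique(tr1$track_id)), 1)
  tr0 <- link_nearest(det, max_disp = 0.5, max_gap = 0)
  expect_equal(length(unique(tr0$track_id)), 2)
})

test_that("linking conserves detections and tolerates unsorted input", {
  withr::local_seed(92)
  det <- data.frame(frame = sample(rep(1:10, 5)), x = runif(50, 0, 10),
                    y = runif(50, 0, 10))
  expect_warning(tr <- link_nearest(rbind(det, det[1, ]), max_disp = 0.4),
                 "duplicated")
  expect_equal(nrow(tr), 51)           # every detection lands in a track
  tr2 <- link_nearest(det, max_disp = 0.4)
  expect_equal(nrow(tr2), 50)
  expect_error(link_nearest(det, max_disp = 0), "max_disp")
})

test_that("well-separated noiseless walkers are recovered exactly", {
  withr::local_seed(93)
  truth <- lapply(1:4, function(k) {
    ox <- (k - 1) %% 2 * 10; oy <- (k - 1) %/% 2 * 10
    data.frame(truth_id = k, frame = 1:30,
               x = ox + cumsum(c(0, rnorm(29, 0, 0.05))),
               y = oy + cumsum(c(0, rnorm(29, 0, 0.05))))
  })
  det <- do.call(rbind, truth)
  det <- det[order(det$frame), ]
  tr <- link_nearest(det[, c("frame", "x", "y")], max_disp = 0.5)
  merged <- merge(as.data.frame(tr), det, by = c("frame", "x", "y"))
  # the recovered partition matches the true partition exactly
  tab <- table(merged$track_id, merged$truth_id)
  expect_equal(length(unique(tr$track_id)), 4)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("rendering and detection round-trip a bright static spot", {
  ip <- image_params(pixel_size = 0.16, width = 32, height = 32,
                     photons = 2000, background = 40)
  tr <- spt_tracks(data.frame(track_id = 1, frame = 1:3,
                              x = 2.48, y = 3.12), 0.025)
  stack <- render_frames(tr, ip, seed = 94)
  det <- detect_spots(stack, ip$pixel_size)
  expect_equal(nrow(det), 3)
  expect_lt(max(abs(det$x - 2.48)), 0.5 * ip$pixel_size)
  expect_lt(max(abs(det$y - 3.12)), 0.5 * ip$pixel_size)
})

test_that("two distant spots give two detections; blank frames give none", {
  ip <- image_params(width = 48, height = 48, photons = 2000)
  tr <- spt_tracks(data.frame(track_id = c(1, 2), frame = 1,
                              x = c(1.5, 6.0), y = c(1.5, 6.0)), 0.025)
  det <- detect_spots(render_frames(tr, ip, seed = 95), ip$pixel_size)
  expect_equal(nrow(det), 2)

  blank <- array(50, dim = c(16, 16, 2))
  expect_equal(nrow(detect_spots(blank, 0.16)), 0)

  # pure background is Poisson with the configured mean
  none <- spt_tracks(data.frame(track_id = 1, frame = 1, x = 100, y = 100), 0.025)
  expect_warning(bg <- render_frames(none, ip, seed = 96), "clipped")
  expect_lt(abs(mean(bg) - ip$background), 3 * sqrt(ip$background / length(bg)))
})

test_that("TIFF stacks round-trip through disk", {
  ip <- image_params(width = 24, height = 24)
  tr <- spt_tracks(data.frame(track_id = 1, frame = 1:2, x = 1.9, y = 2.1), 0.025)
  path <- withr::local_tempfile(fileext = ".tif")
  stack <- render_frames(tr, ip, path = path, seed = 97)
  back <- read_stack(path)
  expect_equal(dim(back), dim(stack))
  expect_equal(back, array(as.numeric(stack), dim(stack)))
})
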