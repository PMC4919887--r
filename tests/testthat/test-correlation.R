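test_that("phasorize centres segments and preserves amplitude/phase", {
  z <- phasorize(data.frame(x = c(3, 0), y = c(4, 0)), origin = "first_point")
  expect_equal(z[1], complex(real = 0, imaginary = 0))
  expect_equal(Mod(z[2]), 5)
  expect_equal(Arg(z[2]), atan2(-4, -3))

  seg <- data.frame(x = rnorm(10), y = rnorm(10))
  expect_equal(sum(phasorize(seg)), complex(real = 0, imaginary = 0),
               tolerance = 1e-12)

  zz <- phasorize(data.frame(x = rep(1, 5), y = rep(2, 5)))
  expect_true(isTRUE(attr(zz, "degenerate")))
})

test_that("the analytic correlation limits are exact", {
  seg <- make_walk(40, seed = 81)[, c("x", "y")]
  expect_equal(degree_of_correlation(seg, seg), 1, tolerance = 1e-12)
  rot <- data.frame(x = -seg$y, y = seg$x)              # 90-degree rotation
  expect_equal(degree_of_correlation(seg, rot), 0, tolerance = 1e-12)
  neg <- data.frame(x = -seg$x, y = -seg$y)
  expect_equal(degree_of_correlation(seg, neg), -1, tolerance = 1e-12)
})

test_that("C agrees with the amplitude-cosine reference to machine precision", {
  for (k in 1:100) {
    a <- make_walk(25, seed = 300 + k)[, c("x", "y")]
    b <- make_walk(25, seed = 600 + k)[, c("x", "y")]
    lag <- sample(c(0, 1, 3), 1)
    expect_equal(degree_of_correlation(a, b, lag = lag),
                 corr_naive(a$x, a$y, b$x, b$y, lag = lag),
                 tolerance = 1e-12)
  }
})

test_that("C is bounded, symmetric, rotation-invariant and offset-free", {
  withr::local_seed(82)
  for (k in 1:30) {
    a <- make_walk(30, seed = 900 + k)[, c("x", "y")]
    b <- make_walk(30, seed = 950 + k)[, c("x", "y")]
    C <- degree_of_correlation(a, b)
    expect_lte(abs(C), 1 + 1e-12)
    expect_equal(degree_of_correlation(b, a), C, tolerance = 1e-12)
    th <- runif(1, 0, 2 * pi)
    ar <- data.frame(x = cos(th) * a$x - sin(th) * a$y,
                     y = sin(th) * a$x + cos(th) * a$y)
    br <- data.frame(x = cos(th) * b$x - sin(th) * b$y,
                     y = sin(th) * b$x + cos(th) * b$y)
    expect_equal(degree_of_correlation(ar, br), C, tolerance = 1e-12)
    bs <- data.frame(x = b$x + 11, y = b$y - 3)
    expect_equal(degree_of_correlation(a, bs), C, tolerance = 1e-12)
  }
  expect_error(degree_of_correlation(a, b, lag = 30), "overlap")
  still <- data.frame(x = rep(0, 30), y = rep(0, 30))
  expect_error(degree_of_correlation(still, b), "zero-norm")
})

test_that("candidate pairs respect time overlap and distance gates", {
  a <- as.data.frame(make_walk(60, D = 0.01, seed = 83, id = "a"))
  b <- a; b$track_id <- "b"; b$x <- b$x + 0.1           # nearby, co-resident
  c <- a; c$track_id <- "c"; c$x <- c$x + 50            # far away
  d <- a; d$track_id <- "d"; d$frame <- d$frame + 100   # disjoint in time
  tr <- spt_tracks(rbind(a, b, c, d), 0.025)
  cp <- candidate_pairs(tr, max_distance = 0.5, min_overlap = 40)
  expect_equal(nrow(cp), 1)
  expect_equal(c(cp$track_id_1, cp$track_id_2), c("a", "b"))
})

test_that("rigidly co-moving pairs keep every window, independent pairs none", {
  base <- as.data.frame(make_walk(200, D = 0.5, seed = 84, id = "a"))
  twin <- base; twin$track_id <- "b"; twin$x <- twin$x + 0.05
  tr <- spt_tracks(rbind(base, twin), 0.025)
  seg <- extract_correlated_segments(tr, window = 40, step = 20)
  expect_equal(nrow(seg), nrow(attr(seg, "scan")))
  expect_true(all(seg$C > 0.999))

  ind <- as.data.frame(make_walk(200, D = 0.5, seed = 85, id = "b"))
  ind$x <- ind$x + 0.1
  tr2 <- spt_tracks(rbind(base, ind), 0.025)
  # independent walkers drift apart, so name the pair explicitly rather
  # than relying on the distance gate
  seg2 <- extract_correlated_segments(
    tr2, pairs = data.frame(track_id_1 = "a", track_id_2 = "b"),
    window = 40, step = 20)
  expect_lt(nrow(seg2) / nrow(attr(seg2, "scan")), 0.15)
})

test_that("correlated sub-trajectories are cut out faithfully", {
  p <- membrane_params("pair", n_frames = 150, seed = 86, substeps = 20)
  tr <- simulate_pair(p, 4)
  seg <- extract_correlated_segments(tr, window = 40, step = 40)
  expect_gt(nrow(seg), 0)
  sub <- correlated_subtracks(tr, seg)
  expect_equal(nrow(sub), 2 * 40 * nrow(seg))
  st <- segment_stats(sub, window = 40, step = 40)
  expect_true(all(st$mean_R2 > 0))
})
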