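test_that("parameter validation enforces the physical constraints", {
  expect_error(membrane_params(D_free = 0), "D_free")
  expect_error(membrane_params(D_free = -1), "D_free")
  expect_error(membrane_params(frame_period = 0), "frame_period")
  expect_error(membrane_params(sigma_loc = -0.01), "sigma_loc")
  expect_error(membrane_params(cholesterol = 1.5), "cholesterol")
  expect_error(membrane_params(barrier_height = -1), "barrier_height")
  expect_error(membrane_params(barrier_width = 0), "barrier_width")
  expect_error(membrane_params("domain", domain_relaxation_time = 0),
               "domain_relaxation_time")
  expect_error(membrane_params(substeps = 0), "substeps")
  expect_error(simulate_pair(membrane_params("pair"), 0), "n_pairs")
  expect_error(simulate_free(membrane_params("corral"), 3), "regime")
})

test_that("free diffusion has exact Brownian increment statistics", {
  p <- membrane_params("free", D_free = 0.12, n_frames = 400, sigma_loc = 0,
                       seed = 101)
  tr <- simulate_free(p, 500)
  d2 <- unlist(lapply(split(as.data.frame(tr), tr$track_id), function(t)
    diff(t$x)^2 + diff(t$y)^2))
  target <- 4 * 0.12 * 0.025          # 0.012 um^2
  se <- sd(d2) / sqrt(length(d2))
  expect_lt(abs(mean(d2) - target), 3 * se)

  # per-axis increments are Gaussian with variance 2*D*tau
  dx <- unlist(lapply(split(as.data.frame(tr), tr$track_id), function(t) diff(t$x)))
  ks <- ks.test(dx, "pnorm", 0, sqrt(2 * 0.12 * 0.025))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulations are bit-reproducible from the seed", {
  p <- membrane_params("corral", n_frames = 60, seed = 7, substeps = 10,
                       barrier_width = 0.2)
  expect_identical(simulate_corral(p, 5), simulate_corral(p, 5))
  pd <- membrane_params("domain", n_frames = 60, seed = 7, substeps = 10)
  expect_identical(simulate_domain(pd, 5), simulate_domain(pd, 5))
  pp <- membrane_params("pair", n_frames = 60, seed = 7, substeps = 10)
  expect_identical(simulate_pair(pp, 3), simulate_pair(pp, 3))
})

test_that("ensemble mean R2 is invariant under rigid rotation", {
  tr <- simulate_free(membrane_params("free", n_frames = 100, seed = 9), 20)
  m1 <- mean(msd_series(tr)$R2)
  m2 <- mean(msd_series(rotate_tracks(tr, 0.7))$R2)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("a zero-height barrier leaves corral diffusion free", {
  pf <- membrane_params("free", D_free = 0.5, n_frames = 200, seed = 11)
  pc <- membrane_params("corral", D_free = 0.5, n_frames = 200, seed = 12,
                        barrier_height = 0, substeps = 20)
  d2 <- function(tr) unlist(lapply(split(as.data.frame(tr), tr$track_id),
                                   function(t) diff(t$x)^2 + diff(t$y)^2))
  ks <- ks.test(d2(simulate_free(pf, 60)), d2(simulate_corral(pc, 60)))
  expect_gt(ks$p.value, 0.01)
})

test_that("barriers suppress corral excursions monotonically and can contain", {
  # slow, strongly corralled receptor observed for 100 s; a smooth ridge of
  # a few kT has a finite Kramers escape time comparable to the observation
  # window, so full containment is asserted only at a high barrier while
  # moderate barriers show graded suppression
  excursion <- function(H, seed) {
    p <- membrane_params("corral", D_free = 0.001, corral_radius = 0.1,
                         barrier_height = H, barrier_width = 0.05,
                         n_frames = 4000, substeps = 10, seed = seed)
    tr <- simulate_corral(p, 10)
    r <- sqrt(tr$x^2 + tr$y^2)
    list(q99 = unname(quantile(r, 0.99)),
         med_max = median(tapply(r, tr$track_id, max)))
  }
  none <- excursion(0, 13)
  soft <- excursion(10, 13)
  hard <- excursion(18, 13)
  expect_lt(hard$q99, 3 * 0.1)                 # contained for the full 100 s
  expect_gt(none$med_max, soft$med_max)        # graded suppression with height
  expect_gt(soft$med_max, hard$med_max)
})

test_that("switching the domain boundary off recovers free diffusion", {
  base <- list(D_free = 0.5, n_frames = 200, substeps = 20,
               domain_center_D = 0)
  pd <- do.call(membrane_params,
                c(list(regime = "domain", cholesterol = 0, seed = 15), base))
  pf <- do.call(membrane_params, c(list(regime = "free", seed = 16), base))
  d2 <- function(tr) unlist(lapply(split(as.data.frame(tr), tr$track_id),
                                   function(t) diff(t$x)^2 + diff(t$y)^2))
  ks <- ks.test(d2(simulate_domain(pd, 60)), d2(simulate_free(pf, 60)))
  expect_gt(ks$p.value, 0.01)
})

test_that("localization noise has the documented radial magnitude", {
  # stationary emitter: observed squared frame-to-frame displacement has
  # mean 2 * sigma_loc^2 (sum of two independent error vectors)
  still <- spt_tracks(data.frame(track_id = 1, frame = 1:2000, x = 0, y = 0))
  noisy <- add_localization_noise(still, sigma_loc = 0.04, seed = 3)
  d2 <- diff(noisy$x)^2 + diff(noisy$y)^2
  se <- sd(d2) / sqrt(length(d2))
  expect_lt(abs(mean(d2) - 2 * 0.04^2), 3 * se)

  expect_identical(add_localization_noise(still, 0), still)
  expect_identical(add_localization_noise(still, 0.04, seed = 5),
                   add_localization_noise(still, 0.04, seed = 5))
  expect_error(add_localization_noise(still, -1), "sigma_loc")
})

test_that("halving the integration step leaves ensemble moments unchanged", {
  # per-track mean squared step: tracks are independent replicates, steps
  # within a track are not
  mk <- function(sub, seed) {
    p <- membrane_params("corral", D_free = 0.5, n_frames = 150,
                         substeps = sub, seed = seed)
    tr <- simulate_corral(p, 100)
    vapply(split(as.data.frame(tr), tr$track_id),
           function(t) mean(diff(t$x)^2 + diff(t$y)^2), numeric(1))
  }
  a <- mk(50, 21); b <- mk(100, 22)    # default step vs half the step
  tt <- t.test(a, b)
  expect_gt(tt$p.value, 0.01)
})
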