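#' Simulate free 2D Brownian diffusion
#'
#' Generates coarse-grained single-molecule trajectories sampled at the
#' camera frame period. Frame-to-frame displacements are exact Brownian
#' increments: Gaussian per axis with variance `2 * D_free * frame_period`.
#' No localization noise is added; apply [add_localization_noise()]
#' separately to emulate the instrument.
#'
#' @param params a [membrane_params()] object with `regime = "free"`.
#' @param n_tracks number of trajectories.
#' @param start_positions optional `n_tracks` x 2 matrix of start positions
#'   (um); default all tracks start at the origin.
#' @return a [spt_tracks] tibble; track ids are `free_0001, ...`.
#' @examples
#' p <- membrane_params("free", D_free = 1, n_frames = 50, seed = 7)
#' tr <- simulate_free(p, n_tracks = 3)
#' @export
simulate_free <- function(params, n_tracks, start_positions = NULL) {
  stopifnot(inherits(params, "membrane_params"))
  if (params$regime != "free") stop("params$regime must be 'free'", call. = FALSE)
  .check_ntracks(n_tracks)
  st <- .start_mat(start_positions, n_tracks)
  nf <- params$n_frames
  withr::local_seed(params$seed)
  s <- sqrt(2 * params$D_free * params$frame_period)
  dx <- matrix(rnorm((nf - 1) * n_tracks, 0, s), nf - 1, n_tracks)
  dy <- matrix(rnorm((nf - 1) * n_tracks, 0, s), nf - 1, n_tracks)
  X <- rbind(st[, 1], sweep(apply(dx, 2, cumsum), 2, st[, 1], `+`))
  Y <- rbind(st[, 2], sweep(apply(dy, 2, cumsum), 2, st[, 2], `+`))
  .mat_to_tracks(X, Y, "free", params$frame_period)
}

#' Simulate diffusion in a soft-walled actin corral
#'
#' Overdamped Langevin dynamics in a radial potential ridge
#' `U(r) = H * exp(-(r - Rc)^2 / (2 w^2))` (height `H = barrier_height` in
#' kT, centred on the corral boundary `Rc = corral_radius`, width
#' `w = barrier_width`), integrated with a stochastic Heun
#' (predictor-corrector) drift update over `substeps` steps per frame and
#' sampled at the frame period. The soft ridge stalls the molecule near
#' the boundary and permits occasional hops, suppressing long-time
#' excursions monotonically in the barrier height; the stalled/free
#' step-size mixture over-disperses R2 (V > 2). Note that a smooth ridge
#' of a few kT has a finite Kramers escape time, so occasional genuine
#' hops out of the corral are expected phenomenology, not an artifact.
#'
#' The corral is centred on each track's start position.
#'
#' @inheritParams simulate_free
#' @return a [spt_tracks] tibble; track ids `corral_0001, ...`.
#' @export
simulate_corral <- function(params, n_tracks, start_positions = NULL) {
  stopifnot(inherits(params, "membrane_params"))
  if (params$regime != "corral") stop("params$regime must be 'corral'", call. = FALSE)
  .check_ntracks(n_tracks)
  st <- .start_mat(start_positions, n_tracks)
  nf <- params$n_frames; sub <- params$substeps
  D <- params$D_free; dt <- params$frame_period / sub
  H <- params$barrier_height; Rc <- params$corral_radius; w <- params$barrier_width
  # stiffest drift gradient ~ D*H/w^2; Heun keeps moment errors below
  # Monte-Carlo noise for rate * dt up to ~0.5
  if (H > 0 && D * H / w^2 * dt > 0.5)
    warning("stiff barrier for the chosen substeps; increase substeps for accuracy")
  withr::local_seed(params$seed)
  sn <- sqrt(2 * D * dt)
  ridge_force <- function(x, y) {
    r <- pmax(sqrt(x^2 + y^2), 1e-12)
    dUdr <- -H * (r - Rc) / w^2 * exp(-(r - Rc)^2 / (2 * w^2))
    list(fx = -dUdr * x / r, fy = -dUdr * y / r)
  }
  px <- st[, 1]; py <- st[, 2]
  cx <- st[, 1]; cy <- st[, 2]      # corral centres
  X <- matrix(0, nf, n_tracks); Y <- matrix(0, nf, n_tracks)
  X[1, ] <- px; Y[1, ] <- py
  for (i in 2:nf) {
    for (k in seq_len(sub)) {
      nx <- rnorm(n_tracks, 0, sn); ny <- rnorm(n_tracks, 0, sn)
      f <- ridge_force(px - cx, py - cy)
      qx <- px + D * f$fx * dt + nx
      qy <- py + D * f$fy * dt + ny
      g <- ridge_force(qx - cx, qy - cy)
      px <- px + D * (f$fx + g$fx) / 2 * dt + nx
      py <- py + D * (f$fy + g$fy) / 2 * dt + ny
    }
    X[i, ] <- px; Y[i, ] <- py
  }
  .mat_to_tracks(X, Y, "corral", params$frame_period)
}

#' Simulate dressed-protein diffusion in a lipid domain
#'
#' The protein diffuses freely (at `D_free`) inside a flat-bottomed disc of
#' radius `domain_radius` around a domain centre that itself drifts slowly
#' (diffusion coefficient `domain_center_D`). Outside the disc the excess
#' radial excursion relaxes back elastically at rate
#' `cholesterol / domain_relaxation_time` (integrated semi-implicitly, so
#' the stiff boundary layer is unconditionally stable). `cholesterol = 0`
#' or `domain_relaxation_time = Inf` switches the boundary off and recovers
#' free diffusion.
#'
#' The flat-bottomed (non-Gaussian) confinement is what produces the
#' under-dispersed coarse-grained steps characteristic of lipid-domain
#' ("dressed") diffusion: in the frame-decorrelated limit the population
#' value of the normalized variance is 3/2, strictly below the
#' free-diffusion value 2. A purely elastic (Ornstein-Uhlenbeck) tether
#' cannot produce V < 2, because any Gaussian process has squared
#' displacements in the exponential family and hence V >= 2.
#'
#' @inheritParams simulate_free
#' @return a [spt_tracks] tibble; track ids `domain_0001, ...`.
#' @export
simulate_domain <- function(params, n_tracks, start_positions = NULL) {
  stopifnot(inherits(params, "membrane_params"))
  if (params$regime != "domain") stop("params$regime must be 'domain'", call. = FALSE)
  .check_ntracks(n_tracks)
  st <- .start_mat(start_positions, n_tracks)
  nf <- params$n_frames; sub <- params$substeps
  D <- params$D_free; dt <- params$frame_period / sub
  a <- params$domain_radius
  lam <- params$cholesterol / params$domain_relaxation_time  # pull-back rate, 1/s
  decay <- exp(-lam * dt)
  withr::local_seed(params$seed)
  sn <- sqrt(2 * D * dt)
  sc <- sqrt(2 * params$domain_center_D * dt)
  px <- st[, 1]; py <- st[, 2]
  cx <- st[, 1]; cy <- st[, 2]
  X <- matrix(0, nf, n_tracks); Y <- matrix(0, nf, n_tracks)
  X[1, ] <- px; Y[1, ] <- py
  for (i in 2:nf) {
    for (k in seq_len(sub)) {
      px <- px + rnorm(n_tracks, 0, sn); py <- py + rnorm(n_tracks, 0, sn)
      if (sc > 0) {
        cx <- cx + rnorm(n_tracks, 0, sc); cy <- cy + rnorm(n_tracks, 0, sc)
      }
      if (decay < 1) {
        rx <- px - cx; ry <- py - cy
        r <- sqrt(rx^2 + ry^2)
        out <- r > a
        if (any(out)) {
          shrink <- (a + (r[out] - a) * decay) / r[out]
          px[out] <- cx[out] + rx[out] * shrink
          py[out] <- cy[out] + ry[out] * shrink
        }
      }
    }
    X[i, ] <- px; Y[i, ] <- py
  }
  .mat_to_tracks(X, Y, "domain", params$frame_period)
}

#' Simulate attractively coupled receptor pairs
#'
#' Each pair consists of two molecules diffusing at `D_free`, coupled by a
#' harmonic attraction of stiffness
#' `pair_spring_k * cholesterol + pair_direct_k` (kT/um^2) acting on their
#' separation, with the pair centroid dressed in a lipid domain exactly as
#' in [simulate_domain()] (boundary stability also scaled by
#' `cholesterol`). Higher cholesterol therefore tightens both the coupling
#' and the shared domain, yielding longer-lived, more correlated joint
#' motion; `pair_direct_k` models direct dimerization that persists when
#' cholesterol is depleted. Linear spring and boundary relaxations use
#' exact exponential (semi-implicit) updates, so stiff couplings remain
#' stable.
#'
#' Members of pair `k` share frames and are emitted as tracks
#' `pair_<k>_a` and `pair_<k>_b`; the `pair` column gives the pair index.
#' Members start `0.1` um apart at the domain centre.
#'
#' @inheritParams simulate_free
#' @param n_pairs number of pairs.
#' @return a [spt_tracks] tibble with an extra `pair` column.
#' @export
simulate_pair <- function(params, n_pairs, start_positions = NULL) {
  stopifnot(inherits(params, "membrane_params"))
  if (params$regime != "pair") stop("params$regime must be 'pair'", call. = FALSE)
  if (!is.numeric(n_pairs) || n_pairs < 1)
    stop("n_pairs must be >= 1", call. = FALSE)
  n_pairs <- as.integer(n_pairs)
  st <- .start_mat(start_positions, n_pairs)
  nf <- params$n_frames; sub <- params$substeps
  D <- params$D_free; dt <- params$frame_period / sub
  a <- params$domain_radius
  lam_w <- params$cholesterol / params$domain_relaxation_time
  wdec <- exp(-lam_w * dt)
  k_eff <- params$pair_spring_k * params$cholesterol + params$pair_direct_k
  sdec <- exp(-2 * D * k_eff * dt)   # relative-coordinate relaxation
  withr::local_seed(params$seed)
  sn <- sqrt(2 * D * dt)
  sc <- sqrt(2 * params$domain_center_D * dt)
  x1 <- st[, 1] + 0.05; y1 <- st[, 2]
  x2 <- st[, 1] - 0.05; y2 <- st[, 2]
  cx <- st[, 1]; cy <- st[, 2]
  X1 <- matrix(0, nf, n_pairs); Y1 <- X1; X2 <- X1; Y2 <- X1
  X1[1, ] <- x1; Y1[1, ] <- y1; X2[1, ] <- x2; Y2[1, ] <- y2
  for (i in 2:nf) {
    for (k in seq_len(sub)) {
      x1 <- x1 + rnorm(n_pairs, 0, sn); y1 <- y1 + rnorm(n_pairs, 0, sn)
      x2 <- x2 + rnorm(n_pairs, 0, sn); y2 <- y2 + rnorm(n_pairs, 0, sn)
      if (sc > 0) {
        cx <- cx + rnorm(n_pairs, 0, sc); cy <- cy + rnorm(n_pairs, 0, sc)
      }
      mx <- (x1 + x2) / 2; my <- (y1 + y2) / 2
      rx <- (x1 - x2) / 2 * sdec; ry <- (y1 - y2) / 2 * sdec
      if (wdec < 1) {
        dx <- mx - cx; dy <- my - cy
        r <- sqrt(dx^2 + dy^2)
        out <- r > a
        if (any(out)) {
          shrink <- (a + (r[out] - a) * wdec) / r[out]
          mx[out] <- cx[out] + dx[out] * shrink
          my[out] <- cy[out] + dy[out] * shrink
        }
      }
      x1 <- mx + rx; y1 <- my + ry
      x2 <- mx - rx; y2 <- my - ry
    }
    X1[i, ] <- x1; Y1[i, ] <- y1; X2[i, ] <- x2; Y2[i, ] <- y2
  }
  fp <- params$frame_period
  out <- vector("list", n_pairs)
  for (j in seq_len(n_pairs)) {
    out[[j]] <- tibble(
      track_id = rep(sprintf(c("pair_%04d_a", "pair_%04d_b"), j), each = nf),
      frame = rep(seq_len(nf), 2L),
      x = c(X1[, j], X2[, j]), y = c(Y1[, j], Y2[, j]),
      pair = j
    )
  }
  tr <- spt_tracks(do.call(rbind, out)[, c("track_id", "frame", "x", "y")], fp)
  tr$pair <- as.integer(sub("^pair_(\\d+)_.*$", "\\1", tr$track_id))
  tr
}

#' Add localization noise to trajectories
#'
#' Adds independent Gaussian localization error to every position. The
#' per-axis standard deviation is `sigma_loc / sqrt(2)`, so `sigma_loc` is
#' the radial RMS error (a stated "40 nm accuracy" is `sigma_loc = 0.04`).
#' The input object is not modified.
#'
#' @param tracks a [spt_tracks] object.
#' @param sigma_loc radial RMS localization error, um.
#' @param seed integer seed for reproducible noise.
#' @return a new [spt_tracks] object.
#' @export
add_localization_noise <- function(tracks, sigma_loc, seed = 1L) {
  if (!is.numeric(sigma_loc) || sigma_loc < 0)
    stop("sigma_loc must be >= 0", call. = FALSE)
  if (sigma_loc == 0) return(tracks)
  withr::local_seed(seed)
  n <- nrow(tracks)
  out <- tracks
  out$x <- tracks$x + rnorm(n, 0, sigma_loc / sqrt(2))
  out$y <- tracks$y + rnorm(n, 0, sigma_loc / sqrt(2))
  out
}

# ---- internal helpers -------------------------------------------------------

.check_ntracks <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n_tracks must be a positive integer", call. = FALSE)
}

.start_mat <- function(start_positions, n) {
  if (is.null(start_positions)) return(matrix(0, n, 2))
  sp <- as.matrix(start_positions)
  if (nrow(sp) != n || ncol(sp) != 2)
    stop("start_positions must be an n x 2 matrix", call. = FALSE)
  sp
}

.mat_to_tracks <- function(X, Y, prefix, frame_period) {
  nf <- nrow(X); nt <- ncol(X)
  spt_tracks(tibble(
    track_id = rep(sprintf("%s_%04d", prefix, seq_len(nt)), each = nf),
    frame = rep(seq_len(nf), nt),
    x = as.vector(X), y = as.vector(Y)
  ), frame_period)
}
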