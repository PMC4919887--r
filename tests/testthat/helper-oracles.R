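# Independent reference implementations and small fixture builders used
# across the suite. The oracles deliberately use naive loops / the printed
# trigonometric form so they share no code path with the package.

# naive double-loop bidirectional single-frame MSD
msd_naive <- function(frames, x, y) {
  out <- NULL
  n <- length(frames)
  for (t in seq_len(n)) {
    if (t == 1 || t == n) next
    if (frames[t] - frames[t - 1] != 1 || frames[t + 1] - frames[t] != 1) next
    fwd <- (x[t + 1] - x[t])^2 + (y[t + 1] - y[t])^2
    bwd <- (x[t] - x[t - 1])^2 + (y[t] - y[t - 1])^2
    out <- rbind(out, data.frame(frame = frames[t], R2 = (fwd + bwd) / 2))
  }
  out
}

# amplitude/phase-cosine form of the phasor correlation (centroid origin)
corr_naive <- function(x1, y1, x2, y2, lag = 0) {
  n <- length(x1)
  if (lag >= 0) { i1 <- seq_len(n - lag); i2 <- i1 + lag }
  else { i2 <- seq_len(n + lag); i1 <- i2 - lag }
  u1x <- x1[i1] - mean(x1[i1]); u1y <- y1[i1] - mean(y1[i1])
  u2x <- x2[i2] - mean(x2[i2]); u2y <- y2[i2] - mean(y2[i2])
  A1 <- sqrt(u1x^2 + u1y^2); th1 <- atan2(u1y, u1x)
  A2 <- sqrt(u2x^2 + u2y^2); th2 <- atan2(u2y, u2x)
  sum(A1 * A2 * cos(th2 - th1)) / (sqrt(sum(A1^2)) * sqrt(sum(A2^2)))
}

# plain random-walk trajectory table
make_walk <- function(n_frames, D = 1, tau = 0.025, seed = 1, id = "w1",
                      gaps = integer(0)) {
  withr::with_seed(seed, {
    s <- sqrt(2 * D * tau)
    x <- cumsum(c(0, rnorm(n_frames - 1, 0, s)))
    y <- cumsum(c(0, rnorm(n_frames - 1, 0, s)))
  })
  df <- data.frame(track_id = id, frame = seq_len(n_frames), x = x, y = y)
  if (length(gaps)) df <- df[!df$frame %in% gaps, ]
  spt_tracks(df, frame_period = tau)
}

rotate_tracks <- function(tracks, angle) {
  out <- tracks
  out$x <- cos(angle) * tracks$x - sin(angle) * tracks$y
  out$y <- sin(angle) * tracks$x + cos(angle) * tracks$y
  out
}
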