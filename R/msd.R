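#' Bidirectional single-frame mean squared displacement series
#'
#' For each interior time point of a track, the single-frame MSD is the
#' average of the squared forward and backward lag-1 displacements,
#' `R2(t) = (|r(t+tau) - r(t)|^2 + |r(t) - r(t-tau)|^2) / 2`,
#' where `tau` is the frame period. A value is produced only where both
#' lag-1 neighbours exist without a frame gap; frames adjacent to gaps are
#' skipped.
#'
#' @param tracks a [spt_tracks] object (one or many tracks).
#' @return a tibble with columns `track_id`, `frame` (the interior time
#'   point) and `R2` (um^2). Tracks with fewer than 3 gap-free consecutive
#'   frames contribute no rows.
#' @examples
#' tr <- spt_tracks(data.frame(track_id = 1, frame = 1:3,
#'                             x = c(0, 3, 3), y = c(0, 4, 4)))
#' msd_series(tr)  # single value (25 + 0) / 2 = 12.5 um^2
#' @export
msd_series <- function(tracks) {
  pieces <- lapply(.track_split(tracks), function(tr) {
    n <- nrow(tr)
    if (n < 3) return(NULL)
    gap1 <- diff(tr$frame) == 1L                    # row i -> i+1 contiguous
    d2 <- diff(tr$x)^2 + diff(tr$y)^2               # squared displacement i -> i+1
    ok <- gap1[-length(gap1)] & gap1[-1]            # interior rows 2..n-1
    if (!any(ok)) return(NULL)
    idx <- which(ok)                                 # index into interior rows
    data.frame(track_id = tr$track_id[1],
               frame = tr$frame[idx + 1L],
               R2 = (d2[idx] + d2[idx + 1L]) / 2,
               stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0)
    return(tibble(track_id = character(), frame = integer(), R2 = numeric()))
  as_tibble(do.call(rbind, pieces))
}

#' Normalized variance of a single-frame MSD series
#'
#' The dimensionless dispersion of R2 over a window,
#' `V = 4 * Var(R2) / mean(R2)^2`, with the constant 4 fixed analytically
#' by the free-diffusion limit: for 2D Brownian motion the two-term
#' averaged R2 of independent Gaussian steps has `Var / mean^2 = 1/2`, so
#' V equals 2 for free diffusion at any diffusion coefficient. Stalling at
#' soft barriers (actin corrals) over-disperses step sizes and drives
#' V above 2; bounded "dressed" diffusion in a lipid domain under-disperses
#' them and drives V below 2.
#'
#' By default the windowed estimator is multiplied by the finite-window
#' null-calibration factor [v_calibration_factor()] so that its
#' *expectation* equals 2 under free diffusion for the actual window
#' length (the plug-in ratio alone is biased low by O(1/n)).
#'
#' @param R2 numeric vector of single-frame MSD values (one window).
#' @param calibrate apply the finite-window calibration factor
#'   (default `TRUE`).
#' @return the dimensionless V (>= 0).
#' @examples
#' normalized_variance(rep(0.4, 25))  # constant series -> 0
#' @export
normalized_variance <- function(R2, calibrate = TRUE) {
  n <- length(R2)
  if (n < 4) stop("need at least 4 R2 values", call. = FALSE)
  m <- mean(R2)
  if (m <= 0) stop("mean R2 is zero: V undefined", call. = FALSE)
  v <- 4 * var(R2) / m^2
  if (calibrate) v <- v * v_calibration_factor(n)
  v
}

#' Convert a mean squared displacement to a diffusion coefficient
#'
#' `D = mean_R2 / (4 * tau)` for 2D diffusion sampled at frame period
#' `tau`.
#'
#' @param mean_R2 mean single-frame MSD, um^2.
#' @param tau frame period, seconds.
#' @return diffusion coefficient, um^2/s.
#' @examples
#' diffusion_coefficient(0.8, 0.025)    # 8 um^2/s
#' diffusion_coefficient(0.012, 0.025)  # 0.12 um^2/s
#' @export
diffusion_coefficient <- function(mean_R2, tau) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  mean_R2 / (4 * tau)
}

#' Sliding-window segment statistics
#'
#' Slides a window of `window` frames in steps of `step` frames along every
#' track and summarizes each window by its mean single-frame MSD, its
#' normalized variance V, and the apparent diffusion coefficient
#' `D = mean_R2 / (4 tau)`. Windows that cross a frame gap are dropped.
#' These per-window summaries are the atoms of the MSD histogram and the
#' (MSD, V) contour map.
#'
#' @param tracks a [spt_tracks] object.
#' @param window window length in frames (>= `min_window`).
#' @param step step between window starts, frames.
#' @param tau frame period in seconds; defaults to the tracks' own.
#' @param min_window smallest admissible window, frames.
#' @param calibrate passed to [normalized_variance()].
#' @return a tibble with columns `track_id`, `start_frame`, `window`,
#'   `mean_R2` (um^2), `V`, `D` (um^2/s).
#' @export
segment_stats <- function(tracks, window = 40, step = 20, tau = NULL,
                          min_window = 20, calibrate = TRUE) {
  if (window < min_window)
    stop("window must be >= min_window (", min_window, ")", call. = FALSE)
  if (step < 1) stop("step must be >= 1", call. = FALSE)
  if (is.null(tau)) tau <- frame_period(tracks)
  ms <- msd_series(tracks)
  n2 <- window - 2L                  # R2 values per gap-free window
  pieces <- lapply(split(as.data.frame(ms), ms$track_id), function(tr) {
    # runs of consecutive frames in the R2 series
    runs <- split(seq_len(nrow(tr)), cumsum(c(1L, diff(tr$frame) != 1L)))
    out <- list()
    for (run in runs) {
      if (length(run) < n2) next
      starts <- seq(1L, length(run) - n2 + 1L, by = step)
      for (s in starts) {
        idx <- run[s:(s + n2 - 1L)]
        w <- tr$R2[idx]
        m <- mean(w)
        out[[length(out) + 1L]] <- data.frame(
          track_id = tr$track_id[1], start_frame = tr$frame[idx[1]] - 1L,
          window = window, mean_R2 = m,
          V = if (m > 0) normalized_variance(w, calibrate) else NA_real_,
          D = m / (4 * tau), stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0)
    return(tibble(track_id = character(), start_frame = integer(),
                  window = integer(), mean_R2 = numeric(), V = numeric(),
                  D = numeric()))
  as_tibble(do.call(rbind, pieces))
}
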