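#' Represent a trajectory segment as a complex phasor series
#'
#' Positions are written as phasors `r(t) = A(t) e^{i theta(t)}`, i.e.
#' `x + i y` relative to a chosen origin. With the default
#' `"segment_centroid"` policy the segment is centred on its own mean, so
#' the phasor measures excursion shape rather than the arbitrary offset
#' from the laboratory origin; `"first_point"` uses the segment's first
#' position instead.
#'
#' @param seg a data frame with `x`, `y` columns (one gap-free segment), or
#'   a complex vector (returned unchanged apart from centring).
#' @param origin `"segment_centroid"` or `"first_point"`.
#' @return a complex vector; amplitude `Mod()`, phase `Arg()`.
#' @examples
#' phasorize(data.frame(x = c(3, 0), y = c(4, 0)), origin = "first_point")
#' @export
phasorize <- function(seg, origin = c("segment_centroid", "first_point")) {
  origin <- match.arg(origin)
  z <- if (is.complex(seg)) seg else complex(real = seg$x, imaginary = seg$y)
  z <- switch(origin,
              segment_centroid = z - mean(z),
              first_point = z - z[1])
  if (all(Mod(z) == 0))
    attr(z, "degenerate") <- TRUE
  z
}

#' Degree of correlation between two trajectory segments
#'
#' The phasor cross-correlation
#' `C = Re[ sum_t r1*(t) r2(t + lag) ] / ( sqrt(sum |r1|^2) sqrt(sum |r2|^2) )`,
#' equivalently the amplitude-weighted mean cosine of the phase difference.
#' Sums run over the overlap after shifting the second segment by `lag`
#' frames, so `|C| <= 1` by Cauchy-Schwarz. `C = 1` for identical motion,
#' `0` for a 90-degree rotated copy, `-1` for anti-phase motion, and is
#' narrowly distributed around 0 for independent molecules.
#'
#' @param seg1,seg2 equal-length gap-free segments: data frames with
#'   `x`, `y`, or complex vectors.
#' @param lag shift (frames) applied to `seg2`.
#' @param origin origin policy, see [phasorize()]; applied to the
#'   overlapping points of each segment.
#' @param min_overlap smallest admissible overlap after shifting.
#' @return C in \[-1, 1\].
#' @export
degree_of_correlation <- function(seg1, seg2, lag = 0,
                                  origin = c("segment_centroid", "first_point"),
                                  min_overlap = 4) {
  origin <- match.arg(origin)
  z1 <- if (is.complex(seg1)) seg1 else complex(real = seg1$x, imaginary = seg1$y)
  z2 <- if (is.complex(seg2)) seg2 else complex(real = seg2$x, imaginary = seg2$y)
  if (length(z1) != length(z2))
    stop("segments must have equal length", call. = FALSE)
  n <- length(z1); lag <- as.integer(lag)
  if (abs(lag) >= n) stop("lag leaves no overlap", call. = FALSE)
  if (lag >= 0) { i1 <- seq_len(n - lag); i2 <- i1 + lag }
  else { i2 <- seq_len(n + lag); i1 <- i2 - lag }
  if (length(i1) < min_overlap)
    stop("overlap after shifting is below min_overlap", call. = FALSE)
  a <- phasorize(z1[i1], origin)
  b <- phasorize(z2[i2], origin)
  na <- sqrt(sum(Mod(a)^2)); nb <- sqrt(sum(Mod(b)^2))
  if (na == 0 || nb == 0)
    stop("zero-norm segment: C undefined", call. = FALSE)
  Re(sum(Conj(a) * b)) / (na * nb)
}

#' Candidate track pairs for correlation analysis
#'
#' Enumerates pairs of tracks that overlap in time for at least
#' `min_overlap` frames and whose median separation over the common frames
#' is at most `max_distance`. These are the pairs worth scanning for
#' correlated motion.
#'
#' @param tracks a [spt_tracks] object.
#' @param max_distance maximum median separation, um.
#' @param min_overlap minimum number of common frames.
#' @return a tibble `track_id_1`, `track_id_2`, `n_overlap`,
#'   `median_separation`.
#' @export
candidate_pairs <- function(tracks, max_distance = 0.5, min_overlap = 40) {
  if (max_distance <= 0) stop("max_distance must be > 0", call. = FALSE)
  trs <- .track_split(tracks)
  ids <- names(trs)
  if (length(ids) < 2)
    return(tibble(track_id_1 = character(), track_id_2 = character(),
                  n_overlap = integer(), median_separation = numeric()))
  cmb <- combn(ids, 2)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    t1 <- trs[[cmb[1, k]]]; t2 <- trs[[cmb[2, k]]]
    common <- intersect(t1$frame, t2$frame)
    if (length(common) < min_overlap) return(NULL)
    i1 <- match(common, t1$frame); i2 <- match(common, t2$frame)
    sep <- median(sqrt((t1$x[i1] - t2$x[i2])^2 + (t1$y[i1] - t2$y[i2])^2))
    if (sep > max_distance) return(NULL)
    data.frame(track_id_1 = cmb[1, k], track_id_2 = cmb[2, k],
               n_overlap = length(common), median_separation = sep,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(tibble(track_id_1 = character(), track_id_2 = character(),
                  n_overlap = integer(), median_separation = numeric()))
  as_tibble(do.call(rbind, rows))
}

#' Extract highly correlated segment windows from track pairs
#'
#' Slides a window along the common gap-free frames of each candidate pair
#' and computes the degree of correlation C per window; windows with
#' `C > threshold` are retained. The retained windows (both members'
#' sub-trajectories) can be materialized with [correlated_subtracks()] and
#' routed through [segment_stats()] to characterize the environment of
#' co-moving receptors.
#'
#' @param tracks a [spt_tracks] object.
#' @param pairs optional tibble of pairs (as from [candidate_pairs()]);
#'   defaults to all candidate pairs at default gates. A `pair` column
#'   produced by [simulate_pair()] is also honoured when `pairs` is
#'   omitted.
#' @param window window length, frames.
#' @param step step between window starts, frames.
#' @param threshold retain windows with `C > threshold`.
#' @param lag phasor lag, frames (see [degree_of_correlation()]).
#' @param origin origin policy, see [phasorize()].
#' @return a tibble `track_id_1`, `track_id_2`, `start_frame`, `window`,
#'   `lag`, `C` of retained windows. The full per-window scan (including
#'   sub-threshold windows) is in `attr(, "scan")`.
#' @export
extract_correlated_segments <- function(tracks, pairs = NULL, window = 40,
                                        step = 20, threshold = 0.8, lag = 0,
                                        origin = "segment_centroid") {
  if (is.null(pairs)) {
    if ("pair" %in% names(tracks)) {
      u <- unique(as.data.frame(tracks)[, c("track_id", "pair")])
      pairs <- do.call(rbind, lapply(split(u$track_id, u$pair), function(v) {
        v <- sort(v)
        data.frame(track_id_1 = v[1], track_id_2 = v[2],
                   stringsAsFactors = FALSE)
      }))
    } else {
      pairs <- candidate_pairs(tracks, min_overlap = window)
    }
  }
  trs <- .track_split(tracks)
  empty <- tibble(track_id_1 = character(), track_id_2 = character(),
                  start_frame = integer(), window = integer(),
                  lag = integer(), C = numeric())
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    t1 <- trs[[as.character(pairs$track_id_1[k])]]
    t2 <- trs[[as.character(pairs$track_id_2[k])]]
    if (is.null(t1) || is.null(t2)) next
    common <- sort(intersect(t1$frame, t2$frame))
    if (length(common) < window) next
    runs <- split(common, cumsum(c(1L, diff(common) != 1L)))
    for (run in runs) {
      if (length(run) < window) next
      for (s in seq(1L, length(run) - window + 1L, by = step)) {
        fr <- run[s:(s + window - 1L)]
        i1 <- match(fr, t1$frame); i2 <- match(fr, t2$frame)
        C <- degree_of_correlation(t1[i1, c("x", "y")], t2[i2, c("x", "y")],
                                   lag = lag, origin = origin)
        rows[[length(rows) + 1L]] <- data.frame(
          track_id_1 = pairs$track_id_1[k], track_id_2 = pairs$track_id_2[k],
          start_frame = fr[1], window = window, lag = as.integer(lag), C = C,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  scan <- as_tibble(do.call(rbind, rows))
  out <- scan[scan$C > threshold, ]
  attr(out, "scan") <- scan
  out
}

#' Materialize the sub-trajectories of correlated segments
#'
#' Cuts the retained windows of [extract_correlated_segments()] out of the
#' parent tracks so they can be analysed with [segment_stats()] like any
#' other trajectory collection. Each window of each member becomes its own
#' track (`<id>@<start>`), keeping windows statistically independent
#' downstream.
#'
#' @param tracks the parent [spt_tracks] object.
#' @param segments tibble from [extract_correlated_segments()].
#' @return a [spt_tracks] object (possibly empty).
#' @export
correlated_subtracks <- function(tracks, segments) {
  trs <- .track_split(tracks)
  rows <- list()
  for (k in seq_len(nrow(segments))) {
    fr <- segments$start_frame[k] + seq_len(segments$window[k]) - 1L
    for (id in c(segments$track_id_1[k], segments$track_id_2[k])) {
      tr <- trs[[as.character(id)]]
      piece <- tr[tr$frame %in% fr, c("track_id", "frame", "x", "y")]
      piece$track_id <- sprintf("%s@%d", id, segments$start_frame[k])
      rows[[length(rows) + 1L]] <- piece
    }
  }
  if (length(rows) == 0)
    return(spt_tracks(data.frame(track_id = character(), frame = integer(),
                                 x = numeric(), y = numeric()),
                      frame_period(tracks)))
  spt_tracks(do.call(rbind, rows), frame_period(tracks))
}
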