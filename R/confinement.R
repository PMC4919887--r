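#' Confinement index along a trajectory
#'
#' Probability-of-staying confinement quantification in the
#' Simson-Sheetz-Jacobson style. For every sliding window of `window`
#' frames the maximal excursion R from the window start is measured, and
#' the probability psi that free diffusion at `D_ref` stays within R over
#' the window duration `t` is evaluated with the standard log-linear
#' approximation `log10(psi) = 0.2048 - 2.5117 * D_ref * t / R^2`. The
#' window's index is `L = max(0, -log10(psi) - 1)`, so L is 0 wherever the
#' approximation gives psi near 1 (free-like excursions) and grows with
#' confinement strength and duration. Each frame is assigned the mean L
#' over all windows covering it.
#'
#' @param tracks a [spt_tracks] object.
#' @param window sliding window length, frames (>= 4).
#' @param D_ref reference free diffusion coefficient, um^2/s (e.g. the
#'   fast-population mode converted via [diffusion_coefficient()]).
#' @param tau frame period, seconds; defaults to the tracks' own.
#' @return a tibble `track_id`, `frame`, `L`. Tracks shorter than `window`
#'   (or interrupted by frame gaps into runs shorter than `window`)
#'   contribute no rows, with a warning.
#' @export
confinement_index <- function(tracks, window = 30, D_ref, tau = NULL) {
  if (window < 4) stop("window must be >= 4", call. = FALSE)
  if (missing(D_ref) || !is.numeric(D_ref) || D_ref <= 0)
    stop("D_ref must be > 0", call. = FALSE)
  if (is.null(tau)) tau <- frame_period(tracks)
  t_win <- (window - 1) * tau
  short <- character(0)
  pieces <- lapply(.track_split(tracks), function(tr) {
    runs <- split(seq_len(nrow(tr)), cumsum(c(1L, diff(tr$frame) != 1L)))
    out <- list()
    for (run in runs) {
      n <- length(run)
      if (n < window) next
      x <- tr$x[run]; y <- tr$y[run]
      nw <- n - window + 1L
      Lw <- numeric(nw)
      for (s in seq_len(nw)) {
        i <- s:(s + window - 1L)
        R2 <- max((x[i] - x[s])^2 + (y[i] - y[s])^2)
        R2 <- max(R2, 1e-12)
        Lw[s] <- max(0, 2.5117 * D_ref * t_win / R2 - 0.2048 - 1)
      }
      L <- vapply(seq_len(n), function(t) {
        ws <- max(1L, t - window + 1L):min(t, nw)
        mean(Lw[ws])
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        track_id = tr$track_id[1], frame = tr$frame[run], L = L,
        stringsAsFactors = FALSE)
    }
    if (length(out) == 0) { short <<- c(short, tr$track_id[1]); NULL }
    else do.call(rbind, out)
  })
  if (length(short) > 0)
    warning("track(s) shorter than the window skipped: ",
            paste(head(short, 5), collapse = ", "),
            if (length(short) > 5) " ...")
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0)
    return(tibble(track_id = character(), frame = integer(), L = numeric()))
  as_tibble(do.call(rbind, pieces))
}

#' Extract confined-diffusion events
#'
#' Turns the confinement-index series into discrete events: maximal runs
#' with `L >= threshold` are found per track, runs separated by fewer than
#' `min_gap` sub-threshold frames are merged, and merged runs shorter than
#' `min_duration` frames are discarded. Each event reports its maximal
#' index `L_max` and its radius (maximal distance of the event's
#' localizations from their centroid).
#'
#' Default constants (window 30 frames, threshold 3.16, minimum duration
#' 10 frames) are conventional operating values for receptor tracking at
#' 25 ms frame period; all are exposed.
#'
#' @param tracks a [spt_tracks] object.
#' @param L optional precomputed [confinement_index()] tibble; computed
#'   here when omitted.
#' @param threshold index threshold (> 0).
#' @param min_duration minimum event length, frames.
#' @param min_gap runs separated by fewer than this many frames merge.
#' @param ... passed on to [confinement_index()] when `L` is omitted
#'   (`window`, `D_ref`, `tau`).
#' @return a tibble `track_id`, `start_frame`, `end_frame`, `L_max`,
#'   `radius` (um); empty if no run qualifies.
#' @export
extract_confined_events <- function(tracks, L = NULL, threshold = 3.16,
                                    min_duration = 10, min_gap = 2, ...) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (is.null(L)) L <- confinement_index(tracks, ...)
  trs <- .track_split(tracks)
  pieces <- lapply(split(as.data.frame(L), L$track_id), function(ls) {
    above <- ls$L >= threshold
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    seg <- data.frame(s = starts[r$values], e = ends[r$values])
    if (nrow(seg) > 1) {                      # merge near-adjacent runs
      merged <- seg[1, , drop = FALSE]
      for (i in 2:nrow(seg)) {
        if (seg$s[i] - merged$e[nrow(merged)] - 1L < min_gap)
          merged$e[nrow(merged)] <- seg$e[i]
        else merged <- rbind(merged, seg[i, ])
      }
      seg <- merged
    }
    seg <- seg[seg$e - seg$s + 1L >= min_duration, , drop = FALSE]
    if (nrow(seg) == 0) return(NULL)
    tr <- trs[[as.character(ls$track_id[1])]]
    do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
      fr <- ls$frame[seg$s[i]:seg$e[i]]
      pos <- tr[tr$frame %in% fr, ]
      data.frame(track_id = ls$track_id[1],
                 start_frame = fr[1], end_frame = fr[length(fr)],
                 L_max = max(ls$L[seg$s[i]:seg$e[i]]),
                 radius = max(sqrt((pos$x - mean(pos$x))^2 +
                                     (pos$y - mean(pos$y))^2)),
                 stringsAsFactors = FALSE)
    }))
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0)
    return(tibble(track_id = character(), start_frame = integer(),
                  end_frame = integer(), L_max = numeric(), radius = numeric()))
  as_tibble(do.call(rbind, pieces))
}
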