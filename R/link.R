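#' Link per-frame detections into trajectories
#'
#' Connects the nearest positions in consecutive frames into
#' single-molecule trajectories by greedy mutual-nearest-neighbour
#' assignment: at each frame, a detection joins the open track whose last
#' position is its nearest neighbour *and* for which it is in turn the
#' nearest candidate, provided the distance does not exceed `max_disp`;
#' the mutual-pair extraction repeats until no admissible pair remains.
#' Unmatched detections seed new tracks; a track stays open across at most
#' `max_gap` missing frames. Every detection belongs to exactly one track
#' (singleton tracks are kept, so detections are conserved). Distance ties
#' resolve to the lower track id, making the output deterministic.
#'
#' @param detections a tibble as from [detect_spots()] (`frame`, `x`, `y`,
#'   optionally `intensity`); sorted internally by frame. Duplicated
#'   `(frame, x, y)` rows are kept with a warning.
#' @param max_disp gating distance, um (> 0). A sensible default for a
#'   maximum expected diffusion coefficient `D_max` is
#'   `4 * sqrt(4 * D_max * tau)`.
#' @param max_gap number of consecutive missing frames a track may bridge.
#' @param frame_period sampling interval, seconds (stored on the output).
#' @return a [spt_tracks] object; integer track ids in creation order.
#' @export
link_nearest <- function(detections, max_disp, max_gap = 0, frame_period = 0.025) {
  if (!is.numeric(max_disp) || max_disp <= 0)
    stop("max_disp must be > 0", call. = FALSE)
  if (max_gap < 0) stop("max_gap must be >= 0", call. = FALSE)
  det <- as.data.frame(detections)
  if (nrow(det) == 0)
    return(spt_tracks(data.frame(track_id = integer(), frame = integer(),
                                 x = numeric(), y = numeric()), frame_period))
  det <- det[order(det$frame), ]
  if (anyDuplicated(det[, c("frame", "x", "y")]))
    warning("duplicated (frame, x, y) detections kept")
  track_of <- integer(nrow(det))
  last_x <- numeric(0); last_y <- numeric(0); last_f <- integer(0)
  n_tracks <- 0L
  for (f in unique(det$frame)) {
    di <- which(det$frame == f)
    open <- which(last_f >= f - 1L - max_gap & last_f < f)
    un_d <- di                       # detection rows still unassigned
    un_t <- open                     # open tracks still unmatched
    while (length(un_d) > 0 && length(un_t) > 0) {
      dm <- outer(last_x[un_t], det$x[un_d], `-`)^2 +
        outer(last_y[un_t], det$y[un_d], `-`)^2
      dm[dm > max_disp^2] <- Inf
      if (!any(is.finite(dm))) break
      # mutual nearest neighbours; which.min takes the first (lowest id)
      bt <- apply(dm, 2, which.min)  # best track per detection
      bd <- apply(dm, 1, which.min)  # best detection per track
      mutual <- which(vapply(seq_along(bt), function(j)
        is.finite(dm[bt[j], j]) && bd[bt[j]] == j, logical(1)))
      if (length(mutual) == 0) break
      for (j in mutual) {
        tr <- un_t[bt[j]]; dr <- un_d[j]
        track_of[dr] <- tr
        last_x[tr] <- det$x[dr]; last_y[tr] <- det$y[dr]; last_f[tr] <- f
      }
      assigned_t <- un_t[bt[mutual]]
      un_d <- un_d[-mutual]
      un_t <- setdiff(un_t, assigned_t)
    }
    for (dr in un_d) {               # leftovers seed new tracks
      n_tracks <- n_tracks + 1L
      track_of[dr] <- n_tracks
      last_x[n_tracks] <- det$x[dr]; last_y[n_tracks] <- det$y[dr]
      last_f[n_tracks] <- f
    }
  }
  spt_tracks(data.frame(track_id = track_of, frame = det$frame,
                        x = det$x, y = det$y), frame_period)
}
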