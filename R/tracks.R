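#' Trajectory tables
#'
#' A trajectory table holds the time-ordered positions of one or more tracked
#' molecules: one row per localization, columns `track_id`, `frame`
#' (integer frame index), `x` and `y` (micrometres). The fixed sampling
#' interval is stored in the `frame_period` attribute (seconds). Frames must
#' be strictly increasing within a track; gaps are allowed (e.g. after
#' linking across missed detections) and are respected by every downstream
#' statistic.
#'
#' @param df data frame with columns `track_id`, `frame`, `x`, `y`.
#' @param frame_period sampling interval in seconds.
#' @return a `spt_tracks` tibble.
#' @examples
#' tr <- spt_tracks(data.frame(track_id = 1, frame = 1:3,
#'                             x = c(0, 3, 3), y = c(0, 4, 4)),
#'                  frame_period = 0.025)
#' frame_period(tr)
#' @export
spt_tracks <- function(df, frame_period = 0.025) {
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(frame_period) || length(frame_period) != 1 || frame_period <= 0)
    stop("frame_period must be a single positive number", call. = FALSE)
  df <- as_tibble(df[, need])
  df$frame <- as.integer(df$frame)
  if (anyNA(df$frame) || !all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("frame, x, y must be finite", call. = FALSE)
  df <- df[order(df$track_id, df$frame), ]
  # rows are normalized to frame order, so the residual failure mode is a
  # duplicated frame within a track
  bad <- tapply(df$frame, df$track_id, function(f) anyDuplicated(f) > 0)
  if (any(unlist(bad))) {
    stop("duplicated frame(s) in track(s): ",
         paste(names(bad)[unlist(bad)], collapse = ", "), call. = FALSE)
  }
  structure(df, class = c("spt_tracks", class(df)),
            frame_period = frame_period)
}

#' @rdname spt_tracks
#' @param x a `spt_tracks` object.
#' @export
frame_period <- function(x) {
  fp <- attr(x, "frame_period")
  if (is.null(fp)) stop("object carries no frame_period attribute", call. = FALSE)
  fp
}

#' @export
print.spt_tracks <- function(x, ...) {
  nt <- length(unique(x$track_id))
  cat(sprintf("<spt_tracks> %d localizations, %d track(s), frame period %g s\n",
              nrow(x), nt, frame_period(x)))
  NextMethod()
}

# split into per-track data frames, preserving order
.track_split <- function(tracks) {
  split(as.data.frame(tracks), tracks$track_id)
}

#' Read and write trajectory CSV files
#'
#' The on-disk format has columns `track_id, frame, x_um, y_um` (header
#' required, '.' decimal separator), one row per localization.
#'
#' @param path file path.
#' @param frame_period sampling interval in seconds (not stored in the CSV).
#' @return `read_tracks_csv` returns a [spt_tracks] object.
#' @export
read_tracks_csv <- function(path, frame_period = 0.025) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_tracks(df, frame_period = frame_period)
}

#' @rdname read_tracks_csv
#' @param tracks a [spt_tracks] object.
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- data.frame(track_id = tracks$track_id, frame = tracks$frame,
                   x_um = tracks$x, y_um = tracks$y)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a trajectory table
#'
#' Checks the schema (`track_id, frame, x_um, y_um` or the in-memory
#' `track_id, frame, x, y`), finiteness of every row, and strict frame
#' monotonicity within each track. Malformed rows are reported with their
#' row numbers; missing columns and non-monotone tracks are hard errors.
#'
#' @param df a data frame or a path to a trajectory CSV.
#' @param frame_period sampling interval in seconds.
#' @return a validated [spt_tracks] object.
#' @export
validate_tracks <- function(df, frame_period = 0.025) {
  if (is.character(df) && length(df) == 1)
    return(read_tracks_csv(df, frame_period = frame_period))
  nm <- names(df)
  if ("x_um" %in% nm) names(df)[nm == "x_um"] <- "x"
  if ("y_um" %in% nm) names(df)[nm == "y_um"] <- "y"
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df$frame <- suppressWarnings(as.numeric(df$frame))
  df$x <- suppressWarnings(as.numeric(df$x))
  df$y <- suppressWarnings(as.numeric(df$y))
  ok <- is.finite(df$frame) & is.finite(df$x) & is.finite(df$y) &
    df$frame == round(df$frame)
  if (!all(ok)) {
    bad <- which(!ok)
    stop("malformed row(s): ", paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10),
         call. = FALSE)
  }
  # frames must already be strictly increasing in input order per track
  mono <- tapply(df$frame, df$track_id, function(f) any(diff(f) <= 0))
  if (any(unlist(mono)))
    stop("non-monotone frames in track(s): ",
         paste(names(mono)[unlist(mono)], collapse = ", "), call. = FALSE)
  spt_tracks(df, frame_period = frame_period)
}
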