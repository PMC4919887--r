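#' Detect diffraction-limited spots in an image stack
#'
#' Per frame, the background level and spread are estimated robustly
#' (median and MAD); pixels that are 8-neighbourhood local maxima above
#' `background + threshold_sd * spread` become candidate spots, and each is
#' refined to sub-pixel precision by an intensity-weighted centroid over a
#' `(2 refine_radius + 1)^2` window of background-subtracted counts.
#' Coordinates are returned in micrometres using the pixel-centre
#' convention of [render_frames()]. An empty frame simply yields no
#' detections.
#'
#' @param stack array `height x width x n_frames` (or a single matrix).
#' @param pixel_size pixel size, um/px.
#' @param threshold_sd detection threshold in robust background SDs (> 0).
#' @param refine_radius half-width of the centroid window, px.
#' @return a tibble `frame`, `x`, `y` (um), `intensity`
#'   (background-subtracted counts in the window).
#' @export
detect_spots <- function(stack, pixel_size, threshold_sd = 6, refine_radius = 2) {
  if (threshold_sd <= 0) stop("threshold_sd must be > 0", call. = FALSE)
  if (length(dim(stack)) == 2) stack <- array(stack, dim = c(dim(stack), 1))
  if (length(dim(stack)) != 3 || any(dim(stack) == 0))
    stop("stack must be a non-empty height x width x frames array", call. = FALSE)
  H <- dim(stack)[1]; W <- dim(stack)[2]; r <- as.integer(refine_radius)
  rows <- list()
  for (fi in seq_len(dim(stack)[3])) {
    img <- stack[, , fi]
    bg <- median(img)
    sdv <- max(mad(img), 1e-9)
    thr <- bg + threshold_sd * sdv
    # 8-neighbourhood local maxima (strict against later neighbours so
    # plateaus yield a single detection)
    pad <- matrix(-Inf, H + 2, W + 2)
    pad[2:(H + 1), 2:(W + 1)] <- img
    nb <- function(di, dj) pad[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
    ismax <- img > thr &
      img >= nb(-1, 0) & img > nb(1, 0) &
      img >= nb(0, -1) & img > nb(0, 1) &
      img >= nb(-1, -1) & img > nb(1, 1) &
      img >= nb(-1, 1) & img > nb(1, -1)
    idx <- which(ismax, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      i0 <- idx[k, 1]; j0 <- idx[k, 2]
      ii <- max(1, i0 - r):min(H, i0 + r)
      jj <- max(1, j0 - r):min(W, j0 + r)
      wts <- pmax(img[ii, jj, drop = FALSE] - bg, 0)
      tot <- sum(wts)
      if (tot <= 0) next
      ci <- sum(rowSums(wts) * ii) / tot
      cj <- sum(colSums(wts) * jj) / tot
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fi, x = (cj - 0.5) * pixel_size, y = (ci - 0.5) * pixel_size,
        intensity = tot)
    }
  }
  if (length(rows) == 0)
    return(tibble(frame = integer(), x = numeric(), y = numeric(),
                  intensity = numeric()))
  as_tibble(do.call(rbind, rows))
}
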