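#' Synthetic image parameters
#'
#' Geometry and photophysics for rendering trajectories into
#' diffraction-limited image stacks.
#'
#' @param pixel_size pixel size, um/px.
#' @param width,height field size in pixels.
#' @param psf_sigma Gaussian PSF standard deviation, um.
#' @param photons expected photons per molecule per frame.
#' @param background expected background counts per pixel per frame.
#' @return an `image_params` list.
#' @export
image_params <- function(pixel_size = 0.16, width = 48, height = 48,
                         psf_sigma = 0.16, photons = 800, background = 50) {
  stopifnot(pixel_size > 0, width >= 4, height >= 4, psf_sigma > 0,
            photons >= 0, background >= 0)
  structure(list(pixel_size = pixel_size, width = as.integer(width),
                 height = as.integer(height), psf_sigma = psf_sigma,
                 photons = photons, background = background),
            class = "image_params")
}

#' Render trajectories into a 16-bit image stack
#'
#' One frame per time point over the full frame range of the input tracks:
#' each molecule present in a frame is drawn as a 2D Gaussian of total
#' intensity `photons` and width `psf_sigma`, added to a uniform
#' `background`, and the pixel values are Poisson-sampled (clipped to
#' 16 bits). Pixel (i, j) is centred at `((j - 0.5), (i - 0.5)) *
#' pixel_size` with x along columns and y along rows, the same convention
#' [detect_spots()] inverts. Molecules outside the field are skipped with
#' a warning.
#'
#' @param tracks a [spt_tracks] object with positions inside the field.
#' @param ip an [image_params()] object.
#' @param path optional file path; when given the stack is written as a
#'   multi-page 16-bit grayscale TIFF.
#' @param seed integer seed for the Poisson noise.
#' @return invisibly, the stack as an array `height x width x n_frames`
#'   of integer counts.
#' @export
render_frames <- function(tracks, ip = image_params(), path = NULL, seed = 1L) {
  stopifnot(inherits(ip, "image_params"))
  frames <- seq(min(tracks$frame), max(tracks$frame))
  W <- ip$width; H <- ip$height; ps <- ip$pixel_size
  xc <- (seq_len(W) - 0.5) * ps
  yc <- (seq_len(H) - 0.5) * ps
  s2 <- 2 * ip$psf_sigma^2
  amp <- ip$photons * ps^2 / (pi * s2)     # peak counts per pixel
  withr::local_seed(seed)
  stack <- array(0L, dim = c(H, W, length(frames)))
  clipped <- 0L
  for (fi in seq_along(frames)) {
    mu <- matrix(ip$background, H, W)
    rows <- tracks[tracks$frame == frames[fi], ]
    for (m in seq_len(nrow(rows))) {
      x <- rows$x[m]; y <- rows$y[m]
      if (x < 0 || x > W * ps || y < 0 || y > H * ps) {
        clipped <- clipped + 1L
        next
      }
      mu <- mu + amp * tcrossprod(exp(-(yc - y)^2 / s2), exp(-(xc - x)^2 / s2))
    }
    stack[, , fi] <- pmin(matrix(rpois(H * W, mu), H, W), 65535L)
  }
  if (clipped > 0)
    warning(clipped, " molecule-frame(s) outside the field were clipped")
  if (!is.null(path)) {
    pages <- lapply(seq_along(frames), function(i) stack[, , i] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(stack)
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file written by [render_frames()] or compatible.
#' @return an array `height x width x n_frames` of counts.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , i] <- round(p * 65535)
  }
  arr
}
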