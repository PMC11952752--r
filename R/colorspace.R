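# Color-space conversions for whole images, vectorized over pixels.
# RGB channels are 8-bit (0..255). Derived spaces:
#   hsv   : h in degrees [0, 360), s and v in [0, 1]
#   lab   : CIE L*a*b*, sRGB primaries, D65 reference white
#   ycbcr : ITU-R BT.601 full-range, all channels 0..255

#' Extract one color channel of a plate image as a matrix
#'
#' @param img a [plate_image].
#' @param space one of `"rgb"`, `"hsv"`, `"lab"`, `"ycbcr"`.
#' @param channel channel name within the space: rgb: r/g/b; hsv: h/s/v;
#'   lab: L/a/b; ycbcr: y/cb/cr.
#' @return numeric H x W matrix.
#' @export
channel_matrix <- function(img, space, channel) {
  stopifnot(inherits(img, "plate_image"))
  space <- tolower(space)
  h <- dim(img$pixels)[1]; w <- dim(img$pixels)[2]
  r <- as.vector(img$pixels[, , 1])
  g <- as.vector(img$pixels[, , 2])
  b <- as.vector(img$pixels[, , 3])
  vals <- switch(space,
    rgb = switch(channel, r = r, g = g, b = b,
                 stop_channel(space, channel)),
    hsv = {
      hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 255)
      switch(channel,
             h = hsv[1, ] * 360,
             s = hsv[2, ],
             v = hsv[3, ],
             stop_channel(space, channel))
    },
    lab = {
      lab <- grDevices::convertColor(cbind(r, g, b) / 255,
                                     from = "sRGB", to = "Lab")
      switch(channel, L = lab[, 1], a = lab[, 2], b = lab[, 3],
             stop_channel(space, channel))
    },
    ycbcr = switch(channel,
      y  = 0.299 * r + 0.587 * g + 0.114 * b,
      cb = 128 - 0.168736 * r - 0.331264 * g + 0.5 * b,
      cr = 128 + 0.5 * r - 0.418688 * g - 0.081312 * b,
      stop_channel(space, channel)),
    stop("unknown color space: ", space, call. = FALSE)
  )
  matrix(vals, nrow = h, ncol = w)
}

stop_channel <- function(space, channel) {
  stop("unknown channel '", channel, "' for color space '", space, "'",
       call. = FALSE)
}

#' Per-channel histogram equalization
#'
#' Applies the standard cumulative-histogram intensity remapping
#' independently to the R, G and B channels:
#' \deqn{v' = \mathrm{round}\left(255\,\frac{\mathrm{cdf}(v) -
#'   \mathrm{cdf}_{min}}{N - \mathrm{cdf}_{min}}\right)}
#' where \eqn{\mathrm{cdf}_{min}} is the cumulative count at the lowest
#' occupied intensity. A constant channel is returned unchanged (the
#' degenerate histogram has nothing to spread).
#'
#' @param img a [plate_image].
#' @return A [plate_image] of identical dimensions.
#' @export
equalize_image <- function(img) {
  stopifnot(inherits(img, "plate_image"))
  px <- img$pixels
  n <- dim(px)[1] * dim(px)[2]
  for (ch in 1:3) {
    v <- as.vector(px[, , ch])
    counts <- tabulate(v + 1L, nbins = 256L)
    cdf <- cumsum(counts)
    cdf_min <- cdf[which(counts > 0L)[1]]
    if (cdf_min == n) next                       # constant channel
    map <- as.integer(round(255 * (cdf - cdf_min) / (n - cdf_min)))
    map[map < 0L] <- 0L
    px[, , ch] <- map[v + 1L]
  }
  out <- img
  out$pixels <- px
  out
}
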