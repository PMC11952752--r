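#' Plate image container
#'
#' A `plate_image` wraps an H x W x 3 array of 8-bit RGB intensities together
#' with an image identifier and the imaging day (days after transfer to
#' treatment plates).
#'
#' @param pixels integer array of dimension H x W x 3 with values in 0..255.
#' @param image_id character scalar identifying the scan.
#' @param day non-negative integer, days after transfer.
#' @param layout optional plate layout `data.frame` with columns `plant_id`,
#'   `genotype`, `condition_mM` mapping left-to-right plant positions to
#'   genotype and NaCl concentration (mM).
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, image_id = "image", day = 0L, layout = NULL) {
  pixels <- validate_pixels(pixels)
  stopifnot(is.character(image_id), length(image_id) == 1L,
            length(day) == 1L, day >= 0)
  structure(
    list(pixels = pixels, image_id = image_id, day = as.integer(day),
         layout = layout),
    class = "plate_image"
  )
}

validate_pixels <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  d <- dim(pixels)
  if (d[3] != 3L)
    stop("plate images must have exactly 3 channels (RGB); got ", d[3],
         call. = FALSE)
  if (d[1] < 1L || d[2] < 1L) stop("empty image", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  storage.mode(pixels) <- "integer"
  pixels
}

#' @export
print.plate_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plate_image> %s  %d x %d px, day %d\n",
              x$image_id, d[1], d[2], x$day))
  invisible(x)
}

#' @export
dim.plate_image <- function(x) dim(x$pixels)

#' Read a plate scan from disk
#'
#' Supported formats: PNG, JPEG and plain-text PPM (P3 or binary P6). The
#' format is chosen by file extension. Images must be RGB; an alpha channel
#' is dropped, grayscale input is rejected.
#'
#' @param path path to the image file.
#' @inheritParams plate_image
#' @return A [plate_image].
#' @export
load_plate_image <- function(path, image_id = NULL, day = 0L, layout = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = try_decode(function() png::readPNG(path), path),
    jpg = ,
    jpeg = try_decode(function() jpeg::readJPEG(path), path),
    ppm = ,
    pnm = read_ppm(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (ext %in% c("png", "jpg", "jpeg")) {
    if (length(dim(arr)) == 2L)
      stop("grayscale images are not supported: ", path, call. = FALSE)
    nch <- dim(arr)[3]
    if (nch == 4L) arr <- arr[, , 1:3, drop = FALSE]      # drop alpha
    if (dim(arr)[3] != 3L)
      stop("expected an RGB image, got ", nch, " channel(s): ", path,
           call. = FALSE)
    arr <- array(as.integer(round(arr * 255)), dim = dim(arr))
  }
  if (is.null(image_id))
    image_id <- tools::file_path_sans_ext(basename(path))
  plate_image(arr, image_id = image_id, day = day, layout = layout)
}

try_decode <- function(fn, path) {
  out <- tryCatch(fn(), error = function(e)
    stop("cannot decode image ", path, ": ", conditionMessage(e),
         call. = FALSE))
  out
}

#' Write a plate image as PNG
#'
#' @param img a [plate_image].
#' @param path output path (.png).
#' @return `path`, invisibly.
#' @export
write_plate_png <- function(img, path) {
  stopifnot(inherits(img, "plate_image"))
  png::writePNG(img$pixels / 255, target = path)
  invisible(path)
}

# Plain-text PPM (P3) / binary PPM (P6) reader; returns an integer H x W x 3
# array. PPM stores pixels row by row, RGB interleaved.
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_ppm_token(con)
  if (!magic %in% c("P3", "P6"))
    stop("not a PPM file (magic ", magic, "): ", path, call. = FALSE)
  w <- as.integer(read_ppm_token(con))
  h <- as.integer(read_ppm_token(con))
  maxval <- as.integer(read_ppm_token(con))
  if (anyNA(c(w, h, maxval)) || maxval <= 0 || maxval > 255)
    stop("malformed PPM header: ", path, call. = FALSE)
  n <- 3L * w * h
  if (magic == "P3") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    vals <- as.integer(readBin(con, "integer", n = n, size = 1L,
                               signed = FALSE))
  }
  if (length(vals) < n) stop("truncated PPM file: ", path, call. = FALSE)
  arr <- array(0L, dim = c(h, w, 3))
  m <- matrix(vals, nrow = 3L)                 # channels fastest
  for (ch in 1:3)
    arr[, , ch] <- matrix(m[ch, ], nrow = h, ncol = w, byrow = TRUE)
  if (maxval != 255L) arr <- array(as.integer(round(arr * 255 / maxval)),
                                   dim = dim(arr))
  arr
}

# Reads one whitespace-delimited token, skipping '#' comments.
read_ppm_token <- function(con) {
  tok <- character(0)
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || ch == "") {
      if (length(tok)) break
      stop("unexpected end of PPM header", call. = FALSE)
    }
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || ch %in% c("\n", "")) break
      }
      next
    }
    if (grepl("^[[:space:]]$", ch)) {
      if (length(tok)) break else next
    }
    tok <- c(tok, ch)
  }
  paste(tok, collapse = "")
}

#' Write a plate image as plain-text PPM (P3)
#'
#' Useful for small text-only fixtures.
#'
#' @inheritParams write_plate_png
#' @export
write_plate_ppm <- function(img, path) {
  stopifnot(inherits(img, "plate_image"))
  px <- img$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  # interleave RGB row by row
  rows <- vapply(seq_len(h), function(r) {
    trip <- rbind(px[r, , 1], px[r, , 2], px[r, , 3])
    paste(as.vector(trip), collapse = " ")
  }, character(1))
  writeLines(c("P3", paste(w, h), "255", rows), path)
  invisible(path)
}

#' Write a pixel class map as a palette PNG
#'
#' Palette: root = white, shoot = green, background = black.
#'
#' @param cmap a [class_map].
#' @param path output path (.png).
#' @export
write_label_png <- function(cmap, path) {
  stopifnot(inherits(cmap, "class_map"))
  lab <- unclass(cmap)
  h <- nrow(lab); w <- ncol(lab)
  arr <- array(0, dim = c(h, w, 3))
  root <- lab == CLASS_ROOT
  shoot <- lab == CLASS_SHOOT
  for (ch in 1:3) {
    pl <- arr[, , ch]
    pl[root] <- 1
    pl[shoot] <- if (ch == 2) 1 else 0
    arr[, , ch] <- pl
  }
  png::writePNG(arr, target = path)
  invisible(path)
}
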