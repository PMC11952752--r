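#' A single color-threshold condition
#'
#' A condition keeps pixels whose value in `channel` of `space` lies in
#' `[low, high]`. All conditions attached to one pixel class are combined
#' conjunctively (logical AND).
#'
#' @param space color space, one of `"rgb"`, `"hsv"`, `"lab"`, `"ycbcr"`.
#' @param channel channel name within the space (see [channel_matrix]).
#' @param low,high inclusive bounds, `low <= high`. HSV hue is in degrees.
#' @return A `color_rule` list.
#' @export
color_rule <- function(space, channel, low, high) {
  space <- tolower(space)
  known <- list(rgb = c("r", "g", "b"), hsv = c("h", "s", "v"),
                lab = c("L", "a", "b"), ycbcr = c("y", "cb", "cr"))
  if (!space %in% names(known))
    stop("unknown color space: ", space, call. = FALSE)
  if (!channel %in% known[[space]])
    stop("unknown channel '", channel, "' for color space '", space, "'",
         call. = FALSE)
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L)
  if (low > high) stop("color_rule: low > high", call. = FALSE)
  structure(list(space = space, channel = channel, low = low, high = high),
            class = "color_rule")
}

#' Segmentation parameters
#'
#' Holds the pixel-classification rule sets and the mask-cleanup /
#' plant-extraction settings. The defaults target scanned agar plates where
#' shoots are green (mid hue, saturated), roots near-achromatic bright
#' (white on the scan) and the agar background blue or dark:
#'
#' * shoot: HSV hue in \[60, 180\] degrees AND saturation >= 0.25 AND
#'   value >= 0.20
#' * root: HSV saturation <= 0.20 AND value >= 0.60
#' * background: everything else
#'
#' Classification priority is shoot > root > background, so a pixel matching
#' both rule sets is labelled shoot.
#'
#' @param shoot_rules,root_rules lists of [color_rule]s, combined with AND.
#' @param min_island_px connected components (per class) smaller than this
#'   are removed as noise islands.
#' @param remove_border_objects drop foreground components touching the
#'   image border band.
#' @param border_margin_px width in px of the border band (0 disables).
#' @param bridge_radius_px dilation radius used to bridge the shoot-root
#'   junction before connected-components plant extraction.
#' @param connectivity pixel connectivity, 4 or 8.
#' @param equalize apply per-channel histogram equalization before
#'   classification.
#' @return A `seg_params` list.
#' @export
seg_params <- function(shoot_rules = list(
                         color_rule("hsv", "h", 60, 180),
                         color_rule("hsv", "s", 0.25, 1),
                         color_rule("hsv", "v", 0.20, 1)),
                       root_rules = list(
                         color_rule("hsv", "s", 0, 0.20),
                         color_rule("hsv", "v", 0.60, 1)),
                       min_island_px = 20L,
                       remove_border_objects = TRUE,
                       border_margin_px = 2L,
                       bridge_radius_px = 5L,
                       connectivity = 8L,
                       equalize = FALSE) {
  stopifnot(length(shoot_rules) >= 1L, length(root_rules) >= 1L)
  check_rules <- function(rules, what) {
    for (r in rules)
      if (!inherits(r, "color_rule"))
        stop(what, " must be a list of color_rule objects", call. = FALSE)
  }
  check_rules(shoot_rules, "shoot_rules")
  check_rules(root_rules, "root_rules")
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  stopifnot(min_island_px >= 0, border_margin_px >= 0, bridge_radius_px >= 0)
  structure(list(shoot_rules = shoot_rules, root_rules = root_rules,
                 min_island_px = as.integer(min_island_px),
                 remove_border_objects = isTRUE(remove_border_objects),
                 border_margin_px = as.integer(border_margin_px),
                 bridge_radius_px = as.integer(bridge_radius_px),
                 connectivity = as.integer(connectivity),
                 equalize = isTRUE(equalize)),
            class = "seg_params")
}

new_class_map <- function(labels) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  structure(labels, class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- tabulate(unclass(x) + 1L, nbins = 3L)
  cat(sprintf("<class_map> %d x %d px: %d background, %d root, %d shoot\n",
              nrow(x), ncol(x), tab[1], tab[2], tab[3]))
  invisible(x)
}

rules_mask <- function(img, rules) {
  mask <- NULL
  for (r in rules) {
    ch <- channel_matrix(img, r$space, r$channel)
    m <- ch >= r$low & ch <= r$high
    mask <- if (is.null(mask)) m else mask & m
  }
  mask
}

#' Classify plate pixels into root, shoot and background
#'
#' Every pixel gets exactly one label. A pixel is labelled shoot if it
#' satisfies all shoot rules, otherwise root if it satisfies all root rules,
#' otherwise background. No white-balance correction is applied; the
#' trichotomy of white/green/blue targets makes it unnecessary.
#'
#' @param img a [plate_image].
#' @param params a [seg_params].
#' @return A `class_map`: integer H x W matrix with values 0 (background),
#'   1 (root), 2 (shoot).
#' @export
classify_pixels <- function(img, params = seg_params()) {
  stopifnot(inherits(img, "plate_image"), inherits(params, "seg_params"))
  if (params$equalize) img <- equalize_image(img)
  shoot <- rules_mask(img, params$shoot_rules)
  root <- rules_mask(img, params$root_rules)
  lab <- matrix(CLASS_BACKGROUND, nrow = dim(img$pixels)[1],
                ncol = dim(img$pixels)[2])
  lab[root] <- CLASS_ROOT
  lab[shoot] <- CLASS_SHOOT       # shoot priority over root
  new_class_map(lab)
}

#' Remove noise islands and border-touching objects from a class map
#'
#' Per non-background class, connected components smaller than
#' `min_island_px` are relabelled background. If `remove_border_objects` is
#' set, components of the combined foreground mask having any pixel within
#' `border_margin_px` of the image border are relabelled background (plate
#' frame and condensation artifacts). The operation is idempotent.
#'
#' @inheritParams classify_pixels
#' @param cmap a `class_map` from [classify_pixels].
#' @return A cleaned `class_map`.
#' @export
clean_class_map <- function(cmap, params = seg_params()) {
  stopifnot(inherits(cmap, "class_map"), inherits(params, "seg_params"))
  lab <- unclass(cmap)
  for (cls in c(CLASS_ROOT, CLASS_SHOOT)) {
    mask <- lab == cls
    if (!any(mask) || params$min_island_px <= 0L) next
    comp <- .cc_label(mask, params$connectivity)
    sizes <- tabulate(comp[comp > 0L])
    drop <- which(sizes < params$min_island_px)
    if (length(drop)) lab[comp %in% drop] <- CLASS_BACKGROUND
  }
  if (params$remove_border_objects && params$border_margin_px > 0L) {
    fg <- lab != CLASS_BACKGROUND
    if (any(fg)) {
      comp <- .cc_label(fg, params$connectivity)
      m <- params$border_margin_px
      nr <- nrow(lab); nc <- ncol(lab)
      band <- matrix(FALSE, nr, nc)
      band[seq_len(min(m, nr)), ] <- TRUE
      band[seq(to = nr, length.out = min(m, nr)), ] <- TRUE
      band[, seq_len(min(m, nc))] <- TRUE
      band[, seq(to = nc, length.out = min(m, nc))] <- TRUE
      drop <- unique(comp[band & comp > 0L])
      if (length(drop)) lab[comp %in% drop] <- CLASS_BACKGROUND
    }
  }
  new_class_map(lab)
}

#' Extract individual plants by connected-components analysis
#'
#' The union foreground mask (root + shoot) is dilated by
#' `bridge_radius_px` to bridge the shoot-root junction, labelled with the
#' configured connectivity, and the component labels are transferred back to
#' the undilated foreground pixels. One `plant_region` is returned per
#' component, ordered left to right by centroid column; `plant_id` follows
#' that order. If `expected_n` is given and the detected count differs, the
#' result carries a QC flag (attribute `qc_flag`) — it is never silently
#' altered.
#'
#' @inheritParams clean_class_map
#' @param expected_n optional expected number of plants on the plate.
#' @return List of `plant_region` objects. Each has `plant_id`, `pixels`
#'   (linear indices into the map, column-major), `centroid` (row, col),
#'   `bbox` (0-based half-open: r0, c0, r1, c1), `root_px`, `shoot_px`.
#'   Attribute `qc_flag` is `""` or a mismatch message.
#' @export
extract_plants <- function(cmap, params = seg_params(), expected_n = NULL) {
  stopifnot(inherits(cmap, "class_map"), inherits(params, "seg_params"))
  lab <- unclass(cmap)
  fg <- lab != CLASS_BACKGROUND
  regions <- list()
  if (any(fg)) {
    dil <- if (params$bridge_radius_px > 0L)
      .dilate_disc(fg, params$bridge_radius_px) else fg
    comp <- .cc_label(dil, params$connectivity)
    idx <- which(fg)
    groups <- split(idx, comp[idx])
    nr <- nrow(lab)
    regions <- lapply(groups, function(px) {
      rows <- (px - 1L) %% nr + 1L
      cols <- (px - 1L) %/% nr + 1L
      structure(list(
        plant_id = NA_integer_,
        pixels = px,
        centroid = c(row = mean(rows), col = mean(cols)),
        bbox = c(r0 = min(rows) - 1L, c0 = min(cols) - 1L,
                 r1 = max(rows), c1 = max(cols)),
        root_px = sum(lab[px] == CLASS_ROOT),
        shoot_px = sum(lab[px] == CLASS_SHOOT)
      ), class = "plant_region")
    })
    ord <- order(vapply(regions, function(r) r$centroid[["col"]], numeric(1)))
    regions <- regions[ord]
    names(regions) <- NULL
    for (i in seq_along(regions)) regions[[i]]$plant_id <- i
  }
  qc <- ""
  if (!is.null(expected_n) && length(regions) != expected_n)
    qc <- sprintf("expected_n_mismatch:expected=%d;found=%d",
                  as.integer(expected_n), length(regions))
  attr(regions, "qc_flag") <- qc
  regions
}

#' @export
print.plant_region <- function(x, ...) {
  cat(sprintf(
    "<plant_region> id %s: %d root px, %d shoot px, centroid (%.1f, %.1f)\n",
    x$plant_id, x$root_px, x$shoot_px, x$centroid[["row"]],
    x$centroid[["col"]]))
  invisible(x)
}

#' Tabulate per-plant pixel areas
#'
#' @param regions list of `plant_region`s from [extract_plants].
#' @param layout `data.frame` with columns `plant_id`, `genotype`,
#'   `condition_mM` mapping plate positions to metadata.
#' @param image_id,day identifiers copied into every row.
#' @return `data.frame` with columns image_id, plant_id, genotype,
#'   condition_mM, day, root_px, shoot_px, total_px, qc_flag.
#' @export
measure_plants <- function(regions, layout, image_id = "image", day = 0L) {
  stopifnot(is.data.frame(layout),
            all(c("plant_id", "genotype", "condition_mM") %in% names(layout)))
  qc <- attr(regions, "qc_flag")
  if (is.null(qc)) qc <- ""
  if (length(regions) == 0L)
    return(data.frame(image_id = character(0), plant_id = integer(0),
                      genotype = character(0), condition_mM = numeric(0),
                      day = integer(0), root_px = integer(0),
                      shoot_px = integer(0), total_px = integer(0),
                      qc_flag = character(0), stringsAsFactors = FALSE))
  rows <- lapply(regions, function(r) {
    m <- match(r$plant_id, layout$plant_id)
    if (is.na(m))
      stop("plant_id ", r$plant_id, " not present in plate layout",
           call. = FALSE)
    data.frame(image_id = image_id, plant_id = r$plant_id,
               genotype = as.character(layout$genotype[m]),
               condition_mM = layout$condition_mM[m],
               day = as.integer(day),
               root_px = r$root_px, shoot_px = r$shoot_px,
               total_px = r$root_px + r$shoot_px,
               qc_flag = qc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Segment one plate image end to end
#'
#' Classification, mask cleanup, plant extraction and measurement in one
#' call, using the layout stored on the image.
#'
#' @inheritParams classify_pixels
#' @param expected_n optional expected plant count (defaults to the number
#'   of layout rows if a layout is attached).
#' @return list with elements `class_map`, `regions`, `measurements`.
#' @export
segment_plate <- function(img, params = seg_params(), expected_n = NULL) {
  stopifnot(inherits(img, "plate_image"))
  if (is.null(expected_n) && !is.null(img$layout))
    expected_n <- nrow(img$layout)
  cmap <- clean_class_map(classify_pixels(img, params), params)
  regions <- extract_plants(cmap, params, expected_n = expected_n)
  layout <- img$layout
  if (is.null(layout))
    layout <- data.frame(plant_id = seq_along(regions),
                         genotype = NA_character_,
                         condition_mM = NA_real_)
  extra <- setdiff(vapply(regions, `[[`, integer(1), "plant_id"),
                   layout$plant_id)
  if (length(extra)) {
    # surplus detections (QC-flagged): carry them with NA metadata rather
    # than aborting the plate
    pad <- layout[rep(1L, length(extra)), , drop = FALSE]
    pad$plant_id <- extra
    pad$genotype <- NA_character_
    pad$condition_mM <- NA_real_
    layout <- rbind(layout, pad)
  }
  meas <- measure_plants(regions, layout, image_id = img$image_id,
                         day = img$day)
  list(class_map = cmap, regions = regions, measurements = meas)
}
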