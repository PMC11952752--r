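#' Specification of a synthetic agar plate
#'
#' Describes the geometry and colors of a simulated flat-bed scan: shoots
#' are filled discs (rosette proxy), roots are narrow vertical traces with
#' small lateral jitter, the junction overlaps by one pixel so the two
#' organs always form one connected plant. Class colors default to the
#' scanned-plate trichotomy (green shoot, white root, blue agar) and can be
#' jittered with per-channel Gaussian noise.
#'
#' @param width,height image size in px.
#' @param n_plants number of plants, placed left to right.
#' @param shoot_radius rosette disc radius (px).
#' @param root_length,root_width root trace length and width (px).
#' @param colors list with `shoot`, `root`, `background` RGB triples
#'   (0..255).
#' @param jitter_sd per-channel Gaussian color noise SD (intensity units).
#' @param min_gap minimum horizontal gap between plant extents; the default
#'   12 px exceeds twice the default bridge radius plus one, so distinct
#'   plants can never be bridged together.
#' @param seed optional RNG seed for reproducible plates.
#' @return A `plate_spec` list.
#' @export
plate_spec <- function(width = 300L, height = 160L, n_plants = 5L,
                       shoot_radius = 8L, root_length = 60L,
                       root_width = 2L,
                       colors = list(shoot = c(0, 160, 40),
                                     root = c(250, 250, 250),
                                     background = c(40, 60, 160)),
                       jitter_sd = 0, min_gap = 12L, seed = NULL) {
  stopifnot(width > 0, height > 0, n_plants >= 1, shoot_radius >= 2,
            root_length >= 10, root_width >= 1, jitter_sd >= 0,
            all(c("shoot", "root", "background") %in% names(colors)))
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_plants = as.integer(n_plants),
                 shoot_radius = as.integer(shoot_radius),
                 root_length = as.integer(root_length),
                 root_width = as.integer(root_width),
                 colors = colors, jitter_sd = jitter_sd,
                 min_gap = as.integer(min_gap), seed = seed),
            class = "plate_spec")
}

#' Generate a synthetic plate image with exact ground truth
#'
#' @param spec a [plate_spec].
#' @param image_id,day,genotypes,condition_mM metadata attached to the
#'   image and its layout (genotypes defaults to `g1..gN`).
#' @return list with `image` (a [plate_image] with layout), `truth`
#'   (`data.frame` plant_id, root_px, shoot_px, total_px — exact drawn
#'   counts), and `label_map` (the ground-truth `class_map`).
#' @export
generate_plate <- function(spec, image_id = "synthetic_plate", day = 0L,
                           genotypes = NULL, condition_mM = 0) {
  stopifnot(inherits(spec, "plate_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  h <- spec$height; w <- spec$width; np <- spec$n_plants
  sr <- spec$shoot_radius
  max_jitter <- 3L
  half_extent <- max(sr, max_jitter + spec$root_width)
  spacing <- w / np
  if (spacing - 2 * half_extent < spec$min_gap)
    stop("infeasible placement: ", np, " plants do not fit in width ", w,
         " with min_gap ", spec$min_gap, call. = FALSE)
  top_row <- 6L + sr
  bottom <- top_row + sr + spec$root_length
  if (bottom > h - 6L)
    stop("infeasible placement: root length exceeds plate height",
         call. = FALSE)
  lab <- matrix(CLASS_BACKGROUND, h, w)
  truth <- data.frame(plant_id = integer(0), root_px = integer(0),
                      shoot_px = integer(0))
  for (i in seq_len(np)) {
    cx <- as.integer(round((i - 0.5) * spacing))
    # root: vertical trace with bounded lateral random walk, drawn first
    start_row <- top_row + sr          # 1 px inside the disc boundary
    steps <- sample(c(-1L, 0L, 1L), spec$root_length, replace = TRUE)
    offset <- pmin(pmax(cumsum(steps), -max_jitter), max_jitter)
    for (j in seq_len(spec$root_length)) {
      r <- start_row + j - 1L
      c0 <- cx + offset[j]
      cc <- c0:(c0 + spec$root_width - 1L)
      lab[r, cc] <- CLASS_ROOT
    }
    # shoot disc overwrites the 1 px junction overlap
    rr <- (top_row - sr):(top_row + sr)
    for (r in rr) {
      dx <- floor(sqrt(sr^2 - (r - top_row)^2))
      lab[r, (cx - dx):(cx + dx)] <- CLASS_SHOOT
    }
    truth <- rbind(truth, data.frame(plant_id = i, root_px = 0L,
                                     shoot_px = 0L))
  }
  # per-plant truth counts from the final label map (left-to-right order)
  fg <- lab != CLASS_BACKGROUND
  comp <- .cc_label(fg, 8L)
  idx <- which(fg)
  cols <- (idx - 1L) %/% h + 1L
  cent <- tapply(cols, comp[idx], mean)
  ord <- order(cent)
  ids <- as.integer(names(cent))[ord]
  if (length(ids) != np)
    stop("internal: drawn plants are not ", np, " connected components",
         call. = FALSE)
  for (i in seq_len(np)) {
    member <- idx[comp[idx] == ids[i]]
    truth$root_px[i] <- sum(lab[member] == CLASS_ROOT)
    truth$shoot_px[i] <- sum(lab[member] == CLASS_SHOOT)
  }
  truth$total_px <- truth$root_px + truth$shoot_px
  # paint the image
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(spec$colors$background[ch], h, w)
    plane[lab == CLASS_ROOT] <- spec$colors$root[ch]
    plane[lab == CLASS_SHOOT] <- spec$colors$shoot[ch]
    if (spec$jitter_sd > 0)
      plane <- plane + matrix(rnorm(h * w, 0, spec$jitter_sd), h, w)
    px[, , ch] <- pmin(pmax(round(plane), 0), 255)
  }
  if (is.null(genotypes)) genotypes <- paste0("g", seq_len(np))
  layout <- data.frame(plant_id = seq_len(np), genotype = genotypes,
                       condition_mM = condition_mM,
                       stringsAsFactors = FALSE)
  img <- plate_image(array(as.integer(px), dim = dim(px)),
                     image_id = image_id, day = day, layout = layout)
  list(image = img, truth = truth, label_map = new_class_map(lab))
}

#' Specification of a synthetic growth series
#'
#' Areas follow \eqn{A(t) = A_0 e^{rt} \epsilon_t} with
#' \eqn{\ln \epsilon_t \sim N(0, \sigma^2)} (multiplicative log-normal
#' noise); `sigma = 0` gives the exact exponential curve.
#'
#' @param A0 initial area (px, > 0).
#' @param r true growth rate per day.
#' @param days day grid (default the every-second-day scan schedule
#'   0, 2, 4, 6, 8).
#' @param sigma log-scale noise SD.
#' @param seed optional RNG seed.
#' @return A `series_spec` list.
#' @export
series_spec <- function(A0 = 100, r = 0.3, days = c(0, 2, 4, 6, 8),
                        sigma = 0.1, seed = NULL) {
  stopifnot(A0 > 0, sigma >= 0, length(days) >= 1)
  structure(list(A0 = A0, r = r, days = days, sigma = sigma, seed = seed),
            class = "series_spec")
}

#' Generate a synthetic area time series
#'
#' @param spec a [series_spec].
#' @return list with `series` (`data.frame` day, area_px) and `true_rate`.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  eps <- if (spec$sigma > 0) exp(rnorm(length(spec$days), 0, spec$sigma))
         else rep(1, length(spec$days))
  area <- spec$A0 * exp(spec$r * spec$days) * eps
  list(series = data.frame(day = spec$days, area_px = area),
       true_rate = spec$r)
}

#' Generate a genotype matrix with haplotype-structured phenotypes
#'
#' Accessions are assigned to `n_haplotypes` distinct binary SNP patterns
#' (near-equal group sizes); the phenotype of an accession is its
#' haplotype's effect plus Gaussian noise.
#'
#' @param n_accessions,n_snps,n_haplotypes design dimensions
#'   (`n_haplotypes <= min(n_accessions, 2^n_snps)`).
#' @param effects numeric vector of haplotype effects (length
#'   `n_haplotypes`; default `0, 1, ..., n_haplotypes - 1`).
#' @param sigma phenotype noise SD.
#' @param seed optional RNG seed.
#' @return list with `genotypes` (`data.frame`: accession + SNP columns),
#'   `phenotypes` (`data.frame`: accession, value), `truth` (`data.frame`:
#'   accession, haplotype index, pattern, effect).
#' @export
generate_genotypes <- function(n_accessions = 60L, n_snps = 8L,
                               n_haplotypes = 3L, effects = NULL,
                               sigma = 1, seed = NULL) {
  stopifnot(n_haplotypes >= 1, n_haplotypes <= n_accessions,
            n_haplotypes <= 2^n_snps, sigma >= 0)
  if (is.null(effects)) effects <- seq_len(n_haplotypes) - 1
  stopifnot(length(effects) == n_haplotypes)
  if (!is.null(seed)) set.seed(seed)
  # distinct haplotype patterns
  pats <- character(0)
  while (length(pats) < n_haplotypes) {
    p <- paste(sample(0:1, n_snps, replace = TRUE), collapse = "")
    if (!p %in% pats) pats <- c(pats, p)
  }
  hap <- sample(rep(seq_len(n_haplotypes), length.out = n_accessions))
  acc <- sprintf("acc%03d", seq_len(n_accessions))
  mat <- t(vapply(hap, function(i)
    as.integer(strsplit(pats[i], "")[[1]]), integer(n_snps)))
  colnames(mat) <- paste0("snp", seq_len(n_snps))
  genotypes <- data.frame(accession = acc, mat, stringsAsFactors = FALSE)
  value <- effects[hap] + rnorm(n_accessions, 0, sigma)
  list(genotypes = genotypes,
       phenotypes = data.frame(accession = acc, value = value,
                               stringsAsFactors = FALSE),
       truth = data.frame(accession = acc, haplotype = hap,
                          pattern = pats[hap], effect = effects[hap],
                          stringsAsFactors = FALSE))
}
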