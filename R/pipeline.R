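# End-to-end plumbing: CSV schemas, config files, and the three pipeline
# stages (segment -> growth -> association) behind the command-line tool.

SEG_SCHEMA <- c("image_id", "plant_id", "genotype", "condition_mM", "day",
                "root_px", "shoot_px", "total_px")
ASSOC_SCHEMA <- c("snp_id", "chrom", "pos", "mac", "pvalue", "trait")

check_schema <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read a segmentation results table
#'
#' @param path CSV with columns image_id, plant_id, genotype, condition_mM,
#'   day, root_px, shoot_px, total_px (qc_flag optional).
#' @return validated `data.frame`.
#' @export
read_segmentation_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, SEG_SCHEMA, basename(path))
  df
}

#' Read a SNP association table
#'
#' @param path CSV with columns snp_id, chrom, pos, mac, pvalue, trait.
#' @return validated `data.frame`.
#' @export
read_association_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, ASSOC_SCHEMA, basename(path))
  if (any(df$pvalue <= 0 | df$pvalue > 1, na.rm = TRUE))
    stop(basename(path), ": pvalue must lie in (0, 1]", call. = FALSE)
  df
}

#' Read an accession-by-SNP genotype matrix
#'
#' @param path CSV whose first column is `accession`; remaining columns are
#'   SNP ids with cells 0, 1 or empty (missing).
#' @return validated `data.frame`.
#' @export
read_genotype_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "accession")
    stop(basename(path), ": first column must be 'accession'",
         call. = FALSE)
  df
}

#' Read a run configuration file (YAML or JSON)
#'
#' Recognized sections: `segmentation` (any [seg_params] argument),
#' `growth` (`outlier_sd`, `control_mM`), `association` (`alpha`,
#' `mac_cutoffs`, `window_bp`, `snp_subset`, `min_accessions`), `seed`.
#' Missing entries fall back to package defaults.
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return nested list with a fully populated configuration.
#' @export
read_run_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
           else yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  seg_args <- raw$segmentation
  # rules, if given, come as lists of {space, channel, low, high}
  for (side in c("shoot_rules", "root_rules")) {
    if (!is.null(seg_args[[side]]))
      seg_args[[side]] <- lapply(seg_args[[side]], function(r)
        color_rule(r$space, r$channel, r$low, r$high))
  }
  growth <- raw$growth
  assoc <- raw$association
  list(
    segmentation = do.call(seg_params, as.list(seg_args)),
    growth = list(
      outlier_sd = growth$outlier_sd %||% 3,
      control_mM = growth$control_mM %||% 0),
    association = list(
      alpha = assoc$alpha %||% 0.05,
      mac_cutoffs = assoc$mac_cutoffs %||% c(5, 10),
      window_bp = assoc$window_bp %||% 10000,
      snp_subset = assoc$snp_subset,
      min_accessions = assoc$min_accessions %||% 3),
    seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment a batch of plate images
#'
#' @param image_paths character vector of image files (PNG/JPEG/PPM).
#' @param layout `data.frame` with columns image_id, day, plant_id,
#'   genotype, condition_mM; rows are matched to images by `image_id`
#'   (file name without extension).
#' @param params a [seg_params].
#' @return segmentation `data.frame` (one row per detected plant per
#'   image) with a `qc_flag` column.
#' @export
run_segment <- function(image_paths, layout, params = seg_params()) {
  if (length(image_paths) == 0L)
    stop("no input images found", call. = FALSE)
  check_schema(layout, c("image_id", "day", "plant_id", "genotype",
                         "condition_mM"), "layout")
  out <- lapply(image_paths, function(p) {
    id <- tools::file_path_sans_ext(basename(p))
    lay <- layout[layout$image_id == id, , drop = FALSE]
    if (nrow(lay) == 0L)
      stop("no layout rows for image ", id, call. = FALSE)
    day <- lay$day[1]
    img <- load_plate_image(p, image_id = id, day = day,
                            layout = lay[c("plant_id", "genotype",
                                           "condition_mM")])
    segment_plate(img, params)$measurements
  })
  do.call(rbind, out)
}

#' Fit growth rates and derive downstream growth statistics
#'
#' Per plant (genotype x condition x plant_id) and organ (root, shoot,
#' total), fits the exponential rate over days; then removes within-group
#' rate outliers (beyond `outlier_sd` SD), computes genotype means, salt
#' tolerance indices against the control condition, per-plant root:shoot
#' rate ratios with the variance-coordination test, and population-wide
#' relative growth fractions.
#'
#' @param seg segmentation `data.frame` (see [read_segmentation_csv]).
#' @param outlier_sd SD multiple for the outlier pass (default 3).
#' @param control_mM control condition label (default 0).
#' @return list with `fits`, `summary`, `sti`, `ratios`, `coordination`
#'   (NULL if fewer than two eligible treatment groups), `fractions`.
#' @export
run_growth <- function(seg, outlier_sd = 3, control_mM = 0) {
  check_schema(seg, SEG_SCHEMA, "segmentation table")
  key <- interaction(seg$genotype, seg$condition_mM, seg$plant_id,
                     drop = TRUE)
  fits <- list()
  for (g in levels(key)) {
    d <- seg[key == g, , drop = FALSE]
    for (organ in c("root", "shoot", "total")) {
      area <- d[[paste0(organ, "_px")]]
      rec <- data.frame(genotype = d$genotype[1], plant_id = d$plant_id[1],
                        condition_mM = d$condition_mM[1], organ = organ,
                        rate = NA_real_, intercept = NA_real_,
                        r2 = NA_real_, n_points = 0L, flag = "",
                        stringsAsFactors = FALSE)
      fit <- tryCatch(fit_exponential(d$day, area), error = function(e) e)
      if (inherits(fit, "error")) {
        rec$flag <- "fit_failed"
      } else {
        rec$rate <- fit$rate; rec$intercept <- fit$intercept
        rec$r2 <- fit$r_squared; rec$n_points <- fit$n_points_used
      }
      fits[[length(fits) + 1L]] <- rec
    }
  }
  fits <- do.call(rbind, fits)
  ok <- fits[fits$flag == "", , drop = FALSE]
  filt <- remove_outliers(ok, "rate",
                          group_cols = c("genotype", "condition_mM",
                                         "organ"), k = outlier_sd)
  summary <- genotype_condition_means(filt$data, "rate",
                                      group_cols = c("genotype",
                                                     "condition_mM",
                                                     "organ"))
  # STI per genotype x organ x salt condition
  ctrl <- summary[summary$condition_mM == control_mM, , drop = FALSE]
  salt <- summary[summary$condition_mM != control_mM, , drop = FALSE]
  sti <- merge(salt, ctrl[c("genotype", "organ", "mean")],
               by = c("genotype", "organ"), suffixes = c("_salt", "_ctrl"))
  sti <- data.frame(genotype = sti$genotype, trait = sti$organ,
                    condition_mM = sti$condition_mM,
                    mean_salt = sti$mean_salt, mean_control = sti$mean_ctrl,
                    sti = compute_sti(sti$mean_salt, sti$mean_ctrl),
                    stringsAsFactors = FALSE)
  # per-plant root:shoot rate ratio
  rw <- merge(
    ok[ok$organ == "root", c("genotype", "plant_id", "condition_mM", "rate")],
    ok[ok$organ == "shoot", c("genotype", "plant_id", "condition_mM",
                              "rate")],
    by = c("genotype", "plant_id", "condition_mM"),
    suffixes = c("_root", "_shoot"))
  rw$ratio <- rate_ratio(rw$rate_root, rw$rate_shoot)
  coord <- NULL
  usable <- !is.na(rw$ratio)
  if (sum(usable) >= 6L &&
      length(unique(rw$condition_mM[usable])) >= 2L &&
      as.character(control_mM) %in% as.character(rw$condition_mM[usable]))
    coord <- tryCatch(
      coordination_test(rw$ratio[usable],
                        rw$condition_mM[usable],
                        control_label = as.character(control_mM)),
      error = function(e) NULL)
  fr <- lapply(c("root", "shoot", "total"), function(organ) {
    d <- summary[summary$organ == organ, , drop = FALSE]
    f <- relative_growth_fractions(d, rate_col = "mean",
                                   control_label = as.character(control_mM))
    if (!is.null(f) && nrow(f)) cbind(organ = organ, f) else NULL
  })
  fractions <- do.call(rbind, fr)
  list(fits = fits, summary = summary, sti = sti, ratios = rw,
       coordination = coord, fractions = fractions)
}

#' Run the post-GWAS association workflow
#'
#' MAC-stratified Bonferroni thresholds, MAC-matched significance
#' filtering, locus clustering, and (when a genotype matrix is supplied)
#' haplotype grouping with the ANOVA/Tukey phenotype test.
#'
#' @param assoc association `data.frame` ([read_association_csv] schema).
#' @param genotypes optional genotype `data.frame`
#'   ([read_genotype_csv] schema).
#' @param phenotypes optional `data.frame` (accession, value) for the
#'   haplotype phenotype test.
#' @param alpha,mac_cutoffs see [mac_bonferroni].
#' @param window_bp see [cluster_loci].
#' @param snp_subset SNP columns used for haplotyping (default: all SNP
#'   columns of `genotypes`).
#' @param min_accessions see [haplotype_group].
#' @return list with `thresholds`, `significant`, `loci`, and optionally
#'   `haplotypes`, `test`.
#' @export
run_assoc <- function(assoc, genotypes = NULL, phenotypes = NULL,
                      alpha = 0.05, mac_cutoffs = c(5, 10),
                      window_bp = 10000, snp_subset = NULL,
                      min_accessions = 3L) {
  check_schema(assoc, ASSOC_SCHEMA, "association table")
  thresholds <- mac_bonferroni(assoc, alpha = alpha,
                               mac_cutoffs = mac_cutoffs)
  significant <- filter_significant(assoc, thresholds)
  loci <- cluster_loci(significant, window_bp = window_bp)
  out <- list(thresholds = thresholds, significant = significant,
              loci = loci)
  if (!is.null(genotypes)) {
    if (is.null(snp_subset))
      snp_subset <- setdiff(names(genotypes), "accession")
    out$haplotypes <- haplotype_group(genotypes, snp_subset,
                                      min_accessions = min_accessions)
    if (!is.null(phenotypes))
      out$test <- haplotype_phenotype_test(out$haplotypes, phenotypes,
                                           alpha = alpha)
  }
  out
}

#' Write a data frame as a pipeline CSV
#'
#' Comma-separated, UTF-8, header row, `.` decimal, missing values as
#' empty cells.
#'
#' @param df `data.frame`.
#' @param path output path.
#' @export
write_pipeline_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
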