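#' MAC-stratified Bonferroni thresholds
#'
#' Low minor-allele-count SNPs give unstable association statistics, so
#' multiple-testing correction is applied per MAC subpopulation: for each
#' cutoff `m` the number of distinct SNPs with `mac >= m` defines the test
#' count `n`, and the significance bar is `-log10(alpha / n)`.
#'
#' @param assoc `data.frame` with at least `snp_id` and `mac`. SNPs
#'   appearing with several traits are counted once.
#' @param alpha family-wise error rate, in (0, 1).
#' @param mac_cutoffs numeric vector of MAC cutoffs (ties at the cutoff are
#'   included: `mac >= cutoff`).
#' @return `data.frame` of class `threshold_table` with columns
#'   `mac_cutoff`, `n_snps`, `threshold_neglog10p` (NA when no SNP
#'   qualifies).
#' @export
mac_bonferroni <- function(assoc, alpha = 0.05, mac_cutoffs = c(5, 10)) {
  stopifnot(is.data.frame(assoc), all(c("snp_id", "mac") %in% names(assoc)),
            alpha > 0, alpha < 1, length(mac_cutoffs) >= 1L)
  snp <- assoc[!duplicated(assoc$snp_id), c("snp_id", "mac")]
  out <- data.frame(
    mac_cutoff = sort(mac_cutoffs),
    n_snps = vapply(sort(mac_cutoffs),
                    function(m) sum(snp$mac >= m), integer(1))
  )
  out$threshold_neglog10p <- ifelse(out$n_snps > 0,
                                    -log10(alpha / out$n_snps), NA_real_)
  class(out) <- c("threshold_table", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Filter associations to the MAC-matched significance threshold
#'
#' Each SNP is judged against the threshold of its MAC stratum: the largest
#' cutoff not exceeding its MAC. SNPs below the smallest cutoff are never
#' significant.
#'
#' @param assoc association `data.frame` (`snp_id`, `chrom`, `pos`, `mac`,
#'   `pvalue`, `trait`).
#' @param thresholds a [mac_bonferroni] threshold table.
#' @return The significant subset of `assoc`, with a `neglog10p` column
#'   added.
#' @export
filter_significant <- function(assoc, thresholds) {
  stopifnot(inherits(thresholds, "threshold_table"),
            all(c("mac", "pvalue") %in% names(assoc)))
  cuts <- thresholds$mac_cutoff
  stratum <- findInterval(assoc$mac, cuts)       # 0 = below smallest cutoff
  bar <- rep(Inf, nrow(assoc))
  ok <- stratum > 0 & !is.na(thresholds$threshold_neglog10p[pmax(stratum, 1)])
  bar[ok] <- thresholds$threshold_neglog10p[stratum[ok]]
  assoc$neglog10p <- -log10(assoc$pvalue)
  assoc[assoc$neglog10p > bar, , drop = FALSE]
}

#' Cluster significant SNPs into candidate loci
#'
#' Single-linkage positional clustering per chromosome: consecutive
#' significant SNPs closer than `window_bp` merge into one locus. Loci are
#' ranked by number of member SNPs, number of associated traits, and best
#' `-log10 p`, all descending — loci supported by multiple SNPs or multiple
#' traits are the prioritization targets.
#'
#' @param assoc significant associations (`snp_id`, `chrom`, `pos`,
#'   `pvalue`, `trait`); a SNP may appear once per associated trait.
#' @param window_bp linkage window in bp (> 0). Default 10 kb, the typical
#'   genome-wide LD decay distance in *Arabidopsis thaliana*.
#' @return `data.frame` with `chrom`, `start`, `end` (1-based inclusive),
#'   `n_snps`, `n_traits`, `best_neglog10p`, `snp_ids`, `traits`
#'   (semicolon-separated), ordered by rank.
#' @export
cluster_loci <- function(assoc, window_bp = 10000) {
  stopifnot(window_bp > 0)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_snps = integer(0),
                      n_traits = integer(0), best_neglog10p = numeric(0),
                      snp_ids = character(0), traits = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(assoc) == 0L) return(empty)
  stopifnot(all(c("snp_id", "chrom", "pos", "pvalue", "trait")
                %in% names(assoc)))
  # collapse multi-trait rows to one row per SNP
  snp <- do.call(rbind, lapply(split(assoc, assoc$snp_id), function(d) {
    data.frame(snp_id = d$snp_id[1], chrom = as.character(d$chrom[1]),
               pos = d$pos[1], best_neglog10p = max(-log10(d$pvalue)),
               traits = paste(sort(unique(d$trait)), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  loci <- list()
  for (ch in sort(unique(snp$chrom))) {
    s <- snp[snp$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos, s$snp_id), , drop = FALSE]
    brk <- c(0, cumsum(diff(s$pos) > window_bp))
    for (g in split(s, brk)) {
      traits <- sort(unique(unlist(strsplit(g$traits, ";", fixed = TRUE))))
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = ch, start = min(g$pos), end = max(g$pos),
        n_snps = nrow(g), n_traits = length(traits),
        best_neglog10p = max(g$best_neglog10p),
        snp_ids = paste(g$snp_id, collapse = ";"),
        traits = paste(traits, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, loci)
  out <- out[order(-out$n_snps, -out$n_traits, -out$best_neglog10p,
                   out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group accessions into haplotypes over a SNP subset
#'
#' Accessions sharing an identical allele pattern across the chosen SNPs
#' (typically all SNPs in a gene's coding region) form one haplotype.
#' Accessions with any missing call over the subset are set aside and
#' reported; haplotypes carried by fewer than `min_accessions` accessions
#' are excluded from analysis. Labels are assigned by descending member
#' count (`H1` = largest; ties broken by pattern string), so label
#' identities are a convention, not biology.
#'
#' @param gm genotype `data.frame`: column `accession` plus one 0/1/NA
#'   column per SNP.
#' @param snp_subset character vector of SNP column names to use.
#' @param min_accessions minimum haplotype size retained (default 3).
#' @return A `haplotype_assignment`: `assignment` (accession, haplotype,
#'   pattern) for retained accessions; `haplotypes` (haplotype, pattern,
#'   n); `excluded` (accession, pattern) for small-haplotype accessions;
#'   `missing` (accessions with missing calls).
#' @export
haplotype_group <- function(gm, snp_subset, min_accessions = 3L) {
  stopifnot(is.data.frame(gm), "accession" %in% names(gm))
  if (length(snp_subset) == 0L)
    stop("snp_subset must be non-empty", call. = FALSE)
  absent <- setdiff(snp_subset, names(gm))
  if (length(absent))
    stop("SNPs absent from genotype matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (anyDuplicated(gm$accession))
    stop("duplicated accession ids", call. = FALSE)
  mat <- as.matrix(gm[snp_subset])
  if (!all(mat %in% c(0, 1, NA)))
    stop("allele codes must be 0, 1 or NA", call. = FALSE)
  miss <- apply(mat, 1L, anyNA)
  acc <- as.character(gm$accession)
  pattern <- apply(mat[!miss, , drop = FALSE], 1L, paste, collapse = "")
  acc_ok <- acc[!miss]
  tab <- table(pattern)
  ord <- order(-as.numeric(tab), names(tab))
  tab <- tab[ord]
  keep_pat <- names(tab)[as.numeric(tab) >= min_accessions]
  if (length(keep_pat) == 0L && length(tab))
    warning("no haplotype reaches min_accessions = ", min_accessions,
            call. = FALSE)
  labels <- if (length(keep_pat))
    setNames(paste0("H", seq_along(keep_pat)), keep_pat)
  else setNames(character(0), character(0))
  retained <- pattern %in% keep_pat
  assignment <- data.frame(
    accession = acc_ok[retained],
    haplotype = unname(labels[pattern[retained]]),
    pattern = pattern[retained], stringsAsFactors = FALSE)
  haplotypes <- data.frame(
    haplotype = unname(labels), pattern = keep_pat,
    n = as.integer(tab[keep_pat]), stringsAsFactors = FALSE)
  excluded <- data.frame(accession = acc_ok[!retained],
                         pattern = pattern[!retained],
                         stringsAsFactors = FALSE)
  structure(list(assignment = assignment, haplotypes = haplotypes,
                 excluded = excluded, missing = acc[miss],
                 snp_subset = snp_subset,
                 min_accessions = as.integer(min_accessions)),
            class = "haplotype_assignment")
}

#' @export
print.haplotype_assignment <- function(x, ...) {
  cat(sprintf(
    "<haplotype_assignment> %d haplotypes over %d SNPs (%d accessions retained, %d in small haplotypes, %d with missing calls)\n",
    nrow(x$haplotypes), length(x$snp_subset), nrow(x$assignment),
    nrow(x$excluded), length(x$missing)))
  print(x$haplotypes, row.names = FALSE)
  invisible(x)
}

#' Test phenotype differences between haplotype groups
#'
#' One-way fixed-effects ANOVA of the phenotype across haplotype groups,
#' followed by Tukey HSD pairwise comparisons at `alpha` and a compact
#' letter display (insert-and-absorb): groups sharing no letter differ
#' significantly.
#'
#' @param assignment a [haplotype_group] result.
#' @param phenotypes `data.frame` with columns `accession` and `value`.
#' @param alpha significance level for the Tukey comparisons.
#' @return A `haplotype_test`: `groups` (haplotype, n, mean, letters),
#'   `anova` (F, df1, df2, p_value), `tukey` (pairwise `data.frame`).
#' @export
haplotype_phenotype_test <- function(assignment, phenotypes, alpha = 0.05) {
  stopifnot(inherits(assignment, "haplotype_assignment"),
            is.data.frame(phenotypes),
            all(c("accession", "value") %in% names(phenotypes)))
  d <- merge(assignment$assignment, phenotypes, by = "accession")
  d <- d[!is.na(d$value), , drop = FALSE]
  sizes <- table(d$haplotype)
  d <- d[d$haplotype %in% names(sizes)[sizes >= 2L], , drop = FALSE]
  hl <- sort(unique(d$haplotype))
  if (length(hl) < 2L)
    stop("need >= 2 haplotype groups with >= 2 phenotyped accessions",
         call. = FALSE)
  d$haplotype <- factor(d$haplotype, levels = hl)
  k <- length(hl); n <- nrow(d)
  gm <- tapply(d$value, d$haplotype, mean)
  ssb <- sum(tapply(d$value, d$haplotype,
                    function(v) length(v) * (mean(v) - mean(d$value))^2))
  ssw <- sum((d$value - ave(d$value, d$haplotype))^2)
  df1 <- k - 1L; df2 <- n - k
  if (ssw == 0 && ssb == 0) {
    # all phenotypes identical: no signal, single letter for everyone
    groups <- data.frame(haplotype = hl, n = as.integer(table(d$haplotype)),
                         mean = as.numeric(gm), letters = "a",
                         stringsAsFactors = FALSE)
    return(structure(list(groups = groups,
                          anova = data.frame(F = 0, df1 = df1, df2 = df2,
                                             p_value = 1),
                          tukey = NULL, alpha = alpha),
                     class = "haplotype_test"))
  }
  fstat <- (ssb / df1) / (ssw / df2)
  pval <- pf(fstat, df1, df2, lower.tail = FALSE)
  fit <- aov(value ~ haplotype, data = d)
  tk <- as.data.frame(stats::TukeyHSD(fit, conf.level = 1 - alpha)$haplotype)
  tk$pair <- rownames(tk)
  rownames(tk) <- NULL
  # significance matrix for the letter display
  sig <- matrix(FALSE, k, k, dimnames = list(hl, hl))
  for (i in seq_len(nrow(tk))) {
    ab <- strsplit(tk$pair[i], "-", fixed = TRUE)[[1]]
    isig <- !is.na(tk$`p adj`[i]) && tk$`p adj`[i] < alpha
    sig[ab[1], ab[2]] <- sig[ab[2], ab[1]] <- isig
  }
  letters_by_group <- compact_letters(sig)
  groups <- data.frame(haplotype = hl, n = as.integer(table(d$haplotype)),
                       mean = as.numeric(gm),
                       letters = letters_by_group[hl],
                       stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  structure(list(groups = groups,
                 anova = data.frame(F = fstat, df1 = df1, df2 = df2,
                                    p_value = pval),
                 tukey = tk, alpha = alpha),
            class = "haplotype_test")
}

#' @export
print.haplotype_test <- function(x, ...) {
  cat(sprintf("<haplotype_test> ANOVA F(%d, %d) = %.3f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p_value))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

# Compact letter display by insert-and-absorb: columns are letter classes;
# every significantly different pair must end up sharing no column, every
# non-significant pair must share at least one.
compact_letters <- function(sig) {
  k <- nrow(sig)
  groups <- rownames(sig)
  cols <- list(rep(TRUE, k))                    # start: one all-inclusive class
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  if (nrow(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      newcols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          newcols <- c(newcols, list(a, b))
        } else newcols <- c(newcols, list(col))
      }
      # absorb: drop any column that is a subset of another
      keep <- rep(TRUE, length(newcols))
      for (a in seq_along(newcols)) for (b in seq_along(newcols)) {
        if (a != b && keep[a] && keep[b] &&
            all(newcols[[a]] <= newcols[[b]]) &&
            any(newcols[[a]] != newcols[[b]]))
          keep[a] <- FALSE
      }
      # drop duplicated columns too
      sig_cols <- newcols[keep]
      key <- vapply(sig_cols, paste, character(1), collapse = "")
      cols <- sig_cols[!duplicated(key)]
    }
  }
  out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, `[`, logical(1), g))], collapse = "")
  }, character(1))
  setNames(out, groups)
}
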