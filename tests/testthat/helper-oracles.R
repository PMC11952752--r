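# Independent brute-force oracles used to cross-check the compiled image
# primitives and the statistics. Deliberately naive implementations.

# Queue-based flood-fill connected-components labeler (pure R).
oracle_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4L)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  cur <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!mask[rr, cc] || lab[rr, cc] != 0L) next
    cur <- cur + 1L
    stack <- integer(64); stack[1] <- (cc - 1L) * nr + rr; top <- 1L
    lab[rr, cc] <- cur
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
      for (k in seq_len(nrow(nb))) {
        r2 <- pr + nb[k, 1]; c2 <- pc + nb[k, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          top <- top + 1L
          if (top > length(stack)) stack <- c(stack, integer(length(stack)))
          stack[top] <- (c2 - 1L) * nr + r2
        }
      }
    }
  }
  lab
}

# Brute-force disc dilation: a pixel is set if any true pixel lies within
# Euclidean distance `radius`.
oracle_dilate <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  on_px <- which(mask, arr.ind = TRUE)
  if (nrow(on_px) == 0L) return(out)
  for (rr in seq_len(nr)) for (cc in seq_len(nc)) {
    d2 <- (on_px[, 1] - rr)^2 + (on_px[, 2] - cc)^2
    if (any(d2 <= radius^2)) out[rr, cc] <- TRUE
  }
  out
}

# Canonical partition of a labelling: list of sorted pixel-index vectors,
# ordered by smallest member, so two labelings compare independent of
# label numbering.
canonical_partition <- function(lab) {
  idx <- which(lab > 0L)
  parts <- split(idx, lab[idx])
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, min, numeric(1)))]
}

# One-pixel plate image from RGB triples (n x 3 matrix -> 1 x n image).
pixel_row_image <- function(rgb) {
  arr <- array(0L, dim = c(1, nrow(rgb), 3))
  for (ch in 1:3) arr[1, , ch] <- as.integer(rgb[, ch])
  plate_image(arr, image_id = "px")
}

# Independent Brown-Forsythe route through R's linear-model ANOVA.
oracle_brown_forsythe <- function(x, y) {
  z <- c(abs(x - median(x)), abs(y - median(y)))
  g <- factor(rep(1:2, c(length(x), length(y))))
  tab <- anova(lm(z ~ g))
  list(statistic = tab$`F value`[1], p_value = tab$`Pr(>F)`[1])
}

# Brute-force haplotype tally: pattern -> accessions, excluding missing.
oracle_haplotypes <- function(gm, snps, min_n) {
  mat <- as.matrix(gm[snps])
  miss <- apply(mat, 1, anyNA)
  pat <- apply(mat[!miss, , drop = FALSE], 1, paste, collapse = "")
  acc <- gm$accession[!miss]
  tab <- table(pat)
  keep <- names(tab)[tab >= min_n]
  list(retained = sort(acc[pat %in% keep]),
       sizes = sort(as.integer(tab[tab >= min_n]), decreasing = TRUE),
       missing = sort(gm$accession[miss]))
}

# Random root/shoot/background class map for oracle-equivalence checks.
random_class_map <- function(nr, nc, p_fg = 0.3) {
  lab <- matrix(sample(0:2, nr * nc, replace = TRUE,
                       prob = c(1 - p_fg, p_fg / 2, p_fg / 2)), nr, nc)
  rootshoot:::new_class_map(lab)
}
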