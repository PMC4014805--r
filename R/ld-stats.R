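# Pairwise genotype correlation, signed r2, LD-decay curves, and windowed
# mean-r2 profiles.

#' Genotype correlation of two dosage vectors
#'
#' Pearson correlation of unphased dosages over pairwise-complete entries
#' (composite LD). Returns `NA` when fewer than 2 jointly non-missing entries
#' remain or either vector has zero variance on the joint support.
#'
#' @param x,y dosage vectors over `{0, 1, 2, NA}`.
#' @return Correlation in `[-1, 1]`, or `NA` (undefined signal).
#' @export
genotype_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  suppressWarnings(stats::cor(x[ok], y[ok]))
}

#' Signed r-squared
#'
#' `sign(r) * r^2` of the genotype correlation: the entry of the windowed LD
#' correlation matrices compared by [varld()].
#'
#' @inheritParams genotype_r
#' @return Signed r2 in `[-1, 1]`, or `NA` (undefined signal).
#' @export
signed_r2 <- function(x, y) {
  r <- genotype_r(x, y)
  sign(r) * r^2
}

# Mean unsigned r2 over all column pairs of a dosage matrix; undefined pairs
# (zero variance on the joint support) contribute 0.
.pair_r2_mean <- function(dosages) {
  m <- ncol(dosages)
  if (m < 2L) return(NA_real_)
  cc <- suppressWarnings(stats::cor(dosages, use = "pairwise.complete.obs"))
  r2 <- cc[upper.tri(cc)]^2
  r2[is.na(r2)] <- 0
  mean(r2)
}

#' LD-decay curve
#'
#' All intra-chromosome SNP pairs separated by at most `max_dist_bp` are
#' binned by physical distance; each bin reports the mean r2 and the pair
#' count. Bins are left-closed right-open, except the final bin which is
#' closed at `max_dist_bp`. Pairs with undefined correlation are dropped.
#'
#' @param dataset a quality-controlled [genotype_dataset()].
#' @param max_dist_bp maximum pair distance in bp.
#' @param bin_width_bp distance bin width in bp.
#' @return Object of class `ld_decay`: data.frame with columns `bin_start`,
#'   `bin_end`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(dataset, max_dist_bp = 100000L, bin_width_bp = 10000L) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  n_bins <- ceiling(max_dist_bp / bin_width_bp)
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  d <- dataset$dosages
  map <- dataset$map
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    m <- length(idx)
    for (ii in seq_len(max(m - 1L, 0L))) {
      hi <- findInterval(pos[ii] + max_dist_bp, pos)
      if (hi <= ii) next
      js <- (ii + 1L):hi
      r <- suppressWarnings(
        stats::cor(d[, idx[ii]], d[, idx[js], drop = FALSE],
                   use = "pairwise.complete.obs")
      )
      r2 <- as.numeric(r)^2
      dist <- pos[js] - pos[ii]
      bin <- pmin(dist %/% bin_width_bp + 1L, n_bins)
      keep <- !is.na(r2)
      if (any(keep)) {
        tb <- tapply(r2[keep], bin[keep], sum)
        ix <- as.integer(names(tb))
        sums[ix] <- sums[ix] + tb
        tbn <- tapply(rep(1L, sum(keep)), bin[keep], sum)
        counts[ix] <- counts[ix] + tbn
      }
    }
  }
  if (!sum(counts)) warning("no SNP pairs within ", max_dist_bp, " bp")
  out <- data.frame(
    bin_start = (seq_len(n_bins) - 1L) * bin_width_bp,
    bin_end = pmin(seq_len(n_bins) * bin_width_bp, max_dist_bp),
    mean_r2 = ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_),
    n_pairs = counts
  )
  class(out) <- c("ld_decay", "data.frame")
  out
}

#' @export
plot.ld_decay <- function(x, ...) {
  mids <- (x$bin_start + x$bin_end) / 2
  graphics::plot(mids / 1000, x$mean_r2, type = "b", pch = 19,
                 xlab = "distance (kb)", ylab = expression(mean ~ r^2),
                 ylim = c(0, max(x$mean_r2, na.rm = TRUE)), ...)
  invisible(x)
}

#' Windowed mean-r2 profile
#'
#' Mean pairwise r2 of all SNP pairs inside physical windows slid along each
#' chromosome; windows holding fewer than `min_snps` SNPs are discarded. Used
#' to contrast regional LD levels between populations when assigning a signal
#' to the population carrying the sweep.
#'
#' @param dataset a quality-controlled [genotype_dataset()].
#' @param window_bp window span in bp.
#' @param step_bp step between window starts in bp.
#' @param min_snps minimum SNPs per reported window.
#' @return Object of class `r2_profile`: data.frame with columns `chrom`,
#'   `start`, `end`, `mean_r2`, `n_snps`.
#' @export
windowed_mean_r2 <- function(dataset, window_bp = 200000L, step_bp = 20000L,
                             min_snps = 50L) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  map <- dataset$map
  res <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    starts <- seq(1L, max(pos), by = step_bp)
    for (s in starts) {
      e <- s + window_bp - 1L
      in_win <- idx[pos >= s & pos <= e]
      if (length(in_win) < min_snps) next
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e,
        mean_r2 = .pair_r2_mean(dataset$dosages[, in_win, drop = FALSE]),
        n_snps = length(in_win),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               mean_r2 = numeric(0), n_snps = integer(0),
               stringsAsFactors = FALSE)
  class(out) <- c("r2_profile", "data.frame")
  out
}
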