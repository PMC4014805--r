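# The VarLD scan: windowed signed-r2 correlation matrices per population,
# eigen-decomposition, raw eigenvalue-difference score, genome-wide
# standardization, and a permutation null.

# Markers with zero variance (ignoring NA) or < 2 observations. Dosages are
# small integers, so the sum-of-squares variance test is exact.
.monomorphic_markers <- function(dosages) {
  nobs <- colSums(!is.na(dosages))
  s1 <- colSums(dosages, na.rm = TRUE)
  s2 <- colSums(dosages * dosages, na.rm = TRUE)
  which(nobs < 2L | s2 * nobs - s1 * s1 == 0)
}

# Banded signed-r2 matrix: S[i, d] = signed r2 between marker i and marker
# i + d (d = 1 .. w - 1), computed on pairwise-complete dosages. Undefined
# entries (zero variance or < 2 observations on the joint support) become 0.
# Pairwise-complete Pearson correlation is assembled exactly from blocked
# cross-products (BLAS) of the zero-filled dosages and the observation
# indicator, which is much faster than per-marker stats::cor() calls.
.signed_r2_band <- function(dosages, w) {
  m <- ncol(dosages)
  band <- matrix(0, m, w - 1L)
  if (m < 2L) return(band)
  obs <- (!is.na(dosages)) * 1
  x0 <- dosages
  x0[is.na(x0)] <- 0
  x2 <- x0 * x0
  block <- 1024L
  for (bs in seq.int(1L, m, by = block)) {
    be <- min(bs + block - 1L, m)
    ce <- min(be + w - 1L, m)
    ii <- bs:be
    jj <- bs:ce
    n_ij <- crossprod(obs[, ii, drop = FALSE], obs[, jj, drop = FALSE])
    s_x <- crossprod(x0[, ii, drop = FALSE], obs[, jj, drop = FALSE])
    s_y <- crossprod(obs[, ii, drop = FALSE], x0[, jj, drop = FALSE])
    s_xy <- crossprod(x0[, ii, drop = FALSE], x0[, jj, drop = FALSE])
    s_xx <- crossprod(x2[, ii, drop = FALSE], obs[, jj, drop = FALSE])
    s_yy <- crossprod(obs[, ii, drop = FALSE], x2[, jj, drop = FALSE])
    num <- n_ij * s_xy - s_x * s_y
    den <- (n_ij * s_xx - s_x^2) * (n_ij * s_yy - s_y^2)
    r <- num / sqrt(den)               # NaN where a pair is undefined
    for (d in seq_len(w - 1L)) {
      gi <- ii[ii + d <= m]
      if (!length(gi)) next
      vals <- r[cbind(gi - bs + 1L, gi + d - bs + 1L)]
      s <- sign(vals) * vals * vals
      s[!is.finite(s)] <- 0
      band[gi, d] <- s
    }
  }
  band
}

# Index helpers that map a window's upper triangle onto the band.
.band_index <- function(w) {
  ut <- which(upper.tri(diag(w)), arr.ind = TRUE)
  list(ut = ut, row_off = ut[, 1L], dcol = ut[, 2L] - ut[, 1L])
}

# Signed-r2 correlation matrix for the window starting at band row `s`.
.window_matrix_from_band <- function(band, s, w, bi) {
  mat <- diag(w)
  vals <- band[cbind(s - 1L + bi$row_off, bi$dcol)]
  mat[bi$ut] <- vals
  mat[bi$ut[, c(2L, 1L)]] <- vals
  mat
}

#' Signed-r2 correlation matrix of one SNP window
#'
#' Builds the `window_size x window_size` matrix whose off-diagonal entries
#' are the signed r2 between marker pairs and whose diagonal is 1.
#'
#' @param dataset a [genotype_dataset()].
#' @param start_index 1-based index of the window's first marker.
#' @param window_size number of consecutive markers in the window.
#' @return Symmetric matrix with unit diagonal.
#' @export
window_corr_matrix <- function(dataset, start_index, window_size) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  m <- nrow(dataset$map)
  if (start_index < 1L || start_index + window_size - 1L > m) {
    stop("window [", start_index, ", ", start_index + window_size - 1L,
         "] outside marker range 1..", m)
  }
  idx <- start_index:(start_index + window_size - 1L)
  chs <- unique(dataset$map$chrom[idx])
  if (length(chs) > 1L) stop("window spans chromosomes: ",
                             paste(chs, collapse = ", "))
  sub <- dataset$dosages[, idx, drop = FALSE]
  mono <- .monomorphic_markers(sub)
  if (length(mono)) {
    stop("monomorphic marker(s) in window: ",
         paste(dataset$map$marker_id[idx[mono]], collapse = ", "))
  }
  cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  s <- sign(cc) * cc^2
  s[is.na(s)] <- 0
  diag(s) <- 1
  dimnames(s) <- list(dataset$map$marker_id[idx], dataset$map$marker_id[idx])
  s
}

#' Raw VarLD score of two correlation matrices
#'
#' Both matrices are eigen-decomposed, their eigenvalues ranked in descending
#' order, and the score is the l1 distance between the ranked spectra:
#' `sum_i |lambda_a(i) - lambda_b(i)|`. Because both matrices have unit
#' diagonal the plain trace difference is identically zero; the absolute form
#' is what gives the score its magnitude interpretation as a degree of
#' dissimilarity between the two LD patterns.
#'
#' @param mat_a,mat_b symmetric matrices of equal dimension.
#' @return Nonnegative real score.
#' @export
raw_varld_score <- function(mat_a, mat_b) {
  if (!is.matrix(mat_a) || !is.matrix(mat_b) ||
      nrow(mat_a) != ncol(mat_a) || nrow(mat_b) != ncol(mat_b) ||
      nrow(mat_a) != nrow(mat_b)) {
    stop("mat_a and mat_b must be square matrices of equal dimension")
  }
  ev_a <- eigen(mat_a, symmetric = TRUE, only.values = TRUE)$values
  ev_b <- eigen(mat_b, symmetric = TRUE, only.values = TRUE)$values
  sum(abs(ev_a - ev_b))                  # eigen() returns descending order
}

# Raw windowed scores for two dosage matrices sharing one marker map.
# Returns a data.frame of windows with raw scores; no polymorphism checks
# (callers decide whether monomorphic columns are an error).
.varld_raw_track <- function(dos_a, dos_b, map, window_size, step) {
  bi <- .band_index(window_size)
  pieces <- list()
  for (ch in .chrom_levels(map$chrom)) {
    idx <- which(map$chrom == ch)
    m <- length(idx)
    if (m < window_size) {
      warning("chromosome ", ch, " has ", m, " markers (< window size ",
              window_size, "); skipped")
      next
    }
    band_a <- .signed_r2_band(dos_a[, idx, drop = FALSE], window_size)
    band_b <- .signed_r2_band(dos_b[, idx, drop = FALSE], window_size)
    starts <- seq(1L, m - window_size + 1L, by = step)
    raw <- numeric(length(starts))
    for (t in seq_along(starts)) {
      s <- starts[t]
      wa <- .window_matrix_from_band(band_a, s, window_size, bi)
      wb <- .window_matrix_from_band(band_b, s, window_size, bi)
      ev_a <- eigen(wa, symmetric = TRUE, only.values = TRUE)$values
      ev_b <- eigen(wb, symmetric = TRUE, only.values = TRUE)$values
      raw[t] <- sum(abs(ev_a - ev_b))
    }
    first_bp <- map$pos[idx[starts]]
    last_bp <- map$pos[idx[starts + window_size - 1L]]
    pieces[[length(pieces) + 1L]] <- data.frame(
      chrom = ch,
      first_index = starts,
      first_bp = first_bp,
      last_bp = last_bp,
      mid_bp = as.integer(round((first_bp + last_bp) / 2)),
      raw_score = raw,
      std_score = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (!length(pieces)) stop("no chromosome holds at least one full window")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' VarLD scan of two populations
#'
#' Slides a window of `window_size` consecutive SNPs along each chromosome
#' (step `step` SNPs, never crossing a chromosome boundary), builds each
#' population's signed-r2 correlation matrix for the window, and scores the
#' window by the l1 distance between the two descending-ranked eigenvalue
#' spectra ([raw_varld_score()]). Scores are then standardized genome-wide to
#' mean 0 and standard deviation 1 (sample sd), so that thresholds are
#' comparable across comparisons with different background LD.
#'
#' @param a,b [genotype_dataset()] objects sharing an identical marker map
#'   (use [intersect_common_snps()] first); every marker must be polymorphic
#'   in both.
#' @param window_size SNPs per window.
#' @param step step in SNPs between consecutive windows.
#' @param standardize if `TRUE` (default) the standardized scores are filled
#'   in via [standardize()].
#' @return An object of class `varld`: a data.frame of windows with columns
#'   `chrom`, `first_index`, `first_bp`, `last_bp`, `mid_bp`, `raw_score`,
#'   `std_score`, plus attributes `comparison`, `window_size`, `step`.
#' @export
varld <- function(a, b, window_size = 50L, step = 1L, standardize = TRUE) {
  stopifnot(inherits(a, "genotype_dataset"), inherits(b, "genotype_dataset"))
  if (window_size < 2L) stop("window_size must be >= 2")
  if (step < 1L) stop("step must be >= 1")
  if (nrow(a$map) != nrow(b$map) ||
      !all(a$map$chrom == b$map$chrom & a$map$pos == b$map$pos)) {
    stop("marker maps differ; run intersect_common_snps() first")
  }
  mono_a <- .monomorphic_markers(a$dosages)
  mono_b <- .monomorphic_markers(b$dosages)
  if (length(mono_a) || length(mono_b)) {
    bad <- unique(c(a$map$marker_id[mono_a], b$map$marker_id[mono_b]))
    stop("monomorphic marker(s) present (exclude before scanning): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) sprintf(" ... (%d total)", length(bad)))
  }
  win <- .varld_raw_track(a$dosages, b$dosages, a$map, window_size, step)
  track <- structure(win,
                     comparison = paste(a$population, b$population, sep = "/"),
                     window_size = as.integer(window_size),
                     step = as.integer(step),
                     class = c("varld", "data.frame"))
  if (standardize && nrow(track) >= 2L) track <- standardize(track)
  track
}

#' Standardize a VarLD track genome-wide
#'
#' `std_score = (raw - mean) / sd` with the mean and sample standard deviation
#' (n - 1 denominator) taken over all windows of the track.
#'
#' @param track a `varld` object with at least 2 windows.
#' @return The track with `std_score` filled in.
#' @export
standardize <- function(track) {
  stopifnot(inherits(track, "varld"))
  if (nrow(track) < 2L) stop("standardization needs at least 2 windows")
  raw <- track$raw_score
  s <- stats::sd(raw)
  if (s == 0) stop("degenerate track: all raw scores equal")
  track$std_score <- (raw - mean(raw)) / s
  track
}

#' Empirical percentile threshold of standardized scores
#'
#' Empirical quantile (linear interpolation between order statistics,
#' [stats::quantile()] type 7) of the standardized scores of a track.
#'
#' @param track a standardized `varld` object.
#' @param percentile percentile in (0, 100], e.g. 99.9.
#' @return The score threshold.
#' @export
percentile_threshold <- function(track, percentile) {
  stopifnot(inherits(track, "varld"))
  if (!nrow(track)) stop("empty track")
  if (anyNA(track$std_score)) stop("track is not standardized")
  if (percentile <= 0 || percentile > 100) stop("percentile must be in (0, 100]")
  stats::quantile(track$std_score, percentile / 100, type = 7, names = FALSE)
}

#' Permutation null for the VarLD scan
#'
#' Individuals from both populations are pooled and randomly reassigned to
#' two groups of the original sizes `n_perm` times; each window's empirical
#' p-value is `(1 + #{permuted raw >= observed raw}) / (n_perm + 1)`.
#' Monomorphic markers arising within a permuted group contribute 0 to the
#' window correlation matrices rather than erroring.
#'
#' @inheritParams varld
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed; the global RNG state is saved and restored.
#' @return The observed `varld` track with an additional `p_value` column.
#' @export
permutation_null <- function(a, b, n_perm, seed, window_size = 50L, step = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  obs <- varld(a, b, window_size = window_size, step = step,
               standardize = FALSE)
  pooled <- rbind(a$dosages, b$dosages)
  n_a <- nrow(a$dosages)
  n_tot <- nrow(pooled)

  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  exceed <- integer(nrow(obs))
  for (t in seq_len(n_perm)) {
    grp_a <- sample.int(n_tot, n_a)
    raw_p <- .varld_raw_track(pooled[grp_a, , drop = FALSE],
                              pooled[-grp_a, , drop = FALSE],
                              a$map, window_size, step)$raw_score
    exceed <- exceed + (raw_p >= obs$raw_score)
  }
  obs$p_value <- (1 + exceed) / (n_perm + 1)
  obs
}

#' @export
print.varld <- function(x, ...) {
  cat("VarLD track:", attr(x, "comparison"), "\n")
  cat("  windows:", nrow(x),
      " window size:", attr(x, "window_size"),
      " step:", attr(x, "step"), "\n")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  if (!anyNA(x$std_score)) {
    cat("  std score range:",
        paste(sprintf("%.2f", range(x$std_score)), collapse = " .. "), "\n")
  } else {
    cat("  (raw scores only; run standardize())\n")
  }
  invisible(x)
}

#' @export
summary.varld <- function(object, percentiles = c(99.9, 99.99), ...) {
  std_ok <- !anyNA(object$std_score)
  thr <- if (std_ok) {
    vapply(percentiles, function(p) percentile_threshold(object, p),
           numeric(1))
  } else rep(NA_real_, length(percentiles))
  top <- object[order(-object$raw_score)[seq_len(min(5L, nrow(object)))],
                c("chrom", "mid_bp", "raw_score", "std_score")]
  out <- list(comparison = attr(object, "comparison"),
              n_windows = nrow(object),
              raw_summary = summary(object$raw_score),
              thresholds = stats::setNames(thr, paste0("p", percentiles)),
              top_windows = top)
  class(out) <- "summary.varld"
  out
}

#' @export
print.summary.varld <- function(x, ...) {
  cat("VarLD scan summary:", x$comparison, "\n")
  cat("  windows:", x$n_windows, "\n")
  cat("  raw score summary:\n")
  print(x$raw_summary)
  cat("  percentile thresholds (standardized):\n")
  print(round(x$thresholds, 3))
  cat("  top windows by raw score:\n")
  print(x$top_windows, row.names = FALSE)
  invisible(x)
}

#' Genome-wide plot of standardized VarLD scores
#'
#' @param x a standardized `varld` object.
#' @param percentiles percentile thresholds drawn as horizontal lines.
#' @param ... passed to [graphics::plot()].
#' @export
plot.varld <- function(x, percentiles = c(99.9, 99.99), ...) {
  if (anyNA(x$std_score)) stop("standardize the track before plotting")
  lev <- .chrom_levels(x$chrom)
  offs <- c(0, cumsum(vapply(lev, function(ch) max(x$mid_bp[x$chrom == ch]),
                             numeric(1))))
  gx <- x$mid_bp + offs[match(x$chrom, lev)]
  graphics::plot(gx, x$std_score, pch = 16, cex = 0.4,
                 col = match(x$chrom, lev) %% 2 + 1,
                 xlab = "genome position (bp, chromosomes concatenated)",
                 ylab = "standardized VarLD score",
                 main = attr(x, "comparison"), ...)
  for (p in percentiles) {
    graphics::abline(h = percentile_threshold(x, p), lty = 2)
  }
  invisible(x)
}

#' Write a VarLD track as a tab-separated table
#'
#' @param track a `varld` object.
#' @param path output path.
#' @export
write_varld_track <- function(track, path) {
  stopifnot(inherits(track, "varld"))
  df <- as.data.frame(track)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
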