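# Shared fixture builders: everything is generated in code at test time.

# Minimal dataset builder: dosage matrix + evenly spaced map on one or more
# chromosomes, alleles A/G everywhere.
make_dataset <- function(dosages, chrom = "1", pos = NULL,
                         population = "POP1", sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (length(chrom) == 1L) chrom <- rep(chrom, m)
  if (is.null(pos)) {
    pos <- integer(m)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- seq_len(length(idx)) * 1000L
    }
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%03d", seq_len(nrow(dosages)))
  }
  map <- data.frame(marker_id = sprintf("m%04d", seq_len(m)),
                    chrom = chrom, pos = pos,
                    allele_a = "A", allele_b = "G",
                    stringsAsFactors = FALSE)
  genotype_dataset(dosages, map, sample_ids, population)
}

# Fabricated VarLD track with given standardized scores (step 1).
make_track <- function(std, chrom = "1", w = 50L, comparison = "A/B") {
  n <- length(std)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  fi <- unlist(lapply(unique(chrom), function(ch) seq_len(sum(chrom == ch))))
  first_bp <- fi * 1000L
  last_bp <- first_bp + (w - 1L) * 1000L
  df <- data.frame(chrom = chrom, first_index = fi, first_bp = first_bp,
                   last_bp = last_bp,
                   mid_bp = as.integer(round((first_bp + last_bp) / 2)),
                   raw_score = std, std_score = std,
                   stringsAsFactors = FALSE)
  structure(df, comparison = comparison, window_size = as.integer(w),
            step = 1L, class = c("varld", "data.frame"))
}

# Random symmetric matrix with unit diagonal (a plausible signed-r2 matrix).
rand_corr_like <- function(d) {
  m <- matrix(stats::runif(d * d, -1, 1), d, d)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# Drop markers monomorphic in either dataset (as QC + intersection would).
drop_monomorphic <- function(a, b) {
  mono <- union(varldscan:::.monomorphic_markers(a$dosages),
                varldscan:::.monomorphic_markers(b$dosages))
  if (length(mono)) {
    keep <- setdiff(seq_len(ncol(a$dosages)), mono)
    a <- varldscan:::.subset_dataset(a, markers = keep)
    b <- varldscan:::.subset_dataset(b, markers = keep)
  }
  list(a = a, b = b)
}

# Split one population into two labelled halves sharing the map.
split_halves <- function(dataset, labels = c("H1", "H2")) {
  n <- nrow(dataset$dosages)
  i1 <- seq_len(floor(n / 2))
  i2 <- setdiff(seq_len(n), i1)
  h1 <- genotype_dataset(dataset$dosages[i1, , drop = FALSE], dataset$map,
                         dataset$sample_ids[i1], labels[1])
  h2 <- genotype_dataset(dataset$dosages[i2, , drop = FALSE], dataset$map,
                         dataset$sample_ids[i2], labels[2])
  list(a = h1, b = h2)
}
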