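# Per-population SNP/sample quality control and relatedness pruning.

#' Quality-control configuration
#'
#' Defaults follow common practice for dense SNP panels: minor allele frequency
#' >= 5%, genotype call rate >= 90% per SNP and per sample, Hardy-Weinberg
#' 1-df goodness-of-fit p > 1e-6, and removal of one member of any pair with
#' genomic kinship > 0.8 (duplicates / clones).
#'
#' @param maf_min minimum minor allele frequency.
#' @param snp_call_min minimum per-SNP call rate.
#' @param sample_call_min minimum per-sample call rate.
#' @param hwe_p_min SNPs with HWE p-value <= this are removed.
#' @param ibs_max maximum allowed pairwise kinship.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.05, snp_call_min = 0.90,
                      sample_call_min = 0.90, hwe_p_min = 1e-6,
                      ibs_max = 0.8) {
  frac <- c(maf_min = maf_min, snp_call_min = snp_call_min,
            sample_call_min = sample_call_min)
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]")
  if (hwe_p_min <= 0 || hwe_p_min >= 1) stop("hwe_p_min must lie in (0, 1)")
  structure(list(maf_min = maf_min, snp_call_min = snp_call_min,
                 sample_call_min = sample_call_min, hwe_p_min = hwe_p_min,
                 ibs_max = ibs_max),
            class = "qc_config")
}

#' Load a QC configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the [qc_config()] defaults.
#'
#' @param path YAML file with any of the keys of [qc_config()].
#' @export
read_qc_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(qc_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown QC config keys: ", paste(extra, collapse = ", "))
  do.call(qc_config, vals)
}

#' Minor allele frequency of a dosage column
#'
#' The allele_b frequency `p` is computed over non-missing entries and the
#' minor allele frequency `min(p, 1 - p)` returned. An all-missing column
#' returns `NA`.
#'
#' @param dosage_column vector over `{0, 1, 2, NA}`.
#' @return A fraction in `[0, 0.5]`, or `NA` for an all-missing column.
#' @export
compute_maf <- function(dosage_column) {
  if (!length(dosage_column)) stop("empty dosage column")
  x <- dosage_column[!is.na(dosage_column)]
  if (!length(x)) return(NA_real_)
  p <- sum(x) / (2 * length(x))
  min(p, 1 - p)
}

# Vectorized per-column MAF (same contract as compute_maf).
.maf_columns <- function(d) {
  nobs <- colSums(!is.na(d))
  p <- ifelse(nobs > 0, colSums(d, na.rm = TRUE) / (2 * nobs), NA_real_)
  pmin(p, 1 - p)
}

# Vectorized per-column HWE p-values (same contract as hwe_test).
.hwe_columns <- function(d) {
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  chi2 <- ifelse(p == 0 | p == 1, 0,
                 (n0 - n * q^2)^2 / (n * q^2) +
                 (n1 - 2 * n * p * q)^2 / (2 * n * p * q) +
                 (n2 - n * p^2)^2 / (n * p^2))
  ifelse(p == 0 | p == 1, 1, stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of the observed genotype counts
#' against Hardy-Weinberg expectations at the sample allele frequency
#' (equivalent to the squared z-test). Monomorphic input returns p = 1.
#'
#' @param n_aa,n_ab,n_bb genotype counts (dosage 0, 1, 2).
#' @return Two-sided p-value.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  if (n_aa < 0 || n_ab < 0 || n_bb < 0) stop("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("at least one observation required")
  p <- (2 * n_bb + n_ab) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((c(n_aa, n_ab, n_bb) - expd)^2 / expd)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Genomic kinship matrix
#'
#' Frequency-weighted marker-based kinship: `K[i,j]` is the mean over markers
#' (non-missing in both samples) of
#' `(g_i - 2p)(g_j - 2p) / (2 p (1 - p))`, with `p` the sample allele_b
#' frequency at the marker. Expected value ~1 for duplicate samples and ~0 for
#' unrelated samples under Hardy-Weinberg proportions. Monomorphic markers
#' contribute nothing.
#'
#' @param dataset a [genotype_dataset()] with at least 2 samples.
#' @return Symmetric `n_samples x n_samples` matrix with sample-id dimnames.
#' @export
ibs_kinship <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  d <- dataset$dosages
  if (nrow(d) < 2L) stop("kinship requires at least 2 samples")
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers available for kinship")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(d, 2L, 2 * p, `-`)
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), `/`)
  obs <- !is.na(z)
  z[!obs] <- 0
  num <- tcrossprod(z)
  den <- tcrossprod(obs * 1)
  if (any(den == 0)) stop("some sample pairs share no non-missing markers")
  k <- num / den
  dimnames(k) <- list(dataset$sample_ids, dataset$sample_ids)
  k
}

#' Greedy relatedness pruning
#'
#' While any off-diagonal kinship exceeds `ibs_max`, the member of the worst
#' pair with the lower genotype call rate is removed (ties broken by removing
#' the lexicographically later sample id).
#'
#' @param dataset a [genotype_dataset()].
#' @param kinship matrix from [ibs_kinship()] matching the dataset.
#' @param ibs_max kinship threshold above which a pair is considered related.
#' @return list with elements `dataset` (pruned) and `removed` (sample ids).
#' @export
prune_related <- function(dataset, kinship, ibs_max = 0.8) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  n <- length(dataset$sample_ids)
  if (!is.matrix(kinship) || nrow(kinship) != n || ncol(kinship) != n) {
    stop("kinship dimensions do not match the dataset")
  }
  call_rate <- rowMeans(!is.na(dataset$dosages))
  ids <- dataset$sample_ids
  active <- rep(TRUE, n)
  removed <- character(0)
  k <- kinship
  diag(k) <- -Inf
  repeat {
    k_act <- k[active, active, drop = FALSE]
    if (!length(k_act) || max(k_act) <= ibs_max) break
    w <- which(k_act == max(k_act), arr.ind = TRUE)[1, ]
    pair <- which(active)[w]
    i <- pair[1]; j <- pair[2]
    drop_idx <- if (call_rate[i] < call_rate[j]) i
                else if (call_rate[j] < call_rate[i]) j
                else if (ids[i] > ids[j]) i else j
    active[drop_idx] <- FALSE
    removed <- c(removed, ids[drop_idx])
  }
  list(dataset = .subset_dataset(dataset, samples = which(active)),
       removed = removed)
}

#' Apply the full quality-control pass to one population
#'
#' Filters are applied in the order: sample call rate, SNP call rate, minor
#' allele frequency, Hardy-Weinberg, relatedness pruning; the pass is repeated
#' until a fixed point so that all thresholds hold jointly on the output
#' (sample removal can shift per-SNP statistics). Removals are attributed to
#' the first filter that caught them.
#'
#' @param dataset a [genotype_dataset()].
#' @param config a [qc_config()].
#' @return list with elements `dataset` (filtered) and `report` (class
#'   `qc_report`).
#' @export
apply_qc <- function(dataset, config = qc_config()) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(config, "qc_config"))
  counts <- c(sample_call_rate = 0L, snp_call_rate = 0L, maf = 0L,
              hwe = 0L, relatedness = 0L)
  removed_samples <- character(0)
  removed_markers <- character(0)
  n_samples_in <- length(dataset$sample_ids)
  n_snps_in <- nrow(dataset$map)
  cur <- dataset

  repeat {
    changed <- FALSE

    cr_sample <- rowMeans(!is.na(cur$dosages))
    bad <- cr_sample < config$sample_call_min
    if (any(bad)) {
      if (all(bad)) stop("QC removed all samples (sample call rate)")
      counts["sample_call_rate"] <- counts["sample_call_rate"] + sum(bad)
      removed_samples <- c(removed_samples, cur$sample_ids[bad])
      cur <- .subset_dataset(cur, samples = which(!bad))
      changed <- TRUE
    }

    cr_snp <- colMeans(!is.na(cur$dosages))
    bad <- cr_snp < config$snp_call_min
    if (any(bad)) {
      if (all(bad)) stop("QC removed all SNPs (call rate)")
      counts["snp_call_rate"] <- counts["snp_call_rate"] + sum(bad)
      removed_markers <- c(removed_markers, cur$map$marker_id[bad])
      cur <- .subset_dataset(cur, markers = which(!bad))
      changed <- TRUE
    }

    maf <- .maf_columns(cur$dosages)
    bad <- is.na(maf) | maf < config$maf_min
    if (any(bad)) {
      if (all(bad)) stop("QC removed all SNPs (MAF)")
      counts["maf"] <- counts["maf"] + sum(bad)
      removed_markers <- c(removed_markers, cur$map$marker_id[bad])
      cur <- .subset_dataset(cur, markers = which(!bad))
      changed <- TRUE
    }

    hwe_p <- .hwe_columns(cur$dosages)
    bad <- hwe_p <= config$hwe_p_min
    if (any(bad)) {
      if (all(bad)) stop("QC removed all SNPs (HWE)")
      counts["hwe"] <- counts["hwe"] + sum(bad)
      removed_markers <- c(removed_markers, cur$map$marker_id[bad])
      cur <- .subset_dataset(cur, markers = which(!bad))
      changed <- TRUE
    }

    if (length(cur$sample_ids) >= 2L) {
      pr <- prune_related(cur, ibs_kinship(cur), config$ibs_max)
      if (length(pr$removed)) {
        counts["relatedness"] <- counts["relatedness"] + length(pr$removed)
        removed_samples <- c(removed_samples, pr$removed)
        cur <- pr$dataset
        changed <- TRUE
      }
    }

    if (!changed) break
  }

  report <- structure(
    list(population = dataset$population,
         n_samples_in = n_samples_in,
         n_samples_out = length(cur$sample_ids),
         n_snps_in = n_snps_in,
         n_snps_out = nrow(cur$map),
         removals = counts,
         removed_sample_ids = removed_samples,
         removed_marker_ids = removed_markers),
    class = "qc_report"
  )
  list(dataset = cur, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report —", x$population, "\n")
  cat(sprintf("  samples: %d -> %d\n", x$n_samples_in, x$n_samples_out))
  cat(sprintf("  SNPs:    %d -> %d\n", x$n_snps_in, x$n_snps_out))
  cat("  removals by filter:\n")
  for (nm in names(x$removals)) {
    cat(sprintf("    %-18s %d\n", nm, x$removals[[nm]]))
  }
  invisible(x)
}

#' Serialize a QC report to a tab-separated summary
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  df <- data.frame(
    field = c("population", "n_samples_in", "n_samples_out", "n_snps_in",
              "n_snps_out", paste0("removed_", names(report$removals)),
              "removed_sample_ids"),
    value = c(report$population, report$n_samples_in, report$n_samples_out,
              report$n_snps_in, report$n_snps_out,
              unname(report$removals),
              paste(report$removed_sample_ids, collapse = ",")),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
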