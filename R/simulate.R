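# Two-population haplotype-mosaic genotype simulator with implantable
# selective sweeps, plus a QC-violation injector for fixture construction.

#' Specify a selective sweep to implant
#'
#' Inside the sweep interval, haplotype copying in the sweep population is
#' restricted to a residual pool of `residual_founders` founder haplotypes,
#' collapsing local haplotype diversity — the LD footprint of a selective
#' sweep. `residual_founders >= 2` keeps markers polymorphic (LD-based
#' contrasts cannot use monomorphic SNPs).
#'
#' @param chrom chromosome label.
#' @param start_bp,end_bp sweep interval, 1-based inclusive.
#' @param population label of the population carrying the sweep.
#' @param residual_founders size of the collapsed founder pool (>= 2). Setting
#'   it equal to the background founder count makes the sweep a no-op null
#'   control.
#' @export
sweep_spec <- function(chrom, start_bp, end_bp, population,
                       residual_founders = 2L) {
  if (residual_founders < 2L) stop("residual_founders must be >= 2")
  if (start_bp > end_bp) stop("start_bp must be <= end_bp")
  list(chrom = as.character(chrom), start_bp = as.integer(start_bp),
       end_bp = as.integer(end_bp), population = as.character(population),
       residual_founders = as.integer(residual_founders))
}

#' Simulation configuration
#'
#' Defaults emulate a desk-scale version of a dense-SNP two-breed contrast:
#' 150 samples per population, 2 chromosomes x 5,000 markers at ~2 kb mean
#' spacing (a 20 Mb genome), 30 founder haplotypes per population, and
#' per-interval founder-switch probabilities of 0.05 vs 0.10 so that the
#' first population holds LD over roughly twice the distance of the second
#' (a slow-decay vs fast-decay contrast). Allele frequencies are shared
#' between populations; founder haplotypes are drawn independently, giving
#' correlated frequency spectra but distinct LD patterns.
#'
#' @param n_samples length-2 vector of samples per population.
#' @param pop_labels length-2 character vector of population labels.
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers on each chromosome.
#' @param mean_spacing_bp mean distance between adjacent markers.
#' @param n_founders founder haplotypes per population (background
#'   diversity).
#' @param switch_prob length-2 vector: per-marker-interval probability of
#'   switching founder during copying (recombination proxy; smaller = slower
#'   LD decay).
#' @param maf_floor founder allele frequencies are drawn uniformly on
#'   `[maf_floor, 1 - maf_floor]`.
#' @param missing_rate genotype missingness rate, applied uniformly.
#' @param n_duplicates duplicate samples to implant per population.
#' @param sweeps list of [sweep_spec()] entries.
#' @param seed integer seed; simulation is fully reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = c(150L, 150L),
                       pop_labels = c("POP1", "POP2"),
                       n_chromosomes = 2L,
                       markers_per_chromosome = 5000L,
                       mean_spacing_bp = 2000L,
                       n_founders = 30L,
                       switch_prob = c(0.05, 0.10),
                       maf_floor = 0.10,
                       missing_rate = 0.02,
                       n_duplicates = 0L,
                       sweeps = list(),
                       seed = 1L) {
  if (length(n_samples) != 2L || any(n_samples < 2L)) {
    stop("n_samples must give two populations of >= 2 samples")
  }
  if (length(pop_labels) != 2L || anyDuplicated(pop_labels)) {
    stop("pop_labels must be two distinct labels")
  }
  if (n_founders < 2L) stop("n_founders must be >= 2")
  if (length(switch_prob) == 1L) switch_prob <- rep(switch_prob, 2L)
  probs <- c(switch_prob, maf_floor, missing_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (maf_floor >= 0.5) stop("maf_floor must be < 0.5")
  for (sw in sweeps) {
    if (!all(c("chrom", "start_bp", "end_bp", "population",
               "residual_founders") %in% names(sw))) {
      stop("each sweep must be built with sweep_spec()")
    }
    if (sw$residual_founders > n_founders) {
      stop("sweep residual_founders must be <= n_founders")
    }
    if (!sw$population %in% pop_labels) {
      stop("sweep population '", sw$population, "' not among pop_labels")
    }
  }
  structure(list(n_samples = as.integer(n_samples), pop_labels = pop_labels,
                 n_chromosomes = as.integer(n_chromosomes),
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 mean_spacing_bp = as.integer(mean_spacing_bp),
                 n_founders = as.integer(n_founders),
                 switch_prob = switch_prob, maf_floor = maf_floor,
                 missing_rate = missing_rate,
                 n_duplicates = as.integer(n_duplicates),
                 sweeps = sweeps, seed = as.integer(seed)),
            class = "sim_config")
}

# One haplotype as a founder mosaic; returns the founder index path.
.founder_path <- function(m, n_founders, switch_prob) {
  switches <- stats::runif(m - 1L) < switch_prob
  n_seg <- 1L + sum(switches)
  seg_founder <- sample.int(n_founders, n_seg, replace = TRUE)
  seg_founder[cumsum(c(1L, switches))]
}

#' Simulate a pair of populations with optional sweeps
#'
#' Founder haplotypes are drawn per population at shared allele frequencies
#' (uniform on `[maf_floor, 1 - maf_floor]`); each sample haplotype is a
#' founder mosaic with per-interval switch probability. Inside a sweep
#' interval the copying pool of the sweep population collapses to the first
#' `residual_founders` founders (founder index mapped by modulus, preserving
#' mosaic continuity). Genotype = sum of two haplotypes; missingness is
#' applied uniformly at random; duplicates overwrite the last samples with
#' copies of the first ones.
#'
#' @param config a [sim_config()].
#' @return list with elements `pop1`, `pop2` ([genotype_dataset()]s) and
#'   `truth` (data.frame of implanted sweeps: `chrom`, `start_bp`, `end_bp`,
#'   `population`, `residual_founders`).
#' @export
simulate_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  mpc <- config$markers_per_chromosome
  n_chr <- config$n_chromosomes
  m_tot <- mpc * n_chr

  # marker map: exponential spacings (floored at 1 bp)
  chrom <- rep(as.character(seq_len(n_chr)), each = mpc)
  pos <- integer(m_tot)
  for (c_i in seq_len(n_chr)) {
    gaps <- pmax(1L, round(stats::rexp(mpc, 1 / config$mean_spacing_bp)))
    pos[(c_i - 1L) * mpc + seq_len(mpc)] <- cumsum(gaps)
  }
  alleles <- t(replicate(m_tot, sort(sample(c("A", "C", "G", "T"), 2L))))
  map <- data.frame(
    marker_id = sprintf("snp_c%s_%05d", chrom, rep(seq_len(mpc), n_chr)),
    chrom = chrom, pos = pos,
    allele_a = alleles[, 1L], allele_b = alleles[, 2L],
    stringsAsFactors = FALSE
  )

  for (sw in config$sweeps) {
    span <- range(pos[chrom == sw$chrom])
    if (sw$start_bp < span[1] || sw$end_bp > span[2]) {
      stop("sweep [", sw$start_bp, ", ", sw$end_bp,
           "] outside the realized span of chromosome ", sw$chrom)
    }
  }

  freq <- stats::runif(m_tot, config$maf_floor, 1 - config$maf_floor)

  datasets <- vector("list", 2L)
  for (k in 1:2) {
    lab <- config$pop_labels[k]
    n <- config$n_samples[k]
    fo <- matrix(stats::rbinom(config$n_founders * m_tot, 1L, rep(freq, each = config$n_founders)),
                 nrow = config$n_founders)
    sweeps_k <- Filter(function(sw) sw$population == lab, config$sweeps)
    sweep_idx <- lapply(sweeps_k, function(sw) {
      which(chrom == sw$chrom & pos >= sw$start_bp & pos <= sw$end_bp)
    })
    geno <- matrix(0, n, m_tot)
    for (i in seq_len(n)) {
      g <- numeric(m_tot)
      for (h in 1:2) {
        path <- .founder_path(m_tot, config$n_founders, config$switch_prob[k])
        for (s_i in seq_along(sweeps_k)) {
          idx <- sweep_idx[[s_i]]
          r <- sweeps_k[[s_i]]$residual_founders
          path[idx] <- ((path[idx] - 1L) %% r) + 1L
        }
        g <- g + fo[cbind(path, seq_len(m_tot))]
      }
      geno[i, ] <- g
    }
    if (config$missing_rate > 0) {
      geno[stats::runif(length(geno)) < config$missing_rate] <- NA_real_
    }
    ids <- sprintf("%s_s%03d", lab, seq_len(n))
    if (config$n_duplicates > 0L) {
      if (2L * config$n_duplicates > n) stop("too many duplicates requested")
      for (dd in seq_len(config$n_duplicates)) {
        geno[n - dd + 1L, ] <- geno[dd, ]
      }
    }
    datasets[[k]] <- genotype_dataset(geno, map, ids, lab)
  }

  truth <- if (length(config$sweeps)) {
    do.call(rbind, lapply(config$sweeps, function(sw) {
      data.frame(chrom = sw$chrom, start_bp = sw$start_bp,
                 end_bp = sw$end_bp, population = sw$population,
                 residual_founders = sw$residual_founders,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(chrom = character(0), start_bp = integer(0),
               end_bp = integer(0), population = character(0),
               residual_founders = integer(0), stringsAsFactors = FALSE)
  }
  list(pop1 = datasets[[1L]], pop2 = datasets[[2L]], truth = truth)
}

#' Inject quality-control violations into a clean dataset
#'
#' Deterministically (given `seed`) implants the requested number of
#' low-call-rate samples, low-call-rate SNPs, low-MAF SNPs, heterozygote-free
#' HWE-violating SNPs, and duplicate sample pairs, choosing disjoint hosts so
#' each violation trips exactly one QC filter. Returns the modified dataset
#' plus a manifest naming every affected record.
#'
#' @param dataset a [genotype_dataset()] that already passes QC.
#' @param spec named list of counts: `n_low_call_samples`, `n_low_call_snps`,
#'   `n_low_maf_snps`, `n_hwe_snps`, `n_duplicate_pairs` (all optional,
#'   default 0).
#' @param seed integer seed for host selection.
#' @return list with elements `dataset` and `manifest` (lists of affected
#'   sample/marker ids; for duplicate pairs, the member expected to be
#'   removed by pruning).
#' @export
implant_qc_violations <- function(dataset, spec = list(), seed = 1L) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  get0n <- function(nm) {
    v <- spec[[nm]]
    if (is.null(v)) 0L else as.integer(v)
  }
  n_lcs <- get0n("n_low_call_samples")
  n_lc_snp <- get0n("n_low_call_snps")
  n_lmaf <- get0n("n_low_maf_snps")
  n_hwe <- get0n("n_hwe_snps")
  n_dup <- get0n("n_duplicate_pairs")

  d <- dataset$dosages
  n <- nrow(d); m <- ncol(d)
  if (n_lcs + 2L * n_dup > n) stop("not enough samples to host the request")
  if (n_lc_snp + n_lmaf + n_hwe > m) stop("not enough markers to host the request")

  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  samp_pool <- sample.int(n)
  mark_pool <- sample.int(m)
  take_s <- function(k) {
    if (k == 0L) return(integer(0))
    out <- samp_pool[seq_len(k)]
    samp_pool <<- samp_pool[-seq_len(k)]
    out
  }
  take_m <- function(k) {
    if (k == 0L) return(integer(0))
    out <- mark_pool[seq_len(k)]
    mark_pool <<- mark_pool[-seq_len(k)]
    out
  }

  low_call_samples <- take_s(n_lcs)
  for (i in low_call_samples) {
    d[i, sample.int(m, ceiling(0.2 * m))] <- NA_real_
  }

  low_call_snps <- take_m(n_lc_snp)
  for (j in low_call_snps) {
    d[sample.int(n, ceiling(0.2 * n)), j] <- NA_real_
  }

  low_maf_snps <- take_m(n_lmaf)
  for (j in low_maf_snps) {
    d[, j] <- 0
    d[sample.int(n, 1L), j] <- 1
  }

  hwe_snps <- take_m(n_hwe)
  for (j in hwe_snps) {
    half <- sample.int(n, floor(n / 2))
    d[, j] <- 0
    d[half, j] <- 2
  }

  dup_pairs <- NULL
  if (n_dup > 0L) {
    for (dd in seq_len(n_dup)) {
      pair <- take_s(2L)
      d[pair[2L], ] <- d[pair[1L], ]
      ids <- dataset$sample_ids[pair]
      dup_pairs <- rbind(dup_pairs, data.frame(
        sample_1 = ids[1L], sample_2 = ids[2L],
        expected_removed = max(ids),   # equal call rates: lex-later removed
        stringsAsFactors = FALSE
      ))
    }
  }

  manifest <- list(
    low_call_samples = dataset$sample_ids[low_call_samples],
    low_call_snps = dataset$map$marker_id[low_call_snps],
    low_maf_snps = dataset$map$marker_id[low_maf_snps],
    hwe_snps = dataset$map$marker_id[hwe_snps],
    duplicate_pairs = dup_pairs
  )
  list(dataset = genotype_dataset(d, dataset$map, dataset$sample_ids,
                                  dataset$population),
       manifest = manifest)
}
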