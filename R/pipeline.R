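# End-to-end orchestration: QC -> intersect -> MDS -> LD decay -> scan ->
# standardize -> call -> assign -> overlap -> coverage, with a run manifest.

#' Run configuration for a two-population comparison
#'
#' @param qc a [qc_config()].
#' @param window_size,step VarLD scan parameters (SNPs).
#' @param percentiles percentile thresholds at which signals are called.
#' @param gene_bed,cnv_bed optional BED annotation paths.
#' @param chromosome_lengths optional named vector of chromosome lengths for
#'   the coverage summary; defaults to the maximum marker position per
#'   chromosome of the intersected map.
#' @param output_dir directory for all output tables.
#' @param seed integer seed recorded in the manifest (the deterministic
#'   pipeline stages do not consume randomness).
#' @export
run_config <- function(qc = qc_config(), window_size = 50L, step = 1L,
                       percentiles = c(99.9, 99.99), gene_bed = NULL,
                       cnv_bed = NULL, chromosome_lengths = NULL,
                       output_dir = tempfile("varld_run_"), seed = 1L) {
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie in (0, 100)")
  }
  if (window_size < 2L) stop("window_size must be >= 2")
  structure(list(qc = qc, window_size = as.integer(window_size),
                 step = as.integer(step), percentiles = percentiles,
                 gene_bed = gene_bed, cnv_bed = cnv_bed,
                 chromosome_lengths = chromosome_lengths,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full two-population comparison pipeline
#'
#' Executes QC on each population, extracts common SNPs, computes the
#' kinship MDS of the pooled samples, per-population LD-decay curves, the
#' VarLD scan with genome-wide standardization, calls signals at each
#' configured percentile, assigns each signal to the population with higher
#' regional LD, overlaps signals with gene/CNV annotations when provided,
#' and writes every table plus a machine-readable JSON manifest (parameters,
#' seed, input/output digests) under `config$output_dir`.
#'
#' @param a,b [genotype_dataset()] objects, or paths: a length-2 character
#'   vector `c(ped, map)` is read via [read_ped_map()].
#' @param config a [run_config()].
#' @param pop_labels labels used when `a`/`b` are paths.
#' @return Invisibly, a list with the in-memory stage results (`qc_a`,
#'   `qc_b`, `common`, `mds`, `decay_a`, `decay_b`, `track`, `signals` — one
#'   `signal_regions` per percentile — `coverage`, `overlaps`, `manifest`).
#' @export
run_pipeline <- function(a, b, config = run_config(),
                         pop_labels = c("POP1", "POP2")) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)

  load_one <- function(x, lab) {
    if (inherits(x, "genotype_dataset")) return(x)
    if (is.character(x) && length(x) == 2L) {
      inputs <<- c(inputs, x)
      return(read_ped_map(x[1], x[2], lab))
    }
    stop("expected a genotype_dataset or c(ped_path, map_path)")
  }
  a <- .stage("load", load_one(a, pop_labels[1]))
  b <- .stage("load", load_one(b, pop_labels[2]))

  # annotation paths are validated up front so a bad path fails cleanly
  anns <- NULL
  for (src in c("gene", "cnv")) {
    p <- config[[paste0(src, "_bed")]]
    if (!is.null(p)) {
      anns <- rbind(anns, .stage("annotations", read_bed_intervals(p, src)))
    }
  }

  qa <- .stage("qc", apply_qc(a, config$qc))
  qb <- .stage("qc", apply_qc(b, config$qc))
  write_qc_report(qa$report, file.path(out_dir, paste0("qc_", a$population, ".tsv")))
  write_qc_report(qb$report, file.path(out_dir, paste0("qc_", b$population, ".tsv")))

  common <- .stage("intersect", intersect_common_snps(qa$dataset, qb$dataset))

  mds <- .stage("mds", {
    pooled <- genotype_dataset(
      rbind(common$a$dosages, common$b$dosages), common$a$map,
      c(common$a$sample_ids, common$b$sample_ids), "pooled"
    )
    classical_mds(kinship_to_sq_distance(ibs_kinship(pooled)), k = 2)
  })
  pops <- c(rep(common$a$population, length(common$a$sample_ids)),
            rep(common$b$population, length(common$b$sample_ids)))
  write_mds_coordinates(mds, pops, file.path(out_dir, "mds_coordinates.tsv"))

  decay_a <- .stage("ld_decay", ld_decay(common$a))
  decay_b <- .stage("ld_decay", ld_decay(common$b))
  utils::write.table(decay_a, file.path(out_dir, paste0("ld_decay_", a$population, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(decay_b, file.path(out_dir, paste0("ld_decay_", b$population, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  track <- .stage("scan", varld(common$a, common$b,
                                window_size = config$window_size,
                                step = config$step, standardize = TRUE))
  write_varld_track(track, file.path(out_dir, "varld_track.tsv"))

  chrom_len <- config$chromosome_lengths
  if (is.null(chrom_len)) {
    chrom_len <- tapply(common$a$map$pos, common$a$map$chrom, max)
    chrom_len <- stats::setNames(as.numeric(chrom_len), names(chrom_len))
  }

  signals <- list()
  coverage <- list()
  overlaps <- list()
  for (p in config$percentiles) {
    key <- paste0("p", p)
    thr <- .stage("call", percentile_threshold(track, p))
    regs <- .stage("call", call_signals(track, thr))
    if (nrow(regs)) {
      asg <- lapply(seq_len(nrow(regs)), function(i) {
        assign_population(regs[i, ], common$a, common$b)
      })
      regs$assigned_population <- vapply(asg, `[[`, character(1), "population")
      regs$assignment_margin <- vapply(asg, `[[`, numeric(1), "margin")
    } else {
      regs$assigned_population <- character(0)
      regs$assignment_margin <- numeric(0)
    }
    signals[[key]] <- regs
    cov <- .stage("coverage", coverage_summary(regs, chrom_len))
    coverage[[key]] <- cov
    ov <- if (!is.null(anns)) .stage("overlap", overlap_annotations(regs, anns))
          else NULL
    overlaps[[key]] <- ov
    write_signal_report(regs, file.path(out_dir, paste0("signals_", key, ".tsv")), ov)
    if (nrow(regs)) {
      write_bed(data.frame(chrom = regs$chrom, start = regs$start_bp,
                           end = regs$end_bp,
                           name = paste0("signal_", seq_len(nrow(regs)))),
                file.path(out_dir, paste0("signals_", key, ".bed")))
    }
    if (!is.null(ov)) {
      utils::write.table(ov, file.path(out_dir, paste0("overlaps_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  cov_df <- data.frame(
    percentile = config$percentiles,
    total_bp = vapply(coverage, `[[`, numeric(1), "total_bp"),
    fraction = vapply(coverage, `[[`, numeric(1), "fraction")
  )
  utils::write.table(cov_df, file.path(out_dir, "coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  out_files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    comparison = attr(track, "comparison"),
    parameters = list(window_size = config$window_size, step = config$step,
                      percentiles = config$percentiles,
                      qc = unclass(config$qc)),
    seed = config$seed,
    inputs = as.list(stats::setNames(
      if (length(inputs)) unname(tools::md5sum(inputs)) else character(0),
      basename(inputs))),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, out_files))), out_files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(qc_a = qa, qc_b = qb, common = common, mds = mds,
                 decay_a = decay_a, decay_b = decay_b, track = track,
                 signals = signals, coverage = coverage, overlaps = overlaps,
                 manifest = manifest, output_dir = out_dir))
}

#' Run all pairwise comparisons among several populations
#'
#' Enumerates every unordered pair of the supplied populations, runs
#' [run_pipeline()] for each into its own subdirectory, concatenates the
#' signal tables with comparison labels, and marks signals shared across
#' comparisons by interval overlap. A failed pair is reported in the result;
#' the remaining pairs still complete.
#'
#' @param datasets named list (>= 2) of [genotype_dataset()] objects.
#' @param config a [run_config()]; each pair writes under
#'   `file.path(config$output_dir, "<A>_vs_<B>")`.
#' @return list with elements `signals` (combined data.frame per percentile,
#'   with a `shared_with` column), `errors` (named list of failure messages)
#'   and `runs` (per-pair results).
#' @export
run_comparisons <- function(datasets, config = run_config()) {
  if (length(datasets) < 2L) stop("need at least 2 populations")
  labs <- vapply(datasets, function(d) d$population, character(1))
  pairs <- utils::combn(length(datasets), 2L)
  runs <- list()
  errors <- list()
  for (p_i in seq_len(ncol(pairs))) {
    i <- pairs[1L, p_i]; j <- pairs[2L, p_i]
    key <- paste0(labs[i], "_vs_", labs[j])
    cfg <- config
    cfg$output_dir <- file.path(config$output_dir, key)
    runs[[key]] <- tryCatch(
      run_pipeline(datasets[[i]], datasets[[j]], cfg),
      error = function(e) {
        errors[[key]] <<- conditionMessage(e)
        NULL
      }
    )
  }
  ok <- !vapply(runs, is.null, logical(1))
  combined <- list()
  pct_keys <- paste0("p", config$percentiles)
  for (key in pct_keys) {
    tabs <- lapply(runs[ok], function(r) as.data.frame(r$signals[[key]]))
    tab <- do.call(rbind, tabs)
    rownames(tab) <- NULL
    if (!is.null(tab) && nrow(tab)) {
      gr <- .to_granges(tab$chrom, tab$start_bp, tab$end_bp)
      hits <- GenomicRanges::findOverlaps(gr, gr)
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      keep <- qi != si & tab$comparison[qi] != tab$comparison[si]
      shared <- split(tab$comparison[si[keep]], qi[keep])
      tab$shared_with <- ""
      tab$shared_with[as.integer(names(shared))] <-
        vapply(shared, function(s) paste(sort(unique(s)), collapse = ","),
               character(1))
    }
    combined[[key]] <- tab
    if (!is.null(tab)) {
      utils::write.table(tab, file.path(config$output_dir,
                                        paste0("combined_signals_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(signals = combined, errors = errors, runs = runs)
}
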