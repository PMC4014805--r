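# Threshold-based signal calling, sweep-to-population assignment, and
# gene/CNV interval overlap with coverage summaries.

#' Call signal regions from a standardized VarLD track
#'
#' Windows with `std_score >= threshold` are flagged; flagged windows on the
#' same chromosome whose SNP-index ranges overlap or abut are merged into one
#' region. A region's `start_bp` is the mid-bp of its first window and its
#' `end_bp` the mid-bp of its last window.
#'
#' @param track a standardized `varld` object.
#' @param threshold score threshold (see [percentile_threshold()]).
#' @return Object of class `signal_regions`: data.frame with columns
#'   `comparison`, `chrom`, `start_bp`, `end_bp`, `peak_std_score`,
#'   `n_windows`, `first_window_index`, `last_window_index`, sorted by
#'   (chromosome, start).
#' @export
call_signals <- function(track, threshold) {
  stopifnot(inherits(track, "varld"))
  if (anyNA(track$std_score)) stop("track is not standardized")
  w <- attr(track, "window_size")
  comparison <- attr(track, "comparison")
  empty <- data.frame(
    comparison = character(0), chrom = character(0),
    start_bp = integer(0), end_bp = integer(0),
    peak_std_score = numeric(0), n_windows = integer(0),
    first_window_index = integer(0), last_window_index = integer(0),
    stringsAsFactors = FALSE
  )
  flagged <- track[track$std_score >= threshold, , drop = FALSE]
  if (!nrow(flagged)) {
    return(structure(empty, class = c("signal_regions", "data.frame")))
  }
  res <- list()
  for (ch in .chrom_levels(flagged$chrom)) {
    fw <- flagged[flagged$chrom == ch, , drop = FALSE]
    fw <- fw[order(fw$first_index), , drop = FALSE]
    run_start <- 1L
    for (i in seq_len(nrow(fw))) {
      last_of_run <- i == nrow(fw) ||
        fw$first_index[i + 1L] > fw$first_index[i] + w - 1L + 1L
      if (last_of_run) {
        block <- fw[run_start:i, , drop = FALSE]
        res[[length(res) + 1L]] <- data.frame(
          comparison = comparison, chrom = ch,
          start_bp = block$mid_bp[1L],
          end_bp = block$mid_bp[nrow(block)],
          peak_std_score = max(block$std_score),
          n_windows = nrow(block),
          first_window_index = block$first_index[1L],
          last_window_index = block$first_index[nrow(block)],
          stringsAsFactors = FALSE
        )
        run_start <- i + 1L
      }
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(match(out$chrom, .chrom_levels(out$chrom)), out$start_bp), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("signal_regions", "data.frame"))
}

#' Assign a signal region to the population with higher regional LD
#'
#' The mean pairwise r2 over all SNP pairs inside `[start_bp, end_bp]` is
#' computed for each population; the region is assigned to the population
#' with the larger mean and the difference reported as the margin. A region
#' holding fewer than 2 SNPs cannot be assigned.
#'
#' @param region one row of a `signal_regions` data.frame (or any list with
#'   `chrom`, `start_bp`, `end_bp`).
#' @param a,b the two [genotype_dataset()] objects of the comparison (shared
#'   marker map).
#' @return list with elements `population` (label or `NA` if unassignable),
#'   `margin` (difference of regional mean r2) and `tie` (logical).
#' @export
assign_population <- function(region, a, b) {
  stopifnot(inherits(a, "genotype_dataset"), inherits(b, "genotype_dataset"))
  idx <- which(a$map$chrom == region$chrom &
               a$map$pos >= region$start_bp & a$map$pos <= region$end_bp)
  if (length(idx) < 2L) {
    return(list(population = NA_character_, margin = NA_real_, tie = FALSE))
  }
  r2_a <- .pair_r2_mean(a$dosages[, idx, drop = FALSE])
  r2_b <- .pair_r2_mean(b$dosages[, idx, drop = FALSE])
  if (r2_a == r2_b) {
    warning("regional LD tie between ", a$population, " and ", b$population,
            "; assigning to ", a$population)
    return(list(population = a$population, margin = 0, tie = TRUE))
  }
  if (r2_a > r2_b) {
    list(population = a$population, margin = r2_a - r2_b, tie = FALSE)
  } else {
    list(population = b$population, margin = r2_b - r2_a, tie = FALSE)
  }
}

# GRanges from 1-based inclusive data.frame columns.
.to_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start), end = as.integer(end))
  )
}

#' Overlap signal regions with annotation intervals
#'
#' Reports every (region, annotation) pair sharing at least 1 bp (1-based
#' inclusive coordinates), with the overlap length.
#'
#' @param regions `signal_regions` data.frame (columns `chrom`, `start_bp`,
#'   `end_bp`).
#' @param annotations data.frame of intervals as returned by
#'   [read_bed_intervals()] (columns `chrom`, `start`, `end`, `name`,
#'   `source`).
#' @return data.frame with one row per overlapping pair: region columns,
#'   annotation name/source/coordinates, and `overlap_bp`.
#' @export
overlap_annotations <- function(regions, annotations) {
  empty <- data.frame(
    region_index = integer(0), comparison = character(0),
    chrom = character(0), region_start = integer(0), region_end = integer(0),
    name = character(0), source = character(0),
    ann_start = integer(0), ann_end = integer(0), overlap_bp = integer(0),
    stringsAsFactors = FALSE
  )
  if (!nrow(regions) || !nrow(annotations)) return(empty)
  gr_r <- .to_granges(regions$chrom, regions$start_bp, regions$end_bp)
  gr_a <- .to_granges(annotations$chrom, annotations$start, annotations$end)
  hits <- GenomicRanges::findOverlaps(gr_r, gr_a)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(gr_r[qi], gr_a[si])
  data.frame(
    region_index = qi,
    comparison = if ("comparison" %in% names(regions))
      regions$comparison[qi] else NA_character_,
    chrom = regions$chrom[qi],
    region_start = regions$start_bp[qi],
    region_end = regions$end_bp[qi],
    name = annotations$name[si],
    source = annotations$source[si],
    ann_start = annotations$start[si],
    ann_end = annotations$end[si],
    overlap_bp = GenomicRanges::width(ov),
    stringsAsFactors = FALSE
  )
}

#' Genomic coverage of a set of signal regions
#'
#' Regions are merged (union) before summing, so overlapping or duplicated
#' regions are counted once. The fraction is taken over the summed chromosome
#' lengths.
#'
#' @param regions data.frame with columns `chrom`, `start_bp`, `end_bp`.
#' @param chromosome_lengths named numeric vector (chromosome -> length in
#'   bp) or data.frame with columns `chrom`, `length`.
#' @return list with elements `total_bp` (union length) and `fraction`
#'   (of the summed chromosome lengths).
#' @export
coverage_summary <- function(regions, chromosome_lengths) {
  if (is.data.frame(chromosome_lengths)) {
    chromosome_lengths <- stats::setNames(
      as.numeric(chromosome_lengths$length),
      as.character(chromosome_lengths$chrom)
    )
  }
  genome_bp <- sum(chromosome_lengths)
  if (!nrow(regions)) return(list(total_bp = 0, fraction = 0))
  known <- regions$chrom %in% names(chromosome_lengths)
  if (!all(known)) {
    stop("regions on chromosomes without a length: ",
         paste(unique(regions$chrom[!known]), collapse = ", "))
  }
  if (any(regions$end_bp > chromosome_lengths[regions$chrom])) {
    stop("region exceeds its chromosome length")
  }
  gr <- .to_granges(regions$chrom, regions$start_bp, regions$end_bp)
  merged <- GenomicRanges::reduce(gr)
  total <- sum(as.numeric(GenomicRanges::width(merged)))
  list(total_bp = total, fraction = total / genome_bp)
}

#' Write signal regions as a tab-separated report
#'
#' Columns follow the comparison / chromosome / start / end / genes layout,
#' with the gene list drawn from an [overlap_annotations()] table when given.
#'
#' @param regions `signal_regions` data.frame.
#' @param path output path.
#' @param overlaps optional [overlap_annotations()] output used to fill the
#'   `genes` column.
#' @export
write_signal_report <- function(regions, path, overlaps = NULL) {
  genes <- rep("", nrow(regions))
  if (!is.null(overlaps) && nrow(overlaps)) {
    gl <- split(overlaps$name, overlaps$region_index)
    genes[as.integer(names(gl))] <-
      vapply(gl, function(g) paste(unique(g), collapse = ","), character(1))
  }
  df <- data.frame(
    comparison = regions$comparison,
    chrom = regions$chrom,
    start_bp = regions$start_bp,
    end_bp = regions$end_bp,
    peak_std_score = regions$peak_std_score,
    n_windows = regions$n_windows,
    assigned_population = if ("assigned_population" %in% names(regions))
      regions$assigned_population else NA_character_,
    genes = genes,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
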