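# Genotype container and PLINK-text / dosage-table IO.

#' Construct a genotype dataset
#'
#' The universal currency of the package: a samples x markers dosage matrix for
#' one labelled population, together with its marker map. Dosages count copies
#' of `allele_b`, defined throughout as the lexicographically later of the two
#' allele characters; missing genotypes are `NA`.
#'
#' @param dosages numeric matrix, `n_samples x n_markers`, entries in
#'   `{0, 1, 2, NA}`.
#' @param map data.frame with columns `marker_id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`; positions are 1-based bp, strictly increasing within each
#'   chromosome.
#' @param sample_ids character vector of unique sample identifiers.
#' @param population single string labelling the population.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosages, map, sample_ids, population) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  needed <- c("marker_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(needed %in% names(map))) {
    stop("map must have columns: ", paste(needed, collapse = ", "))
  }
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  map$allele_a <- as.character(map$allele_a)
  map$allele_b <- as.character(map$allele_b)
  sample_ids <- as.character(sample_ids)
  if (length(population) != 1L || !nzchar(population)) {
    stop("population must be a single non-empty string")
  }
  if (nrow(dosages) != length(sample_ids)) {
    stop("dosage rows (", nrow(dosages), ") != number of samples (",
         length(sample_ids), ")")
  }
  if (ncol(dosages) != nrow(map)) {
    stop("dosage columns (", ncol(dosages), ") != number of markers (",
         nrow(map), ")")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(map$marker_id)) stop("duplicate marker ids")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (any(map$pos < 1L)) stop("positions must be >= 1")
  if (any(map$allele_a == map$allele_b)) stop("allele_a must differ from allele_b")
  if (anyDuplicated(paste(map$chrom, map$pos))) {
    stop("duplicate (chromosome, position) pairs in map")
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  dimnames(dosages) <- list(sample_ids, map$marker_id)
  structure(
    list(dosages = dosages, map = map, sample_ids = sample_ids,
         population = population),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", x$population, "\n")
  cat("  samples:", length(x$sample_ids),
      " markers:", nrow(x$map),
      " chromosomes:", length(unique(x$map$chrom)), "\n")
  miss <- mean(is.na(x$dosages))
  cat("  missing genotype rate:", format(round(miss, 4)), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

# Order chromosome labels numerically when all are numeric-like, else
# lexicographically.
.chrom_levels <- function(chroms) {
  u <- unique(as.character(chroms))
  n <- suppressWarnings(as.numeric(u))
  if (!anyNA(n)) u[order(n)] else sort(u)
}

# Subset a dataset, keeping invariants (marker order must stay sorted).
.subset_dataset <- function(x, samples = NULL, markers = NULL) {
  d <- x$dosages
  ids <- x$sample_ids
  map <- x$map
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    ids <- ids[samples]
  }
  if (!is.null(markers)) {
    d <- d[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
  }
  rownames(map) <- NULL
  genotype_dataset(d, map, ids, x$population)
}

# Sort markers by (chromosome, position) with numeric-aware chromosome order.
.marker_order <- function(map) {
  lev <- .chrom_levels(map$chrom)
  order(match(map$chrom, lev), map$pos)
}

# Resolve the (allele_a, allele_b) pair from the alleles observed at a marker.
# A marker observed with a single allele gets a synthetic placeholder partner
# so that allele_a != allele_b; its dosages are coded 0 (the observed allele is
# allele_a). The placeholder is never written back to disk.
.resolve_alleles <- function(observed, marker_id) {
  observed <- sort(unique(observed[observed != "0"]))
  if (length(observed) > 2L) {
    stop("more than 2 distinct alleles at marker ", marker_id, ": ",
         paste(observed, collapse = ","))
  }
  if (length(observed) == 2L) {
    return(observed)                       # sorted: allele_b is lex-later
  }
  if (length(observed) == 1L) {
    placeholder <- if (observed == "Z") "z" else "Z"   # lex-later than A-T,a-y
    return(c(observed, placeholder))
  }
  c("A", "Z")                              # all-missing column
}

#' Read a PLINK text PED/MAP pair
#'
#' Alleles at each marker are inferred from the characters observed in the PED
#' file; the dosage counts copies of the lexicographically later allele
#' (`allele_b`). A genotype containing the missing code `0` becomes `NA`.
#' Markers are sorted by (chromosome, position) on read.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param population_label population label to attach.
#' @return A [genotype_dataset()].
#' @export
read_ped_map <- function(ped_path, map_path, population_label) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) == 4L) {
    map <- data.frame(marker_id = map_raw[[2]], chrom = map_raw[[1]],
                      pos = as.integer(map_raw[[4]]),
                      stringsAsFactors = FALSE)
  } else if (ncol(map_raw) == 3L) {
    map <- data.frame(marker_id = map_raw[[2]], chrom = map_raw[[1]],
                      pos = as.integer(map_raw[[3]]),
                      stringsAsFactors = FALSE)
  } else {
    stop("MAP file must have 3 or 4 columns, found ", ncol(map_raw))
  }
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (length(fields)) {
    len <- lengths(fields)
    if (length(unique(len)) > 1L) {
      stop("ragged PED file: rows with ", paste(unique(len), collapse = ", "),
           " fields")
    }
    if (len[1] != 6L + 2L * m) {
      stop("PED row has ", (len[1] - 6L) / 2, " genotype columns but MAP has ",
           m, " markers")
    }
  }
  n <- length(fields)
  sample_ids <- vapply(fields, `[`, character(1), 2L)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  for (i in seq_len(n)) {
    g <- fields[[i]][-(1:6)]
    a1[i, ] <- g[seq(1L, 2L * m, by = 2L)]
    a2[i, ] <- g[seq(2L, 2L * m, by = 2L)]
  }

  dos <- matrix(NA_real_, n, m)
  allele_a <- character(m)
  allele_b <- character(m)
  for (j in seq_len(m)) {
    ab <- .resolve_alleles(c(a1[, j], a2[, j]), map$marker_id[j])
    allele_a[j] <- ab[1]
    allele_b[j] <- ab[2]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dos[, j] <- (a1[, j] == ab[2]) + (a2[, j] == ab[2])
    dos[miss, j] <- NA_real_
  }
  map$allele_a <- allele_a
  map$allele_b <- allele_b

  ord <- .marker_order(map)
  genotype_dataset(dos[, ord, drop = FALSE], map[ord, , drop = FALSE],
                   sample_ids, population_label)
}

#' Write a dataset as PLINK text PED/MAP
#'
#' Missing dosages are written as `0 0`. The output is re-readable by
#' [read_ped_map()] with dosages preserved for all markers observed with both
#' alleles.
#'
#' @param dataset a [genotype_dataset()].
#' @param ped_path,map_path output paths.
#' @export
write_ped_map <- function(dataset, ped_path, map_path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  map <- dataset$map
  map_lines <- paste(map$chrom, map$marker_id, 0L, map$pos, sep = "\t")
  ok <- tryCatch(writeLines(map_lines, map_path), error = function(e) {
    stop("cannot write MAP file ", map_path, ": ", conditionMessage(e))
  })
  n <- length(dataset$sample_ids)
  m <- nrow(map)
  geno <- matrix("0 0", n, m)
  d <- dataset$dosages
  for (j in seq_len(m)) {
    a <- map$allele_a[j]; b <- map$allele_b[j]
    codes <- c(paste(a, a), paste(a, b), paste(b, b))
    col <- d[, j]
    geno[, j] <- ifelse(is.na(col), "0 0", codes[col + 1L])
  }
  ped_lines <- vapply(seq_len(n), function(i) {
    paste(c(dataset$sample_ids[i], dataset$sample_ids[i], "0", "0", "0", "-9",
            geno[i, ]), collapse = " ")
  }, character(1))
  tryCatch(writeLines(ped_lines, ped_path), error = function(e) {
    stop("cannot write PED file ", ped_path, ": ", conditionMessage(e))
  })
  invisible(NULL)
}

#' Write / read the internal tab-separated dosage format
#'
#' The dosage table has a `sample_id` column followed by one column per marker
#' (header = marker ids); the companion map file carries the marker map.
#'
#' @param dataset a [genotype_dataset()].
#' @param dosage_path,map_path file paths.
#' @export
write_dosage <- function(dataset, dosage_path, map_path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  df <- data.frame(sample_id = dataset$sample_ids,
                   dataset$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, dosage_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_dosage
#' @param population_label population label to attach on read.
#' @export
read_dosage <- function(dosage_path, map_path, population_label) {
  df <- utils::read.table(dosage_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  map$pos <- as.integer(map$pos)
  d <- as.matrix(df[, -1, drop = FALSE])
  genotype_dataset(d, map, df$sample_id, population_label)
}

#' Restrict two datasets to their common markers, harmonizing alleles
#'
#' Markers are matched on (chromosome, position). When a marker's alleles are
#' swapped between the two datasets, dosages in `b` are recoded as `2 - d` and
#' its allele labels swapped; markers whose allele sets differ beyond a swap
#' are dropped. Both outputs carry the same markers in the same order.
#'
#' @param a,b [genotype_dataset()] objects (assumed already quality-controlled).
#' @return A list with elements `a` and `b`.
#' @export
intersect_common_snps <- function(a, b) {
  stopifnot(inherits(a, "genotype_dataset"), inherits(b, "genotype_dataset"))
  key_a <- paste(a$map$chrom, a$map$pos)
  key_b <- paste(b$map$chrom, b$map$pos)
  common <- intersect(key_a, key_b)
  if (!length(common)) stop("no common markers between the two datasets")
  ia <- match(common, key_a)
  ib <- match(common, key_b)

  same <- a$map$allele_a[ia] == b$map$allele_a[ib] &
          a$map$allele_b[ia] == b$map$allele_b[ib]
  swapped <- a$map$allele_a[ia] == b$map$allele_b[ib] &
             a$map$allele_b[ia] == b$map$allele_a[ib]
  keep <- same | swapped
  if (!any(keep)) stop("no common markers with compatible alleles")
  ia <- ia[keep]; ib <- ib[keep]; swapped <- swapped[keep]

  b_dos <- b$dosages[, ib, drop = FALSE]
  b_map <- b$map[ib, , drop = FALSE]
  if (any(swapped)) {
    b_dos[, swapped] <- 2 - b_dos[, swapped]
    tmp <- b_map$allele_a[swapped]
    b_map$allele_a[swapped] <- b_map$allele_b[swapped]
    b_map$allele_b[swapped] <- tmp
  }
  a_out <- .subset_dataset(a, markers = ia)
  ord <- .marker_order(a_out$map)
  a_out <- .subset_dataset(a_out, markers = ord)
  b_out <- genotype_dataset(b_dos[, ord, drop = FALSE],
                            {m <- b_map[ord, , drop = FALSE]; rownames(m) <- NULL; m},
                            b$sample_ids, b$population)
  list(a = a_out, b = b_out)
}

#' Read a BED-style annotation file
#'
#' BED intervals are 0-based half-open on disk and converted to the package's
#' 1-based inclusive convention on read. A 4th column, when present, supplies
#' interval names.
#'
#' @param path path to a 3+ column BED file.
#' @param source annotation source tag, `"gene"` or `"cnv"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `source`
#'   (1-based inclusive coordinates).
#' @export
read_bed_intervals <- function(path, source = c("gene", "cnv")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("BED file must have >= 3 columns: ", path)
  out <- data.frame(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]) + 1L,
    end = as.integer(raw[[3]]),
    name = if (ncol(raw) >= 4L) as.character(raw[[4]])
           else paste0(source, "_", seq_len(nrow(raw))),
    source = source,
    stringsAsFactors = FALSE
  )
  if (any(out$start > out$end)) stop("invalid interval (start > end) in ", path)
  out
}

#' Write genomic regions as BED (0-based half-open)
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`.
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  nm <- if ("name" %in% names(regions)) regions$name
        else paste0("region_", seq_len(nrow(regions)))
  lines <- paste(regions$chrom, regions$start - 1L, regions$end, nm,
                 sep = "\t")
  writeLines(lines, path)
  invisible(NULL)
}
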