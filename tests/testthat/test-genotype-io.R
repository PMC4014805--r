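# Genotype container, PLINK text IO, dosage tables, marker intersection.

test_that("PED/MAP round-trips preserve dosages and the missing-code convention", {
  dos <- rbind(c(0, 1, 2), c(2, NA, 1))
  ds <- make_dataset(dos, population = "toy")
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  write_ped_map(ds, ped, map)

  # missing dosage is written as the PLINK missing genotype "0 0"
  ped_fields <- strsplit(readLines(ped)[2], " ")[[1]]
  expect_equal(ped_fields[9:10], c("0", "0"))

  back <- read_ped_map(ped, map, "toy")
  expect_equal(unname(back$dosages), unname(ds$dosages))
  expect_equal(back$map$chrom, ds$map$chrom)
  expect_equal(back$map$pos, ds$map$pos)

  # read-write-read is the identity
  ped2 <- tempfile(); map2 <- tempfile()
  write_ped_map(back, ped2, map2)
  again <- read_ped_map(ped2, map2, "toy")
  expect_identical(again$dosages, back$dosages)
})

test_that("PED parsing rejects ragged rows and PED/MAP dimension mismatches", {
  map <- tempfile()
  writeLines(c("1\tm1\t0\t100", "1\tm2\t0\t200", "1\tm3\t0\t300"), map)
  ped <- tempfile()
  # 5 genotype columns against a 3-marker map
  writeLines("f1 s1 0 0 0 -9 A A A G G G A A G G", ped)
  expect_error(read_ped_map(ped, map, "x"), "genotype columns")
  writeLines(c("f1 s1 0 0 0 -9 A A A G G G",
               "f2 s2 0 0 0 -9 A A A G"), ped)
  expect_error(read_ped_map(ped, map, "x"), "ragged")
  writeLines("f1 s1 0 0 0 -9 A A A G G C", ped)
  ok <- read_ped_map(ped, map, "x")
  expect_equal(unname(ok$dosages[1, ]), c(0, 1, 1))  # lex-later allele counted
  writeLines("f1 s1 0 0 0 -9 A A A G G 0", ped)
  na_ds <- read_ped_map(ped, map, "x")
  expect_true(is.na(na_ds$dosages[1, 3]))
  # three distinct alleles at one marker
  writeLines(c("f1 s1 0 0 0 -9 A A C C G G",
               "f2 s2 0 0 0 -9 A A C C T C"), ped)
  expect_error(read_ped_map(ped, map, "x"), "m3")
})

test_that("an empty dataset writes an empty PED and a full MAP", {
  ds <- make_dataset(matrix(numeric(0), nrow = 0, ncol = 3))
  ped <- tempfile(); map <- tempfile()
  write_ped_map(ds, ped, map)
  expect_length(readLines(ped), 0)
  expect_length(readLines(map), 3)
  back <- read_ped_map(ped, map, "empty")
  expect_equal(nrow(back$dosages), 0L)
  expect_equal(back$map$pos, ds$map$pos)
})

test_that("the tabular dosage format round-trips", {
  dos <- rbind(c(0, 1, 2, NA), c(2, 0, 1, 1), c(1, NA, 0, 2))
  ds <- make_dataset(dos, population = "p")
  dp <- tempfile(); mp <- tempfile()
  write_dosage(ds, dp, mp)
  back <- read_dosage(dp, mp, "p")
  expect_equal(unname(back$dosages), unname(ds$dosages))
  expect_equal(back$map, ds$map)
})

test_that("dataset invariants are enforced", {
  expect_error(make_dataset(rbind(c(0, 3))), "dosages must be")
  expect_error(make_dataset(rbind(c(0, 1)), pos = c(200L, 100L)),
               "strictly increasing")
  expect_error(make_dataset(rbind(c(0, 1)), pos = c(100L, 100L)),
               "duplicate \\(chromosome, position\\)")
  expect_error(
    genotype_dataset(rbind(c(0, 1)),
                     data.frame(marker_id = c("m1", "m2"), chrom = "1",
                                pos = c(1L, 2L), allele_a = "A",
                                allele_b = "A"),
                     "s1", "p"),
    "allele_a must differ")
})

test_that("intersect_common_snps handles identity, subsetting and allele swaps", {
  a <- make_dataset(rbind(c(0, 1, 2), c(1, 2, 0)), pos = c(100L, 200L, 300L))
  # identical maps: both unchanged
  b <- make_dataset(rbind(c(2, 1, 0), c(0, 0, 1)), pos = c(100L, 200L, 300L),
                    population = "POP2")
  out <- intersect_common_snps(a, b)
  expect_equal(out$a$dosages, a$dosages)
  expect_equal(out$b$dosages, b$dosages)

  # a has {m1,m2,m3} at 100/200/300; b has {200,300,400}: intersection {200,300}
  b2 <- make_dataset(rbind(c(1, 0, 2), c(2, 1, 0)),
                     pos = c(200L, 300L, 400L), population = "POP2")
  out2 <- intersect_common_snps(a, b2)
  expect_equal(out2$a$map$pos, c(200L, 300L))
  expect_equal(out2$b$map$pos, c(200L, 300L))
  expect_equal(unname(out2$a$dosages), unname(a$dosages[, 2:3]))

  # swapped alleles are recoded 2 - d
  swap_map <- data.frame(marker_id = "x1", chrom = "1", pos = 100L,
                         allele_a = "G", allele_b = "A",
                         stringsAsFactors = FALSE)
  b3 <- genotype_dataset(rbind(2, 0), swap_map, c("t1", "t2"), "POP2")
  a3 <- make_dataset(rbind(0, 1), pos = 100L)
  out3 <- intersect_common_snps(a3, b3)
  expect_equal(unname(out3$b$dosages[, 1]), c(0, 2))
  expect_equal(out3$b$map$allele_a, "A")

  # incompatible allele sets are dropped; empty intersection errors
  b4 <- genotype_dataset(rbind(2, 0),
                         data.frame(marker_id = "x1", chrom = "1", pos = 100L,
                                    allele_a = "C", allele_b = "T",
                                    stringsAsFactors = FALSE),
                         c("t1", "t2"), "POP2")
  expect_error(intersect_common_snps(a3, b4), "compatible alleles")
  b5 <- make_dataset(rbind(0, 1), pos = 999L, population = "POP2")
  expect_error(intersect_common_snps(a3, b5), "no common markers")
})

test_that("intersection is symmetric in content and harmonizes allele sets", {
  set.seed(42)
  for (rep_i in 1:5) {
    mk <- function(pos, pop, swap = NULL) {
      if (is.null(swap)) swap <- rep(FALSE, length(pos))
      map <- data.frame(marker_id = paste0(pop, "_", seq_along(pos)),
                        chrom = "1", pos = pos,
                        allele_a = ifelse(swap, "G", "A"),
                        allele_b = ifelse(swap, "A", "G"),
                        stringsAsFactors = FALSE)
      genotype_dataset(matrix(sample(0:2, 4 * length(pos), TRUE), 4),
                       map, paste0(pop, 1:4), pop)
    }
    pos_a <- sort(sample.int(5000L, 20L)) * 10L
    pos_b <- sort(unique(c(sample(pos_a, 12L),
                           sort(sample.int(5000L, 8L)) * 10L + 5L)))
    a <- mk(pos_a, "a")
    b <- mk(pos_b, "b", swap = stats::runif(length(pos_b)) < 0.5)
    ab <- intersect_common_snps(a, b)
    ba <- intersect_common_snps(b, a)
    # same marker set either way; orientation follows the first argument
    expect_equal(ab$a$map$pos, ba$a$map$pos)
    recoded <- ab$b$map$allele_b != ba$a$map$allele_b
    d_back <- ab$b$dosages
    d_back[, recoded] <- 2 - d_back[, recoded]
    expect_equal(d_back, ba$a$dosages, ignore_attr = TRUE)
    # after harmonization the allele pairs agree between the two outputs
    expect_equal(ab$a$map$allele_a, ab$b$map$allele_a)
    expect_equal(ab$a$map$allele_b, ab$b$map$allele_b)
  }
})

test_that("BED ingestion converts to 1-based inclusive and regions export back", {
  bed <- tempfile()
  writeLines(c("1\t99\t200\tgeneA", "2\t0\t50\tgeneB"), bed)
  iv <- read_bed_intervals(bed, "gene")
  expect_equal(iv$start, c(100L, 1L))
  expect_equal(iv$end, c(200L, 50L))
  out <- tempfile()
  write_bed(data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                       name = iv$name), out)
  expect_equal(readLines(out), readLines(bed))
  expect_error(read_bed_intervals(tempfile(), "gene"), "not found")
})
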