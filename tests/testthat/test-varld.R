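# Windowed signed-r2 matrices, the eigenvalue-difference score, the scan,
# standardization, and the permutation null.

test_that("window_corr_matrix has unit diagonal, perfect-LD entries and full trace", {
  set.seed(41)
  n <- 80L
  g <- sapply(runif(10, 0.2, 0.8), function(p) rbinom(n, 2, p))
  g[, 4] <- g[, 3]                               # SNP 4 duplicates SNP 3
  ds <- make_dataset(g, pos = seq_len(10L) * 1000L)
  m <- window_corr_matrix(ds, 1L, 10L)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 10))
  expect_equal(unname(m[3, 4]), 1)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev), 10, tolerance = 1e-10)   # trace of unit-diagonal matrix

  # independent SNPs, large n: off-diagonals near 0
  set.seed(43)
  n2 <- 500L
  g2 <- sapply(runif(8, 0.3, 0.7), function(p) rbinom(n2, 2, p))
  ds2 <- make_dataset(g2, pos = seq_len(8L) * 1000L)
  m2 <- window_corr_matrix(ds2, 1L, 8L)
  off <- m2[upper.tri(m2)]
  expect_lt(max(abs(off)), (4 / sqrt(n2))^2)

  # monomorphic column is an explicit, named error
  g3 <- g; g3[, 5] <- 2
  ds3 <- make_dataset(g3, pos = seq_len(10L) * 1000L)
  expect_error(window_corr_matrix(ds3, 1L, 10L), "m0005")
  # windows never span chromosomes
  ds4 <- make_dataset(g, chrom = rep(c("1", "2"), each = 5))
  expect_error(window_corr_matrix(ds4, 3L, 5L), "spans chromosomes")
})

test_that("raw_varld_score matches closed-form 2x2 eigenvalues", {
  a <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(raw_varld_score(a, a), 0)
  expect_equal(raw_varld_score(a, diag(2)), 1)   # eigs {1.5, 0.5} vs {1, 1}
  ones <- matrix(1, 2, 2)
  rep2 <- matrix(c(1, -1, -1, 1), 2)
  expect_equal(raw_varld_score(ones, rep2), 0)   # both spectra {2, 0}
  expect_error(raw_varld_score(diag(2), diag(3)), "equal dimension")

  set.seed(45)
  for (i in 1:100) {
    m1 <- rand_corr_like(2); m2 <- rand_corr_like(2)
    # closed form: unit-diagonal 2x2 has eigenvalues 1 +/- |offdiag|
    o1 <- abs(m1[1, 2]); o2 <- abs(m2[1, 2])
    expected <- sum(abs(c(1 + o1, 1 - o1) - c(1 + o2, 1 - o2)))
    expect_equal(raw_varld_score(m1, m2), expected, tolerance = 1e-12)
  }
})

test_that("raw_varld_score matches the characteristic-polynomial oracle for 3x3", {
  set.seed(47)
  char_eigs <- function(m) {
    # roots of x^3 - tr x^2 + (sum of principal 2-minors) x - det, via
    # polyroot: an oracle independent of eigen()
    minors <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1] +
              m[1, 1] * m[3, 3] - m[1, 3] * m[3, 1] +
              m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]
    sort(Re(polyroot(c(-det(m), minors, -sum(diag(m)), 1))),
         decreasing = TRUE)
  }
  for (i in 1:100) {
    m1 <- rand_corr_like(3); m2 <- rand_corr_like(3)
    expected <- sum(abs(char_eigs(m1) - char_eigs(m2)))
    expect_equal(raw_varld_score(m1, m2), expected, tolerance = 1e-8)
  }
})

test_that("raw_varld_score is symmetric, nonnegative and obeys the l1 triangle bound", {
  set.seed(49)
  for (i in 1:200) {
    d <- sample(2:6, 1)
    a <- rand_corr_like(d); b <- rand_corr_like(d); c <- rand_corr_like(d)
    ab <- raw_varld_score(a, b)
    expect_gte(ab, 0)
    expect_identical(ab, raw_varld_score(b, a))
    expect_lte(raw_varld_score(a, c),
               ab + raw_varld_score(b, c) + 1e-12)
  }
})

test_that("scan window arithmetic: M markers, window w, step 1 gives M - w + 1", {
  set.seed(51)
  n <- 40L
  g <- sapply(runif(100, 0.3, 0.7), function(p) rbinom(n, 2, p))
  ds_a <- make_dataset(g, pos = seq_len(100L) * 1000L)
  g2 <- sapply(runif(100, 0.3, 0.7), function(p) rbinom(n, 2, p))
  ds_b <- make_dataset(g2, pos = seq_len(100L) * 1000L, population = "POP2")
  fix <- drop_monomorphic(ds_a, ds_b)
  m_kept <- nrow(fix$a$map)
  tr <- varld(fix$a, fix$b, window_size = 50L, step = 1L)
  expect_equal(nrow(tr), m_kept - 49L)
  expect_equal(tr$first_index, seq_len(m_kept - 49L))
  expect_equal(tr$mid_bp,
               as.integer(round((tr$first_bp + tr$last_bp) / 2)))
  expect_true(all(tr$raw_score >= 0))
  # scan is symmetric in its arguments
  tr_rev <- varld(fix$b, fix$a, window_size = 50L, step = 1L)
  expect_equal(tr_rev$raw_score, tr$raw_score)

  # chromosomes shorter than the window are skipped with a warning
  short <- make_dataset(g[, 1:10], pos = seq_len(10L) * 1000L)
  short_b <- make_dataset(g2[, 1:10], pos = seq_len(10L) * 1000L,
                          population = "POP2")
  sfix <- drop_monomorphic(short, short_b)
  expect_warning(expect_error(varld(sfix$a, sfix$b, window_size = 50L),
                              "no chromosome"),
                 "skipped")
  # mismatched maps are rejected
  shifted <- make_dataset(g2, pos = seq_len(100L) * 1000L + 5L,
                          population = "POP2")
  expect_error(varld(ds_a, shifted), "marker maps differ")
  # monomorphic markers are a named error
  gm <- g; gm[, 7] <- 0
  dm <- make_dataset(gm, pos = seq_len(100L) * 1000L)
  expect_error(varld(dm, ds_b), "monomorphic")
})

test_that("the banded scan engine agrees with window_corr_matrix windows", {
  set.seed(53)
  sim <- simulate_pair(sim_config(n_samples = c(40L, 40L), n_chromosomes = 1L,
                                  markers_per_chromosome = 120L,
                                  missing_rate = 0.05, seed = 53))
  fix <- drop_monomorphic(sim$pop1, sim$pop2)
  w <- 20L
  tr <- varld(fix$a, fix$b, window_size = w, standardize = FALSE)
  for (s in c(1L, 15L, nrow(tr))) {
    ma <- window_corr_matrix(fix$a, tr$first_index[s], w)
    mb <- window_corr_matrix(fix$b, tr$first_index[s], w)
    expect_equal(tr$raw_score[s], raw_varld_score(ma, mb), tolerance = 1e-10)
  }
})

test_that("standardize centers and scales; affine raw changes leave it unchanged", {
  tr <- make_track(c(1, 2, 3), w = 5L)
  tr$std_score <- NA_real_
  std <- standardize(tr)
  expect_equal(std$std_score, c(-1, 0, 1))

  set.seed(55)
  tr2 <- make_track(runif(200, 0, 10), w = 10L)
  tr2$std_score <- NA_real_
  s2 <- standardize(tr2)
  expect_equal(mean(s2$std_score), 0, tolerance = 1e-12)
  expect_equal(sd(s2$std_score), 1, tolerance = 1e-12)
  tr3 <- tr2
  tr3$raw_score <- 3.7 * tr2$raw_score + 11
  expect_equal(standardize(tr3)$std_score, s2$std_score, tolerance = 1e-10)

  const <- make_track(rep(2, 10), w = 5L)
  const$std_score <- NA_real_
  expect_error(standardize(const), "degenerate")
  one <- make_track(1, w = 5L)
  expect_error(standardize(one), "at least 2 windows")
})

test_that("a homogeneous split shows no structure; an implanted sweep dominates", {
  sim <- simulate_pair(sim_config(n_samples = c(120L, 2L), n_chromosomes = 1L,
                                  markers_per_chromosome = 1200L,
                                  missing_rate = 0.01, seed = 57))
  halves <- split_halves(sim$pop1)
  fix <- drop_monomorphic(halves$a, halves$b)
  tr0 <- varld(fix$a, fix$b)
  # null: extreme standardized scores behave like mild order statistics
  expect_lt(max(tr0$std_score), 8)
  expect_gt(max(tr0$std_score), 1.5)

  # keep the sweep a small fraction of the scanned genome so genome-wide
  # standardization is not dominated by the sweep windows themselves
  cfg <- sim_config(n_samples = c(80L, 80L), n_chromosomes = 1L,
                    markers_per_chromosome = 1500L, missing_rate = 0.01,
                    sweeps = list(sweep_spec("1", 1200000L, 1350000L, "POP1", 2L)),
                    seed = 59)
  sw <- simulate_pair(cfg)
  fix2 <- drop_monomorphic(sw$pop1, sw$pop2)
  tr1 <- varld(fix2$a, fix2$b)
  peak <- tr1[which.max(tr1$raw_score), ]
  expect_equal(peak$chrom, "1")
  expect_gte(peak$mid_bp, 1200000L)
  expect_lte(peak$mid_bp, 1350000L)
  expect_gt(max(tr1$std_score), 6)
})

test_that("permutation p-values are reproducible, calibrated, and small at a sweep", {
  cfg <- sim_config(n_samples = c(60L, 2L), n_chromosomes = 1L,
                    markers_per_chromosome = 200L, missing_rate = 0,
                    seed = 61)
  sim <- simulate_pair(cfg)
  halves <- split_halves(sim$pop1)
  fix <- drop_monomorphic(halves$a, halves$b)
  p1 <- permutation_null(fix$a, fix$b, n_perm = 19, seed = 7,
                         window_size = 30L)
  p2 <- permutation_null(fix$a, fix$b, n_perm = 19, seed = 7,
                         window_size = 30L)
  expect_identical(p1$p_value, p2$p_value)
  expect_true(all(p1$p_value >= 1 / 20 & p1$p_value <= 1))
  # null: p-values spread over the unit interval rather than piling up
  expect_gt(mean(p1$p_value), 0.25)
  expect_lt(mean(p1$p_value), 0.75)
  expect_error(permutation_null(fix$a, fix$b, n_perm = 0, seed = 1),
               "n_perm")

  # sweep window: p hits the permutation floor 1/(n_perm + 1)
  cfg_sw <- sim_config(n_samples = c(50L, 50L), n_chromosomes = 1L,
                       markers_per_chromosome = 220L, missing_rate = 0,
                       mean_spacing_bp = 2000L,
                       sweeps = list(sweep_spec("1", 150000L, 250000L,
                                                "POP1", 2L)),
                       seed = 63)
  sw <- simulate_pair(cfg_sw)
  fix_sw <- drop_monomorphic(sw$pop1, sw$pop2)
  pn <- permutation_null(fix_sw$a, fix_sw$b, n_perm = 199, seed = 11,
                         window_size = 30L)
  in_sweep <- pn$chrom == "1" & pn$mid_bp >= 150000 & pn$mid_bp <= 250000
  expect_true(any(in_sweep))
  expect_equal(min(pn$p_value[in_sweep]), 1 / 200)
})

test_that("varld tracks print, summarize and serialize", {
  set.seed(65)
  tr <- make_track(rnorm(120), w = 10L)
  expect_output(print(tr), "windows: 120")
  s <- summary(tr, percentiles = c(95, 99))
  expect_output(print(s), "percentile thresholds")
  f <- tempfile()
  write_varld_track(tr, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 120L)
  expect_equal(back$std_score, tr$std_score)
})
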