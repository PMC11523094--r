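# Interval algebra and coverage statistics.

test_that("merging projects blocks to disjoint sorted intervals", {
  b <- data.frame(qchrom = "W", qstart = c(0, 5, 20), qend = c(10, 15, 25),
                  tchrom = "Z", stringsAsFactors = FALSE)
  m <- merge_nonoverlapping(b, group_by_target = FALSE)
  expect_equal(m$start, c(0L, 20L))
  expect_equal(m$end, c(15L, 25L))
  expect_equal(sum(m$end - m$start), 20L)
  expect_equal(nrow(merge_nonoverlapping(b[0, ], group_by_target = FALSE)), 0L)
})

test_that("merge matches the per-base boolean oracle on random instances", {
  set.seed(31)
  for (rep in 1:25) {
    L <- sample(2000:10000, 1)
    iv <- random_intervals(200, L)
    b <- data.frame(qchrom = "c", qstart = iv$start, qend = iv$end,
                    tchrom = "t", stringsAsFactors = FALSE)
    b <- b[b$qend > b$qstart, ]
    m <- merge_nonoverlapping(b, group_by_target = FALSE)
    expect_equal(sum(m$end - m$start), sum(bool_mask(m, L)))
    expect_equal(sum(bool_mask(data.frame(start = m$start, end = m$end), L)),
                 sum(bool_mask(iv, L)))
    expect_true(all(m$start[-1L] > m$end[-nrow(m)] - 1L)) # disjoint, sorted
  }
})

test_that("repeat subtraction trims rather than discards", {
  cov <- data.frame(qchrom = "W", start = 0L, end = 100L)
  reps <- data.frame(chrom = "W", start = 40L, end = 60L)
  s <- subtract_repeats(cov, reps)
  expect_equal(s$start, c(0L, 60L))
  expect_equal(s$end, c(40L, 100L))
  ann <- subtract_repeats(cov, data.frame(chrom = "W", start = 0L, end = 100L))
  expect_equal(nrow(ann), 0L)
})

test_that("subtraction matches the per-base oracle on random instances", {
  set.seed(32)
  for (rep in 1:25) {
    L <- sample(2000:10000, 1)
    a <- random_intervals(50, L); b <- random_intervals(50, L)
    cov <- merge_nonoverlapping(
      data.frame(qchrom = "c", qstart = a$start, qend = a$end),
      group_by_target = FALSE)
    reps <- data.frame(chrom = "c", start = b$start, end = b$end)
    s <- subtract_repeats(cov, reps)
    oracle <- bool_mask(cov, L) & !bool_mask(b, L)
    expect_equal(sum(if (nrow(s)) s$end - s$start else 0L), sum(oracle))
  }
})

test_that("coverage fractions behave at the boundaries", {
  expect_equal(coverage_fraction(data.frame(start = 0L, end = 50L), 200), 0.25)
  expect_equal(coverage_fraction(data.frame(start = integer(), end = integer()), 200), 0)
  expect_equal(coverage_fraction(data.frame(start = 0L, end = 200L), 200), 1)
  expect_error(coverage_fraction(data.frame(start = 0L, end = 1L), 0))
})

test_that("targets rank by fraction with lexicographic flagged ties", {
  tab <- data.frame(qchrom = "W", tchrom = c("Z", "chr2", "chr5"),
                    covered_bp = c(10L, 12L, 1L), length_bp = 100L,
                    fraction = c(0.10, 0.12, 0.01),
                    repeat_filtered = FALSE, identity_min = NA_real_)
  rk <- rank_targets(tab, "W")
  expect_equal(rk$target, c("chr2", "Z", "chr5"))
  tab0 <- tab; tab0$fraction <- 0
  rk0 <- rank_targets(tab0, "W")
  expect_true(all(rk0$tie))
})

test_that("coverage is monotone under repeat filtering and stricter identity", {
  set.seed(33)
  q <- random_dna(30000)
  t <- evolve_jc(q, 0.08)
  reps <- data.frame(chrom = "q", start = c(2000L, 9000L), end = c(5000L, 12000L))
  b45 <- find_synteny_blocks(c(q = q), c(t = t), scan_config(identity_min = 0.45))
  b70 <- find_synteny_blocks(c(q = q), c(t = t), scan_config(identity_min = 0.70))
  qlen <- c(q = 30000L)
  cu <- coverage_table(b45, qlen)
  cf <- coverage_table(b45, qlen, repeats = reps,
                       repeat_filter_denominator = FALSE)
  c70 <- coverage_table(b70, qlen)
  expect_lte(cf$covered_bp[1], cu$covered_bp[1])
  expect_lte(c70$covered_bp[1], cu$covered_bp[1])
})

test_that("per-target unions are subadditive against the global union", {
  set.seed(34)
  b <- data.frame(qchrom = "W",
                  qstart = sample.int(5000, 120, replace = TRUE) - 1L,
                  tchrom = sample(c("A", "B", "C"), 120, replace = TRUE),
                  stringsAsFactors = FALSE)
  b$qend <- b$qstart + sample.int(300, 120, replace = TRUE)
  per <- merge_nonoverlapping(b, group_by_target = TRUE)
  glob <- merge_nonoverlapping(b, group_by_target = FALSE)
  expect_lte(sum(glob$end - glob$start),
             sum(per$end - per$start))
})

test_that("out-of-bounds blocks are rejected with the offender named", {
  b <- data.frame(qchrom = "W", qstart = 50L, qend = 200L, tchrom = "Z")
  expect_error(merge_nonoverlapping(b, chrom_lengths = c(W = 100L)), "exceeds")
})
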