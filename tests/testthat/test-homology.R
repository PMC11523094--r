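# Marker-based homology, best protein hits, fusion detection.

test_that("marker homology recovers the simulated chromosome map", {
  cl <- fx_small31()
  m1 <- cl$genomes$sp1$markers
  m2 <- cl$genomes$sp2$markers
  M <- marker_hit_matrix(m1, m2)
  hm <- assign_homology(M)
  expect_gte(sum(hm$homolog == hm$chrom), nrow(hm) - 1L)
})

test_that("argmax assignment flags ties and near-ties, maps empty rows away", {
  M <- matrix(c(40L, 38L, 0L,
                2L, 30L, 1L,
                0L, 0L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("chrZ", "chr5", "chr9"),
                              c("chrZ", "chr19", "chr3")))
  hm <- assign_homology(M, near_margin = 0.10)
  expect_equal(hm$homolog[hm$chrom == "chrZ"], "chrZ")
  expect_true(hm$near_tie[hm$chrom == "chrZ"])
  expect_false(hm$near_tie[hm$chrom == "chr5"])
  expect_equal(hm$homolog[hm$chrom == "chr9"], "unassigned")
  # exact tie: lexicographic winner, flagged
  M2 <- matrix(c(5L, 5L), nrow = 1,
               dimnames = list("a", c("x2", "x1")))
  hm2 <- assign_homology(M2)
  expect_equal(hm2$homolog, "x1")
  expect_true(hm2$tie)
})

test_that("duplicated markers are excluded from the hit matrix", {
  ma <- data.frame(marker_id = c("m1", "m1", "m2"), chrom = c("a", "b", "a"))
  mb <- data.frame(marker_id = c("m1", "m2"), chrom = c("a", "a"))
  M <- marker_hit_matrix(ma, mb)
  expect_equal(sum(M), 1L) # only m2 counts
})

test_that("best-hit selection follows e-value then identity then subject id", {
  h <- data.frame(qseqid = "p1", sseqid = c("s1", "s2", "s3"),
                  pident = c(80, 91, 99), length = 100L, mismatch = 0L,
                  gapopen = 0L, qstart = 1L, qend = 100L, sstart = 1L,
                  send = 100L, evalue = c(1e-50, 1e-50, 1e-20),
                  bitscore = 100, stringsAsFactors = FALSE)
  b <- best_hit_per_protein(h)
  expect_equal(b$sseqid, "s2")
  expect_equal(b$pident, 91)
  expect_false(b$residual_tie)
  single <- best_hit_per_protein(h[1L, ])
  expect_equal(single$sseqid, "s1")
  # full residual tie resolved lexicographically and flagged
  h2 <- h; h2$evalue <- 1e-50; h2$pident <- 90
  b2 <- best_hit_per_protein(h2)
  expect_equal(b2$sseqid, "s1")
  expect_true(b2$residual_tie)
})

test_that("best-hit selection equals the exhaustive comparator oracle", {
  set.seed(41)
  for (rep in 1:300) {
    n <- sample(3:25, 1)
    h <- data.frame(
      qseqid = sample(paste0("p", 1:4), n, replace = TRUE),
      sseqid = sample(paste0("s", 1:8), n, replace = TRUE),
      pident = sample(c(70, 80, 90, 95), n, replace = TRUE),
      evalue = 10^-sample(c(5, 12, 20, 50), n, replace = TRUE),
      stringsAsFactors = FALSE)
    got <- best_hit_per_protein(h)
    want <- oracle_best_hits(h)
    got <- got[order(got$qseqid), ]
    want <- want[order(want$qseqid), ]
    expect_equal(got$qseqid, want$qseqid)
    expect_equal(got$sseqid, want$sseqid)
    expect_equal(got$evalue, want$evalue)
  }
})

test_that("tallies count best hits per chromosome with a mean", {
  best <- data.frame(qseqid = c("p1", "p2", "p3"),
                     target_chrom = c("Z", "Z", "chr2"))
  tl <- tally_best_hits_by_chromosome(best)
  expect_equal(tl$counts$n_hits[tl$counts$chrom == "Z"], 2L)
  expect_equal(tl$counts$n_hits[tl$counts$chrom == "chr2"], 1L)
  expect_equal(tl$mean_hits, 1.5)
  empty <- tally_best_hits_by_chromosome(best[0, ])
  expect_equal(nrow(empty$counts), 0L)
})

test_that("fusion detection reads split and interleaved partner tracks", {
  trk <- data.frame(pos = 1:9 * 100,
                    partner = c(rep("Z", 5), rep("chr19", 4)))
  f <- detect_fusion(trk)
  expect_true(f$fusion)
  expect_equal(f$partner_1, "Z")
  expect_equal(f$partner_2, "chr19")
  expect_equal(f$fraction_1, 5 / 9, tolerance = 1e-12)
  expect_equal(f$fraction_2, 4 / 9, tolerance = 1e-12)
  expect_equal(f$interleaving_index, 1 / 8, tolerance = 1e-12)

  one <- detect_fusion(data.frame(pos = 1:6, partner = "Z"))
  expect_false(one$fusion)
  few <- detect_fusion(data.frame(pos = 1:3, partner = c("Z", "A", "Z")))
  expect_true(is.na(few$fusion))
  expect_match(few$reason, "insufficient")

  inter <- detect_fusion(data.frame(pos = 1:8,
                                    partner = rep(c("Z", "chr19"), 4)))
  expect_true(inter$fusion)
  expect_equal(inter$interleaving_index, 1)
})
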