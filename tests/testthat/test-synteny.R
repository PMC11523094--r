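# Synteny detector: anchoring, identity thresholds, strand handling,
# concordance chaining and battleship refinement.

test_that("an exact substring match is found at identity 1.0 on the + strand", {
  set.seed(21)
  t <- random_dna(5000)
  q <- substr(t, 2001, 3000)
  cfg <- scan_config(window = 1000, step = 1000)
  m <- scan_windows(c(q = q), c(t = t), cfg)
  expect_equal(nrow(m), 1L)
  expect_equal(m$identity, 1.0)
  expect_equal(m$orientation, "+")
  expect_equal(m$tstart, 2000L)
  expect_equal(m$tend, 3000L)
})

test_that("a 55/100 window is kept at the 45% floor and dropped at 70%", {
  set.seed(22)
  w0 <- random_dna(100)
  target <- paste0(random_dna(150), w0, random_dna(150))
  # mutate 45 bases but keep an intact seed so the true diagonal anchors
  v <- utf8ToInt(w0)
  mut <- 10:54
  codes <- utf8ToInt("ACGT")
  v[mut] <- codes[(match(v[mut], codes) %% 4L) + 1L]
  q <- intToUtf8(v)
  cfg45 <- scan_config(window = 100, step = 100, seed_k = 8, seed_stride = 1,
                       identity_min = 0.45)
  m45 <- scan_windows(c(q = q), c(t = target), cfg45)
  expect_equal(nrow(m45), 1L)
  expect_equal(m45$identity, 0.55)
  cfg70 <- scan_config(window = 100, step = 100, seed_k = 8, seed_stride = 1,
                       identity_min = 0.70)
  expect_equal(nrow(scan_windows(c(q = q), c(t = target), cfg70)), 0L)
})

test_that("a reverse-complement target yields reflected minus-strand matches", {
  set.seed(23)
  q <- random_dna(10000)
  t_fwd <- evolve_jc(q, 0.05)
  t_rc <- revcomp(t_fwd)
  cfg <- scan_config()
  mf <- scan_windows(c(q = q), c(t = t_fwd), cfg)
  mr <- scan_windows(c(q = q), c(t = t_rc), cfg)
  expect_true(all(mr$orientation == "-"))
  Lt <- nchar(t_rc)
  mf <- mf[order(mf$qstart), ]
  mr <- mr[order(mr$qstart), ]
  expect_equal(mr$qstart, mf$qstart)
  expect_equal(Lt - mr$tend, mf$tstart)
  expect_equal(Lt - mr$tstart, mf$tend)
  expect_equal(mr$identity, mf$identity)
})

test_that("reported identities match a brute-force all-diagonal oracle", {
  set.seed(24)
  q <- random_dna(1200)
  t <- paste0(random_dna(300), evolve_jc(q, 0.05), random_dna(300))
  cfg <- scan_config(window = 200, step = 200, seed_k = 8, seed_stride = 1,
                     max_matches_per_window = 1)
  m <- scan_windows(c(q = q), c(t = t), cfg)
  expect_gt(nrow(m), 0)
  tr_f <- charToRaw(t)
  Lt <- nchar(t)
  for (i in seq_len(nrow(m))) {
    qwin <- substr(q, m$qstart[i] + 1, m$qend[i])
    w <- nchar(qwin)
    best <- 0
    for (d in 0:(Lt - w)) { # all + diagonals
      best <- max(best, ungapped_identity(qwin, substr(t, d + 1, d + w)))
    }
    qrc <- revcomp(qwin)
    for (d in 0:(Lt - w)) {
      best <- max(best, ungapped_identity(qrc, substr(t, d + 1, d + w)))
    }
    expect_equal(m$identity[i], best, tolerance = 1e-12)
  }
})

test_that("windows that are mostly N are skipped and Ns never match", {
  q <- paste0(strrep("N", 700), random_dna(300))
  t <- q
  cfg <- scan_config(window = 1000, step = 1000)
  m <- scan_windows(c(q = q), c(t = t), cfg)
  expect_equal(nrow(m), 0L) # 70% N window skipped
  q2 <- strrep("N", 400)
  t2 <- paste0(strrep("N", 400), random_dna(600))
  m2 <- scan_windows(c(q = paste0(q2, random_dna(600))), c(t = t2),
                     scan_config(window = 1000, step = 1000))
  if (nrow(m2)) expect_true(all(m2$identity <= 0.6))
})

test_that("chaining keeps collinear runs and discards isolated hits", {
  mk <- function(qs, ts, ori = "+") {
    data.frame(qchrom = "q", qstart = qs, qend = qs + 1000,
               tchrom = "t", tstart = ts, tend = ts + 1000,
               orientation = ori, identity = 0.9, stringsAsFactors = FALSE)
  }
  cfg <- scan_config()
  run <- mk(seq(0, 4000, 1000), seq(10000, 14000, 1000))
  ch <- chain_concordant(run, cfg)
  expect_equal(nrow(ch), 5L)
  expect_true(all(ch$support >= 2))
  iso <- rbind(run, mk(1e6, 5e6))
  ch2 <- chain_concordant(iso, cfg)
  expect_equal(nrow(ch2), 5L)
  expect_false(any(ch2$qstart == 1e6))
})

test_that("chaining support equals the exhaustive neighbour-count oracle", {
  set.seed(25)
  cfg <- scan_config()
  # one 10-window collinear run plus 10 scattered singletons
  run <- data.frame(qchrom = "q", qstart = seq(0, 9000, 1000),
                    qend = seq(0, 9000, 1000) + 1000,
                    tchrom = "t", tstart = seq(50000, 59000, 1000),
                    tend = seq(50000, 59000, 1000) + 1000,
                    orientation = "+", identity = 0.8, stringsAsFactors = FALSE)
  sing <- data.frame(qchrom = "q",
                     qstart = sample(seq(100000, 900000, 1000), 10),
                     tchrom = "t",
                     tstart = sample(seq(1000000, 2000000, 1000), 10),
                     orientation = "+", identity = 0.8, stringsAsFactors = FALSE)
  sing$qend <- sing$qstart + 1000
  sing$tend <- sing$tstart + 1000
  m <- rbind(run, sing[, names(run)])
  supp <- oracle_chain_support(m, cfg$chain_radius)
  ch <- chain_concordant(m, cfg)
  expect_setequal(ch$qstart, m$qstart[supp >= cfg$min_chain_support])
  expect_equal(nrow(ch), 10L) # exactly the collinear run survives
  key <- paste(m$qstart, m$tstart)
  expect_equal(ch$support, supp[match(paste(ch$qstart, ch$tstart), key)])
})

test_that("battleship refinement recovers sub-seed gap windows and is idempotent", {
  set.seed(26)
  a <- random_dna(3000)
  gap <- random_dna(1000)
  b <- random_dna(3000)
  target <- paste0(a, gap, b)
  # gap window at ~50% identity: detectable by direct diagonal evaluation
  # but essentially unseedable with 16-mers
  v <- utf8ToInt(gap)
  flip <- sample(1000, 500)
  codes <- utf8ToInt("ACGT")
  v[flip] <- codes[(match(v[flip], codes) %% 4L) + 1L]
  query <- paste0(a, intToUtf8(v), b)
  cfg <- scan_config(window = 1000, step = 1000)
  m <- scan_windows(c(q = query), c(t = target), cfg)
  ch <- chain_concordant(m, cfg)
  expect_false(any(ch$qstart == 3000)) # the gap window was not seeded
  rf <- battleship_refine(c(q = query), c(t = target), ch, cfg)
  gapm <- rf[rf$qstart == 3000 & rf$tstart == 3000, ]
  expect_equal(nrow(gapm), 1L)
  expect_gte(gapm$identity, 0.45)
  rf2 <- battleship_refine(c(q = query), c(t = target), rf, cfg)
  expect_equal(nrow(rf2), nrow(rf))
  expect_equal(battleship_refine(c(q = 0)[0], c(t = 0)[0],
                                 ch[0, ], cfg)$qstart, integer(0))
})

test_that("raising the identity floor never enlarges the block set", {
  set.seed(27)
  q <- random_dna(30000)
  t <- evolve_jc(q, 0.25) # mixed identities around both thresholds
  b45 <- find_synteny_blocks(c(q = q), c(t = t),
                             scan_config(identity_min = 0.45))
  b70 <- find_synteny_blocks(c(q = q), c(t = t),
                             scan_config(identity_min = 0.70))
  k45 <- paste(b45$qstart, b45$tchrom, b45$tstart, b45$orientation)
  k70 <- paste(b70$qstart, b70$tchrom, b70$tstart, b70$orientation)
  expect_true(all(k70 %in% k45))
})

test_that("block output is invariant to target chromosome order", {
  set.seed(28)
  t1 <- random_dna(8000); t2 <- evolve_jc(random_dna(8000), 0)
  q <- paste0(substr(t1, 1000, 4000), substr(t2, 2000, 5000))
  cfg <- scan_config()
  b_ab <- find_synteny_blocks(c(q = q), c(a = t1, b = t2), cfg)
  b_ba <- find_synteny_blocks(c(q = q), c(b = t2, a = t1), cfg)
  o1 <- b_ab[order(b_ab$qstart, b_ab$tchrom, b_ab$tstart), ]
  o2 <- b_ba[order(b_ba$qstart, b_ba$tchrom, b_ba$tstart), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("non-repeat verification drops blocks that only match via repeats", {
  set.seed(29)
  rep_seq <- random_dna(1500)
  uniq_q <- random_dna(1500)
  uniq_t <- random_dna(1500) # unrelated unique sequence
  q <- paste0(uniq_q, rep_seq)
  t <- paste0(uniq_t, rep_seq)
  cfg <- scan_config(window = 1000, step = 500, min_chain_support = 1)
  m <- scan_windows(c(q = q), c(t = t), cfg)
  b <- chain_concordant(m, cfg)
  expect_gt(nrow(b), 0) # repeat-driven matches exist and chain
  reps <- data.frame(chrom = "q", start = 1500L, end = 3000L)
  v <- verify_nonrepeat_blocks(b, c(q = q), c(t = t), reps, cfg)
  expect_equal(nrow(v), 0L)
  # but truly homologous flanks survive verification
  t2 <- paste0(uniq_q, rep_seq)
  m2 <- chain_concordant(scan_windows(c(q = q), c(t = t2), cfg), cfg)
  v2 <- verify_nonrepeat_blocks(m2, c(q = q), c(t = t2), reps, cfg)
  expect_gt(nrow(v2), 0)
  expect_true(all(v2$nonrepeat_identity >= cfg$identity_min))
})

test_that("degenerate inputs are handled per contract", {
  expect_equal(nrow(scan_windows(character(0), c(t = "ACGT"))), 0L)
  expect_error(scan_config(seed_k = 1000, window = 100), class = "lepw_config_error")
  expect_error(scan_windows(c(q = "ACGT"), c(t = "ACGT"),
                            scan_config(window = 10, seed_k = 16)),
               class = "lepw_config_error")
})
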