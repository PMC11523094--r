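# Origin classifier rules and end-to-end orchestration.

test_that("shared-origin calls follow the supermajority rule", {
  mk <- function(ww, wz = 0.02, power = 0.8) {
    data.frame(pair = paste0("p", seq_along(ww)), w_w = ww, w_z = wz,
               w_auto_max = 0.01, power = power, stringsAsFactors = FALSE)
  }
  expect_equal(test_shared_origin(mk(rep(0.5, 10)))$shared_origin, "single")
  expect_equal(test_shared_origin(mk(rep(0.0, 10)))$shared_origin, "multiple")
  mixed <- test_shared_origin(mk(c(rep(0.5, 7), rep(0, 3))))
  expect_equal(mixed$shared_origin, "inconclusive")
  # "all but one" still reads as single at the 80% supermajority
  expect_equal(test_shared_origin(mk(c(rep(0.5, 9), 0)))$shared_origin, "single")
  # pairs whose W aligns nowhere are uninformative
  nopower <- test_shared_origin(mk(rep(0.5, 10), power = 0.0))
  expect_equal(nopower$shared_origin, "inconclusive")
  expect_equal(nopower$n_informative, 0L)
})

test_that("mechanism calls encode the ranking logic", {
  rk <- function(fr) data.frame(target = names(fr), fraction = unname(fr),
                                rank = rank(-fr, ties.method = "first"),
                                tie = FALSE)
  # Z clearly first: autosomal pair
  m1 <- test_mechanism(rk(c(Z = 0.2, chr1 = 0.01, chr2 = 0.02)), power = 0.5)
  expect_equal(m1$mechanism, "autosomal_pair")
  # Z at the autosomal median: B chromosome
  m2 <- test_mechanism(rk(c(Z = 0.01, chr1 = 0.01, chr2 = 0.01)), power = 0.5)
  expect_equal(m2$mechanism, "b_chromosome")
  # Z second in coverage but first in protein tallies: combined evidence
  tl <- list(counts = data.frame(chrom = c("Z", "chr2"), n_hits = c(38L, 35L)),
             mean_hits = 15)
  m3 <- test_mechanism(rk(c(chr2 = 0.12, Z = 0.10, chr1 = 0.01)),
                       tally = tl, power = 0.5)
  expect_equal(m3$mechanism, "autosomal_pair")
  # fusion trumps ranking
  fus <- list(fusion = TRUE, partner_1 = "Z", partner_2 = "chr19")
  m4 <- test_mechanism(rk(c(Z = 0.2, chr1 = 0.01)), fusion = fus, power = 0.5)
  expect_equal(m4$mechanism, "z_autosome_fusion")
  # no usable W signal: ambiguous, never a confident call
  m5 <- test_mechanism(rk(c(Z = 0, chr1 = 0)), power = 0.0)
  expect_equal(m5$mechanism, "ambiguous")
})

test_that("the pipeline is deterministic and serializes its verdict", {
  cfg <- fx_pipe_cfg("AUTOSOMAL_PAIR", TRUE, seed = 301, n_species = 2)
  v1 <- run_pipeline(cfg, confirm_sexchrom = FALSE)
  v2 <- run_pipeline(cfg, confirm_sexchrom = FALSE)
  p1 <- file.path(tempdir(), "v1.json"); p2 <- file.path(tempdir(), "v2.json")
  write_verdict_json(v1, p1); write_verdict_json(v2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_s3_class(v1, "origin_verdict")
  expect_equal(v1$shared_origin, "single")
  expect_equal(v1$mechanism, "autosomal_pair")
  unlink(c(p1, p2))
})

test_that("within-species evidence reports filtered and unfiltered ranks side by side", {
  cfg <- fx_pipe_cfg("AUTOSOMAL_PAIR", TRUE, seed = 302, n_species = 2)
  v <- run_pipeline(cfg, confirm_sexchrom = FALSE)
  wc <- v$within_coverage[[1]]
  expect_false(any(wc$unfiltered$repeat_filtered))
  if (nrow(wc$filtered)) expect_true(all(wc$filtered$repeat_filtered))
  expect_true(all(c("target", "fraction", "rank") %in% names(wc$ranks_unfiltered)))
  # the Z tops the W's homology ranking in an autosomal-pair clade
  expect_equal(wc$ranks_filtered$target[1], "Z")
})
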