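# Clade simulator: construction contracts, determinism, and the
# closed-form checks that anchor the evolutionary model.

test_that("ancestor has the requested karyotype and jittered lengths", {
  cfg <- scenario_config(n_autosomes = 30, chrom_length = 50000, n_species = 2,
                         n_proteins_per_chrom = 2, seed = 3)
  anc <- simulate_ancestor(cfg)
  expect_length(anc$seq, 31L)
  expect_equal(unname(anc$class[["Z"]]), "Z")
  expect_true(all(abs(chrom_lengths(anc) - 50000) <= 0.2 * 50000))
  # gene tracts non-overlapping per chromosome, markers inside chromosomes
  for (cn in names(anc$seq)) {
    g <- anc$genes[anc$genes$chrom == cn, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1L) expect_true(all(g$start[-1L] >= g$end[-nrow(g)]))
  }
  expect_true(all(anc$markers$pos >= 0 &
                    anc$markers$pos < chrom_lengths(anc)[anc$markers$chrom]))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- scenario_config(n_species = 2, n_autosomes = 4, chrom_length = 12000,
                         n_markers = 40, n_proteins_per_chrom = 2, seed = 11)
  d1 <- file.path(tempdir(), "cladeA"); d2 <- file.path(tempdir(), "cladeB")
  write_clade(simulate_clade(cfg), d1)
  write_clade(simulate_clade(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("derive_W copy semantics: autosomal-pair W equals Z before decay", {
  cfg <- scenario_config(hypothesis = "AUTOSOMAL_PAIR", n_species = 2,
                         n_autosomes = 3, chrom_length = 10000,
                         w_stem_length = 0, gc_boost_W = 0, w_retained_frac = 1,
                         repeat_frac_autosome = 0, repeat_frac_W = 0,
                         n_markers = 10, n_proteins_per_chrom = 2, seed = 5)
  anc <- simulate_ancestor(cfg)
  g <- derive_W(anc, cfg)
  expect_identical(g$seq[["W"]], g$seq[["Z"]])
  expect_equal(g$w_origin, "Z")
})

test_that("B-chromosome W sits at composition background identity vs Z", {
  cfg <- scenario_config(hypothesis = "B_CHROMOSOME", n_species = 2,
                         n_autosomes = 3, chrom_length = 50000,
                         w_stem_length = 0, gc_boost_W = 0,
                         repeat_frac_autosome = 0, repeat_frac_W = 0,
                         n_markers = 10, n_proteins_per_chrom = 2, seed = 6)
  anc <- simulate_ancestor(cfg)
  g <- derive_W(anc, cfg)
  n <- min(nchar(g$seq[["W"]]), nchar(g$seq[["Z"]]))
  a <- substr(g$seq[["W"]], 1, n); b <- substr(g$seq[["Z"]], 1, n)
  obs <- ungapped_identity(a, b, denom = n)
  exp_bg <- lepWorigin:::background_identity(a, b)
  se <- sqrt(exp_bg * (1 - exp_bg) / n)
  expect_lt(abs(obs - exp_bg), 4 * se)
})

test_that("fusion concatenates the partner onto the Z and records truth", {
  cfg <- scenario_config(hypothesis = "Z_AUTOSOME_FUSION", n_species = 2,
                         n_autosomes = 4, chrom_length = 10000,
                         w_stem_length = 0, gc_boost_W = 0, w_retained_frac = 1,
                         repeat_frac_autosome = 0, repeat_frac_W = 0,
                         n_translocations_post_fusion = 0,
                         n_markers = 20, n_proteins_per_chrom = 2, seed = 8)
  anc <- simulate_ancestor(cfg)
  lens <- chrom_lengths(anc)
  g <- derive_W(anc, cfg)
  partner <- g$w_origin
  expect_true(partner %in% paste0("chr", 1:4))
  expect_false(partner %in% names(g$seq))
  expect_equal(nchar(g$seq[["Z"]]), unname(lens[["Z"]] + lens[[partner]]))
  expect_equal(nchar(g$seq[["W"]]), unname(lens[[partner]]))
  expect_equal(g$fusion, c("Z", partner))
})

test_that("zero-length branches leave every species identical to the root", {
  tr <- ape::read.tree(text = "(sp1:0,sp2:0);")
  cfg <- scenario_config(n_species = 2, tree = tr, n_autosomes = 3,
                         chrom_length = 10000, n_inversions_per_branch = 0,
                         repeat_frac_autosome = 0, repeat_frac_W = 0,
                         w_stem_length = 0, gc_boost_W = 0,
                         n_markers = 10, n_proteins_per_chrom = 2, seed = 9)
  cl <- simulate_clade(cfg)
  expect_identical(cl$genomes$sp1$seq, cl$genomes$sp2$seq)
  anc <- simulate_ancestor(cfg)
  expect_identical(cl$genomes$sp1$seq[["chr1"]], anc$seq[["chr1"]])
})

test_that("pairwise divergence follows the Jukes-Cantor expectation", {
  tr <- ape::read.tree(text = "(sp1:0.05,sp2:0.05);")
  cfg <- scenario_config(n_species = 2, tree = tr, n_autosomes = 1,
                         chrom_length = 100000, n_inversions_per_branch = 0,
                         repeat_frac_autosome = 0, repeat_frac_W = 0,
                         w_stem_length = 0, gc_boost_W = 0, cons_rate_mult = 1,
                         n_markers = 4, n_proteins_per_chrom = 1, seed = 10)
  cl <- simulate_clade(cfg)
  a <- cl$genomes$sp1$seq[["chr1"]]; b <- cl$genomes$sp2$seq[["chr1"]]
  L <- nchar(a)
  pdiff <- 1 - ungapped_identity(a, b, denom = L)
  d <- 0.10
  expct <- 0.75 * (1 - exp(-4 * d / 3))
  se <- sqrt(expct * (1 - expct) / L)
  expect_lt(abs(pdiff - expct), 3 * se)
})

test_that("realized repeat fractions sit within 5 points of their targets", {
  cfg <- scenario_config(n_species = 2, n_autosomes = 5, chrom_length = 60000,
                         n_markers = 30, n_proteins_per_chrom = 2, seed = 12)
  cl <- simulate_clade(cfg)
  for (sp in names(cl$genomes)) {
    g <- cl$genomes[[sp]]
    st <- repeat_content_stats(chrom_lengths(g), g$repeats)
    target <- ifelse(st$chrom == "W", cfg$repeat_frac_W, cfg$repeat_frac_autosome)
    expect_true(all(abs(st$repeat_fraction - target) <= 0.05),
                info = paste(sp, paste(round(st$repeat_fraction, 3), collapse = ",")))
  }
})

test_that("markers stay on their host chromosome through rearrangements", {
  cfg <- scenario_config(n_species = 2, n_autosomes = 5, chrom_length = 20000,
                         n_inversions_per_branch = 4, n_markers = 60,
                         marker_loss_prob = 0, marker_dup_prob = 0,
                         n_proteins_per_chrom = 2, seed = 13)
  anc <- simulate_ancestor(cfg)
  cl <- evolve_clade(anc, cfg)
  for (sp in names(cl$genomes)) {
    g <- cl$genomes[[sp]]
    lens <- chrom_lengths(g)
    expect_true(all(g$markers$pos >= 0 & g$markers$pos < lens[g$markers$chrom]))
    m <- merge(anc$markers, g$markers, by = "marker_id")
    expect_true(all(m$chrom.x == m$chrom.y))
  }
})

test_that("depth tracks reproduce the trio half-depth pattern exactly at zero noise", {
  cl <- fx_small31()
  dt <- simulate_depth_tracks(cl, "sp1", mean_depth = 30, window = 5000,
                              cv = 0, seed = 1)
  m <- dt$mother; f <- dt$father
  expect_equal(unique(m$depth[m$chrom == "Z"]), 15)
  expect_equal(unique(m$depth[m$chrom == "W"]), 15)
  expect_equal(unique(m$depth[m$chrom == "chr1"]), 30)
  expect_equal(unique(f$depth[f$chrom == "Z"]), 30)
  expect_true(all(f$depth[f$chrom == "W"] < 0.25 * 30))
})

test_that("a window larger than the chromosome yields one whole-chromosome window", {
  w <- make_windows(100000, 200000)
  expect_equal(nrow(w), 1L)
  expect_equal(w$end, 100000L)
  w2 <- make_windows(100001, 50000)
  expect_equal(nrow(w2), 3L)
  expect_equal(w2$end[3L], 100001L)
})

test_that("simulated protein hits are homology-driven and tie-breakable", {
  cl <- fx_small31()
  hits <- simulate_protein_hits(cl, "sp1")
  expect_true(all(hits$evalue <= 10))
  best <- best_hit_per_protein(hits)
  if (nrow(best)) {
    tl <- tally_best_hits_by_chromosome(best)
    # an autosomal-pair W carries Z-derived genes: Z gets the top tally
    expect_equal(tl$counts$chrom[1L], "Z")
  }
})
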