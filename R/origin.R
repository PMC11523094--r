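# Origin classifier: formalizes the ranking arguments used to weigh the
# competing W-origin hypotheses into explicit margin-based decision
# rules, and orchestrates the whole pipeline on a simulated clade.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single versus multiple W origin from species-pair coverage evidence
#'
#' Under a single shared origin, W chromosomes are expected to share more
#' synteny with each other than with the Z or any autosome. Each species
#' pair contributes a score: W-vs-W coverage minus the best of W-vs-Z and
#' W-vs-autosome. A pair is *informative* only if its query W retains
#' detectable homology to anything in the partner genome (unfiltered
#' coverage >= `power_floor`): a W that aligns nowhere carries no signal
#' about origin, it has simply decayed beyond the detector's reach. The
#' call is `"single"` when at least `supermajority` of informative pairs
#' score above `min_margin` ("all but one species" logic), `"multiple"`
#' when at most `multiple_max` do, and `"inconclusive"` otherwise or when
#' fewer than half the pairs are informative.
#'
#' @param evidence data.frame with one row per species pair: columns
#'   `pair`, `w_w`, `w_z`, `w_auto_max` (repeat-filtered coverage
#'   fractions) and `power` (unfiltered total W coverage).
#' @param min_margin minimum score for a pair to count as shared-origin
#'   evidence.
#' @param supermajority fraction of informative pairs required for
#'   "single".
#' @param multiple_max maximum positive fraction still read as
#'   "multiple".
#' @param power_floor minimum unfiltered coverage for a pair to be
#'   informative.
#' @return list(shared_origin, share_positive, n_informative,
#'   exceptions, evidence).
#' @export
test_shared_origin <- function(evidence, min_margin = 0.02,
                               supermajority = 0.8, multiple_max = 0.5,
                               power_floor = 0.05) {
  ev <- evidence
  if (!nrow(ev)) return(list(shared_origin = "inconclusive",
                             share_positive = NA_real_, n_informative = 0L,
                             exceptions = character(), evidence = ev))
  ev$score <- ev$w_w - pmax(ev$w_z, ev$w_auto_max)
  ev$informative <- ev$power >= power_floor
  ev$positive <- ev$informative & ev$score > min_margin
  n_inf <- sum(ev$informative)
  call <- if (n_inf < max(1L, ceiling(nrow(ev) / 2))) "inconclusive" else {
    share <- sum(ev$positive) / n_inf
    if (share >= supermajority) "single"
    else if (share <= multiple_max) "multiple"
    else "inconclusive"
  }
  list(shared_origin = call,
       share_positive = if (n_inf) sum(ev$positive) / n_inf else NA_real_,
       n_informative = as.integer(n_inf),
       exceptions = ev$pair[ev$informative & !ev$positive],
       evidence = ev)
}

#' Mechanism of W origin within one species
#'
#' Encodes the within-species ranking logic: an autosomal-pair origin is
#' supported when the Z ranks first for W coverage (or within the top two
#' while also ranking first in best protein hits — the combined-evidence
#' pattern); a B-chromosome origin when the Z's coverage is no better
#' than the autosomal median; a Z-autosome fusion when the fusion
#' detector fires on the Z. Calls require usable W signal: if the
#' unfiltered W coverage (`power`) is below `min_evidence` the verdict is
#' `"ambiguous"` — an unalignable W supports nothing. Both the
#' repeat-filtered and unfiltered rankings are returned, since they can
#' disagree on real data.
#'
#' @param ranks_unfiltered,ranks_filtered [rank_targets()] outputs for
#'   the W query (filtered may be NULL; filtered ranks drive the call
#'   when available).
#' @param tally optional [tally_best_hits_by_chromosome()] result.
#' @param fusion optional [detect_fusion()] report for the Z.
#' @param power unfiltered total W coverage fraction.
#' @param min_evidence minimum `power` for any confident call.
#' @return list(mechanism, z_rank_filtered, z_rank_unfiltered,
#'   z_tally_rank, details).
#' @export
test_mechanism <- function(ranks_unfiltered, ranks_filtered = NULL,
                           tally = NULL, fusion = NULL, power = NA_real_,
                           min_evidence = 0.05) {
  zr_u <- ranks_unfiltered$rank[ranks_unfiltered$target == "Z"]
  zr_u <- if (length(zr_u)) zr_u else NA_integer_
  rk <- ranks_filtered %||% ranks_unfiltered
  zr <- rk$rank[rk$target == "Z"]
  zr <- if (length(zr)) zr else NA_integer_
  ztally <- NA_integer_
  ztally_hits <- 0L
  if (!is.null(tally) && nrow(tally$counts)) {
    o <- tally$counts
    ztally <- match("Z", o$chrom)
    if (!is.na(ztally)) ztally_hits <- o$n_hits[ztally]
  }
  zfrac <- rk$fraction[rk$target == "Z"]
  zfrac <- if (length(zfrac)) zfrac else 0
  autofrac <- rk$fraction[rk$target != "Z"]
  automed <- if (length(autofrac)) median(autofrac) else 0
  z_enriched <- zfrac > 0 && zfrac > automed # a zero-coverage Z supports nothing
  # a W protein with its best hit on the Z below the e-value cutoff is
  # direct homology evidence a B-derived W cannot produce; it carries the
  # call unless verified coverage actively contradicts it
  z_tally_support <- !is.na(ztally) && ztally == 1L && ztally_hits > 0L
  mech <- if (!is.na(power) && power < min_evidence) "ambiguous"
  else if (!is.null(fusion) && isTRUE(fusion$fusion)) "z_autosome_fusion"
  else if ((z_enriched && !is.na(zr) && zr == 1L) ||
           (z_tally_support && (is.na(zr) || zr <= 2L || automed == 0)))
    "autosomal_pair"
  else if (zfrac <= automed && !z_tally_support) "b_chromosome"
  else "ambiguous"
  list(mechanism = mech, z_rank_filtered = zr, z_rank_unfiltered = zr_u,
       z_tally_rank = ztally,
       details = list(z_fraction = zfrac, autosome_median = automed,
                      power = power))
}

# ---- orchestration --------------------------------------------------------

# coverage evidence of one W query against a target genome; filtered
# coverage only counts blocks whose non-repeat bases verify
w_coverage_evidence <- function(blocks, w_seq, target_seqs, w_repeats,
                                target_classes, scan_cfg) {
  w_len <- nchar(w_seq)
  power <- if (nrow(blocks))
    coverage_fraction(merge_nonoverlapping(blocks, group_by_target = FALSE), w_len)
  else 0
  vblocks <- verify_nonrepeat_blocks(blocks, setNames(w_seq, "W"), target_seqs,
                                     w_repeats, scan_cfg)
  tabf <- coverage_table(vblocks, setNames(w_len, "W"), repeats = w_repeats)
  frac <- function(tn) {
    f <- tabf$fraction[tabf$tchrom == tn]
    if (length(f)) f else 0
  }
  autos <- names(target_classes)[target_classes == "autosome"]
  w_auto <- if (length(autos)) max(vapply(autos, frac, numeric(1))) else 0
  list(w_w = frac("W"), w_z = frac("Z"), w_auto_max = w_auto, power = power,
       table = tabf)
}

#' Run the whole origin-inference pipeline on a simulated clade
#'
#' Executes simulate -> scan -> chain -> refine -> merge -> subtract ->
#' coverage -> homology -> sex-chromosome confirmation -> verdicts, fully
#' deterministic given the scenario seed. Within each species the W is
#' compared against the remaining chromosomes (secondary matches kept);
#' across species each W is compared to the partner genome; the Z is
#' screened for fusions against a partner species; depth tracks and
#' chromosome profiles confirm the W.
#'
#' @param x a `sim_clade` from [simulate_clade()], or a
#'   [scenario_config()] (which is simulated first).
#' @param scan_cfg a [scan_config()].
#' @param check_fusion scan the Z of each species against a partner
#'   species for fusion signal?
#' @param confirm_sexchrom simulate trio depth and build chromosome
#'   profiles?
#' @param depth_cv coefficient of variation for simulated depth windows.
#' @param min_margin,supermajority,power_floor,min_evidence forwarded to
#'   [test_shared_origin()] / [test_mechanism()].
#' @return an `origin_verdict`: list with `shared_origin`, `mechanism`,
#'   per-pair `evidence`, per-species `mechanism_by_species`,
#'   `within_coverage`, `fusion_reports`, `profiles` and `truth` (when
#'   simulated).
#' @export
run_pipeline <- function(x, scan_cfg = scan_config(),
                         check_fusion = TRUE, confirm_sexchrom = TRUE,
                         depth_cv = 0.15, min_margin = 0.02,
                         supermajority = 0.8, power_floor = 0.05,
                         min_evidence = 0.05) {
  clade <- if (inherits(x, "scenario_config")) simulate_clade(x) else x
  stopifnot(inherits(clade, "sim_clade"))
  species <- sort(names(clade$genomes))
  idx <- lapply(setNames(species, species), function(sp)
    build_kmer_index(clade$genomes[[sp]]$seq, scan_cfg$seed_k, scan_cfg$max_seed_hits))

  within_cov <- list(); mech_by_sp <- list(); fusion_reports <- list()
  profiles <- list(); tallies <- list()
  for (sp in species) {
    g <- clade$genomes[[sp]]
    if (!"W" %in% names(g$seq)) next
    targets <- g$seq[names(g$seq) != "W"]
    tidx <- build_kmer_index(targets, scan_cfg$seed_k, scan_cfg$max_seed_hits)
    blocks <- find_synteny_blocks(g$seq["W"], targets, scan_cfg, index = tidx)
    w_len <- nchar(g$seq[["W"]])
    w_rep <- g$repeats[g$repeats$chrom == "W", , drop = FALSE]
    tab_u <- coverage_table(blocks, c(W = w_len), identity_min = scan_cfg$identity_min)
    vblocks <- verify_nonrepeat_blocks(blocks, setNames(g$seq["W"], "W"),
                                       targets, w_rep, scan_cfg)
    tab_f <- coverage_table(vblocks, c(W = w_len), repeats = w_rep,
                            identity_min = scan_cfg$identity_min)
    power <- if (nrow(blocks))
      coverage_fraction(merge_nonoverlapping(blocks, group_by_target = FALSE), w_len)
    else 0
    tgt_names <- names(targets)
    ranks_u <- rank_targets(tab_u, "W", all_targets = tgt_names)
    # an empty filtered table is evidence (no verified non-repeat homology
    # anywhere), not a missing measurement: rank it as all-zero
    ranks_f <- rank_targets(tab_f, "W", all_targets = tgt_names)
    hits <- simulate_protein_hits(g)
    tl <- tally_best_hits_by_chromosome(best_hit_per_protein(hits),
                                        all_chroms = tgt_names)
    tallies[[sp]] <- tl
    fus <- NULL
    if (check_fusion && length(species) > 1L) {
      partner <- setdiff(species, sp)[1L]
      # the partner's W is the Z's gametolog, not fusion evidence: exclude it
      ptargets <- clade$genomes[[partner]]$seq
      ptargets <- ptargets[clade$genomes[[partner]]$class[names(ptargets)] != "W"]
      zb <- find_synteny_blocks(g$seq["Z"], ptargets, scan_cfg)
      zb <- verify_nonrepeat_blocks(zb, g$seq["Z"], ptargets,
                                    g$repeats[g$repeats$chrom == "Z", , drop = FALSE],
                                    scan_cfg)
      fus <- detect_fusion(zb)
      fusion_reports[[sp]] <- fus
    }
    mech_by_sp[[sp]] <- test_mechanism(ranks_u, ranks_f, tally = tl,
                                       fusion = fus, power = power,
                                       min_evidence = min_evidence)
    within_cov[[sp]] <- list(unfiltered = tab_u, filtered = tab_f,
                             ranks_unfiltered = ranks_u, ranks_filtered = ranks_f,
                             power = power)
    if (confirm_sexchrom) {
      # 200 kb windows suit megabase chromosomes; at desk scale keep
      # ~20 windows per chromosome so the median depth is stable
      dwin <- min(200000L, max(1000L, clade$cfg$chrom_length %/% 60L))
      dt <- simulate_depth_tracks(clade, sp, cv = depth_cv, window = dwin,
                                  seed = derive_seed(clade$cfg$seed, 900L + match(sp, species)))
      profiles[[sp]] <- chromosome_profiles(g, dt)
    }
  }

  pairs <- if (length(species) > 1L) utils::combn(species, 2L, simplify = FALSE) else list()
  ev_rows <- lapply(pairs, function(pr) {
    a <- pr[1L]; b <- pr[2L]
    ga <- clade$genomes[[a]]
    if (!"W" %in% names(ga$seq)) return(NULL)
    blocks <- find_synteny_blocks(ga$seq["W"], clade$genomes[[b]]$seq,
                                  scan_cfg, index = idx[[b]])
    ev <- w_coverage_evidence(blocks, ga$seq[["W"]], clade$genomes[[b]]$seq,
                              ga$repeats[ga$repeats$chrom == "W", , drop = FALSE],
                              clade$genomes[[b]]$class, scan_cfg)
    data.frame(pair = paste(a, b, sep = "-"), w_w = ev$w_w, w_z = ev$w_z,
               w_auto_max = ev$w_auto_max, power = ev$power,
               stringsAsFactors = FALSE)
  })
  evidence <- do.call(rbind, Filter(Negate(is.null), ev_rows))
  if (is.null(evidence))
    evidence <- data.frame(pair = character(), w_w = numeric(), w_z = numeric(),
                           w_auto_max = numeric(), power = numeric())

  shared <- test_shared_origin(evidence, min_margin = min_margin,
                               supermajority = supermajority,
                               power_floor = power_floor)
  mechs <- vapply(mech_by_sp, `[[`, character(1), "mechanism")
  mech <- if (!length(mechs)) "ambiguous" else {
    tb <- sort(table(mechs), decreasing = TRUE)
    if (length(tb) > 1L && tb[1L] == tb[2L]) "ambiguous" else names(tb)[1L]
  }
  structure(list(shared_origin = shared$shared_origin, mechanism = mech,
                 share_positive = shared$share_positive,
                 n_informative = shared$n_informative,
                 exceptions = shared$exceptions,
                 evidence = shared$evidence,
                 mechanism_by_species = mech_by_sp,
                 within_coverage = within_cov, tallies = tallies,
                 fusion_reports = fusion_reports, profiles = profiles,
                 truth = clade$truth, seed = clade$cfg$seed),
            class = "origin_verdict")
}

#' @export
print.origin_verdict <- function(x, ...) {
  cat(sprintf("origin_verdict: shared_origin=%s mechanism=%s (%d informative pairs)\n",
              x$shared_origin, x$mechanism, x$n_informative))
  invisible(x)
}

#' Serialize an origin verdict to JSON
#'
#' @param verdict an `origin_verdict`.
#' @param path output path.
#' @export
write_verdict_json <- function(verdict, path) {
  out <- list(shared_origin = verdict$shared_origin,
              mechanism = verdict$mechanism,
              share_positive = verdict$share_positive,
              n_informative = verdict$n_informative,
              exceptions = verdict$exceptions,
              evidence = verdict$evidence,
              mechanism_by_species = lapply(verdict$mechanism_by_species,
                                            function(m) m[c("mechanism", "z_rank_filtered",
                                                            "z_rank_unfiltered", "z_tally_rank")]),
              seed = verdict$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
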