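#' Scenario configuration for the clade simulator
#'
#' Bundles every knob of the synthetic-genome generator: which W-origin
#' hypothesis to simulate, whether the W arose once at the clade root or
#' independently on each terminal branch, and the evolutionary parameters
#' (tree, substitution rates, repeat model, inversion counts, marker and
#' gene complements).
#'
#' Defaults encode the study conditions: 30 autosomes plus a Z (the
#' ancestral ditrysian karyotype of 31 chromosomes), a W repeat fraction of
#' 0.71 (typical of a well-assembled butterfly W), and a W
#' substitution multiplier of 3 reflecting the faster decay of a
#' non-recombining chromosome. Chromosome length defaults to 100 kb, a
#' desk-scale stand-in for multi-megabase chromosomes.
#'
#' @param hypothesis one of `"AUTOSOMAL_PAIR"` (W and Z from the same
#'   autosomal pair), `"B_CHROMOSOME"` (W recruited from a dispensable B),
#'   `"Z_AUTOSOME_FUSION"` (Z fused to an autosome, W formed from that
#'   autosome's homolog).
#' @param w_shared_origin logical; `TRUE` derives the W once at the clade
#'   root (single origin), `FALSE` derives it independently at the start of
#'   each terminal branch (multiple origins).
#' @param n_species number of extant species (tree tips), >= 2.
#' @param tree optional `ape::phylo` rooted tree with branch lengths in
#'   expected substitutions/site and exactly `n_species` tips. `NULL` draws
#'   a coalescent tree scaled to `tree_height`.
#' @param n_autosomes number of autosomes (Z is added on top).
#' @param chrom_length nominal chromosome length in bp (jittered per
#'   chromosome by up to `length_jitter`).
#' @param sub_rate_scale multiplier applied to all branch lengths.
#' @param w_extra_sub_multiplier extra substitution multiplier for the W
#'   (>= 1); models accelerated W degradation.
#' @param repeat_library_size number of repeat families in the shared
#'   library.
#' @param repeat_frac_autosome,repeat_frac_W target repeat fractions; the W
#'   target must be >= the autosomal target.
#' @param n_inversions_per_branch intra-chromosomal inversions per branch.
#' @param n_markers total single-copy markers (BUSCO-like) spread over the
#'   ancestral chromosomes.
#' @param n_proteins_per_chrom protein-coding gene tracts per chromosome.
#' @param gc_boost_W additive GC shift applied to the nascent W, in
#'   \[0, 0.3\].
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @param gene_length length of each gene tract in bp.
#' @param length_jitter relative chromosome-length jitter (uniform +/-).
#' @param gc_base,gc_jitter ancestral GC fraction and per-chromosome jitter.
#' @param marker_loss_prob,marker_dup_prob per-branch probability that a
#'   marker is lost, or duplicated (duplicates are later excluded from
#'   homology matrices, mimicking BUSCO "Duplicated" calls).
#' @param repeat_copy_divergence max per-copy divergence of an inserted
#'   repeat from its family consensus.
#' @param n_translocations_post_fusion segment swaps between the two parts
#'   of a neo-Z after a fusion (creates the interleaved homology pattern).
#' @param tree_height root height (substitutions/site) of the default tree.
#' @param father_w_depth_frac relative depth of mismapped reads on the W in
#'   a ZZ father.
#' @param w_stem_length W-specific decay accumulated between the W's
#'   origin and the clade root (expected substitutions/site on the stem):
#'   the W is far older than the splits among the sampled species, so its
#'   bulk sequence is saturated against the Z while W-W comparisons within
#'   the clade are not.
#' @param cons_frac fraction of each chromosome in slow-evolving conserved
#'   tracts (genic neighbourhoods under purifying selection); gene tracts
#'   live inside them. These tracts are what keeps ancient homology
#'   detectable after the intergenic bulk has saturated.
#' @param cons_tract_len length of one conserved tract (bp).
#' @param cons_rate_mult substitution-rate multiplier inside conserved
#'   tracts (<< 1).
#' @param w_retained_frac contiguous fraction of the source chromosome
#'   retained by the nascent W. Real W chromosomes keep only part of
#'   their ancestral sequence, so the W is not a length outlier relative
#'   to the rest of the karyotype; set to 1 for literal full-copy
#'   semantics.
#' @return a validated `scenario_config` list.
#' @export
scenario_config <- function(hypothesis = c("AUTOSOMAL_PAIR", "B_CHROMOSOME", "Z_AUTOSOME_FUSION"),
                            w_shared_origin = TRUE,
                            n_species = 3L,
                            tree = NULL,
                            n_autosomes = 30L,
                            chrom_length = 100000L,
                            sub_rate_scale = 1,
                            w_extra_sub_multiplier = 3,
                            repeat_library_size = 20L,
                            repeat_frac_autosome = 0.20,
                            repeat_frac_W = 0.71,
                            n_inversions_per_branch = 1L,
                            n_markers = 310L,
                            n_proteins_per_chrom = 8L,
                            gc_boost_W = 0.07,
                            seed = 1L,
                            gene_length = 300L,
                            length_jitter = 0.10,
                            gc_base = 0.35,
                            gc_jitter = 0.03,
                            marker_loss_prob = 0.05,
                            marker_dup_prob = 0.02,
                            repeat_copy_divergence = 0.10,
                            n_translocations_post_fusion = 3L,
                            tree_height = 0.05,
                            father_w_depth_frac = 0.05,
                            w_stem_length = 1.2,
                            cons_frac = 0.15,
                            cons_tract_len = 1000L,
                            cons_rate_mult = 0.15,
                            w_retained_frac = 0.4) {
  hypothesis <- match.arg(hypothesis)
  cfg <- list(
    hypothesis = hypothesis, w_shared_origin = isTRUE(w_shared_origin),
    n_species = as.integer(n_species), tree = tree,
    n_autosomes = as.integer(n_autosomes),
    chrom_length = as.integer(chrom_length),
    sub_rate_scale = sub_rate_scale,
    w_extra_sub_multiplier = w_extra_sub_multiplier,
    repeat_library_size = as.integer(repeat_library_size),
    repeat_frac_autosome = repeat_frac_autosome,
    repeat_frac_W = repeat_frac_W,
    n_inversions_per_branch = as.integer(n_inversions_per_branch),
    n_markers = as.integer(n_markers),
    n_proteins_per_chrom = as.integer(n_proteins_per_chrom),
    gc_boost_W = gc_boost_W, seed = as.integer(seed),
    gene_length = as.integer(gene_length), length_jitter = length_jitter,
    gc_base = gc_base, gc_jitter = gc_jitter,
    marker_loss_prob = marker_loss_prob, marker_dup_prob = marker_dup_prob,
    repeat_copy_divergence = repeat_copy_divergence,
    n_translocations_post_fusion = as.integer(n_translocations_post_fusion),
    tree_height = tree_height,
    father_w_depth_frac = father_w_depth_frac,
    w_stem_length = w_stem_length,
    cons_frac = cons_frac,
    cons_tract_len = as.integer(cons_tract_len),
    cons_rate_mult = cons_rate_mult,
    w_retained_frac = w_retained_frac
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("lepw_config_error", "error")))
}

validate_scenario_config <- function(cfg) {
  if (cfg$n_species < 2L) config_error("n_species must be >= 2")
  if (cfg$n_autosomes < 1L) config_error("n_autosomes must be >= 1")
  if (cfg$hypothesis == "Z_AUTOSOME_FUSION" && cfg$n_autosomes < 1L)
    config_error("fusion requires at least one autosome")
  if (cfg$chrom_length < 1000L) config_error("chrom_length must be >= 1000 bp")
  if (cfg$repeat_frac_W < cfg$repeat_frac_autosome)
    config_error("repeat_frac_W must be >= repeat_frac_autosome")
  if (cfg$repeat_frac_autosome < 0 || cfg$repeat_frac_W >= 1)
    config_error("repeat fractions must lie in [0, 1)")
  if (cfg$w_extra_sub_multiplier < 1)
    config_error("w_extra_sub_multiplier must be >= 1")
  if (cfg$gc_boost_W < 0 || cfg$gc_boost_W > 0.3)
    config_error("gc_boost_W must lie in [0, 0.3]")
  if (cfg$cons_frac < 0 || cfg$cons_frac > 0.9)
    config_error("cons_frac must lie in [0, 0.9]")
  if (cfg$cons_rate_mult <= 0 || cfg$cons_rate_mult > 1)
    config_error("cons_rate_mult must lie in (0, 1]")
  if (cfg$w_stem_length < 0) config_error("w_stem_length must be >= 0")
  if (cfg$w_retained_frac <= 0 || cfg$w_retained_frac > 1)
    config_error("w_retained_frac must lie in (0, 1]")
  if (!is.null(cfg$tree)) {
    if (!inherits(cfg$tree, "phylo")) config_error("tree must be an ape phylo object")
    if (length(cfg$tree$tip.label) != cfg$n_species)
      config_error("tree must have exactly n_species tips")
    if (is.null(cfg$tree$edge.length) || any(cfg$tree$edge.length < 0))
      config_error("tree must carry nonnegative branch lengths")
  }
  invisible(cfg)
}

#' Read a scenario configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [scenario_config()]; a `tree` key,
#' if present, holds a Newick string.
#'
#' @param path YAML file path.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$tree) && is.character(vals$tree))
    vals$tree <- ape::read.tree(text = vals$tree)
  do.call(scenario_config, vals)
}

# Default clade tree: a coalescent tree rescaled so the root sits at
# cfg$tree_height expected substitutions/site.
default_tree <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 3L))
  tr <- ape::rcoal(cfg$n_species, tip.label = paste0("sp", seq_len(cfg$n_species)))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth * cfg$tree_height
  tr
}
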