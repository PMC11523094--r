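---
title: "Inferring the origin of lepidopteran W chromosomes from whole-genome synteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the origin of lepidopteran W chromosomes from whole-genome synteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Moths and butterflies have ZW sex chromosomes: females are ZW, males ZZ.
The Z is deeply conserved across the order, but where the W came from is
contested. Three hypotheses compete:

1. **Autosomal pair** — the W descends from the same ancestral autosomal
   pair as the Z (the canonical model of sex-chromosome evolution).
2. **B chromosome** — the W is a recruited dispensable B chromosome,
   with no sequence relationship to the Z.
3. **Z–autosome fusion** — an autosome fused to the Z (forming a neo-Z)
   and the free homolog of that autosome became the W.

Orthogonal to the mechanism is the question of *how many times* the W
arose: a single shared origin predicts that W chromosomes of different
species resemble each other more than they resemble any Z or autosome;
independent origins predict either W-to-own-Z similarity (repeated
autosomal recruitment) or no similarity at all (repeated B recruitment).

Because W chromosomes do not recombine, they decay fast: they accumulate
substitutions, fill up with repeats (about 71% repeat content is typical
for a well-assembled butterfly W) and shed ancestral sequence. Any
inference must therefore work from weak, partial homology signals and be
honest when the signal has decayed past detectability.

`lepWorigin` implements the full inference chain — synteny-block
detection, nonoverlapping coverage statistics with repeat filtering,
marker- and protein-based chromosome homology, trio-depth confirmation
of W identity, neo-Z fusion detection, and the origin classifier — and a
clade simulator that generates genomes under each hypothesis so every
stage can be validated by parameter recovery.

## The synteny detector

The detector follows the observable contract of window-based
whole-genome aligners: it maps fixed-size query windows (default 1 kb,
step 500 bp) onto the target with shared 16-mer seeds, anchors each
window at its best-supported ungapped diagonal, and scores it by
ungapped identity — matching bases over window length, with `N` never
matching. Windows are kept above an identity floor of 0.45; an optional
stricter run at 0.70 mirrors the standard sensitivity/stringency
contrast. Matches then pass a *concordance* filter: a match survives
only if at least 2 other matches fall on the same target chromosome,
same orientation, within 20 kb in query and target, in a consistent
order along the diagonal. This removes isolated repeat-driven hits.
Finally, *battleship refinement* re-scans half-step-offset windows in
the flanks of every retained block against the local diagonal only, so
windows too diverged to seed (but still above the identity floor) are
recovered; the operation runs to a fixed point and is idempotent.

Design choices worth stating:

* **Ungapped identity, no affine alignment.** At the simulated
  divergences indels are absent and gaps are rare in practice at window
  scale; an ungapped score keeps every number in the pipeline exactly
  reproducible by a brute-force oracle, which the test suite exploits.
* **Determinism.** Diagonal ties break toward the leftmost target
  position; per-window match lists are ordered by identity, then target
  name and position. Scanning a reverse-complemented target yields
  exactly the orientation-flipped, coordinate-reflected block set.
* **Repeat-seed cutoff.** Seed k-mers occurring more than 100 times in
  the target are ignored, as in any practical seeded aligner. Repeat
  homology is still found (via rarer seeds within long copies) but
  cannot explode the candidate set.

## Coverage statistics and the repeat confound

Block projections on the query are merged into disjoint intervals
(per target chromosome) and summarized as the fraction of the query
covered — the central statistic. Repeat filtering subtracts the query's
repeat annotation from numerator *and* denominator by default, so the
filtered fraction reads "share of the non-repeat W covered";
numerator-only subtraction is available by flag.

One subtlety matters at every scale: a window that straddles a
repeat/unique boundary can clear the 45% floor on its repeat half alone,
so its unique flank leaks into repeat-filtered coverage without being
homologous. Sex chromosomes are the worst case — both accumulate the
same repeat families independently, which is exactly the confound that
motivates repeat filtering in the first place. The pipeline therefore
*verifies* blocks before filtered coverage: each block's identity is
recomputed on its non-repeat query positions only, and blocks whose
unique bases do not independently reach the identity floor are dropped
(`verify_nonrepeat_blocks()`). Unfiltered and filtered tables are always
reported side by side, because they can rank chromosomes differently on
real data.

## The origin classifier

The classifier formalizes ranking arguments with explicit margins
instead of inventing a likelihood, because the underlying reasoning is
ordinal ("the Z shares the most blocks with the W").

**Single vs multiple origin.** For each species pair, the score is the
W-vs-W repeat-filtered coverage minus the best of W-vs-Z and
W-vs-autosome. A pair is *informative* only if its query W has
unfiltered coverage of at least 0.05 against the partner genome: a W
that aligns to nothing (not even shared repeats) carries no information
about origin — it has simply decayed beyond reach. The call is `single`
if at least 80% of informative pairs score above 0.02 (the "all but one
species" pattern), `multiple` if at most 50% do, otherwise
`inconclusive`; fewer than half the pairs informative is also
`inconclusive`. This separation is what lets the classifier distinguish
"the Ws are unrelated to each other although they still align
somewhere" (evidence for independent origins) from "nothing aligns"
(no power).

**Mechanism.** Within a species, with the W as query against its 31
non-W chromosomes: `autosomal_pair` when the Z ranks first in verified,
repeat-filtered coverage with strictly positive, above-median coverage —
or within the top two while ranking first in best protein hits (the
combined-evidence pattern); `b_chromosome` when the Z does no better
than the autosomal median; `z_autosome_fusion` when the fusion detector
fires on the Z. Any confident call requires unfiltered W coverage of at
least 0.05; below that the verdict is `ambiguous`. A zero-coverage Z is
never read as support for an autosomal origin, and an empty filtered
table is treated as an all-zero ranking (real evidence of absence), not
as a missing measurement.

**Fusion detection.** Along a candidate chromosome, per-block homology
assignments against a partner species are reduced to partner fractions
and an interleaving index (partner switches over blocks − 1). A fusion
is flagged when the top two partners each explain ≥ 0.25 of the blocks
and jointly ≥ 0.8. The partner's W is excluded from the target set —
for a Z query, the W is its gametolog, not fusion evidence — and the
track is repeat-verified first, since scattered repeat blocks otherwise
dilute the joint fraction. The thresholds 0.25/0.8 formalize
"approximately half of the chromosome" as a declared default.

**Best protein hits.** Hits are pre-filtered at e-value ≤ 1e−10; per
query the minimal e-value wins, e-value ties resolve by percent
identity, residual ties lexicographically by subject id (flagged rather
than dropped). Tallies per target chromosome are reported with their
mean across the chromosome set.

**Marker homology.** Chromosomes are paired across species by the
argmax of shared single-copy markers; markers seen more than once
within a species (the "Duplicated" analogue) are excluded so
repeat-driven placements cannot distort counts. Ties are flagged, and
the map is allowed to be non-injective because fusions legitimately
send two ancestral chromosomes to one.

## What the simulator emulates — and what it does not

`simulate_clade()` generates a rooted clade (default: coalescent tree
rescaled to 0.05 substitutions/site root height) from an ancestor of 30
autosomes plus Z, ~100 kb per chromosome at desk scale, GC 0.35 with
per-chromosome jitter. Sequence evolution is Jukes–Cantor via exact
per-site transition probabilities (so the closed form
$p = \frac{3}{4}(1 - e^{-4d/3})$ is testable); the W runs at a
3× substitution multiplier. Each chromosome carries slow-evolving
conserved tracts (15% of its length, 1 kb tracts at a 0.15 rate
multiplier) hosting the protein-coding gene tracts — this is the
mechanism by which ancient homology stays detectable in a saturated
background, exactly the regime in which real W–Z homology is found.
Inversions (uniform breakpoints, 1–20% of the chromosome) and
marker loss/duplication act per branch; a shared 20-family repeat
library (300–3000 bp consensus, per-copy divergence up to 0.1) tops
every chromosome up to its target repeat fraction (0.20 autosomes,
0.71 W), inserting — never overwriting — outside genes and conserved
tracts, so unique sequence stays recoverable.

The W is derived once at the root (shared origin) or independently at
the start of each terminal branch. Key simulator decisions:

* **W stem decay** (`w_stem_length`, default 1.2 substitutions/site on
  the W before the clade root): the W is far older than the splits among
  sampled species, so its bulk sequence is saturated against the Z
  while W–W comparisons within the clade are not. This reproduces the
  paradoxical-looking empirical pattern — strong W–W synteny across
  species together with only weak, tract-limited W–Z homology within a
  species — that the whole inference rests on.
* **Partial retention** (`w_retained_frac`, default 0.4): the nascent W
  keeps a contiguous fraction of its source chromosome, anchored on a
  conserved tract (a W fragment with no recognizable ancestral content
  would not be analyzable at all). Full-copy semantics are available
  with `w_retained_frac = 1`.
* **Fusion scenario**: the fused autosome is chosen uniformly at
  random per derivation event; post-fusion translocations (default 3
  segment swaps across the fusion point) create the interleaved
  homology pattern characteristic of a real neo-Z. Two independent
  lineages occasionally fuse with the same partner, in which case
  cross-species detection legitimately sees a single partner.
* **Trio depth** is gamma noise around the expected pattern (mother
  Z and W at half the autosomal depth; father Z at full depth, father W
  at 5% mimicking mismapping), averaged in 200 kb windows at full scale
  and proportionally smaller windows at desk scale (about 20–60 windows
  per chromosome, matching the window count of megabase chromosomes).
* **Protein "BLAST"**: gene tracts are compared orientation-aware with
  an ungapped +1/−2 score converted to Karlin–Altschul-style e-values,
  emitted in tabular (outfmt-6) layout. Homologous families yield tiny
  e-values; unrelated tracts never pass 1e−10.

Not emulated: indels, realistic transposable-element dynamics or
insertion-age structure, recombination, gene conversion, segmental
duplication, assembly error, and Wolbachia-style biology. Passing tests
therefore show that the *inference logic* recovers the truth when the
data match its assumptions at desk scale; they do not show robustness
to assembly artifacts or to repeat landscapes more adversarial than the
shared-library model.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere outside R internals;
  FASTA headers carry `class=` tags.
* Identity denominators are always the nominal window length, so
  clipped alignments at chromosome ends are penalized, never
  renormalized.
* Windows with more than 50% `N` are skipped; `N` never counts as a
  match and is excluded from GC numerator and denominator.
* Empty inputs (no blocks, empty queries) return empty, typed results;
  configuration errors (seed length ≥ window, invalid fractions) raise
  a dedicated condition class.
* Depth windows larger than the chromosome collapse to one
  whole-chromosome window; a zero-CV request returns exact means.
* All randomness flows from a single integer seed through fixed
  sub-seed derivations per event (ancestor, library, tree, branch,
  derivation), so identical configurations reproduce byte-identical
  files.

## Problem sizes used by the tests

The full study conditions (multi-hundred-megabase assemblies) are not
reproducible on a desk, so validation is parameter recovery at reduced
scale, with sizes chosen once: detector sensitivity/specificity on
100 kb sequence pairs; marker-homology and trio-depth recovery on
31-chromosome clades with 20 kb chromosomes; fusion recovery on
2-species clades with 30 autosomes of 12 kb; end-to-end origin recovery
on 3-species clades with 6 autosomes of 30 kb, 20 seeds per scenario.
At these sizes the complete suite and the acceptance script run in tens
of minutes on one core.

## Known limitations

* The mechanism call cannot separate "autosomal pair" from "fusion
  origin" when the fusion is ancestral to the whole clade — the W then
  shows exactly the Z-first ranking of an autosomal-pair origin. This
  mirrors the biological reality that hypothesis (3) is a special case
  of (1) once the neo-Z is fixed.
* Under extreme W decay (substitution multipliers far above the
  default), even conserved tracts saturate and the classifier returns
  `inconclusive`/`ambiguous`. That is by design: absence of signal is
  reported as absence of power, not as evidence for a B origin.
* The detector's fixed-window blocks are coarse relative to short
  repeats, which is why filtered coverage goes through non-repeat
  verification; on data with much shorter unique tracts than 1 kb the
  window size should be reduced accordingly.

## A minimal run

```{r example}
library(lepWorigin)

cfg <- scenario_config(hypothesis = "AUTOSOMAL_PAIR", w_shared_origin = TRUE,
                       n_species = 3, n_autosomes = 6, chrom_length = 30000,
                       n_markers = 100, n_proteins_per_chrom = 4, seed = 1)
verdict <- run_pipeline(cfg)
verdict$shared_origin   # "single"
verdict$mechanism       # "autosomal_pair"
verdict$evidence        # per-pair W-vs-W / W-vs-Z / W-vs-autosome fractions
```

The numbered scripts under `analysis/` walk the same pipeline step by
step — simulation, scanning, coverage, homology and fusion, trio
confirmation, and the final verdict grid — writing their tables under
`results/`.
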