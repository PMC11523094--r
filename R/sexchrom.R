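# Four-test confirmation of W identity: trio depth ratios, cross-species
# W correspondence, GC content, repeat content.

#' Classify chromosomes from mother/father depth tracks
#'
#' Uses the hallmark trio pattern of a ZW system: in the ZW mother both
#' sex chromosomes sit at half the autosomal depth, while in the ZZ
#' father the Z matches the autosomes and the W collects only mismapped
#' reads. Per parent, the baseline is the median window depth across all
#' chromosomes (autosomes dominate the window count, so the median is an
#' autosomal baseline robust to repeat pileups); pass `autosomes` to pin
#' it explicitly. A chromosome is called
#' `Z` when mother ratio is within `tol` of 0.5 and father within `tol`
#' of 1; `W` when mother is near 0.5 and father below `w_father_max`;
#' `autosome` when both are near 1; otherwise `ambiguous`.
#'
#' @param mother,father depth data.frames (chrom, start, end, depth).
#' @param tol tolerance around the 0.5 and 1.0 ratios ("roughly half").
#' @param w_father_max maximum father ratio for a W call.
#' @param autosomes optional chromosomes to use for the baseline.
#' @return data.frame(chrom, mother_ratio, father_ratio, class_call).
#' @export
depth_ratio_call <- function(mother, father, tol = 0.15, w_father_max = 0.25,
                             autosomes = NULL) {
  stopifnot(setequal(unique(mother$chrom), unique(father$chrom)))
  baseline <- function(track) {
    rows <- if (is.null(autosomes)) track else track[track$chrom %in% autosomes, ]
    if (!nrow(rows)) stop("no windows available for the autosomal baseline")
    median(rows$depth)
  }
  bm <- baseline(mother)
  bf <- baseline(father)
  if (bm <= 0 || bf <= 0) stop("non-positive autosomal baseline depth")
  chroms <- sort(unique(mother$chrom))
  out <- lapply(chroms, function(cn) {
    rm_ <- median(mother$depth[mother$chrom == cn]) / bm
    rf <- median(father$depth[father$chrom == cn]) / bf
    call <- if (abs(rm_ - 0.5) <= tol && rf < w_father_max) "W"
            else if (abs(rm_ - 0.5) <= tol && abs(rf - 1) <= tol) "Z"
            else if (abs(rm_ - 1) <= tol && abs(rf - 1) <= tol) "autosome"
            else "ambiguous"
    data.frame(chrom = cn, mother_ratio = rm_, father_ratio = rf,
               class_call = call, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Repeat content per chromosome, with length-expectation residuals
#'
#' Fraction of each chromosome covered by the union of its repeat
#' intervals, plus the residual from a least-squares fit of repeat bp
#' against chromosome length across chromosomes — the "more repeats than
#' expected given its length" check that singles out W chromosomes.
#'
#' @param lengths named chromosome lengths (bp).
#' @param repeats data.frame(chrom, start, end).
#' @return data.frame(chrom, length_bp, repeat_bp, repeat_fraction,
#'   residual_bp).
#' @export
repeat_content_stats <- function(lengths, repeats) {
  rep_bp <- vapply(names(lengths), function(cn) {
    rr <- repeats[repeats$chrom == cn, , drop = FALSE]
    if (!nrow(rr)) return(0L)
    as.integer(sum(IRanges::width(IRanges::reduce(.to_ir(rr$start, rr$end)))))
  }, integer(1))
  df <- data.frame(chrom = names(lengths), length_bp = as.integer(lengths),
                   repeat_bp = rep_bp,
                   repeat_fraction = rep_bp / as.numeric(lengths),
                   stringsAsFactors = FALSE)
  df$residual_bp <- if (nrow(df) >= 3L)
    as.numeric(residuals(lm(repeat_bp ~ length_bp, data = df))) else NA_real_
  df
}

#' Repeat fraction of a single chromosome
#'
#' @param chrom_length chromosome length in bp.
#' @param repeats data.frame(start, end) of repeats on that chromosome.
#' @return fraction of the chromosome covered by the repeat union.
#' @export
repeat_fraction <- function(chrom_length, repeats) {
  stopifnot(chrom_length > 0)
  if (is.null(repeats) || !nrow(repeats)) return(0)
  if (any(repeats$start < 0L | repeats$end > chrom_length))
    stop("repeat interval exceeds chromosome bounds")
  sum(IRanges::width(IRanges::reduce(.to_ir(repeats$start, repeats$end)))) /
    chrom_length
}

#' Does a candidate W correspond to the W of a complete reference?
#'
#' TRUE iff the candidate chromosome's top-ranked homolog in the
#' reference coverage table is the reference chromosome labelled W.
#'
#' @param tab [coverage_table()] of candidate-query vs reference-target.
#' @param candidate query chromosome name.
#' @param ref_classes named class vector of the reference genome (must
#'   contain a `W`).
#' @return logical.
#' @export
cross_species_w_check <- function(tab, candidate, ref_classes) {
  wname <- names(ref_classes)[ref_classes == "W"]
  if (!length(wname)) stop("reference genome has no labelled W chromosome")
  rows <- tab[tab$qchrom == candidate, , drop = FALSE]
  if (!nrow(rows)) return(FALSE)
  rk <- rank_targets(tab, candidate)
  rk$target[1L] %in% wname && rk$fraction[1L] > 0
}

#' Per-chromosome profile combining the four W-identity tests
#'
#' @param gnm a `sim_genome` (sequences + repeats).
#' @param depth list(mother, father) from [simulate_depth_tracks()] or
#'   read from TSVs.
#' @param tol passed to [depth_ratio_call()].
#' @return data.frame with depth ratios, class call, GC and repeat
#'   fraction per chromosome, plus a `gc_z` column (z-score of GC against
#'   the autosomal GC distribution).
#' @export
chromosome_profiles <- function(gnm, depth, tol = 0.15) {
  calls <- depth_ratio_call(depth$mother, depth$father, tol = tol)
  lens <- chrom_lengths(gnm)
  rep_stats <- repeat_content_stats(lens, gnm$repeats)
  gc <- vapply(gnm$seq, gc_fraction, numeric(1))
  df <- merge(calls, rep_stats, by = "chrom")
  df$gc_fraction <- gc[df$chrom]
  auto <- names(gnm$class)[gnm$class == "autosome"]
  mu <- mean(gc[auto]); sdev <- sd(gc[auto])
  df$gc_z <- if (is.finite(sdev) && sdev > 0) (df$gc_fraction - mu) / sdev else NA_real_
  df[order(df$chrom), , drop = FALSE]
}
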