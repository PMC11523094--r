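# Cross-species chromosome homology from shared single-copy markers,
# best protein hits with explicit tie-breaking, and neo-Z fusion
# detection from split, interleaved homology tracks.

#' Marker hit matrix between two species
#'
#' Counts, for every chromosome pair, the single-copy markers placed on
#' chromosome A in species A and chromosome B in species B. Markers seen
#' more than once within a species (the BUSCO "Duplicated" analogue) are
#' excluded so repeat-driven placements cannot distort the counts.
#'
#' @param markers_a,markers_b data.frames (marker_id, chrom, ...).
#' @return integer matrix; rows = species A chromosomes, cols = species B.
#' @export
marker_hit_matrix <- function(markers_a, markers_b) {
  dedup <- function(m) {
    dup <- m$marker_id[duplicated(m$marker_id)]
    m[!m$marker_id %in% dup, , drop = FALSE]
  }
  a <- dedup(markers_a)
  b <- dedup(markers_b)
  j <- merge(a[, c("marker_id", "chrom")], b[, c("marker_id", "chrom")],
             by = "marker_id", suffixes = c("_a", "_b"))
  if (!nrow(j)) return(matrix(0L, 0L, 0L))
  as.matrix(table(j$chrom_a, j$chrom_b))
}

#' Assign chromosome homology from a marker hit matrix
#'
#' Each row chromosome maps to the column chromosome sharing the most
#' markers. Exact ties break lexicographically and are flagged; runner-up
#' counts within `near_margin` of the winner get a proximity flag.
#' All-zero rows map to `"unassigned"`. The map need not be injective:
#' fusions legitimately send two ancestral chromosomes to one.
#'
#' @param mat matrix from [marker_hit_matrix()].
#' @param near_margin relative margin for the near-tie warning flag.
#' @return data.frame(chrom, homolog, count, runner_up, runner_count,
#'   tie, near_tie).
#' @export
assign_homology <- function(mat, near_margin = 0.10) {
  if (!nrow(mat)) stop("empty marker hit matrix")
  out <- lapply(rownames(mat), function(rn) {
    v <- mat[rn, ]
    if (all(v == 0L))
      return(data.frame(chrom = rn, homolog = "unassigned", count = 0L,
                        runner_up = NA_character_, runner_count = 0L,
                        tie = FALSE, near_tie = FALSE, stringsAsFactors = FALSE))
    o <- order(-v, names(v))
    best <- o[1L]
    second <- if (length(v) > 1L) o[2L] else NA_integer_
    rc <- if (is.na(second)) 0L else v[second]
    data.frame(chrom = rn, homolog = names(v)[best], count = as.integer(v[best]),
               runner_up = if (is.na(second)) NA_character_ else names(v)[second],
               runner_count = as.integer(rc),
               tie = !is.na(second) && v[best] == rc,
               near_tie = !is.na(second) && rc >= (1 - near_margin) * v[best] && rc > 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Best hit per query protein
#'
#' Per query: minimal e-value; e-value ties resolved by maximal percent
#' identity; residual ties by lexicographically smallest subject id
#' (flagged). Hits above `max_evalue` are discarded first; queries with
#' no surviving hit are simply absent.
#'
#' @param hits data.frame with qseqid, sseqid, evalue, pident (outfmt-6
#'   naming; extra columns are carried along).
#' @param max_evalue e-value cutoff (default 1e-10).
#' @return one row per query, plus a `residual_tie` flag.
#' @export
best_hit_per_protein <- function(hits, max_evalue = 1e-10) {
  h <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (!nrow(h)) {
    h$residual_tie <- logical(0)
    return(h)
  }
  dt <- data.table::as.data.table(h)
  data.table::setorder(dt, qseqid, evalue, -pident, sseqid)
  best <- dt[, {
    tie <- .N > 1L && evalue[2L] == evalue[1L] && pident[2L] == pident[1L]
    c(.SD[1L], list(residual_tie = tie))
  }, by = qseqid]
  as.data.frame(best)
}

#' Tally best protein hits by target chromosome
#'
#' @param best output of [best_hit_per_protein()] with a `target_chrom`
#'   column (or supply `protein_chrom` to map subject ids).
#' @param protein_chrom optional named vector sseqid -> chromosome.
#' @param all_chroms optional chromosome universe to include with zero
#'   counts (the averaging set).
#' @return list(counts = data.frame(chrom, n_hits), mean_hits = mean over
#'   the reported chromosomes).
#' @export
tally_best_hits_by_chromosome <- function(best, protein_chrom = NULL,
                                          all_chroms = NULL) {
  if (!nrow(best)) {
    counts <- data.frame(chrom = character(), n_hits = integer(),
                         stringsAsFactors = FALSE)
    if (!is.null(all_chroms))
      counts <- data.frame(chrom = all_chroms, n_hits = 0L,
                           stringsAsFactors = FALSE)
    return(list(counts = counts,
                mean_hits = if (nrow(counts)) 0 else NaN))
  }
  chrom <- if ("target_chrom" %in% names(best)) best$target_chrom
           else unname(protein_chrom[best$sseqid])
  tb <- table(chrom)
  counts <- data.frame(chrom = names(tb), n_hits = as.integer(tb),
                       stringsAsFactors = FALSE)
  if (!is.null(all_chroms)) {
    missing <- setdiff(all_chroms, counts$chrom)
    if (length(missing))
      counts <- rbind(counts, data.frame(chrom = missing, n_hits = 0L,
                                         stringsAsFactors = FALSE))
  }
  counts <- counts[order(-counts$n_hits, counts$chrom), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, mean_hits = mean(counts$n_hits))
}

#' Detect a chromosome fusion from a partner track
#'
#' Takes per-block homology assignments along a candidate chromosome
#' (position + partner chromosome, e.g. from synteny blocks against
#' another species) and flags a fusion when the top two partners each
#' explain at least `min_frac` of the assigned blocks and jointly at
#' least `joint_min`. The interleaving index is the number of partner
#' switches along the chromosome divided by (blocks - 1): 0 means two
#' clean halves, values near 1 a fully interleaved pattern.
#'
#' @param track data.frame(pos, partner) or a block data.frame with
#'   qstart/tchrom columns.
#' @param min_frac minimum fraction per partner (default 0.25).
#' @param joint_min minimum joint fraction of the top two partners.
#' @param min_blocks fewer assigned blocks than this returns an
#'   "insufficient signal" report.
#' @return list(fusion, partner_1, partner_2, fraction_1, fraction_2,
#'   interleaving_index, n_blocks, reason).
#' @export
detect_fusion <- function(track, min_frac = 0.25, joint_min = 0.8,
                          min_blocks = 4L) {
  if (!is.null(track$qstart) && is.null(track$pos))
    track <- data.frame(pos = track$qstart, partner = track$tchrom,
                        stringsAsFactors = FALSE)
  track <- track[order(track$pos), , drop = FALSE]
  n <- nrow(track)
  no_call <- function(reason) list(fusion = NA, partner_1 = NA_character_,
                                   partner_2 = NA_character_,
                                   fraction_1 = NA_real_, fraction_2 = NA_real_,
                                   interleaving_index = NA_real_,
                                   n_blocks = n, reason = reason)
  if (n < min_blocks) return(no_call("insufficient signal"))
  tb <- sort(table(track$partner), decreasing = TRUE)
  f1 <- tb[1L] / n
  if (length(tb) < 2L)
    return(list(fusion = FALSE, partner_1 = names(tb)[1L], partner_2 = NA_character_,
                fraction_1 = unname(f1), fraction_2 = 0,
                interleaving_index = 0, n_blocks = n, reason = "single partner"))
  f2 <- tb[2L] / n
  p1 <- names(tb)[1L]; p2 <- names(tb)[2L]
  switches <- sum(head(track$partner, -1L) != track$partner[-1L])
  list(fusion = unname(f1 >= min_frac && f2 >= min_frac && (f1 + f2) >= joint_min),
       partner_1 = p1, partner_2 = p2,
       fraction_1 = unname(f1), fraction_2 = unname(f2),
       interleaving_index = switches / (n - 1L),
       n_blocks = n, reason = "ok")
}
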