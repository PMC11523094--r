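# Simulated protein-homology search: compares the W chromosome's gene
# tracts against the gene complement of the remaining chromosomes and
# emits a BLAST-tabular-like hit table, so the best-hit/tally machinery
# can be exercised without running BLAST.

extract_gene_seq <- function(gnm, row) {
  s <- substr(gnm$seq[[row$chrom]], row$start + 1L, row$end)
  if (row$strand == "-") s <- revcomp(s)
  s
}

#' Simulate a protein homology search of W genes against the genome
#'
#' Every gene tract on the W is compared (ungapped, orientation-aware)
#' against every gene tract on the other chromosomes of the same species.
#' Scores follow a simple ungapped scheme (+1 match, -2 mismatch) and are
#' converted to Karlin-Altschul-style e-values, so genuinely homologous
#' tracts (shared ancestral family) produce tiny e-values while unrelated
#' tracts fall far above any sensible cutoff. Output columns follow BLAST
#' outfmt-6 order.
#'
#' @param clade a `sim_clade` (or a `sim_genome`).
#' @param species species name within the clade.
#' @param max_evalue hits above this e-value are dropped (BLAST-style
#'   reporting cutoff; the best-hit selector applies its own stricter one).
#' @return data.frame in outfmt-6 column order plus a `target_chrom`
#'   column mapping each subject protein to its chromosome.
#' @export
simulate_protein_hits <- function(clade, species = NULL, max_evalue = 10) {
  gnm <- if (inherits(clade, "sim_genome")) clade else clade$genomes[[species]]
  stopifnot(inherits(gnm, "sim_genome"))
  qry <- gnm$genes[gnm$genes$chrom == "W", , drop = FALSE]
  db <- gnm$genes[gnm$genes$chrom != "W", , drop = FALSE]
  if (!nrow(qry) || !nrow(db)) return(empty_hits())
  db_len <- sum(db$end - db$start)
  rows <- list()
  for (i in seq_len(nrow(qry))) {
    qseq <- extract_gene_seq(gnm, qry[i, ])
    qlen <- nchar(qseq)
    qraw <- charToRaw(qseq)
    # only same-family tracts can plausibly align; unrelated tracts score
    # below zero and would never pass any reporting threshold
    cand <- db[db$family == qry$family[i], , drop = FALSE]
    if (!nrow(cand)) next
    for (j in seq_len(nrow(cand))) {
      sseq <- extract_gene_seq(gnm, cand[j, ])
      m <- .match_count(qraw, charToRaw(sseq))
      mm <- min(qlen, nchar(sseq)) - m
      score <- m - 2L * mm
      ev <- 0.35 * qlen * db_len * exp(-1.1 * max(score, 0L))
      ev <- max(ev, 1e-180)
      if (score <= 0L || ev > max_evalue) next
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = qry$gene_id[i], sseqid = cand$gene_id[j],
        pident = 100 * m / qlen, length = qlen, mismatch = mm,
        gapopen = 0L, qstart = 1L, qend = qlen, sstart = 1L,
        send = nchar(sseq), evalue = ev, bitscore = score,
        target_chrom = cand$chrom[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_hits())
  do.call(rbind, rows)
}

empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             target_chrom = character(), stringsAsFactors = FALSE)
}
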