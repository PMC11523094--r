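# Readers and writers for the pipeline's plain-text interchange formats:
# FASTA genomes (with class tags in headers), BED repeats, marker TSVs,
# depth TSVs, synteny-block TSVs, BLAST outfmt-6 tables and truth JSON.

#' Write a simulated clade to disk
#'
#' Per species: a 60-column-wrapped FASTA whose headers carry class tags
#' (`chr1 class=autosome`, `Z class=Z`, ...), a repeat BED
#' (chrom, start, end, family), a marker TSV (marker_id, chrom, start) and
#' a gene-tract FASTA. A `truth.json` records the simulated origins.
#'
#' @param clade a `sim_clade`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_clade <- function(clade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(clade$genomes)) {
    g <- clade$genomes[[sp]]
    write_genome_fasta(g, file.path(dir, paste0(sp, ".fa")))
    rep_df <- g$repeats[order(g$repeats$chrom, g$repeats$start), , drop = FALSE]
    write.table(rep_df, file.path(dir, paste0(sp, ".repeats.bed")),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    mk <- g$markers[order(g$markers$marker_id), , drop = FALSE]
    write.table(mk, file.path(dir, paste0(sp, ".markers.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(g$genes)) {
      gs <- vapply(seq_len(nrow(g$genes)),
                   function(i) extract_gene_seq(g, g$genes[i, ]), character(1))
      prot <- Biostrings::DNAStringSet(setNames(gs, g$genes$gene_id))
      Biostrings::writeXStringSet(prot, file.path(dir, paste0(sp, ".genes.fa")), width = 60L)
    }
  }
  jsonlite::write_json(clade$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Write a `sim_genome` as FASTA with class-tagged headers
#' @param gnm a `sim_genome`.
#' @param path output path.
#' @export
write_genome_fasta <- function(gnm, path) {
  xs <- Biostrings::DNAStringSet(gnm$seq)
  names(xs) <- sprintf("%s class=%s", names(gnm$seq), gnm$class[names(gnm$seq)])
  Biostrings::writeXStringSet(xs, path, width = 60L)
  invisible(path)
}

#' Read a class-tagged genome FASTA
#'
#' @param path FASTA path.
#' @return list(seq = named character vector, class = named character
#'   vector); chromosomes without a `class=` tag are called autosomes.
#' @export
read_genome_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  hdr <- names(xs)
  nm <- sub("\\s.*$", "", hdr)
  cls <- ifelse(grepl("class=", hdr), sub(".*class=(\\S+).*", "\\1", hdr), "autosome")
  list(seq = setNames(as.character(xs), nm), class = setNames(cls, nm))
}

#' Read a repeat BED (chrom, start, end\[, family\])
#' @param path BED path.
#' @return data.frame(chrom, start, end, family).
#' @export
read_bed_repeats <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "family" else df$family <- NA_character_
  df[, c("chrom", "start", "end", "family")]
}

#' Write/read depth TSVs (chrom, start, end, depth)
#' @param track data.frame from [simulate_depth_tracks()].
#' @param path TSV path.
#' @export
write_depth_tsv <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_tsv
#' @export
read_depth_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write synteny blocks as TSV
#'
#' One block per line, Satsuma-like column order:
#' qchrom qstart qend tchrom tstart tend orientation identity support.
#'
#' @param blocks block data.frame.
#' @param path TSV path.
#' @export
write_blocks <- function(blocks, path) {
  cols <- c("qchrom", "qstart", "qend", "tchrom", "tstart", "tend",
            "orientation", "identity", "support")
  miss <- setdiff(cols, names(blocks))
  for (m in miss) blocks[[m]] <- NA
  write.table(blocks[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blocks
#' @export
read_blocks <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a Satsuma2 chained summary file as synteny blocks
#'
#' Maps the whitespace-separated columns of
#' `satsuma_summary.chained.out` onto the package's block layout. Satsuma
#' prints target coordinates first; set `query_first = TRUE` for files
#' already in query-first order.
#'
#' @param path file path.
#' @param query_first whether columns 1-3 are the query side.
#' @return block data.frame (qchrom, qstart, qend, tchrom, tstart, tend,
#'   orientation, identity, support).
#' @export
read_satsuma_chained <- function(path, query_first = FALSE) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 8L) stop("expected >= 8 columns in a Satsuma chained file")
  a <- df[, 1:3]; b <- df[, 4:6]
  if (query_first) { q <- a; t <- b } else { q <- b; t <- a }
  out <- data.frame(qchrom = q[, 1], qstart = as.integer(q[, 2]),
                    qend = as.integer(q[, 3]), tchrom = t[, 1],
                    tstart = as.integer(t[, 2]), tend = as.integer(t[, 3]),
                    orientation = as.character(df[, 8]),
                    identity = as.numeric(df[, 7]),
                    support = NA_integer_, stringsAsFactors = FALSE)
  out$orientation <- ifelse(out$orientation %in% c("+", "-"), out$orientation, "+")
  out
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Standard column order: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore. An optional protein-to-
#' chromosome map adds a `target_chrom` column.
#'
#' @param path tabular file path.
#' @param protein_chrom optional named vector: subject id -> chromosome.
#' @return data.frame of hits.
#' @export
read_blast_outfmt6 <- function(path, protein_chrom = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  if (!is.null(protein_chrom)) df$target_chrom <- unname(protein_chrom[df$sseqid])
  df
}

#' Read a marker placement TSV (marker_id, chrom, start/pos)
#' @param path TSV path.
#' @return data.frame(marker_id, chrom, pos).
#' @export
read_marker_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if ("start" %in% names(df) && !"pos" %in% names(df)) df$pos <- df$start
  df[, c("marker_id", "chrom", "pos")]
}
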