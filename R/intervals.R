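# Nonoverlapping-coverage statistics: project blocks to the query side,
# merge to disjoint intervals, optionally subtract repeat annotations,
# and compute per-target-chromosome coverage fractions. Interval algebra
# is delegated to IRanges (reduce/setdiff); all public coordinates stay
# 0-based half-open.

.to_ir <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)
.from_ir <- function(ir) {
  data.frame(start = as.integer(IRanges::start(ir) - 1L),
             end = as.integer(IRanges::end(ir)))
}

#' Merge block projections into nonoverlapping intervals
#'
#' Projects synteny blocks onto the query side and unions them into
#' disjoint sorted intervals, optionally separately per target chromosome
#' (needed for per-chromosome coverage fractions).
#'
#' @param blocks data.frame with qchrom, qstart, qend (and tchrom when
#'   grouping by target).
#' @param group_by_target union separately per (query, target) pair?
#' @param chrom_lengths optional named lengths; blocks exceeding them
#'   raise an error naming the offender.
#' @return data.frame (qchrom \[, tchrom\], start, end), disjoint and
#'   sorted within each group.
#' @export
merge_nonoverlapping <- function(blocks, group_by_target = TRUE,
                                 chrom_lengths = NULL) {
  if (is.null(blocks) || !nrow(blocks)) {
    out <- data.frame(qchrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
    if (group_by_target) out$tchrom <- character()
    return(out[, if (group_by_target) c("qchrom", "tchrom", "start", "end")
               else c("qchrom", "start", "end")])
  }
  stopifnot(all(blocks$qend > blocks$qstart))
  if (!is.null(chrom_lengths)) {
    bad <- which(blocks$qstart < 0L | blocks$qend > chrom_lengths[blocks$qchrom])
    if (length(bad))
      stop(sprintf("block %d (%s:%d-%d) exceeds chromosome bounds",
                   bad[1L], blocks$qchrom[bad[1L]],
                   blocks$qstart[bad[1L]], blocks$qend[bad[1L]]))
  }
  keys <- if (group_by_target) c("qchrom", "tchrom") else "qchrom"
  sp <- split(blocks, blocks[, keys, drop = FALSE], drop = TRUE, sep = "\r")
  out <- lapply(names(sp), function(nm) {
    b <- sp[[nm]]
    ir <- IRanges::reduce(.to_ir(b$qstart, b$qend))
    cbind(b[rep(1L, length(ir)), keys, drop = FALSE], .from_ir(ir))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  o <- if (group_by_target) order(out$qchrom, out$tchrom, out$start)
       else order(out$qchrom, out$start)
  out[o, , drop = FALSE]
}

#' Subtract repeat intervals from a coverage interval set
#'
#' Trimming (not whole-interval discard) set difference, per chromosome.
#'
#' @param cov data.frame with chromosome column (`qchrom` or `chrom`),
#'   start, end.
#' @param repeats data.frame(chrom, start, end).
#' @return `cov` minus `repeats`, disjoint and sorted; grouping columns
#'   preserved.
#' @export
subtract_repeats <- function(cov, repeats) {
  if (is.null(cov) || !nrow(cov)) return(cov)
  ccol <- if ("qchrom" %in% names(cov)) "qchrom" else "chrom"
  if (is.null(repeats) || !nrow(repeats)) return(cov)
  rcol <- if ("chrom" %in% names(repeats)) "chrom" else "qchrom"
  keys <- intersect(c(ccol, "tchrom"), names(cov))
  sp <- split(cov, cov[, keys, drop = FALSE], drop = TRUE, sep = "\r")
  out <- lapply(sp, function(b) {
    rr <- repeats[repeats[[rcol]] == b[[ccol]][1L], , drop = FALSE]
    ir <- .to_ir(b$start, b$end)
    if (nrow(rr)) ir <- IRanges::setdiff(ir, .to_ir(rr$start, rr$end))
    if (!length(ir)) return(NULL)
    cbind(b[rep(1L, length(ir)), keys, drop = FALSE], .from_ir(ir))
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out))
    return(cov[0L, c(keys, "start", "end"), drop = FALSE])
  rownames(out) <- NULL
  out[order(out[[ccol]], out$start), , drop = FALSE]
}

#' Coverage fraction of an interval set
#'
#' Sum of interval lengths over `denom_length`.
#'
#' @param cov data.frame with start/end (assumed disjoint).
#' @param denom_length denominator in bp; must be > 0.
#' @return fraction in \[0,1\].
#' @export
coverage_fraction <- function(cov, denom_length) {
  if (denom_length <= 0) stop("denom_length must be > 0")
  if (is.null(cov) || !nrow(cov)) return(0)
  sum(cov$end - cov$start) / denom_length
}

#' Per-target-chromosome coverage table for a query
#'
#' For every (query chromosome, target chromosome) pair: base pairs of the
#' query covered by the merged nonoverlapping block projections, and the
#' corresponding fraction. With `repeat_filter = TRUE`, repeats are
#' subtracted from numerator *and* denominator, so the fraction reads
#' "share of the non-repeat query covered" rather than conflating repeat
#' content with homology loss (set `repeat_filter_denominator = FALSE`
#' for numerator-only subtraction).
#'
#' @param blocks synteny blocks.
#' @param query_lengths named vector of query chromosome lengths.
#' @param repeats optional repeat intervals on the query.
#' @param repeat_filter subtract repeats?
#' @param repeat_filter_denominator also shrink the denominator?
#' @param identity_min recorded threshold (metadata column).
#' @return data.frame(qchrom, tchrom, covered_bp, length_bp, fraction,
#'   repeat_filtered, identity_min).
#' @export
coverage_table <- function(blocks, query_lengths, repeats = NULL,
                           repeat_filter = !is.null(repeats),
                           repeat_filter_denominator = TRUE,
                           identity_min = NA_real_) {
  merged <- merge_nonoverlapping(blocks, group_by_target = TRUE,
                                 chrom_lengths = query_lengths)
  if (repeat_filter && !is.null(repeats) && nrow(merged))
    merged <- subtract_repeats(merged, repeats)
  qnames <- names(query_lengths)
  denom <- query_lengths
  if (repeat_filter && !is.null(repeats) && repeat_filter_denominator) {
    rcol <- if ("chrom" %in% names(repeats)) "chrom" else names(repeats)[1L]
    for (qn in qnames) {
      rr <- repeats[repeats[[rcol]] == qn, , drop = FALSE]
      if (nrow(rr)) {
        un <- IRanges::reduce(.to_ir(rr$start, rr$end))
        denom[qn] <- denom[qn] - sum(IRanges::width(un))
      }
    }
  }
  if (!nrow(merged)) {
    return(data.frame(qchrom = character(), tchrom = character(),
                      covered_bp = integer(), length_bp = integer(),
                      fraction = numeric(), repeat_filtered = logical(),
                      identity_min = numeric(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(cbind(covered = merged$end - merged$start),
                          by = list(qchrom = merged$qchrom, tchrom = merged$tchrom),
                          FUN = sum)
  data.frame(qchrom = agg$qchrom, tchrom = agg$tchrom,
             covered_bp = as.integer(agg$covered),
             length_bp = as.integer(denom[agg$qchrom]),
             fraction = agg$covered / pmax(denom[agg$qchrom], 1L),
             repeat_filtered = isTRUE(repeat_filter) && !is.null(repeats),
             identity_min = identity_min, stringsAsFactors = FALSE)
}

#' Rank target chromosomes by coverage of a query chromosome
#'
#' Descending by fraction; exact ties break lexicographically on the
#' target name and are flagged.
#'
#' @param tab a [coverage_table()].
#' @param query_chrom query chromosome to rank targets for.
#' @param all_targets optional vector of target names to include with
#'   zero coverage if absent from the table.
#' @return data.frame(target, fraction, rank, tie).
#' @export
rank_targets <- function(tab, query_chrom, all_targets = NULL) {
  rows <- tab[tab$qchrom == query_chrom, , drop = FALSE]
  fr <- setNames(rows$fraction, rows$tchrom)
  if (!is.null(all_targets)) {
    missing <- setdiff(all_targets, names(fr))
    fr <- c(fr, setNames(rep(0, length(missing)), missing))
  }
  if (!length(fr)) stop("no coverage rows for query chromosome ", query_chrom)
  o <- order(-fr, names(fr))
  fr <- fr[o]
  data.frame(target = names(fr), fraction = unname(fr),
             rank = seq_along(fr),
             tie = duplicated(fr) | duplicated(fr, fromLast = TRUE),
             stringsAsFactors = FALSE)
}
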