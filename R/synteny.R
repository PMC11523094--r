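# Simplified whole-genome synteny-block detector: map fixed-size query
# windows onto a target genome by shared-k-mer seeding and ungapped
# identity, keep windows above an identity floor, then retain only
# matches that are concordant at large scale, and finally re-scan the
# neighbourhood of retained blocks ("battleship" refinement).

#' Detector configuration
#'
#' @param window query window size (bp).
#' @param step distance between window starts (bp).
#' @param seed_k k-mer length used for seeding; must be < `window`.
#' @param seed_stride spacing of probed k-mers inside a window.
#' @param identity_min minimum ungapped identity for a window match (the
#'   classic 45% floor of whole-genome window mapping).
#' @param identity_strict optional stricter threshold (e.g. 0.70) recorded
#'   alongside results; rerun with `identity_min = identity_strict` to
#'   apply it.
#' @param max_matches_per_window matches retained per window, best-first.
#' @param max_seed_hits seed k-mers occurring more often than this in the
#'   target are ignored (repeat-seed cutoff).
#' @param mode `"all_matches"` keeps up to `max_matches_per_window`
#'   (secondary/tertiary matches reported; use for a single-chromosome
#'   query such as a W); `"primary_only"` keeps each window's single best
#'   match (use when whole assemblies are the query).
#' @param chain_radius neighbourhood (bp, both in query and target) within
#'   which matches must support each other.
#' @param min_chain_support minimum number of concordant neighbours for a
#'   match to survive chaining.
#' @return a `scan_config` list.
#' @export
scan_config <- function(window = 1000L, step = 500L, seed_k = 16L,
                        seed_stride = 4L, identity_min = 0.45,
                        identity_strict = NULL,
                        max_matches_per_window = 5L,
                        max_seed_hits = 100L,
                        mode = c("all_matches", "primary_only"),
                        chain_radius = 20000L, min_chain_support = 2L) {
  mode <- match.arg(mode)
  cfg <- list(window = as.integer(window), step = as.integer(step),
              seed_k = as.integer(seed_k), seed_stride = as.integer(seed_stride),
              identity_min = identity_min, identity_strict = identity_strict,
              max_matches_per_window = as.integer(max_matches_per_window),
              max_seed_hits = as.integer(max_seed_hits), mode = mode,
              chain_radius = as.integer(chain_radius),
              min_chain_support = as.integer(min_chain_support))
  if (cfg$seed_k >= cfg$window)
    config_error("seed_k must be smaller than the window size")
  if (cfg$identity_min <= 0 || cfg$identity_min > 1)
    config_error("identity_min must lie in (0, 1]")
  if (!is.null(cfg$identity_strict) &&
      (cfg$identity_strict < cfg$identity_min || cfg$identity_strict > 1))
    config_error("need identity_min <= identity_strict <= 1")
  class(cfg) <- "scan_config"
  cfg
}

as_seqset <- function(x) {
  if (inherits(x, "sim_genome")) return(x$seq)
  if (is.list(x) && !is.null(x$seq)) return(x$seq)
  if (inherits(x, "DNAStringSet")) return(setNames(as.character(x), names(x)))
  if (is.character(x)) {
    if (length(x) && is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("cannot interpret input as a chromosome set")
}

empty_matches <- function() {
  data.frame(qchrom = character(), qstart = integer(), qend = integer(),
             tchrom = character(), tstart = integer(), tend = integer(),
             orientation = character(), identity = numeric(),
             support = integer(), stringsAsFactors = FALSE)
}

#' Build a k-mer index of a target chromosome set
#'
#' Positions of every k-mer (N-free, below the repeat-seed occurrence
#' cutoff), keyed for fast joins. Reusable across scans against the same
#' target.
#'
#' @param target chromosome set (named character vector / `sim_genome`).
#' @param k k-mer length.
#' @param max_seed_hits occurrence cutoff.
#' @return keyed data.table(kmer, tchrom, tpos).
#' @export
build_kmer_index <- function(target, k, max_seed_hits = 100L) {
  ts <- as_seqset(target)
  parts <- lapply(names(ts), function(cn) {
    L <- nchar(ts[[cn]])
    if (L < k) return(NULL)
    pos <- 0:(L - k)
    data.table(kmer = substring(ts[[cn]], pos + 1L, pos + k),
               tchrom = cn, tpos = pos)
  })
  idx <- data.table::rbindlist(parts)
  if (!nrow(idx)) return(idx)
  idx <- idx[!grepl("N", kmer, fixed = TRUE)]
  idx[, `:=`(nocc = .N), by = kmer]
  idx <- idx[idx$nocc <= max_seed_hits][, `:=`(nocc = NULL)]
  data.table::setkey(idx, kmer)
  idx
}

window_starts <- function(L, window, step) {
  w <- min(window, L)
  unique(c(seq.int(0L, max(L - w, 0L), by = step), max(L - w, 0L)))
}

#' Map query windows onto a target genome
#'
#' Every query window (both strands) is seeded by shared k-mers, anchored
#' at its best-supported diagonal, scored by ungapped identity
#' (matching bases / window length; Ns never match), and reported if the
#' identity reaches `identity_min`. Windows with more than 50% N are
#' skipped. Diagonal ties break towards the leftmost target position.
#'
#' @param query,target chromosome sets (named character vectors,
#'   `sim_genome`s or DNAStringSets).
#' @param cfg a [scan_config()].
#' @param index optional prebuilt [build_kmer_index()] of `target`.
#' @return data.frame of raw matches (qchrom, qstart, qend, tchrom,
#'   tstart, tend, orientation, identity); 0-based half-open coordinates.
#' @export
scan_windows <- function(query, target, cfg = scan_config(), index = NULL) {
  qs <- as_seqset(query)
  ts <- as_seqset(target)
  if (!length(qs) || !length(ts) || all(nchar(ts) == 0L) || all(nchar(qs) == 0L))
    return(empty_matches()[, 1:8])
  if (cfg$seed_k >= cfg$window) config_error("seed_k must be < window")
  if (is.null(index)) index <- build_kmer_index(ts, cfg$seed_k, cfg$max_seed_hits)
  tlens <- vapply(ts, nchar, integer(1))
  out <- lapply(names(qs), function(qn)
    scan_one_chrom(qn, qs[[qn]], ts, tlens, index, cfg))
  res <- data.table::rbindlist(out)
  if (!nrow(res)) return(empty_matches()[, 1:8])
  as.data.frame(res)
}

scan_one_chrom <- function(qname, qseq, ts, tlens, index, cfg) {
  L <- nchar(qseq)
  w <- min(cfg$window, L)
  k <- cfg$seed_k
  if (L < k) return(NULL)
  wstarts <- window_starts(L, cfg$window, cfg$step)
  # skip windows that are mostly N
  isN <- cumsum(c(0L, utf8ToInt(qseq) == 78L))
  nfrac <- (isN[wstarts + w + 1L] - isN[wstarts + 1L]) / w
  wstarts <- wstarts[nfrac <= 0.5]
  if (!length(wstarts)) return(NULL)
  offs <- seq.int(0L, w - k, by = cfg$seed_stride)
  qrc <- revcomp(qseq)

  probe <- function(seqstr, strand) {
    ws0 <- if (strand == "+") wstarts else L - wstarts - w
    grid <- data.table(ws = rep(wstarts, each = length(offs)),
                       ps = rep(ws0, each = length(offs)) + offs,
                       qoff = rep(offs, times = length(wstarts)))
    grid[, `:=`(kmer = substring(seqstr, ps + 1L, ps + k))]
    cand <- index[grid, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(cand)) return(NULL)
    cand[, `:=`(diag_ = tpos - qoff, strand = strand)]
    cand[, .(ws, tchrom, strand, diag_)]
  }
  cand <- data.table::rbindlist(Filter(Negate(is.null),
                                       list(probe(qseq, "+"), probe(qrc, "-"))))
  if (is.null(cand) || !nrow(cand)) return(NULL)
  votes <- cand[, .(votes = .N), by = .(ws, tchrom, strand, diag_)]
  data.table::setorder(votes, ws, -votes, tchrom, diag_)
  ncand <- max(8L, 3L * cfg$max_matches_per_window)
  votes <- votes[, head(.SD, ncand), by = ws]

  qraw_f <- charToRaw(qseq)
  qraw_r <- charToRaw(qrc)
  rows <- vector("list", nrow(votes))
  for (i in seq_len(nrow(votes))) {
    vws <- votes$ws[i]; tcn <- votes$tchrom[i]
    strand <- votes$strand[i]; ts0 <- votes$diag_[i]
    tlen <- tlens[[tcn]]
    a <- max(ts0, 0L); b <- min(ts0 + w, tlen)
    if (b - a < k) next
    # oriented query window bytes aligned to the clipped target segment
    if (strand == "+") {
      qa <- vws + (a - ts0)
      qb <- qa + (b - a)
      qr <- qraw_f[(qa + 1L):qb]
    } else {
      rs <- L - vws - w          # window start within the revcomp query
      qa <- rs + (a - ts0)
      qb <- qa + (b - a)
      qr <- qraw_r[(qa + 1L):qb]
    }
    tr <- charToRaw(substr(ts[[tcn]], a + 1L, b))
    ident <- .match_count(qr, tr) / w
    if (ident < cfg$identity_min) next
    rows[[i]] <- list(qchrom = qname, qstart = vws, qend = vws + w,
                      tchrom = tcn, tstart = a, tend = b,
                      orientation = strand, identity = ident)
  }
  res <- data.table::rbindlist(Filter(Negate(is.null), rows))
  if (!nrow(res)) return(NULL)
  keep_n <- if (cfg$mode == "primary_only") 1L else cfg$max_matches_per_window
  data.table::setorder(res, qstart, -identity, tchrom, tstart)
  res[, head(.SD, keep_n), by = qstart][
    , .(qchrom, qstart, qend, tchrom, tstart, tend, orientation, identity)]
}

#' Filter window matches for large-scale concordance
#'
#' A match survives iff at least `min_chain_support` other matches lie on
#' the same target chromosome, same orientation, within `chain_radius` of
#' it in both query and target, with a diagonal ordering consistent with
#' the orientation. Isolated (typically repeat-driven) hits are thereby
#' removed. Survivors carry their neighbour count as `support`.
#'
#' @param matches raw matches from [scan_windows()].
#' @param cfg a [scan_config()].
#' @return data.frame of synteny blocks (matches + `support`).
#' @export
chain_concordant <- function(matches, cfg = scan_config()) {
  if (is.null(matches) || !nrow(matches)) return(empty_matches())
  dt <- data.table::as.data.table(matches)
  dt[, `:=`(support = 0L)]
  R <- cfg$chain_radius
  grp <- dt[, .(idx = list(.I)), by = .(qchrom, tchrom, orientation)]
  for (g in grp$idx) {
    n <- length(g)
    if (n < 2L) next
    qm <- (dt$qstart[g] + dt$qend[g]) / 2
    tm <- (dt$tstart[g] + dt$tend[g]) / 2
    ori <- dt$orientation[g][1L]
    o <- order(qm)
    qs <- qm[o]; tms <- tm[o]
    lo <- findInterval(qs - R, qs, rightmost.closed = FALSE) + 1L
    hi <- findInterval(qs + R, qs)
    supp <- integer(n)
    for (i in seq_len(n)) {
      j <- lo[i]:hi[i]
      dq <- qs[j] - qs[i]
      dtm <- tms[j] - tms[i]
      ok <- abs(dtm) <= R & dq != 0 &
        (if (ori == "+") dq * dtm > 0 else dq * dtm < 0)
      supp[i] <- sum(ok)
    }
    dt$support[g[o]] <- supp
  }
  out <- dt[support >= cfg$min_chain_support]
  as.data.frame(out)
}

#' Battleship refinement around retained blocks
#'
#' Re-scans half-step-offset query windows in the flanks of every
#' retained block against the local target neighbourhood only (same
#' diagonal, within `chain_radius`), adding any window that now passes
#' the identity floor. Runs to a fixed point, so a second application
#' changes nothing. New matches inherit the support of the block that
#' recruited them.
#'
#' @param query,target chromosome sets.
#' @param blocks blocks from [chain_concordant()].
#' @param cfg a [scan_config()].
#' @return superset of `blocks`.
#' @export
battleship_refine <- function(query, target, blocks, cfg = scan_config()) {
  if (is.null(blocks) || !nrow(blocks)) return(empty_matches())
  qs <- as_seqset(query)
  ts <- as_seqset(target)
  qlens <- vapply(qs, nchar, integer(1))
  tlens <- vapply(ts, nchar, integer(1))
  R <- cfg$chain_radius
  step2 <- max(1L, cfg$step %/% 2L)
  cur <- data.table::as.data.table(blocks)
  if (!"support" %in% names(cur)) cur[, `:=`(support = NA_integer_)]
  for (iter in seq_len(8L)) {
    # blocks on the same diagonal pool their flanks: along a diagonal the
    # per-block query and target neighbourhood constraints coincide
    cur[, `:=`(dkey = ifelse(orientation == "+", tstart - qstart, tstart + qstart))]
    grp <- cur[, .(lo = min(qstart) - R, hi = max(qend) + R,
                   support = max(support)),
               by = .(qchrom, tchrom, orientation, dkey)]
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (key in cur[, paste(qchrom, qstart, tchrom, tstart, orientation)])
      assign(key, TRUE, envir = seen)
    added <- list()
    for (i in seq_len(nrow(grp))) {
      g <- grp[i]
      L <- qlens[[g$qchrom]]
      w <- min(cfg$window, L)
      tlen <- tlens[[g$tchrom]]
      lo <- max(0L, g$lo)
      hi <- min(L - w, g$hi)
      if (hi < lo) next
      qseq <- qs[[g$qchrom]]
      for (vws in seq.int(lo, hi, by = step2)) {
        ts0 <- if (g$orientation == "+") g$dkey + vws else g$dkey - vws
        a <- max(ts0, 0L); bb <- min(ts0 + w, tlen)
        if (bb - a < cfg$seed_k) next
        key <- paste(g$qchrom, vws, g$tchrom, a, g$orientation)
        if (!is.null(seen[[key]])) next
        oriented <- if (g$orientation == "+") substr(qseq, vws + 1L, vws + w)
                    else revcomp(substr(qseq, vws + 1L, vws + w))
        qa <- a - ts0
        qr <- charToRaw(oriented)[(qa + 1L):(qa + (bb - a))]
        tr <- charToRaw(substr(ts[[g$tchrom]], a + 1L, bb))
        ident <- .match_count(qr, tr) / w
        if (ident < cfg$identity_min) next
        assign(key, TRUE, envir = seen)
        added[[length(added) + 1L]] <- data.table(
          qchrom = g$qchrom, qstart = vws, qend = vws + w,
          tchrom = g$tchrom, tstart = a, tend = bb,
          orientation = g$orientation, identity = ident, support = g$support)
      }
    }
    if (!length(added)) break
    cur <- rbind(cur[, !"dkey"], data.table::rbindlist(added), fill = TRUE)
  }
  if ("dkey" %in% names(cur)) cur[, `:=`(dkey = NULL)]
  data.table::setorder(cur, qchrom, qstart, tchrom, tstart)
  as.data.frame(unique(cur))
}

#' Verify blocks against the non-repeat part of the query
#'
#' A window that straddles a repeat/unique boundary can clear the identity
#' floor on its repeat half alone, so its unique flank would leak into
#' repeat-filtered coverage without being homologous. This filter
#' recomputes each block's ungapped identity restricted to query positions
#' outside the repeat annotation and keeps only blocks whose non-repeat
#' bases independently reach `cfg$identity_min`. Blocks with fewer than
#' `min_bases` non-repeat positions (or with clipped alignments) carry no
#' unique-sequence evidence and are dropped.
#'
#' @param blocks synteny blocks.
#' @param query,target chromosome sets.
#' @param repeats query-side repeat intervals (chrom, start, end).
#' @param cfg a [scan_config()].
#' @param min_bases minimum non-repeat bases to judge a block.
#' @return the verified subset of `blocks` with a `nonrepeat_identity`
#'   column.
#' @export
verify_nonrepeat_blocks <- function(blocks, query, target, repeats,
                                    cfg = scan_config(), min_bases = 100L) {
  if (is.null(blocks) || !nrow(blocks)) return(blocks)
  if (is.null(repeats) || !nrow(repeats)) {
    blocks$nonrepeat_identity <- blocks$identity
    return(blocks)
  }
  qs <- as_seqset(query)
  ts <- as_seqset(target)
  rcol <- if ("chrom" %in% names(repeats)) "chrom" else names(repeats)[1L]
  keep <- logical(nrow(blocks))
  nrid <- rep(NA_real_, nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    w <- b$qend - b$qstart
    if (b$tend - b$tstart != w) next # clipped alignment: no clean mapping
    qwin <- substr(qs[[b$qchrom]], b$qstart + 1L, b$qend)
    oriented <- if (b$orientation == "+") qwin else revcomp(qwin)
    qr <- charToRaw(oriented)
    tr <- charToRaw(substr(ts[[b$tchrom]], b$tstart + 1L, b$tend))
    m <- qr == tr & qr != as.raw(78L)
    if (b$orientation == "-") m <- rev(m) # back to query-forward positions
    rr <- repeats[repeats[[rcol]] == b$qchrom, , drop = FALSE]
    mask <- rep(FALSE, w)
    if (nrow(rr)) {
      s <- pmax(rr$start, b$qstart) - b$qstart
      e <- pmin(rr$end, b$qend) - b$qstart
      for (j in which(e > s)) mask[(s[j] + 1L):e[j]] <- TRUE
    }
    nr <- sum(!mask)
    if (nr < min_bases) next
    ident <- sum(m[!mask]) / nr
    nrid[i] <- ident
    keep[i] <- ident >= cfg$identity_min
  }
  out <- blocks[keep, , drop = FALSE]
  out$nonrepeat_identity <- nrid[keep]
  rownames(out) <- NULL
  out
}

#' Full synteny-block search: scan, chain, refine
#'
#' @param query,target chromosome sets.
#' @param cfg a [scan_config()].
#' @param refine apply [battleship_refine()]?
#' @param index optional prebuilt target k-mer index.
#' @return data.frame of synteny blocks.
#' @export
find_synteny_blocks <- function(query, target, cfg = scan_config(),
                                refine = TRUE, index = NULL) {
  m <- scan_windows(query, target, cfg, index = index)
  b <- chain_concordant(m, cfg)
  if (refine) b <- battleship_refine(query, target, b, cfg)
  b
}
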