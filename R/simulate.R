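# Synthetic clade simulator. A `sim_genome` is a list with:
#   seq       named character vector (chromosome name -> sequence)
#   class     named character vector in {autosome, Z, W}
#   genes     data.frame(chrom, start, end, strand, family, gene_id)  [0-based half-open]
#   markers   data.frame(marker_id, chrom, pos)                       [0-based points]
#   repeats   data.frame(chrom, start, end, family)                   [0-based half-open]
#   conserved data.frame(chrom, start, end)   slow-evolving tracts hosting the genes
#   w_origin  ancestral origin of the W ("Z", "B", or an autosome name)
#   fusion    NULL or c("Z", <autosome>) for a neo-Z

new_sim_genome <- function(seq, class, genes, markers, repeats, conserved,
                           w_origin = NA_character_, fusion = NULL) {
  g <- list(seq = seq, class = class, genes = genes, markers = markers,
            repeats = repeats, conserved = conserved,
            w_origin = w_origin, fusion = fusion)
  class(g) <- "sim_genome"
  g
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d chromosomes (%s), %d genes, %d markers, %d repeat copies\n",
              length(x$seq), paste(names(which(x$class != "autosome")), collapse = ","),
              nrow(x$genes), nrow(x$markers), nrow(x$repeats)))
  invisible(x)
}

#' Chromosome lengths of a simulated genome
#' @param gnm a `sim_genome`.
#' @return named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(gnm) vapply(gnm$seq, nchar, integer(1))

empty_genes <- function() data.frame(chrom = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     family = character(), gene_id = character(),
                                     stringsAsFactors = FALSE)
empty_repeats <- function() data.frame(chrom = character(), start = integer(),
                                       end = integer(), family = character(),
                                       stringsAsFactors = FALSE)
empty_markers <- function() data.frame(marker_id = character(), chrom = character(),
                                       pos = integer(), stringsAsFactors = FALSE)
empty_conserved <- function() data.frame(chrom = character(), start = integer(),
                                         end = integer(), stringsAsFactors = FALSE)

#' Simulate the ancestral genome of a clade
#'
#' Builds the root genome: `n_autosomes` autosomes plus a Z chromosome,
#' with i.i.d. nucleotide sequences at GC `gc_base` (plus per-chromosome
#' jitter), slow-evolving conserved tracts covering about `cons_frac` of
#' each chromosome, non-overlapping protein-coding gene tracts embedded
#' inside those conserved tracts, and single-copy marker anchors. Lengths
#' are jittered uniformly by up to `length_jitter` around `chrom_length`.
#'
#' @param cfg a [scenario_config()].
#' @return a `sim_genome`.
#' @export
simulate_ancestor <- function(cfg) {
  validate_scenario_config(cfg)
  set.seed(derive_seed(cfg$seed, 0L))
  chroms <- c(paste0("chr", seq_len(cfg$n_autosomes)), "Z")
  cls <- setNames(c(rep("autosome", cfg$n_autosomes), "Z"), chroms)
  lens <- as.integer(round(cfg$chrom_length *
                             runif(length(chroms), 1 - cfg$length_jitter, 1 + cfg$length_jitter)))
  names(lens) <- chroms
  gcs <- cfg$gc_base + runif(length(chroms), -cfg$gc_jitter, cfg$gc_jitter)
  seqs <- setNames(mapply(random_dna, lens, gcs, SIMPLIFY = TRUE), chroms)

  feat <- lapply(chroms, function(cn) place_conserved_and_genes(cn, lens[[cn]], cfg))
  conserved <- do.call(rbind, lapply(feat, `[[`, "conserved"))
  genes <- do.call(rbind, lapply(feat, `[[`, "genes"))
  # markers round-robin across chromosomes, outside gene tracts
  mchrom <- rep(chroms, length.out = cfg$n_markers)
  markers <- do.call(rbind, lapply(chroms, function(cn) {
    ids <- which(mchrom == cn)
    if (!length(ids)) return(empty_markers())
    blocked <- genes[genes$chrom == cn, c("start", "end")]
    pos <- sample_free_points(lens[[cn]], length(ids), blocked)
    data.frame(marker_id = sprintf("busco%04d", ids), chrom = cn, pos = pos,
               stringsAsFactors = FALSE)
  }))
  new_sim_genome(seqs, cls, genes, markers, empty_repeats(), conserved)
}

# Conserved tracts evenly spaced with random offsets; genes distributed
# round-robin over the tracts at within-tract slots.
place_conserved_and_genes <- function(chrom, len, cfg, family_prefix = chrom,
                                      gene_prefix = chrom) {
  tl <- min(cfg$cons_tract_len, len %/% 2L)
  n_cons <- max(1L, as.integer(round(cfg$cons_frac * len / tl)))
  slot <- len %/% n_cons
  if (slot <= tl + 2L) { n_cons <- max(1L, len %/% (2L * tl)); slot <- len %/% n_cons }
  off <- sample.int(max(slot - tl, 1L), n_cons, replace = TRUE) - 1L
  cstart <- (seq_len(n_cons) - 1L) * slot + off
  conserved <- data.frame(chrom = chrom, start = as.integer(cstart),
                          end = as.integer(cstart + tl), stringsAsFactors = FALSE)
  ng <- cfg$n_proteins_per_chrom
  genes <- empty_genes()
  if (ng > 0L) {
    per_tract <- ceiling(ng / n_cons)
    gslot <- tl %/% per_tract
    if (gslot <= cfg$gene_length)
      stop("conserved tracts too small for the requested gene tracts")
    tract_idx <- rep(seq_len(n_cons), each = per_tract)[seq_len(ng)]
    within <- (seq_len(ng) - 1L) %% per_tract
    gstart <- conserved$start[tract_idx] + within * gslot +
      sample.int(gslot - cfg$gene_length, ng, replace = TRUE) - 1L
    genes <- data.frame(chrom = chrom, start = as.integer(gstart),
                        end = as.integer(gstart + cfg$gene_length),
                        strand = sample(c("+", "-"), ng, replace = TRUE),
                        family = sprintf("%s_fam%03d", family_prefix, seq_len(ng)),
                        gene_id = sprintf("%s_g%03d", gene_prefix, seq_len(ng)),
                        stringsAsFactors = FALSE)
  }
  list(conserved = conserved, genes = genes)
}

# sample n integer points in [0, len] avoiding the open interiors of blocked
sample_free_points <- function(len, n, blocked = NULL, inclusive_end = FALSE) {
  top <- if (inclusive_end) len else len - 1L
  out <- integer(0)
  guard <- 0L
  while (length(out) < n && guard < 200L) {
    guard <- guard + 1L
    p <- sample.int(top + 1L, n, replace = TRUE) - 1L
    if (!is.null(blocked) && nrow(blocked)) {
      bad <- vapply(p, function(x) any(x > blocked$start & x < blocked$end), logical(1))
      p <- p[!bad]
    }
    out <- c(out, p)
  }
  sort(out[seq_len(n)])
}

# Heterogeneous-rate Jukes-Cantor: conserved tracts evolve at
# d * cons_rate_mult, the rest at d.
evolve_het <- function(x, d, cons_rows, cons_mult) {
  if (d <= 0) return(x)
  v <- utf8ToInt(x)
  L <- length(v)
  slow <- logical(L)
  if (!is.null(cons_rows) && nrow(cons_rows)) {
    for (i in seq_len(nrow(cons_rows))) {
      s <- max(cons_rows$start[i], 0L) + 1L
      e <- min(cons_rows$end[i], L)
      if (e >= s) slow[s:e] <- TRUE
    }
  }
  pstay <- ifelse(slow, 0.25 + 0.75 * exp(-4 * d * cons_mult / 3),
                  0.25 + 0.75 * exp(-4 * d / 3))
  hit <- which(runif(L) > pstay & v != 78L)
  if (length(hit)) {
    codes <- utf8ToInt("ACGT")
    cur <- match(v[hit], codes)
    r <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- codes[((cur - 1L + r) %% 4L) + 1L]
  }
  intToUtf8(v)
}

# ---- shared repeat library ------------------------------------------------

make_repeat_library <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1L))
  lens <- as.integer(round(runif(cfg$repeat_library_size, 300, 3000)))
  seqs <- vapply(lens, random_dna, character(1), gc = cfg$gc_base)
  data.frame(family = sprintf("rfam%02d", seq_along(lens)),
             length = lens, seq = seqs, stringsAsFactors = FALSE)
}

# ---- coordinate bookkeeping ----------------------------------------------

# Insert `pieces` (character vector) at 0-based positions `positions`
# (sorted, outside gene/repeat/conserved interiors). Shifts all features;
# returns the genome plus the new-coordinate intervals of the pieces.
insert_into_chrom <- function(gnm, chrom, pieces, positions) {
  stopifnot(length(pieces) == length(positions), !is.unsorted(positions))
  if (!length(pieces)) return(list(gnm = gnm, intervals = NULL))
  seq <- gnm$seq[[chrom]]
  L <- nchar(seq)
  plen <- nchar(pieces)
  csum <- cumsum(plen)
  old_parts <- substring(seq, c(0L, positions) + 1L, c(positions, L))
  n <- length(pieces)
  woven <- character(2L * n + 1L)
  woven[seq(1L, 2L * n + 1L, by = 2L)] <- old_parts
  woven[seq(2L, 2L * n, by = 2L)] <- pieces
  gnm$seq[[chrom]] <- paste(woven, collapse = "")

  shift_at <- function(x, closed) {
    vapply(x, function(p) {
      k <- if (closed) sum(positions <= p) else sum(positions < p)
      p + if (k > 0L) csum[k] else 0L
    }, numeric(1))
  }
  shift_intervals <- function(df) {
    sel <- df$chrom == chrom
    if (any(sel)) {
      df$start[sel] <- as.integer(shift_at(df$start[sel], TRUE))
      df$end[sel] <- as.integer(shift_at(df$end[sel], FALSE))
    }
    df
  }
  gnm$genes <- shift_intervals(gnm$genes)
  gnm$repeats <- shift_intervals(gnm$repeats)
  gnm$conserved <- shift_intervals(gnm$conserved)
  sel <- gnm$markers$chrom == chrom
  if (any(sel)) gnm$markers$pos[sel] <- as.integer(shift_at(gnm$markers$pos[sel], TRUE))
  new_start <- as.integer(positions + c(0L, csum[-n]))
  list(gnm = gnm,
       intervals = data.frame(chrom = chrom, start = new_start,
                              end = as.integer(new_start + plen),
                              stringsAsFactors = FALSE))
}

# Top up one chromosome's repeat fraction to `target` (fraction of the
# final, post-insertion length) by inserting mutated library copies at
# uniform positions outside genes, conserved tracts and existing repeats
# (transposable elements persist where selection tolerates them).
insert_repeats_chrom <- function(gnm, chrom, target, lib, copy_div) {
  L <- nchar(gnm$seq[[chrom]])
  sel <- gnm$repeats$chrom == chrom
  rep_bp <- if (any(sel)) sum(gnm$repeats$end[sel] - gnm$repeats$start[sel]) else 0L
  need <- (target * L - rep_bp) / (1 - target)
  if (need < 50) return(gnm)
  fams <- integer(0); copies <- character(0); tot <- 0
  while (tot < need) {
    f <- sample.int(nrow(lib), 1L)
    cp <- evolve_jc(lib$seq[f], runif(1, 0, copy_div))
    if (tot + nchar(cp) > need) cp <- substr(cp, 1L, max(50L, ceiling(need - tot)))
    fams <- c(fams, f); copies <- c(copies, cp); tot <- tot + nchar(cp)
  }
  blocked <- rbind(gnm$genes[gnm$genes$chrom == chrom, c("start", "end")],
                   gnm$conserved[gnm$conserved$chrom == chrom, c("start", "end")],
                   gnm$repeats[gnm$repeats$chrom == chrom, c("start", "end")])
  pos <- sample_free_points(L, length(copies), blocked, inclusive_end = TRUE)
  o <- order(pos)
  ins <- insert_into_chrom(gnm, chrom, copies[o], pos[o])
  gnm <- ins$gnm
  ins$intervals$family <- lib$family[fams[o]]
  gnm$repeats <- rbind(gnm$repeats, ins$intervals)
  gnm
}

top_up_repeats <- function(gnm, cfg, lib, chroms = names(gnm$seq)) {
  for (cn in chroms) {
    target <- if (gnm$class[[cn]] == "W") cfg$repeat_frac_W else cfg$repeat_frac_autosome
    gnm <- insert_repeats_chrom(gnm, cn, target, lib, cfg$repeat_copy_divergence)
  }
  gnm
}

# split intervals of df (start/end cols) at the given cut positions
split_intervals_at <- function(df, cuts) {
  if (!nrow(df)) return(df)
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- df$end[i]
    inner <- sort(unique(cuts[cuts > s & cuts < e]))
    bounds <- c(s, inner, e)
    rows <- df[rep(i, length(bounds) - 1L), , drop = FALSE]
    rows$start <- bounds[-length(bounds)]
    rows$end <- bounds[-1L]
    out[[i]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Reverse-complement the segment [s, e) of a chromosome, reflecting genes
# (fully inside, guaranteed by the caller), markers and repeat/conserved
# pieces (which may be split at the breakpoints).
invert_segment <- function(gnm, chrom, s, e) {
  seq <- gnm$seq[[chrom]]
  gnm$seq[[chrom]] <- paste0(substr(seq, 1L, s),
                             revcomp(substr(seq, s + 1L, e)),
                             substr(seq, e + 1L, nchar(seq)))
  reflect <- function(st, en) list(start = s + e - en, end = s + e - st)
  sel <- which(gnm$genes$chrom == chrom & gnm$genes$start >= s & gnm$genes$end <= e)
  if (length(sel)) {
    r <- reflect(gnm$genes$start[sel], gnm$genes$end[sel])
    gnm$genes$start[sel] <- as.integer(r$start)
    gnm$genes$end[sel] <- as.integer(r$end)
    gnm$genes$strand[sel] <- ifelse(gnm$genes$strand[sel] == "+", "-", "+")
  }
  sel <- which(gnm$markers$chrom == chrom & gnm$markers$pos >= s & gnm$markers$pos < e)
  if (length(sel)) gnm$markers$pos[sel] <- as.integer(s + e - 1L - gnm$markers$pos[sel])
  flip_split <- function(df) {
    dsel <- df$chrom == chrom
    if (!any(dsel)) return(df)
    dd <- split_intervals_at(df[dsel, , drop = FALSE], c(s, e))
    inside <- dd$start >= s & dd$end <= e
    if (any(inside)) {
      r <- reflect(dd$start[inside], dd$end[inside])
      dd$start[inside] <- as.integer(r$start)
      dd$end[inside] <- as.integer(r$end)
    }
    rbind(df[!dsel, , drop = FALSE], dd)
  }
  gnm$repeats <- flip_split(gnm$repeats)
  gnm$conserved <- flip_split(gnm$conserved)
  gnm
}

# One random inversion on a random chromosome; breakpoints avoid splitting
# gene tracts (resampled; inversion skipped if no clean placement found).
apply_random_inversion <- function(gnm, cfg) {
  cn <- sample(names(gnm$seq), 1L)
  L <- nchar(gnm$seq[[cn]])
  genes <- gnm$genes[gnm$genes$chrom == cn, , drop = FALSE]
  for (try in seq_len(25L)) {
    len <- as.integer(round(L * runif(1, 0.01, 0.20)))
    if (len < 2L) next
    s <- sample.int(L - len + 1L, 1L) - 1L
    e <- s + len
    splits <- nrow(genes) && any((genes$start < s & genes$end > s) |
                                   (genes$start < e & genes$end > e))
    if (!splits) return(invert_segment(gnm, cn, s, e))
  }
  gnm
}

# Swap two equal-length segments between the Z-part [0, mid) and the
# autosome-part [mid, L) of a neo-Z: a post-fusion translocation.
swap_segments_across <- function(gnm, chrom, mid) {
  L <- nchar(gnm$seq[[chrom]])
  genes <- gnm$genes[gnm$genes$chrom == chrom, , drop = FALSE]
  for (try in seq_len(25L)) {
    len <- as.integer(round(min(mid, L - mid) * runif(1, 0.05, 0.20)))
    if (len < 2L || len >= mid || len >= L - mid) next
    s1 <- sample.int(mid - len, 1L) - 1L
    s2 <- mid + sample.int(L - mid - len, 1L) - 1L
    cuts <- c(s1, s1 + len, s2, s2 + len)
    splits <- nrow(genes) && any(vapply(cuts, function(p)
      any(genes$start < p & genes$end > p), logical(1)))
    if (splits) next
    seq <- gnm$seq[[chrom]]
    seg1 <- substr(seq, s1 + 1L, s1 + len)
    seg2 <- substr(seq, s2 + 1L, s2 + len)
    gnm$seq[[chrom]] <- paste0(substr(seq, 1L, s1), seg2,
                               substr(seq, s1 + len + 1L, s2), seg1,
                               substr(seq, s2 + len + 1L, L))
    delta <- s2 - s1
    shift_df <- function(df, scol, ecol = NULL) {
      if (!nrow(df)) return(df)
      if (!is.null(ecol)) df <- split_intervals_at(df, cuts)
      ref <- df[[scol]]
      in1 <- ref >= s1 & ref < s1 + len
      in2 <- ref >= s2 & ref < s2 + len
      df[[scol]][in1] <- df[[scol]][in1] + delta
      df[[scol]][in2] <- df[[scol]][in2] - delta
      if (!is.null(ecol)) {
        df[[ecol]][in1] <- df[[ecol]][in1] + delta
        df[[ecol]][in2] <- df[[ecol]][in2] - delta
      }
      df
    }
    bych <- function(df, scol, ecol = NULL) {
      dsel <- df$chrom == chrom
      if (!any(dsel)) return(df)
      rbind(df[!dsel, , drop = FALSE], shift_df(df[dsel, , drop = FALSE], scol, ecol))
    }
    gnm$genes <- bych(gnm$genes, "start", "end")
    gnm$markers <- bych(gnm$markers, "pos")
    gnm$repeats <- bych(gnm$repeats, "start", "end")
    gnm$conserved <- bych(gnm$conserved, "start", "end")
    return(gnm)
  }
  gnm
}

# ---- W derivation ---------------------------------------------------------

#' Derive a W chromosome under a given origin hypothesis
#'
#' Adds a W chromosome to `genome` according to `cfg$hypothesis`:
#' * `AUTOSOMAL_PAIR`: the W starts as an exact copy of the Z (the shared
#'   autosomal pair).
#' * `B_CHROMOSOME`: the W is drawn from a B-segment pool; its sequence is
#'   unrelated to the Z and the autosomes.
#' * `Z_AUTOSOME_FUSION`: a random autosome is fused onto the Z (neo-Z);
#'   the W starts as a copy of that autosome, and
#'   `cfg$n_translocations_post_fusion` segment swaps between the two
#'   neo-Z parts create an interleaved homology pattern.
#'
#' The nascent W then decays along its stem (`cfg$w_stem_length`
#' substitutions/site, conserved tracts slowed by `cons_rate_mult`),
#' receives repeat insertions from the shared library up to
#' `cfg$repeat_frac_W`, and is GC-shifted by `cfg$gc_boost_W` via biased
#' substitution. With `w_stem_length = 0`, `gc_boost_W = 0` and
#' `repeat_frac_W` at the autosomal level an AUTOSOMAL_PAIR W stays
#' identical to the Z.
#'
#' @param genome a `sim_genome` containing a Z.
#' @param cfg a [scenario_config()].
#' @param seed integer seed for this derivation event (defaults to a
#'   sub-seed of `cfg$seed`); independent per-lineage derivations pass
#'   distinct seeds.
#' @param lib repeat library (defaults to the config's shared library).
#' @return the genome with a W chromosome and `w_origin`/`fusion` truth.
#' @export
derive_W <- function(genome, cfg, seed = derive_seed(cfg$seed, 5L),
                     lib = make_repeat_library(cfg)) {
  if (!"Z" %in% names(genome$seq)) stop("genome has no Z chromosome")
  if ("W" %in% names(genome$seq)) stop("genome already has a W chromosome")
  set.seed(seed)
  # the nascent W retains a contiguous fraction of its source chromosome
  copy_segment <- function(from, prefix) {
    L <- nchar(genome$seq[[from]])
    wlen <- max(1000L, as.integer(round(cfg$w_retained_frac * L)))
    cons <- genome$conserved[genome$conserved$chrom == from, , drop = FALSE]
    s <- if (wlen >= L) 0L else sample.int(L - wlen + 1L, 1L) - 1L
    # a W fragment worth assembling retains recognizable ancestral
    # sequence: anchor the retained segment on a conserved tract
    if (wlen < L && nrow(cons)) {
      for (try in seq_len(50L)) {
        if (any(cons$start >= s & cons$end <= s + wlen)) break
        s <- sample.int(L - wlen + 1L, 1L) - 1L
      }
      if (!any(cons$start >= s & cons$end <= s + wlen)) {
        anchor <- cons[sample.int(nrow(cons), 1L), ]
        s <- min(max(0L, anchor$start - (wlen - (anchor$end - anchor$start)) %/% 2L),
                 L - wlen)
      }
    }
    e <- s + wlen
    genome$seq[["W"]] <<- substr(genome$seq[[from]], s + 1L, e)
    genome$class[["W"]] <<- "W"
    gg <- genome$genes[genome$genes$chrom == from &
                         genome$genes$start >= s & genome$genes$end <= e, , drop = FALSE]
    if (nrow(gg)) {
      gg$chrom <- "W"
      gg$start <- gg$start - s; gg$end <- gg$end - s
      gg$gene_id <- paste0(prefix, gg$gene_id)
      genome$genes <<- rbind(genome$genes, gg)
    }
    clip <- function(df) {
      dd <- df[df$chrom == from & df$end > s & df$start < e, , drop = FALSE]
      if (!nrow(dd)) return(dd)
      dd$chrom <- "W"
      dd$start <- pmax(dd$start, s) - s
      dd$end <- pmin(dd$end, e) - s
      dd
    }
    genome$repeats <<- rbind(genome$repeats, clip(genome$repeats))
    genome$conserved <<- rbind(genome$conserved, clip(genome$conserved))
  }
  if (cfg$hypothesis == "AUTOSOMAL_PAIR") {
    copy_segment("Z", "W_")
    genome$w_origin <- "Z"
  } else if (cfg$hypothesis == "B_CHROMOSOME") {
    blen <- as.integer(round(cfg$w_retained_frac * cfg$chrom_length *
                               runif(1, 1 - cfg$length_jitter, 1 + cfg$length_jitter)))
    genome$seq[["W"]] <- random_dna(blen, cfg$gc_base)
    genome$class[["W"]] <- "W"
    bf <- place_conserved_and_genes("W", blen, cfg,
                                    family_prefix = sprintf("B%d", seed %% 997L),
                                    gene_prefix = sprintf("B%d", seed %% 997L))
    genome$genes <- rbind(genome$genes, bf$genes)
    genome$conserved <- rbind(genome$conserved, bf$conserved)
    genome$w_origin <- "B"
  } else { # Z_AUTOSOME_FUSION
    autos <- names(genome$class)[genome$class == "autosome"]
    if (!length(autos)) config_error("fusion requested but no autosomes present")
    partner <- sample(autos, 1L)
    zlen <- nchar(genome$seq[["Z"]])
    copy_segment(partner, "W_")
    # fuse the partner onto the Z
    genome$seq[["Z"]] <- paste0(genome$seq[["Z"]], genome$seq[[partner]])
    genome$seq <- genome$seq[names(genome$seq) != partner]
    genome$class <- genome$class[names(genome$class) != partner]
    move <- function(df, poscols) {
      sel <- df$chrom == partner
      for (pc in poscols) df[[pc]][sel] <- df[[pc]][sel] + zlen
      df$chrom[sel] <- "Z"
      df
    }
    genome$genes <- move(genome$genes, c("start", "end"))
    genome$markers <- move(genome$markers, "pos")
    genome$repeats <- move(genome$repeats, c("start", "end"))
    genome$conserved <- move(genome$conserved, c("start", "end"))
    genome$w_origin <- partner
    genome$fusion <- c("Z", partner)
    for (i in seq_len(cfg$n_translocations_post_fusion))
      genome <- swap_segments_across(genome, "Z", zlen)
  }
  # W-specific decay since the (ancient) origin of the W
  genome$seq[["W"]] <- evolve_het(
    genome$seq[["W"]], cfg$w_stem_length * cfg$sub_rate_scale,
    genome$conserved[genome$conserved$chrom == "W", , drop = FALSE],
    cfg$cons_rate_mult)
  genome <- insert_repeats_chrom(genome, "W", cfg$repeat_frac_W, lib,
                                 cfg$repeat_copy_divergence)
  genome$seq[["W"]] <- gc_boost(genome$seq[["W"]], cfg$gc_boost_W)
  genome
}

# ---- branch evolution -----------------------------------------------------

evolve_branch <- function(gnm, bl, cfg, seed, lib) {
  set.seed(seed)
  for (cn in names(gnm$seq)) {
    d <- bl * cfg$sub_rate_scale *
      if (gnm$class[[cn]] == "W") cfg$w_extra_sub_multiplier else 1
    gnm$seq[[cn]] <- evolve_het(
      gnm$seq[[cn]], d,
      gnm$conserved[gnm$conserved$chrom == cn, , drop = FALSE],
      cfg$cons_rate_mult)
  }
  if (cfg$n_inversions_per_branch > 0L && bl > 0)
    for (i in seq_len(cfg$n_inversions_per_branch))
      gnm <- apply_random_inversion(gnm, cfg)
  if (bl > 0 && nrow(gnm$markers)) {
    lost <- runif(nrow(gnm$markers)) < cfg$marker_loss_prob
    gnm$markers <- gnm$markers[!lost, , drop = FALSE]
    dup <- which(runif(nrow(gnm$markers)) < cfg$marker_dup_prob)
    if (length(dup)) {
      extra <- gnm$markers[dup, , drop = FALSE]
      extra$chrom <- sample(names(gnm$seq), length(dup), replace = TRUE)
      extra$pos <- vapply(extra$chrom, function(cn)
        sample.int(nchar(gnm$seq[[cn]]), 1L) - 1L, integer(1))
      gnm$markers <- rbind(gnm$markers, extra)
    }
  }
  if (bl > 0) gnm <- top_up_repeats(gnm, cfg, lib)
  gnm
}

#' Evolve a clade from an ancestral genome
#'
#' Walks the scenario tree from the root: ancestral repeats are inserted
#' first, the W is derived at the root (`w_shared_origin = TRUE`) or at the
#' start of each terminal branch (`FALSE`), and along every branch each
#' chromosome accumulates Jukes-Cantor substitutions at
#' `branch length x sub_rate_scale` (the W additionally multiplied by
#' `w_extra_sub_multiplier`; conserved tracts slowed by
#' `cons_rate_mult`), random intra-chromosomal inversions, marker
#' loss/duplication and repeat top-ups. Markers and genes inherit their
#' coordinates through every rearrangement.
#'
#' @param ancestor a `sim_genome` from [simulate_ancestor()].
#' @param cfg a [scenario_config()].
#' @return a `sim_clade`: list with `genomes` (one `sim_genome` per
#'   species), `tree`, `cfg` and `truth` (per-species W origin, fusion
#'   partners and chromosome-to-ancestor homology).
#' @export
evolve_clade <- function(ancestor, cfg) {
  validate_scenario_config(cfg)
  tree <- if (is.null(cfg$tree)) default_tree(cfg) else cfg$tree
  lib <- make_repeat_library(cfg)
  set.seed(derive_seed(cfg$seed, 4L))
  root <- top_up_repeats(ancestor, cfg, lib)
  if (cfg$w_shared_origin)
    root <- derive_W(root, cfg, seed = derive_seed(cfg$seed, 5L), lib = lib)

  ntips <- length(tree$tip.label)
  rootnode <- ntips + 1L
  genomes <- list()
  walk <- function(node, gnm) {
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    if (!length(kids)) {
      genomes[[tree$tip.label[node]]] <<- gnm
      return(invisible(NULL))
    }
    for (kid in kids) {
      bl <- tree$edge.length[which(tree$edge[, 1L] == node & tree$edge[, 2L] == kid)]
      g <- gnm
      if (kid <= ntips && !cfg$w_shared_origin)
        g <- derive_W(g, cfg, seed = derive_seed(cfg$seed, 500L + kid), lib = lib)
      g <- evolve_branch(g, bl, cfg, derive_seed(cfg$seed, 100L + kid), lib)
      walk(kid, g)
    }
  }
  walk(rootnode, root)
  genomes <- genomes[tree$tip.label]

  truth <- list(
    hypothesis = cfg$hypothesis,
    w_shared_origin = cfg$w_shared_origin,
    w_origin = lapply(genomes, `[[`, "w_origin"),
    fusion = lapply(genomes, `[[`, "fusion"),
    homology = lapply(genomes, function(g) {
      nm <- names(g$seq)[g$class != "W"]
      setNames(nm, nm) # chromosomes keep ancestral names; fusions tracked above
    })
  )
  structure(list(genomes = genomes, tree = tree, cfg = cfg, truth = truth),
            class = "sim_clade")
}

#' Simulate a full clade in one call
#'
#' Convenience wrapper: [simulate_ancestor()] then [evolve_clade()].
#'
#' @param cfg a [scenario_config()].
#' @return a `sim_clade`.
#' @export
simulate_clade <- function(cfg) evolve_clade(simulate_ancestor(cfg), cfg)

#' @export
print.sim_clade <- function(x, ...) {
  cat(sprintf("sim_clade: %d species, hypothesis %s, %s W origin\n",
              length(x$genomes), x$cfg$hypothesis,
              if (x$cfg$w_shared_origin) "shared" else "independent"))
  invisible(x)
}

#' Combined marker table of a clade
#'
#' @param clade a `sim_clade`.
#' @return data.frame(species, marker_id, chrom, pos).
#' @export
clade_marker_table <- function(clade) {
  do.call(rbind, lapply(names(clade$genomes), function(sp) {
    m <- clade$genomes[[sp]]$markers
    if (!nrow(m)) return(NULL)
    cbind(species = sp, m, stringsAsFactors = FALSE)
  }))
}
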