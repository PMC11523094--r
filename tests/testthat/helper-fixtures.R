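# Shared fixtures: everything is generated in code, deterministically.

fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (is.null(fx_cache[[key]])) fx_cache[[key]] <- force(expr)
  fx_cache[[key]]
}

# a small default-karyotype clade (31 chromosomes) for marker/profile tests
fx_small31 <- function(seed = 7) {
  fx_memo(paste0("small31_", seed),
          simulate_clade(scenario_config(n_species = 2, n_autosomes = 30,
                                         chrom_length = 20000,
                                         n_proteins_per_chrom = 5,
                                         n_markers = 310, seed = seed)))
}

# a compact clade for pipeline-level tests
fx_pipe_cfg <- function(hypothesis, shared, seed,
                        n_species = 3, w_extra = 3) {
  scenario_config(hypothesis = hypothesis, w_shared_origin = shared,
                  n_species = n_species, n_autosomes = 6,
                  chrom_length = 30000, n_markers = 100,
                  n_proteins_per_chrom = 4,
                  w_extra_sub_multiplier = w_extra, seed = seed)
}

# per-base boolean-array oracle for interval algebra
bool_mask <- function(df, L) {
  v <- logical(L)
  if (!is.null(df) && nrow(df)) {
    for (i in seq_len(nrow(df))) {
      if (df$end[i] > df$start[i]) v[(df$start[i] + 1):df$end[i]] <- TRUE
    }
  }
  v
}

random_intervals <- function(n, L, max_w = NULL) {
  if (is.null(max_w)) max_w <- max(2L, L %/% 5L)
  s <- sample.int(L, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(start = s, end = pmin(s + w, L))
}

# exhaustive comparator oracle for best protein hits
oracle_best_hits <- function(h, max_evalue = 1e-10) {
  h <- h[h$evalue <= max_evalue, , drop = FALSE]
  if (!nrow(h)) return(h)
  out <- lapply(split(h, h$qseqid), function(g) {
    g[order(g$evalue, -g$pident, g$sseqid), ][1L, ]
  })
  do.call(rbind, out)
}

# exhaustive neighbour-count oracle for concordance chaining
oracle_chain_support <- function(m, R) {
  n <- nrow(m)
  qm <- (m$qstart + m$qend) / 2
  tm <- (m$tstart + m$tend) / 2
  supp <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (m$qchrom[i] != m$qchrom[j] || m$tchrom[i] != m$tchrom[j]) next
      if (m$orientation[i] != m$orientation[j]) next
      dq <- qm[j] - qm[i]; dt_ <- tm[j] - tm[i]
      if (abs(dq) > R || abs(dt_) > R || dq == 0) next
      okdir <- if (m$orientation[i] == "+") dq * dt_ > 0 else dq * dt_ < 0
      if (okdir) supp[i] <- supp[i] + 1L
    }
  }
  supp
}
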