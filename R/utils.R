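# Low-level sequence helpers. Sequences are plain upper-case character
# scalars over {A,C,G,T,N}; all public coordinates are 0-based half-open.

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}

#' Ungapped identity between two equal-length strings
#'
#' Fraction of positions with matching bases. `N` never counts as a match.
#' The denominator is `denom` (defaults to the string length), so clipped or
#' partially missing alignments are penalised rather than renormalised.
#'
#' @param a,b character scalars of equal length.
#' @param denom denominator in bases; default `nchar(a)`.
#' @return fraction in \[0,1\].
#' @export
ungapped_identity <- function(a, b, denom = nchar(a)) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L || denom <= 0) return(0)
  ra <- ra[seq_len(n)]
  rb <- rb[seq_len(n)]
  nraw <- as.raw(78L) # 'N'
  sum(ra == rb & ra != nraw) / denom
}

# Match count (not fraction) between raw vectors; Ns never match.
.match_count <- function(ra, rb) {
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  nraw <- as.raw(78L)
  sum(ra[seq_len(n)] == rb[seq_len(n)] & ra[seq_len(n)] != nraw)
}

# Derive a reproducible 31-bit sub-seed from a parent seed and an index.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + as.double(i) * 9973 + 1) %% 2147483647)
}

#' Random DNA string with a given GC fraction
#'
#' i.i.d. nucleotides; the building block of every simulated sequence.
#'
#' @param n length in bp.
#' @param gc GC fraction.
#' @return character scalar.
#' @export
random_dna <- function(n, gc = 0.35) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Evolve a sequence under the Jukes-Cantor model
#'
#' Exact per-site transition sampling for `d` expected
#' substitutions/site: P(stay) = 1/4 + 3/4 exp(-4d/3), changed sites
#' move uniformly to one of the three other bases. `N`s are never
#' mutated. Uses the current RNG stream.
#'
#' @param x character scalar over A/C/G/T/N.
#' @param d expected substitutions per site (branch length).
#' @return the evolved sequence.
#' @export
evolve_jc <- function(x, d) {
  if (d <= 0) return(x)
  v <- utf8ToInt(x)
  L <- length(v)
  pstay <- 0.25 + 0.75 * exp(-4 * d / 3)
  hit <- which(runif(L) > pstay)
  # never mutate Ns
  hit <- hit[v[hit] != 78L]
  if (length(hit)) {
    codes <- utf8ToInt("ACGT")
    cur <- match(v[hit], codes)
    # uniform choice among the 3 other bases
    r <- sample.int(3L, length(hit), replace = TRUE)
    newb <- ((cur - 1L + r) %% 4L) + 1L
    v[hit] <- codes[newb]
  }
  intToUtf8(v)
}

# Shift GC content up by `boost` (fraction of sites) by flipping random A/T
# sites to G or C: a biased-substitution caricature of GC-elevating decay.
gc_boost <- function(x, boost) {
  if (boost <= 0) return(x)
  v <- utf8ToInt(x)
  at <- which(v == 65L | v == 84L) # A or T
  n <- min(length(at), round(boost * length(v)))
  if (n > 0L) {
    sel <- sample(at, n)
    v[sel] <- ifelse(runif(n) < 0.5, 71L, 67L) # G or C
  }
  intToUtf8(v)
}

#' GC fraction of a sequence
#'
#' (G+C)/(A+C+G+T); `N`s are excluded from numerator and denominator.
#' Returns `NA` for an all-N (or empty) sequence.
#'
#' @param seq character scalar.
#' @return fraction in \[0,1\] or `NA`.
#' @export
gc_fraction <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  v <- utf8ToInt(toupper(seq))
  gc <- sum(v == 71L | v == 67L)
  acgt <- sum(v == 65L | v == 67L | v == 71L | v == 84L)
  if (acgt == 0L) return(NA_real_)
  gc / acgt
}

# Expected per-base match rate of two unrelated sequences given their base
# compositions: sum over bases of p_b * q_b. Used as the "background
# identity" oracle for B-chromosome-derived Ws.
background_identity <- function(a, b) {
  pa <- base_composition(a)
  pb <- base_composition(b)
  sum(pa * pb)
}

base_composition <- function(x) {
  v <- utf8ToInt(x)
  n <- vapply(utf8ToInt("ACGT"), function(cc) sum(v == cc), integer(1))
  n / sum(n)
}
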