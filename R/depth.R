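# Parent read-depth simulation for trio-based sex-chromosome confirmation.

#' Tile a chromosome into fixed windows
#'
#' 0-based half-open windows; a window larger than the chromosome yields a
#' single whole-chromosome window.
#'
#' @param len chromosome length (bp).
#' @param window window size (bp).
#' @return data.frame(start, end).
#' @export
make_windows <- function(len, window) {
  stopifnot(len >= 1L, window >= 1L)
  start <- seq.int(0L, len - 1L, by = window)
  data.frame(start = as.integer(start),
             end = as.integer(pmin(start + window, len)))
}

#' Simulate per-window read depth for a ZW mother and a ZZ father
#'
#' Models the expected trio pattern: in the ZW mother, Z and W windows sit
#' at half the autosomal depth; in the ZZ father the Z matches the
#' autosomes while the W receives only a small fraction
#' (`father_w_frac`) of the autosomal depth, mimicking repeat-driven
#' mismapping. Window depths are gamma-distributed with coefficient of
#' variation `cv` (exact means when `cv <= 0`).
#'
#' @param clade a `sim_clade` (or a single `sim_genome` via `species = NULL`).
#' @param species species name within the clade.
#' @param mean_depth autosomal mean depth (x coverage).
#' @param window window size in bp; 200 kb by default, the scale at which
#'   depth is averaged in trio-based W confirmation.
#' @param cv coefficient of variation of window noise.
#' @param father_w_frac father W depth relative to autosomes.
#' @param seed integer seed.
#' @return list(mother, father) of data.frames
#'   (chrom, start, end, depth), each with a `sex_role` attribute.
#' @export
simulate_depth_tracks <- function(clade, species = NULL, mean_depth = 30,
                                  window = 200000L, cv = 0.15,
                                  father_w_frac = NULL, seed = 1L) {
  gnm <- if (inherits(clade, "sim_genome")) clade else clade$genomes[[species]]
  stopifnot(inherits(gnm, "sim_genome"))
  if (is.null(father_w_frac))
    father_w_frac <- if (inherits(clade, "sim_clade")) clade$cfg$father_w_depth_frac else 0.05
  set.seed(seed)
  draw <- function(mu, n) {
    if (cv <= 0) return(rep(mu, n))
    shape <- 1 / cv^2 # gamma with mean mu and the requested CV
    rgamma(n, shape = shape, scale = mu * cv^2)
  }
  one_parent <- function(role) {
    out <- do.call(rbind, lapply(names(gnm$seq), function(cn) {
      w <- make_windows(nchar(gnm$seq[[cn]]), window)
      mu <- switch(gnm$class[[cn]],
                   autosome = mean_depth,
                   Z = if (role == "mother_ZW") mean_depth / 2 else mean_depth,
                   W = if (role == "mother_ZW") mean_depth / 2 else father_w_frac * mean_depth)
      w$depth <- draw(mu, nrow(w))
      cbind(chrom = cn, w, stringsAsFactors = FALSE)
    }))
    attr(out, "sex_role") <- role
    out
  }
  list(mother = one_parent("mother_ZW"), father = one_parent("father_ZZ"))
}
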