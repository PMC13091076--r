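# Codon bookkeeping shared by the metrics and the simulator (translation
# table 11: standard code with bacterial start codons; codon->aa map is the
# standard one, stops TAA/TAG/TGA).

.codon_info <- function() {
  if (!is.null(.pkg_cache$codon_info)) return(.pkg_cache$codon_info)
  code <- .code11()
  codons <- names(code)
  aa <- unname(code)
  gc_n <- vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")),
                 integer(1))
  is_stop <- aa == "*"
  fam <- split(codons[!is_stop], aa[!is_stop])
  fam_size <- lengths(fam)
  degenerate <- names(fam)[fam_size >= 2L]
  info <- list(codons = codons, aa = stats::setNames(aa, codons),
               gc_n = stats::setNames(gc_n, codons),
               is_stop = stats::setNames(is_stop, codons),
               families = fam, fam_size = fam_size,
               degenerate_aas = degenerate,
               sense_codons = codons[!is_stop])
  .pkg_cache$codon_info <- info
  info
}

#' Default background codon-usage table
#'
#' Within-family codon probabilities emulating a biased, GC-rich bacterial
#' genome (bifidobacteria-like): inside each synonymous family the probability
#' of a codon grows exponentially with its G+C count, so third positions are
#' strongly G/C-enriched and usage is far from uniform. Probabilities sum to 1
#' within each amino-acid family.
#'
#' @param gc_strength exponential weight per G/C nucleotide in the codon
#'   (default 1.2; 0 gives uniform synonymous usage).
#' @return named numeric vector over the 61 sense codons.
#' @export
defaultCodonTable <- function(gc_strength = 1.2) {
  info <- .codon_info()
  w <- exp(gc_strength * info$gc_n[info$sense_codons])
  out <- numeric(0)
  for (a in names(info$families)) {
    cs <- info$families[[a]]
    out[cs] <- w[cs] / sum(w[cs])
  }
  out[info$sense_codons]
}

#' Default amino-acid background frequencies
#'
#' A fixed, plausible bacterial proteome composition used when drawing random
#' background proteins and background genes.
#'
#' @return named numeric vector over the 20 standard amino acids, summing to 1.
#' @export
defaultAAFreqs <- function() {
  f <- c(A = 0.095, R = 0.055, N = 0.035, D = 0.055, C = 0.010,
         Q = 0.035, E = 0.060, G = 0.080, H = 0.020, I = 0.055,
         L = 0.100, K = 0.045, M = 0.025, F = 0.040, P = 0.045,
         S = 0.055, T = 0.055, W = 0.012, Y = 0.028, V = 0.075)
  f / sum(f)
}

# Joint distribution over sense codons implied by aa frequencies and a
# within-family codon table.
.joint_codon_dist <- function(codon_table, aa_freqs) {
  info <- .codon_info()
  aa <- info$aa[names(codon_table)]
  q <- codon_table * aa_freqs[aa]
  q / sum(q)
}

.dist_gc <- function(q) {
  info <- .codon_info()
  sum(q * info$gc_n[names(q)]) / 3
}

#' Derive an alien (GC-shifted, flattened) codon distribution
#'
#' Builds the joint codon distribution used to emit putatively transferred
#' genes. Two orthogonal departures from the host are combined. First, the
#' within-family synonymous usage is mixed with a uniform distribution
#' (\code{flatten}): a flatter synonymous profile raises ENC, inflates the
#' RSCU deviation from the biased host pool, and lowers CAI against it.
#' Second, the amino-acid marginal is exponentially tilted towards families
#' with G/C-rich codons until the distribution's expected GC content equals
#' the background GC plus \code{gc_shift}; tilting the marginal (rather than
#' individual codons) shifts GC through first/second codon positions without
#' re-sharpening the flattened synonymous usage.
#'
#' @param codon_table within-family background codon table
#'   (see \code{\link{defaultCodonTable}}).
#' @param aa_freqs background amino-acid frequencies.
#' @param gc_shift target increase in expected GC fraction (e.g. 0.15).
#' @param flatten mixing weight of the uniform within-family component in
#'   [0, 1).
#' @return named numeric joint distribution over the 61 sense codons.
#' @export
alienCodonTable <- function(codon_table = defaultCodonTable(),
                            aa_freqs = defaultAAFreqs(),
                            gc_shift = 0.15, flatten = 0.5) {
  info <- .codon_info()
  q0 <- .joint_codon_dist(codon_table, aa_freqs)
  target <- .dist_gc(q0) + gc_shift
  if (target <= 0.03 || target >= 0.97)
    stop("config error: alien_gc_shift pushes the codon distribution ",
         "outside the attainable GC range")
  # flattened within-family conditional
  cond <- codon_table
  for (a in names(info$families)) {
    cs <- info$families[[a]]
    cond[cs] <- (1 - flatten) * codon_table[cs] + flatten / length(cs)
  }
  fam_gc <- vapply(names(info$families), function(a) {
    cs <- info$families[[a]]
    sum(cond[cs] * info$gc_n[cs])
  }, numeric(1))
  joint_for <- function(lam) {
    af <- aa_freqs[names(info$families)] * exp(lam * fam_gc)
    af <- af / sum(af)
    q <- cond
    for (a in names(info$families))
      q[info$families[[a]]] <- cond[info$families[[a]]] * af[[a]]
    q[info$sense_codons]
  }
  f <- function(lam) .dist_gc(joint_for(lam)) - target
  if (f(-40) * f(40) > 0)
    stop("config error: alien_gc_shift pushes the codon distribution ",
         "outside the attainable GC range")
  lam <- stats::uniroot(f, c(-40, 40), tol = 1e-12)$root
  joint_for(lam)
}
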