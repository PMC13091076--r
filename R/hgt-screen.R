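#' Per-gene percentile flags for the HGT screen
#'
#' Applies the dynamic per-genome thresholds: for each gene and each metric,
#' the comparison set is the metric's values over all OTHER genes of the same
#' genome (leave-one-out). GC content, RSCU deviation and ENC flag a gene when
#' its value strictly exceeds at least the \code{hi} fraction (default 90\%)
#' of the comparison set; CAI flags when the value lies strictly below at
#' least \code{1 - lo} (default 90\%) of it. This rank-based rule guarantees
#' that on tie-free data each flag fires for at most \code{ceiling(0.1 * N)}
#' genes. An undefined metric never contributes a TRUE flag.
#'
#' @param profiles data.frame from \code{\link{profileGenome}}.
#' @param hi,lo upper/lower percentile thresholds (defaults 0.9 / 0.1).
#' @param floor_n minimum number of profiles for percentiles to be meaningful.
#' @return data.frame with columns \code{gene_id}, \code{flag_gc},
#'   \code{flag_rscu}, \code{flag_enc}, \code{flag_cai}, \code{n_flags},
#'   \code{is_hgt} (NA until \code{\link{compositeCall}}).
#' @export
percentileFlags <- function(profiles, hi = 0.9, lo = 0.1, floor_n = 20L) {
  n <- nrow(profiles)
  if (n < floor_n)
    stop("percentileFlags needs at least ", floor_n, " profiles (got ", n, ")")
  flag_hi <- function(v) {
    vapply(seq_len(n), function(i) {
      if (is.na(v[i])) return(FALSE)
      others <- v[-i]; others <- others[!is.na(others)]
      if (length(others) == 0L) return(FALSE)
      sum(others < v[i]) >= hi * length(others)
    }, logical(1))
  }
  flag_lo <- function(v) {
    vapply(seq_len(n), function(i) {
      if (is.na(v[i])) return(FALSE)
      others <- v[-i]; others <- others[!is.na(others)]
      if (length(others) == 0L) return(FALSE)
      sum(others > v[i]) >= (1 - lo) * length(others)
    }, logical(1))
  }
  out <- data.frame(
    gene_id = profiles$gene_id,
    flag_gc = flag_hi(profiles$gc),
    flag_rscu = flag_hi(profiles$rscu_dev),
    flag_enc = flag_hi(profiles$enc),
    flag_cai = flag_lo(profiles$cai),
    stringsAsFactors = FALSE)
  out$n_flags <- out$flag_gc + out$flag_rscu + out$flag_enc + out$flag_cai
  out$is_hgt <- NA
  out
}

#' Composite HGT call
#'
#' A gene is called horizontally acquired when at least \code{k} of its four
#' per-metric flags are TRUE (default 3 of 4).
#'
#' @param calls data.frame from \code{\link{percentileFlags}}.
#' @param k integer in 1..4.
#' @return the same data.frame with \code{is_hgt} filled in.
#' @export
compositeCall <- function(calls, k = 3L) {
  if (!(k %in% 1:4)) stop("k must be in 1..4")
  calls$is_hgt <- calls$n_flags >= k
  calls
}

#' Per-family acquisition rates across genomes
#'
#' For each gene family, the fraction of genomes carrying the family in which
#' at least one member gene is called horizontally acquired. Families present
#' in zero genomes are omitted.
#'
#' @param calls data.frame of composite calls with a \code{genome_id} column
#'   (rbind of per-genome \code{\link{compositeCall}} outputs).
#' @param family_table data.frame with columns \code{genome_id},
#'   \code{gene_id}, \code{family} (e.g. from \code{\link{assignFamilies}});
#'   relabel rows to split contexts such as in-locus versus scattered copies.
#' @return data.frame with \code{family}, \code{n_genomes_with_family},
#'   \code{n_flagged}, \code{rate}.
#' @export
acquisitionRates <- function(calls, family_table) {
  key <- paste(calls$genome_id, calls$gene_id)
  hgt <- setNames(calls$is_hgt, key)
  fams <- sort(unique(family_table$family))
  rows <- lapply(fams, function(f) {
    ft <- family_table[family_table$family == f, , drop = FALSE]
    by_g <- split(paste(ft$genome_id, ft$gene_id), ft$genome_id)
    n_g <- length(by_g)
    n_flag <- sum(vapply(by_g, function(kk)
      any(hgt[kk], na.rm = TRUE), logical(1)))
    data.frame(family = f, n_genomes_with_family = n_g, n_flagged = n_flag,
               rate = n_flag / n_g, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
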