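#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject
#' @importFrom Matrix sparseMatrix crossprod
NULL

.blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

# Identity and reference coverage from one aligned pattern/subject pair.
# Identity = matches / alignment columns, excluding terminal-gap columns
# (columns before the first and after the last position at which both
# sequences carry a residue). Coverage = subject residues inside that
# region / subject length.
.aln_stats <- function(pat, sub, ref_len) {
  p <- strsplit(pat, "", fixed = TRUE)[[1]]
  s <- strsplit(sub, "", fixed = TRUE)[[1]]
  both <- which(p != "-" & s != "-")
  if (length(both) == 0L)
    return(c(identity = 0, coverage = 0))
  a <- both[1L]; b <- both[length(both)]
  cols <- b - a + 1L
  matches <- sum(p[a:b] == s[a:b] & p[a:b] != "-")
  covered <- sum(s[a:b] != "-")
  c(identity = matches / cols, coverage = covered / ref_len)
}

#' Global pairwise protein identity
#'
#' Needleman-Wunsch alignment (BLOSUM62, affine gaps: opening 10, extension
#' 0.5) of two proteins. Identity is matches divided by alignment columns
#' excluding terminal gaps; coverage is the fraction of the second (reference)
#' protein spanned by the non-terminal-gap region.
#'
#' @param query,ref protein sequences (character or \code{AAString}).
#' @return named numeric vector \code{c(identity=, coverage=)}.
#' @examples
#' pairwiseIdentity("MKLVAT", "MKLVAT")
#' @export
pairwiseIdentity <- function(query, ref) {
  aln <- pairwiseAlignment(AAString(as.character(query)),
                           AAString(as.character(ref)),
                           substitutionMatrix = .blosum62(),
                           gapOpening = 10, gapExtension = 0.5,
                           type = "global")
  .aln_stats(as.character(alignedPattern(aln)),
             as.character(alignedSubject(aln)),
             nchar(as.character(ref)))
}

# Align query/reference pairs elementwise in one vectorized call.
# Returns a data.frame(identity, coverage, score), one row per pair;
# coverage is relative to the reference (second) sequence.
.align_pairs <- function(queries, refs) {
  n <- length(queries)
  stopifnot(length(refs) == n)
  if (n == 0L)
    return(data.frame(identity = numeric(0), coverage = numeric(0),
                      score = numeric(0)))
  aln <- pairwiseAlignment(AAStringSet(as.character(queries)),
                           AAStringSet(as.character(refs)),
                           substitutionMatrix = .blosum62(),
                           gapOpening = 10, gapExtension = 0.5,
                           type = "global")
  pats <- as.character(alignedPattern(aln))
  subs <- as.character(alignedSubject(aln))
  rl <- nchar(as.character(refs))
  st <- vapply(seq_len(n),
               function(i) .aln_stats(pats[i], subs[i], rl[i]), numeric(2))
  data.frame(identity = st[1, ], coverage = st[2, ],
             score = Biostrings::score(aln))
}

# Align many queries against a single reference in one vectorized call.
# Returns a data.frame(identity, coverage, score), one row per query.
.align_many_to_one <- function(queries, ref) {
  n <- length(queries)
  if (n == 0L)
    return(data.frame(identity = numeric(0), coverage = numeric(0),
                      score = numeric(0)))
  aln <- pairwiseAlignment(AAStringSet(queries), AAString(as.character(ref)),
                           substitutionMatrix = .blosum62(),
                           gapOpening = 10, gapExtension = 0.5,
                           type = "global")
  pats <- as.character(alignedPattern(aln))
  subs <- as.character(alignedSubject(aln))
  rl <- nchar(as.character(ref))
  st <- vapply(seq_len(n),
               function(i) .aln_stats(pats[i], subs[i], rl), numeric(2))
  data.frame(identity = st[1, ], coverage = st[2, ],
             score = Biostrings::score(aln))
}

# Sparse protein x k-mer incidence matrix (presence/absence of distinct
# k-mers). Used to prefilter pairs before exact alignment.
.kmer_incidence <- function(seqs, k = 4L) {
  seqs <- as.character(seqs)
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  all_k <- unique(unlist(km, use.names = FALSE))
  if (length(all_k) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                dims = c(length(seqs), 0L)))
  i <- rep.int(seq_along(km), lengths(km))
  j <- match(unlist(km, use.names = FALSE), all_k)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(seqs), length(all_k)))
}

# Candidate pairs among one protein set: pairs whose shared distinct k-mer
# count reaches max(min_shared, min_frac of the smaller k-mer set). The
# fractional term keeps the expected number of spurious long-vs-long
# candidates near zero while pairs above ~50% identity share far more.
# Returns a 2-column matrix of indices (i < j).
.kmer_candidate_pairs <- function(seqs, k = 4L, min_shared = 3L,
                                  min_frac = 0.05) {
  M <- .kmer_incidence(seqs, k)
  nk <- Matrix::rowSums(M)
  S <- Matrix::tcrossprod(M)
  S <- methods::as(S, "TsparseMatrix")
  i <- S@i + 1L; j <- S@j + 1L
  thr <- pmax(min_shared, min_frac * pmin(nk[i], nk[j]))
  keep <- i < j & S@x >= thr
  cbind(i = i[keep], j = j[keep])
}

# Candidate query x reference pairs across two sets (same thresholds).
.kmer_candidates_vs <- function(queries, refs, k = 4L, min_shared = 3L,
                                min_frac = 0.05) {
  qs <- as.character(queries); rs <- as.character(refs)
  M <- .kmer_incidence(c(qs, rs), k)
  nk <- Matrix::rowSums(M)
  nq <- length(qs)
  S <- Matrix::tcrossprod(M[seq_len(nq), , drop = FALSE],
                          M[nq + seq_along(rs), , drop = FALSE])
  S <- methods::as(S, "TsparseMatrix")
  q <- S@i + 1L; r <- S@j + 1L
  thr <- pmax(min_shared, min_frac * pmin(nk[q], nk[nq + r]))
  keep <- S@x >= thr
  cbind(q = q[keep], r = r[keep])
}
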