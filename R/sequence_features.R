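#' Alignment scoring scheme
#'
#' Linear (per-symbol) gap model for global alignment of short RNA sequences.
#' The default — match +1, mismatch -1, gap -2 — is a standard simple scheme
#' for comparing mature miRNA sequences; all three values are configurable.
#'
#' @param match_score score for identical residues (must exceed
#'   `mismatch_score`).
#' @param mismatch_score score for a substitution.
#' @param gap_penalty penalty per gap symbol (must be <= 0).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match_score = 1, mismatch_score = -1,
                           gap_penalty = -2) {
  stopifnot(is.numeric(match_score), is.numeric(mismatch_score),
            is.numeric(gap_penalty))
  if (match_score <= mismatch_score)
    stopf("match_score must exceed mismatch_score")
  if (gap_penalty > 0) stopf("gap_penalty must be <= 0")
  structure(list(match_score = match_score, mismatch_score = mismatch_score,
                 gap_penalty = gap_penalty), class = "scoring_scheme")
}

#' Needleman-Wunsch global alignment of two sequences
#'
#' Computes the optimal global alignment under a linear gap model, with
#' deterministic tie-breaking (diagonal over up over left, on the
#' lexicographically canonical orientation of the pair, so that the percent
#' identity of co-optimal alignments is reproducible and symmetric). Percent
#' identity is the fraction of alignment columns with identical non-gap
#' residues, over the full alignment length including gap columns by default.
#'
#' @param a,b non-empty RNA sequences (character scalars, or length-1 named
#'   vectors as returned by [read_fasta()]).
#' @param scheme a [scoring_scheme()].
#' @param identity_denom `"alignment"` (full alignment length, default) or
#'   `"shorter"` (length of the shorter input).
#' @return an `alignment_result`: list with `aligned_a`, `aligned_b`,
#'   `score`, `identity_pct`, `n_matches`, `alignment_length`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme(),
                         identity_denom = c("alignment", "shorter")) {
  identity_denom <- match.arg(identity_denom)
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stopf("cannot align empty sequences")
  swap <- a > b  # canonical orientation: deterministic + symmetric identity
  res <- if (swap) {
    nw_align_cpp(b, a, scheme$match_score, scheme$mismatch_score,
                 scheme$gap_penalty, identity_denom == "shorter")
  } else {
    nw_align_cpp(a, b, scheme$match_score, scheme$mismatch_score,
                 scheme$gap_penalty, identity_denom == "shorter")
  }
  if (swap) res[c("aligned_a", "aligned_b")] <- res[c("aligned_b", "aligned_a")]
  structure(res, class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score %g, identity %.1f%%\n", x$score, x$identity_pct))
  invisible(x)
}

#' Pairwise percent-identity matrix
#'
#' @param sequences named character vector of sequences.
#' @inheritParams global_align
#' @return symmetric numeric matrix of identities in `[0,100]`, with the
#'   sequence names as dimnames and 100 on the diagonal.
#' @export
identity_matrix <- function(sequences, scheme = scoring_scheme(),
                            identity_denom = c("alignment", "shorter")) {
  identity_denom <- match.arg(identity_denom)
  stopifnot(is.character(sequences), length(sequences) >= 1L,
            !is.null(names(sequences)))
  m <- nw_identity_matrix_cpp(unname(sequences), scheme$match_score,
                              scheme$mismatch_score, scheme$gap_penalty,
                              identity_denom == "shorter")
  dimnames(m) <- list(names(sequences), names(sequences))
  m
}

#' Build the thresholded miRNA-miRNA similarity graph
#'
#' Two miRNAs are connected iff their global-alignment percent identity is
#' strictly greater than `threshold_pct` (default 60). The adjacency is
#' symmetric and the diagonal is zero (self-loops are not stored; density
#' reporting over n^2 ordered pairs is handled by [graph_stats()]).
#'
#' @inheritParams identity_matrix
#' @param threshold_pct identity cutoff in `(0,100)`.
#' @return symmetric binary (0/1) adjacency matrix with zero diagonal.
#' @export
build_similarity_graph <- function(sequences, scheme = scoring_scheme(),
                                   threshold_pct = 60,
                                   identity_denom = c("alignment", "shorter")) {
  stopifnot(length(sequences) >= 2L)
  if (!(threshold_pct > 0 && threshold_pct < 100))
    stopf("threshold_pct must lie in (0,100)")
  idm <- identity_matrix(sequences, scheme, identity_denom)
  adj <- (idm > threshold_pct) * 1
  diag(adj) <- 0
  adj
}

kmer_names <- function(k) {
  bases <- c("A", "C", "G", "U")
  g <- do.call(expand.grid,
               c(rep(list(bases), k), KEEP.OUT.ATTRS = FALSE,
                 stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  sort(apply(g, 1L, paste, collapse = ""))
}

#' k-mer frequency profile of a sequence
#'
#' Counts every length-k substring for each k in `ks` and concatenates the
#' blocks (all 4^k k-mers in lexicographic order over A < C < G < U). With the
#' defaults `ks = c(2, 3)` this yields the 80-dimensional sequence embedding
#' (16 dinucleotides followed by 64 trinucleotides). `normalize =
#' "frequency"` rescales each k-block to sum to 1.
#'
#' @param sequence a single RNA sequence (length >= max(ks)).
#' @param ks integer k-mer sizes.
#' @param normalize `"frequency"` (per-k-block relative frequencies, the
#'   model-input default) or `"counts"` (raw sliding-window counts).
#' @return named numeric vector of length `sum(4^ks)`.
#' @export
kmer_profile <- function(sequence, ks = c(2, 3),
                         normalize = c("frequency", "counts")) {
  normalize <- match.arg(normalize)
  profs <- kmer_profiles(stats::setNames(as.character(sequence), "x"),
                         ks = ks, normalize = normalize)
  stats::setNames(profs[1L, ], colnames(profs))
}

#' k-mer profiles for a collection of sequences
#'
#' @param sequences named character vector of sequences.
#' @inheritParams kmer_profile
#' @return numeric matrix, one row per sequence, `sum(4^ks)` columns.
#' @export
kmer_profiles <- function(sequences, ks = c(2, 3),
                          normalize = c("frequency", "counts")) {
  normalize <- match.arg(normalize)
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  ks <- as.integer(ks)
  stopifnot(all(ks >= 1L))
  lens <- nchar(sequences)
  short <- lens < max(ks)
  if (any(short)) {
    stopf("sequence(s) shorter than k=%d: %s", max(ks),
          paste(names(sequences)[short], collapse = ", "))
  }
  set <- Biostrings::RNAStringSet(sequences)
  blocks <- lapply(ks, function(k) {
    counts <- Biostrings::oligonucleotideFrequency(set, width = k)
    storage.mode(counts) <- "double"
    if (normalize == "frequency") {
      counts <- counts / pmax(rowSums(counts), 1)
    }
    counts
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- names(sequences)
  out
}

#' Binary pattern (motif) incidence matrix
#'
#' Marks which length-k motifs occur at least once as a substring of each
#' sequence; with `k = 4` this is the 256-column miRNA-pattern matrix used as
#' an adjacency layer of the heterogeneous graph (presence/absence, not
#' occurrence counts).
#'
#' @param sequences named character vector of sequences (all of length >= k).
#' @param k motif length (default 4).
#' @return binary matrix, rows = sequences, `4^k` columns named by motif in
#'   lexicographic order.
#' @export
motif_incidence <- function(sequences, k = 4) {
  k <- as.integer(k)
  stopifnot(is.character(sequences), length(sequences) >= 1L, k >= 1L)
  short <- nchar(sequences) < k
  if (any(short)) {
    stopf("sequence(s) shorter than k=%d: %s", k,
          paste(names(sequences)[short], collapse = ", "))
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::RNAStringSet(sequences), width = k)
  inc <- (counts > 0) * 1
  rownames(inc) <- names(sequences)
  inc
}
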