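# Transcript similarity: the stand-in for a BLAT-style alignment score.
# A single ends-free global alignment of the two transcripts gives
# identity (matches / aligned columns, end gaps excluded by construction)
# and coverage of the shorter transcript; the score is their product,
# bounded in [0, 1] so the 0.5 match threshold keeps its meaning.

sim_submat <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      mat <<- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -1,
                                                       baseOnly = TRUE)
    }
    mat
  }
})

#' Similarity score between two transcripts
#'
#' Globally aligns the two transcript sequences with free end gaps
#' ([Biostrings::pairwiseAlignment()], type `"overlap"`).
#' `identity_fraction` is matches over aligned columns (end gaps excluded);
#' `coverage_fraction` is the aligned span of the *shorter* transcript over
#' its full length, so a perfect prefix scores 1; `score` is the product.
#'
#' @param a,b transcript sequences (character or DNAString).
#' @return list with `identity_fraction`, `coverage_fraction`, `score`.
#' @examples
#' transcript_similarity("ATGGCTTGA", "ATGGCTTGA")$score
#' @export
transcript_similarity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("transcript sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = sim_submat(), gapOpening = 4, gapExtension = 1)
  aligned_cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  if (aligned_cols == 0) {
    return(list(identity_fraction = 0, coverage_fraction = 0, score = 0))
  }
  ident <- Biostrings::nmatch(pa) / aligned_cols
  shorter_is_a <- nchar(a) <= nchar(b)
  rng <- if (shorter_is_a) pattern_range(pa) else subject_range(pa)
  cov <- (rng[2] - rng[1] + 1) / min(nchar(a), nchar(b))
  list(identity_fraction = ident, coverage_fraction = cov,
       score = ident * cov)
}

pattern_range <- function(pa) {
  r <- pa@pattern@range
  c(BiocGenerics::start(r), BiocGenerics::end(r))
}

subject_range <- function(pa) {
  r <- pa@subject@range
  c(BiocGenerics::start(r), BiocGenerics::end(r))
}

#' Pairwise similarity matrix between two transcript sets
#'
#' Computes [transcript_similarity()] scores for every cross pair, using
#' one vectorised alignment call per query transcript.
#'
#' @param ref_tx,qry_tx named character vectors of transcript sequences.
#' @return numeric matrix (rows = `names(ref_tx)`, cols = `names(qry_tx)`)
#'   of scores in \[0, 1\].
#' @export
similarity_matrix <- function(ref_tx, qry_tx) {
  m <- matrix(0, nrow = length(ref_tx), ncol = length(qry_tx),
              dimnames = list(names(ref_tx), names(qry_tx)))
  if (!length(ref_tx) || !length(qry_tx)) return(m)
  refs <- Biostrings::DNAStringSet(ref_tx)
  ref_len <- nchar(ref_tx)
  for (j in seq_along(qry_tx)) {
    subj <- Biostrings::DNAString(qry_tx[[j]])
    pa <- Biostrings::pairwiseAlignment(refs, subj, type = "overlap",
                                        substitutionMatrix = sim_submat(),
                                        gapOpening = 4, gapExtension = 1)
    cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
    ident <- ifelse(cols > 0, Biostrings::nmatch(pa) / cols, 0)
    q_len <- nchar(qry_tx[[j]])
    pr <- pa@pattern@range
    sr <- pa@subject@range
    p_span <- BiocGenerics::end(pr) - BiocGenerics::start(pr) + 1
    s_span <- BiocGenerics::end(sr) - BiocGenerics::start(sr) + 1
    cov <- ifelse(ref_len <= q_len, p_span / ref_len, s_span / q_len)
    m[, j] <- ident * pmax(0, cov)
  }
  m
}
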