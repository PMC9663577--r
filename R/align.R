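#' Pairwise sequence alignment
#'
#' Affine-gap pairwise alignment of two nucleotide sequences, either local
#' (Smith--Waterman) or global (Needleman--Wunsch), implemented in C++ for
#' throughput. A gap of length L costs `gap_open + L * gap_ext`, the same
#' convention as [Biostrings::pairwiseAlignment()], so scores are directly
#' comparable.
#'
#' @param pattern,subject Single character strings (or objects coercible via
#'   `as.character()`) over the DNA alphabet. Comparison is case-sensitive;
#'   use uppercase.
#' @param type `"local"` or `"global"`.
#' @param match Positive match score.
#' @param mismatch Positive mismatch penalty (applied as a negative score).
#' @param gap_open,gap_ext Positive gap opening / extension penalties.
#'
#' @return A list with elements `score`, `pattern_start`, `pattern_end`,
#'   `subject_start`, `subject_end` (1-based inclusive coordinates of the
#'   aligned span within each input; 0 when a local alignment is empty),
#'   `aligned_pattern`, `aligned_subject` (gapped strings), `length`
#'   (alignment columns), `matches`, `mismatches`, `gaps` (gap columns), and
#'   `identity` (percent, `100 * matches / length`).
#' @export
#' @examples
#' align_pair("ACGTACGT", "TTACGTACGTTT", type = "local")$identity
align_pair <- function(pattern, subject, type = c("local", "global"),
                       match = 1L, mismatch = 2L, gap_open = 5L, gap_ext = 2L) {
  type <- match.arg(type)
  pattern <- as.character(pattern)
  subject <- as.character(subject)
  stopifnot(length(pattern) == 1L, length(subject) == 1L)
  if (type == "global" && (nchar(pattern) == 0L || nchar(subject) == 0L)) {
    abort("global alignment requires two non-empty sequences")
  }
  res <- if (type == "local") {
    .sw_align(pattern, subject, as.integer(match), as.integer(mismatch),
              as.integer(gap_open), as.integer(gap_ext))
  } else {
    .nw_align(pattern, subject, as.integer(match), as.integer(mismatch),
              as.integer(gap_open), as.integer(gap_ext))
  }
  res$identity <- if (res$length > 0) 100 * res$matches / res$length else 0
  res
}

#' Local alignment score only
#'
#' Smith--Waterman optimal score without traceback; linear memory and several
#' times faster than [align_pair()]. Used as the screening pass of the
#' degenerated-TE permutation control.
#'
#' @inheritParams align_pair
#' @return Integer optimal local alignment score (0 when nothing aligns).
#' @export
align_score <- function(pattern, subject, match = 1L, mismatch = 2L,
                        gap_open = 5L, gap_ext = 2L) {
  .sw_score(as.character(pattern), as.character(subject), as.integer(match),
            as.integer(mismatch), as.integer(gap_open), as.integer(gap_ext))
}

#' Test for a shared exact k-mer between two sequences
#'
#' Seed screen in the style of BLAST word matching: reports whether the two
#' sequences share any exact k-mer. Used to skip hopeless alignment pairs in
#' the degenerated-TE scans; non-ACGT characters break k-mer runs.
#'
#' @param a,b DNA character strings.
#' @param k Word size (4..15, default 12).
#' @return Logical.
#' @export
shared_kmer <- function(a, b, k = 12) {
  stopifnot(k >= 4, k <= 15)
  .shared_kmer(as.character(a), as.character(b), as.integer(k))
}

#' Reverse-complement a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] returning a plain
#' character string.
#'
#' @param x Single DNA character string.
#' @return Reverse-complemented character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
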