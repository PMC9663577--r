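PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Kimura two-parameter distance between two aligned sequences
#'
#' Computes the K2P nucleotide distance, which models transitions
#' (purine--purine and pyrimidine--pyrimidine changes) as more frequent than
#' transversions. Alignment columns containing a gap (`-`) or an ambiguous
#' base in either sequence are excluded before counting; the distance is then
#'
#' \deqn{d = -\tfrac12 \ln(1 - 2p - q) - \tfrac14 \ln(1 - 2q)}
#'
#' with `p` and `q` the transition and transversion proportions over the
#' retained columns.
#'
#' Distances are reported in substitutions per site; multiply by 100 for a
#' "per 100 bases" display.
#'
#' @param x,y Aligned sequences of equal length (character strings).
#' @return List with `p`, `q`, `sites` (compared columns) and `distance`.
#' @section Errors:
#' * class `polytereg_k2p_undefined` when no comparable columns remain;
#' * class `polytereg_k2p_saturation` when `1 - 2p - q <= 0` or
#'   `1 - 2q <= 0` (distance undefined because substitutions are saturated).
#' @export
#' @examples
#' k2p_distance("ACGTACGT", "ACGTACGT")$distance  # 0
k2p_distance <- function(x, y) {
  cnt <- k2p_counts(x, y)
  if (cnt$sites == 0) {
    abort("no comparable (gap-free, unambiguous) columns",
          class = "polytereg_k2p_undefined")
  }
  p <- cnt$transitions / cnt$sites
  q <- cnt$transversions / cnt$sites
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  if (w1 <= 0 || w2 <= 0) {
    abort(sprintf("K2P distance saturated (p = %.3f, q = %.3f)", p, q),
          class = "polytereg_k2p_saturation")
  }
  list(p = p, q = q, sites = cnt$sites,
       distance = -0.5 * log(w1) - 0.25 * log(w2))
}

# Transition/transversion counts over comparable columns.
k2p_counts <- function(x, y) {
  a <- toupper(strsplit(as.character(x), "", fixed = TRUE)[[1]])
  b <- toupper(strsplit(as.character(y), "", fixed = TRUE)[[1]])
  if (length(a) != length(b)) {
    abort("aligned sequences must have equal length")
  }
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  diffs <- a != b
  ts <- sum(diffs & ((a %in% PURINES) == (b %in% PURINES)))
  list(sites = length(a), transitions = ts, transversions = sum(diffs) - ts)
}

# k2p_distance that returns NA fields instead of erroring; used by the
# distribution-level operations which must drop and count saturated pairs.
k2p_or_na <- function(x, y) {
  tryCatch(
    c(k2p_distance(x, y), list(saturated = FALSE)),
    polytereg_k2p_saturation = function(e)
      list(p = NA_real_, q = NA_real_, sites = NA_integer_,
           distance = NA_real_, saturated = TRUE),
    polytereg_k2p_undefined = function(e)
      list(p = NA_real_, q = NA_real_, sites = 0L,
           distance = NA_real_, saturated = FALSE)
  )
}

#' K2P distance of an unaligned sequence pair
#'
#' Globally aligns two sequences ([align_pair()], affine gaps) and computes
#' the K2P distance on the alignment, ignoring gapped columns.
#'
#' @param x,y DNA character strings.
#' @param match,mismatch,gap_open,gap_ext Alignment scoring (defaults match
#'   +1 / mismatch -1 / open 5 / extend 1).
#' @return As [k2p_distance()], plus `alignment_length`.
#' @export
k2p_pair <- function(x, y, match = 1L, mismatch = 1L, gap_open = 5L, gap_ext = 1L) {
  al <- align_pair(x, y, type = "global", match = match, mismatch = mismatch,
                   gap_open = gap_open, gap_ext = gap_ext)
  res <- k2p_distance(al$aligned_pattern, al$aligned_subject)
  res$alignment_length <- al$length
  res
}

#' Generate a random DNA sequence
#'
#' @param n Length in bp.
#' @param gc GC content (probability of C or G per site).
#' @return Character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Evolve a sequence under the K2P substitution process
#'
#' Applies the Kimura two-parameter substitution process to a sequence for a
#' total expected divergence of `distance` substitutions per site, using the
#' exact finite-time K2P transition probabilities (so multiple hits are
#' modelled and [k2p_distance()] is a consistent estimator of `distance`).
#' The transition:transversion *rate* ratio is `ti_tv` (alpha / 2 beta).
#'
#' @param x DNA character string.
#' @param distance Expected substitutions per site (`>= 0`).
#' @param ti_tv Transition:transversion rate ratio (default 2, matching the
#'   simulator's stated mutation model).
#' @return Mutated character string of the same length.
#' @export
#' @examples
#' set.seed(1)
#' evolve_sequence("ACGTACGTAC", 0.1)
evolve_sequence <- function(x, distance, ti_tv = 2) {
  stopifnot(distance >= 0, ti_tv > 0)
  if (distance == 0) return(x)
  # rate decomposition: alpha * t = R d / (R + 1); beta * t = d / (2 (R + 1))
  R <- ti_tv
  bt <- distance / (2 * (R + 1))
  abt <- distance * (2 * R + 1) / (2 * (R + 1))  # (alpha + beta) t
  p <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * abt)
  q <- 0.5 - 0.5 * exp(-4 * bt)
  s <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  n <- length(s)
  u <- runif(n)
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  # transversion targets: the two bases of the other chemical class
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  acgt <- s %in% c("A", "C", "G", "T")
  is_ts <- acgt & u < p
  is_tv <- acgt & u >= p & u < p + q
  if (any(is_ts)) s[is_ts] <- transition_of[s[is_ts]]
  if (any(is_tv)) {
    pick <- runif(sum(is_tv)) < 0.5
    tv_bases <- ifelse(pick, tv1[s[is_tv]], tv2[s[is_tv]])
    s[is_tv] <- tv_bases
  }
  paste(s, collapse = "")
}

#' Randomly substitute a fraction of sites
#'
#' Degeneration process used for TE relics: each site is replaced by a
#' uniformly chosen different base with probability `prob` (no
#' transition/transversion structure -- this models decay, not neutral
#' divergence).
#'
#' @param x DNA character string.
#' @param prob Per-site substitution probability.
#' @return Mutated character string.
#' @export
degenerate_sequence <- function(x, prob) {
  stopifnot(prob >= 0, prob <= 1)
  s <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  hit <- which(runif(length(s)) < prob & s %in% c("A", "C", "G", "T"))
  if (length(hit) > 0) {
    others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
    s[hit] <- vapply(s[hit], function(b) sample(others[[b]], 1), character(1))
  }
  paste(s, collapse = "")
}
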