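#' Date TE insertions from 5'/3' LTR divergence
#'
#' LTR retrotransposons carry identical long terminal repeats at insertion;
#' their subsequent divergence dates the copy. For each full-length element
#' the two LTRs are globally aligned, the K2P distance computed (gapped
#' columns ignored), and the insertion age estimated as
#' `age = distance / (2 * mutation_rate)`.
#'
#' @param tes TE annotation tibble; only rows with `full_length = TRUE` and
#'   LTR coordinates are dated.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param mutation_rate Substitutions per site per year (default 1.3e-8).
#' @param match,mismatch,gap_open,gap_ext Global alignment scoring
#'   (defaults +1/-1/5/1).
#' @return Tibble `te_id`, `subfamily`, `sites`, `p`, `q`, `ltr_distance`,
#'   `age_years`, `saturated`. Saturated elements get `NA` distance/age.
#' @export
te_insertion_age <- function(tes, genome, mutation_rate = 1.3e-8,
                             match = 1L, mismatch = 1L, gap_open = 5L,
                             gap_ext = 1L) {
  fl <- filter(tes, .data$full_length)
  if (nrow(fl) == 0) abort("no full-length TEs with LTR coordinates")
  purrr::map_dfr(seq_len(nrow(fl)), function(i) {
    x <- fl[i, ]
    l5 <- seq_region(genome, x$chrom, x$ltr5_start, x$ltr5_end)
    l3 <- seq_region(genome, x$chrom, x$ltr3_start, x$ltr3_end)
    al <- align_pair(l5, l3, type = "global", match = match,
                     mismatch = mismatch, gap_open = gap_open,
                     gap_ext = gap_ext)
    k <- k2p_or_na(al$aligned_pattern, al$aligned_subject)
    tibble(te_id = x$te_id, subfamily = x$subfamily,
           sites = k$sites, p = k$p, q = k$q,
           ltr_distance = k$distance,
           age_years = k$distance / (2 * mutation_rate),
           saturated = k$saturated)
  })
}

#' Pairwise K2P distance distribution of TFBS sequences
#'
#' Samples up to `n_sample` TFBS sequences without replacement, computes all
#' pairwise global-alignment K2P distances, and reports the distribution's
#' kernel-density modes. Multiple expansion waves of a repeat-derived TFBS
#' family appear as multiple modes.
#'
#' @param seqs Character vector (or [Biostrings::DNAStringSet]) of TFBS
#'   sequences.
#' @param n_sample Sample size (default 500; all sequences when fewer).
#' @param seed Integer seed for the sampling step.
#' @param prominence Relative prominence floor for mode calling (fraction of
#'   the maximum density, default 0.05).
#' @return Object of class `expansion_profile`: list with `distances`
#'   (tibble `i`, `j`, `distance`), `modes` (tibble `location`, `density`,
#'   `prominence`), `n_saturated` (pairs dropped for saturation),
#'   `bandwidth` (Silverman bandwidth used), `n_sequences`.
#' @export
tfbs_expansion_profile <- function(seqs, n_sample = 500, seed = 1,
                                   prominence = 0.05) {
  seqs <- as.character(seqs)
  if (length(seqs) < 2) abort("need at least two sequences")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (length(seqs) > n_sample) seqs <- sample(seqs, n_sample)
  n <- length(seqs)
  pairs <- utils::combn(n, 2)
  d <- vapply(seq_len(ncol(pairs)), function(k) {
    al <- align_pair(seqs[pairs[1, k]], seqs[pairs[2, k]], type = "global",
                     match = 1L, mismatch = 1L, gap_open = 5L, gap_ext = 1L)
    k2p_or_na(al$aligned_pattern, al$aligned_subject)$distance
  }, double(1))
  dist_tbl <- tibble(i = pairs[1, ], j = pairs[2, ], distance = d)
  ok <- dist_tbl[!is.na(dist_tbl$distance), ]
  modes <- find_density_modes(ok$distance, prominence = prominence)
  structure(list(distances = dist_tbl, modes = modes$modes,
                 n_saturated = sum(is.na(d)), bandwidth = modes$bandwidth,
                 n_sequences = n),
            class = "expansion_profile")
}

#' @export
print.expansion_profile <- function(x, ...) {
  cat(sprintf(
    "TFBS expansion profile: %d sequences, %d pairs (%d saturated dropped)\n",
    x$n_sequences, nrow(x$distances), x$n_saturated))
  if (nrow(x$modes) > 0) {
    cat("modes at:", paste(signif(x$modes$location, 3), collapse = ", "), "\n")
  } else cat("no modes above prominence floor\n")
  invisible(x)
}

#' Modes of a kernel density estimate
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth; modes are local
#' maxima whose topographic prominence (height above the higher of the two
#' saddle minima separating them from taller peaks) is at least
#' `prominence` times the maximum density.
#'
#' @param x Numeric sample.
#' @param prominence Relative prominence floor (default 0.05).
#' @param bw Bandwidth or selection rule passed to [stats::density()]
#'   (default `"nrd0"`, Silverman).
#' @return List with `modes` (tibble `location`, `density`, `prominence`)
#'   and `bandwidth`.
#' @export
find_density_modes <- function(x, prominence = 0.05, bw = "nrd0") {
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    return(list(modes = tibble(location = double(), density = double(),
                               prominence = double()),
                bandwidth = NA_real_))
  }
  den <- stats::density(x, bw = bw)
  y <- den$y
  n <- length(y)
  is_max <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  if (length(is_max) == 0) {
    return(list(modes = tibble(location = double(), density = double(),
                               prominence = double()),
                bandwidth = den$bw))
  }
  prom <- vapply(is_max, function(k) {
    h <- y[k]
    left <- y[seq_len(k - 1)]
    right <- if (k < n) y[(k + 1):n] else numeric(0)
    side_min <- function(v, from_end) {
      # walk away from the peak until a taller point; prominence base is the
      # minimum seen up to there (or the series edge)
      if (length(v) == 0) return(0)
      v <- if (from_end) rev(v) else v
      taller <- which(v > h)
      if (length(taller) == 0) min(c(v, 0)) else min(v[seq_len(taller[1])])
    }
    lmin <- side_min(left, from_end = TRUE)
    rmin <- side_min(right, from_end = FALSE)
    h - max(lmin, rmin)
  }, double(1))
  keep <- prom >= prominence * max(y)
  list(modes = tibble(location = den$x[is_max[keep]],
                      density = y[is_max[keep]],
                      prominence = prom[keep]),
       bandwidth = den$bw)
}

#' Highly similar TFBS pairs within a subgenome
#'
#' All-versus-all local alignment of subgenome-specific TFBS sequences;
#' pairs are reported when identity exceeds `min_identity` percent over more
#' than `min_coverage` percent of the query (the first sequence of the
#' pair), with an alignment-score floor standing in for a database-size
#' dependent E-value cutoff.
#'
#' @param seqs Named character vector (or [Biostrings::DNAStringSet]) of
#'   TFBS sequences.
#' @param min_identity Percent identity, strict lower bound (default 70).
#' @param min_coverage Percent query coverage, strict lower bound (default
#'   70).
#' @param min_score Minimum local alignment score (default 40).
#' @param match,mismatch,gap_open,gap_ext Alignment scoring (defaults
#'   +1/-2/5/2).
#' @return Tibble `query`, `subject` (names or indices), `score`, `length`,
#'   `identity`, `coverage`.
#' @export
find_similar_tfbs_pairs <- function(seqs, min_identity = 70, min_coverage = 70,
                                    min_score = 40, match = 1L, mismatch = 2L,
                                    gap_open = 5L, gap_ext = 2L) {
  nm <- names(seqs) %||% as.character(seq_along(seqs))
  seqs <- as.character(seqs)
  n <- length(seqs)
  out <- list()
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      sc <- align_score(seqs[i], seqs[j], match, mismatch, gap_open, gap_ext)
      if (sc < min_score) next
      al <- align_pair(seqs[i], seqs[j], type = "local", match = match,
                       mismatch = mismatch, gap_open = gap_open,
                       gap_ext = gap_ext)
      coverage <- 100 * (al$pattern_end - al$pattern_start + 1) / nchar(seqs[i])
      if (al$identity > min_identity && coverage > min_coverage) {
        out[[length(out) + 1]] <- tibble(
          query = nm[i], subject = nm[j], score = al$score,
          length = al$length, identity = al$identity, coverage = coverage)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(query = character(), subject = character(), score = integer(),
                  length = integer(), identity = double(), coverage = double()))
  }
  bind_rows(out)
}

#' Cross-lineage K2P distance distributions of full-length TE copies
#'
#' For each full-length copy of a TE subfamily the 5' and 3' LTR sequences
#' are merged (concatenated) and aligned against the merged LTRs of copies
#' in other lineages (subgenomes). Copy numbers are subsampled
#' proportionally to lineage totals; lineages with fewer than `min_copies`
#' full-length copies are skipped with a warning. Within-lineage
#' distributions are returned alongside for comparison: a family expanded in
#' the common ancestor shares a between-lineage mode across lineage pairs,
#' while an independently (lineage-specifically) expanded family shows
#' between-lineage modes shifted away from its within-lineage modes.
#'
#' @param tes TE annotation tibble (full-length rows used); lineage is the
#'   subgenome parsed from `chrom`.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param subfamily Subfamily to profile. May be omitted when `tes` contains
#'   a single subfamily; with several present it is required, since mixing
#'   families makes the distance distribution meaningless.
#' @param n_sample Target copies sampled from the largest lineage (default
#'   500); other lineages are sampled proportionally.
#' @param seed Integer seed.
#' @param min_copies Minimum full-length copies for a lineage to enter
#'   (default 25).
#' @param max_pairs Cap on aligned pairs per lineage pair (default 2000).
#' @param prominence Mode-calling floor, see [find_density_modes()].
#' @param subgenome_pattern Passed to [subgenome_of()].
#' @return Object of class `lineage_distance`: list with `distances`
#'   (tibble `lineage_1`, `lineage_2`, `within`, `distance`), `modes`
#'   (per lineage pair), `skipped` (tibble `lineage`, `n_copies`),
#'   `n_saturated`.
#' @export
cross_lineage_te_distance <- function(tes, genome, subfamily = NULL,
                                      n_sample = 500, seed = 1,
                                      min_copies = 25, max_pairs = 2000,
                                      prominence = 0.05,
                                      subgenome_pattern = "([ABD])$") {
  fl <- filter(tes, .data$full_length)
  if (!is.null(subfamily)) {
    fl <- fl[fl$subfamily == subfamily, ]
  } else if (length(unique(fl$subfamily)) > 1) {
    abort("tes contains several subfamilies; pass `subfamily`")
  }
  fl <- mutate(fl, lineage = subgenome_of(.data$chrom, subgenome_pattern))
  counts <- count(fl, .data$lineage)
  skipped <- filter(counts, .data$n < min_copies)
  if (nrow(skipped) > 0) {
    warn(sprintf("lineage(s) with fewer than %d full-length copies skipped: %s",
                 min_copies, paste(skipped$lineage, collapse = ", ")))
  }
  keep <- filter(counts, .data$n >= min_copies)
  if (nrow(keep) < 2) abort("need at least two lineages with enough copies")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_max <- max(keep$n)
  sampled <- purrr::map(setNames(keep$lineage, keep$lineage), function(lg) {
    rows <- fl[fl$lineage == lg, ]
    take <- min(nrow(rows), max(2, round(n_sample * nrow(rows) / n_max)))
    rows <- rows[sample.int(nrow(rows), take), ]
    vapply(seq_len(nrow(rows)), function(i) {
      paste0(seq_region(genome, rows$chrom[i], rows$ltr5_start[i], rows$ltr5_end[i]),
             seq_region(genome, rows$chrom[i], rows$ltr3_start[i], rows$ltr3_end[i]))
    }, character(1))
  })
  lgs <- names(sampled)
  combos <- list()
  for (a in seq_along(lgs)) {
    for (b in a:length(lgs)) {
      combos[[length(combos) + 1]] <- c(a, b)
    }
  }
  dist_tbl <- purrr::map_dfr(combos, function(ab) {
    s1 <- sampled[[ab[1]]]; s2 <- sampled[[ab[2]]]
    within <- ab[1] == ab[2]
    idx <- if (within) {
      t(utils::combn(length(s1), 2))
    } else {
      as.matrix(expand.grid(seq_along(s1), seq_along(s2)))
    }
    if (nrow(idx) > max_pairs) idx <- idx[sample.int(nrow(idx), max_pairs), , drop = FALSE]
    d <- vapply(seq_len(nrow(idx)), function(k) {
      al <- align_pair(s1[idx[k, 1]], s2[idx[k, 2]], type = "global",
                       match = 1L, mismatch = 1L, gap_open = 5L, gap_ext = 1L)
      k2p_or_na(al$aligned_pattern, al$aligned_subject)$distance
    }, double(1))
    tibble(lineage_1 = lgs[ab[1]], lineage_2 = lgs[ab[2]],
           within = within, distance = d)
  })
  n_sat <- sum(is.na(dist_tbl$distance))
  if (all(is.na(dist_tbl$distance))) abort("all pairs saturated")
  modes <- purrr::map_dfr(
    split(dist_tbl, paste(dist_tbl$lineage_1, dist_tbl$lineage_2)),
    function(g) {
      m <- find_density_modes(g$distance, prominence = prominence)$modes
      if (nrow(m) == 0) return(tibble())
      mutate(m, lineage_1 = g$lineage_1[1], lineage_2 = g$lineage_2[1],
             within = g$within[1])
    })
  structure(list(distances = filter(dist_tbl, !is.na(.data$distance)),
                 modes = modes, skipped = rename(skipped, n_copies = "n"),
                 n_saturated = n_sat),
            class = "lineage_distance")
}

#' @export
print.lineage_distance <- function(x, ...) {
  cat(sprintf("Cross-lineage TE distances: %d pairs (%d saturated dropped)\n",
              nrow(x$distances), x$n_saturated))
  if (nrow(x$skipped) > 0) {
    cat("skipped lineages:", paste(x$skipped$lineage, collapse = ", "), "\n")
  }
  invisible(x)
}
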