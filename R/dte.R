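#' Find TE-embedded TFBSs in triad promoters
#'
#' A TE-embedded TFBS is a peak whose summit lies both inside a triad
#' promoter and inside an annotated TE. One row is emitted per (peak, TE,
#' promoter) combination, carrying the TE footprint and a fixed-width TFBS
#' window centered on the peak summit; these rows are the query set of the
#' degenerated-TE search.
#'
#' @param peaks Peak tibble (`tf_id`, `chrom`, `summit`, ...).
#' @param tes TE annotation tibble.
#' @param promoters Promoter tibble: `triad_id`, `subgenome`, `chrom`,
#'   `start`, `end`.
#' @param window TFBS window width in bp (default 60), clipped to the TE.
#' @return Tibble `triad_id`, `tf_id`, `subgenome`, `te_id`, `family`,
#'   `subfamily`, `chrom`, `start`, `end` (TE footprint), `tfbs_start`,
#'   `tfbs_end`.
#' @export
find_te_tfbs <- function(peaks, tes, promoters, window = 60) {
  sgr <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(peaks$summit + 1, peaks$summit + 1))
  in_prom <- GenomicRanges::findOverlaps(sgr, as_gr(promoters))
  in_te <- GenomicRanges::findOverlaps(sgr, as_gr(tes))
  pr <- tibble(peak = S4Vectors::queryHits(in_prom),
               prom = S4Vectors::subjectHits(in_prom))
  tr <- tibble(peak = S4Vectors::queryHits(in_te),
               te = S4Vectors::subjectHits(in_te))
  hits <- inner_join(pr, tr, by = "peak", relationship = "many-to-many")
  if (nrow(hits) == 0) {
    return(tibble(triad_id = character(), tf_id = character(),
                  subgenome = character(), te_id = character(),
                  family = character(), subfamily = character(),
                  chrom = character(), start = integer(), end = integer(),
                  tfbs_start = integer(), tfbs_end = integer()))
  }
  half <- window %/% 2
  out <- tibble(
    triad_id = promoters$triad_id[hits$prom],
    tf_id = peaks$tf_id[hits$peak],
    subgenome = promoters$subgenome[hits$prom],
    te_id = tes$te_id[hits$te],
    family = tes$family[hits$te],
    subfamily = tes$subfamily[hits$te],
    chrom = tes$chrom[hits$te],
    start = tes$start[hits$te],
    end = tes$end[hits$te],
    tfbs_start = pmax(peaks$summit[hits$peak] - half, tes$start[hits$te]),
    tfbs_end = pmin(peaks$summit[hits$peak] + half, tes$end[hits$te])
  )
  distinct(arrange(out, .data$triad_id, .data$tf_id, .data$subgenome, .data$te_id))
}

# Extract a subsequence (0-based half-open coords) as a character string.
seq_region <- function(genome, chrom, start, end) {
  as.character(Biostrings::subseq(genome[[chrom]], start + 1, end))
}

# Align one TE sequence against one promoter sequence on both strands and
# return the best qualifying local alignment, or NULL.
# tfbs_rel: 1-based [w1, w2] window within the forward-oriented TE sequence.
# A shared exact seed k-mer is required per orientation before aligning.
dte_align_one <- function(te_seq, te_seq_rc, prom_seq, tfbs_rel,
                          min_len, min_identity, min_score,
                          match, mismatch, gap_open, gap_ext, seed_k = 12) {
  n <- nchar(te_seq)
  best <- NULL
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") te_seq else te_seq_rc
    win <- if (strand == "+") tfbs_rel else c(n - tfbs_rel[2] + 1, n - tfbs_rel[1] + 1)
    if (!shared_kmer(pat, prom_seq, seed_k)) next
    al <- align_pair(pat, prom_seq, type = "local", match = match,
                     mismatch = mismatch, gap_open = gap_open, gap_ext = gap_ext)
    if (al$score < min_score || al$length < min_len || al$identity < min_identity) next
    if (!is.null(best) && al$score <= best$al$score) next
    best <- list(al = al, strand = strand, win = win)
  }
  if (is.null(best)) return(NULL)
  al <- best$al
  ap <- strsplit(al$aligned_pattern, "", fixed = TRUE)[[1]]
  as_ <- strsplit(al$aligned_subject, "", fixed = TRUE)[[1]]
  pat_pos <- rep(NA_integer_, length(ap))
  pat_pos[ap != "-"] <- seq(al$pattern_start, al$pattern_end)
  in_win <- !is.na(pat_pos) & pat_pos >= best$win[1] & pat_pos <= best$win[2]
  covered <- in_win & as_ != "-"
  win_len <- best$win[2] - best$win[1] + 1
  n_cov <- sum(covered)
  tfbs_identity <- if (n_cov > 0) 100 * sum(ap[covered] == as_[covered]) / n_cov else 0
  tfbs_coverage <- 100 * n_cov / win_len
  list(strand = best$strand, score = al$score,
       alignment_length = al$length, identity = al$identity,
       subject_start = al$subject_start, subject_end = al$subject_end,
       tfbs_coverage = tfbs_coverage, tfbs_identity = tfbs_identity,
       tfbs_conserved = tfbs_coverage >= 70 && tfbs_identity >= 70)
}

#' Detect degenerated TEs (dTEs) in sister triad promoters
#'
#' For every TE-embedded TFBS (from [find_te_tfbs()]), the TE sequence is
#' locally aligned (both orientations) against the promoters of the sister
#' homoeologs of the same triad that lack an annotated copy of the same TE
#' family. Alignable target regions overlapping any annotated TE are
#' discarded; remaining optimal alignments longer than 50 bp that meet the
#' identity and score floors are reported as dTEs. The TFBS window is
#' projected through the alignment columns; it counts as conserved when at
#' least 70% of the window aligns to bases (not gaps) at >= 70% identity.
#'
#' @param te_sites TE-embedded TFBS tibble from [find_te_tfbs()].
#' @param promoters Promoter tibble (`triad_id`, `subgenome`, `chrom`,
#'   `start`, `end`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param tes TE annotation tibble (for family exclusion and target-overlap
#'   removal).
#' @param min_len Minimum alignment length in columns (default 51, i.e.
#'   strictly more than 50 bp).
#' @param min_identity Minimum percent identity within the aligned region
#'   (default 60).
#' @param min_score Minimum optimal local alignment score (default 20); the
#'   deterministic stand-in for a database-size-dependent E-value cutoff.
#' @param match,mismatch,gap_open,gap_ext Alignment scoring (defaults
#'   +1/-2/5/2).
#' @param seed_k Word size of the exact-seed requirement (default 12): a
#'   TE/promoter pair is only aligned in an orientation sharing an exact
#'   k-mer, mirroring BLAST-style word seeding.
#' @return Tibble of dTE hits: `triad_id`, `tf_id`, `source_subgenome`,
#'   `target_subgenome`, `te_id`, `family`, `chrom`, `start`, `end`
#'   (0-based half-open target region), `strand`, `score`,
#'   `alignment_length`, `identity`, `tfbs_coverage`, `tfbs_identity`,
#'   `tfbs_conserved`.
#' @export
find_dte <- function(te_sites, promoters, genome, tes,
                     min_len = 51, min_identity = 60, min_score = 20,
                     match = 1L, mismatch = 2L, gap_open = 5L, gap_ext = 2L,
                     seed_k = 12) {
  te_fp <- flatten_intervals(tes)
  # which promoters carry an annotated copy of which family (computed once)
  pgr <- as_gr(promoters)
  fam_ov <- GenomicRanges::findOverlaps(pgr, as_gr(tes))
  fam_present <- distinct(tibble(
    prom = S4Vectors::queryHits(fam_ov),
    family = tes$family[S4Vectors::subjectHits(fam_ov)]))
  out <- list()
  for (i in seq_len(nrow(te_sites))) {
    site <- te_sites[i, ]
    if (site$end - site$start < 1) next
    te_seq <- seq_region(genome, site$chrom, site$start, site$end)
    te_seq_rc <- revcomp(te_seq)
    tfbs_rel <- c(site$tfbs_start - site$start + 1, site$tfbs_end - site$start)
    cand_idx <- which(promoters$triad_id == site$triad_id &
                        promoters$subgenome != site$subgenome)
    for (j in cand_idx) {
      prom <- promoters[j, ]
      if (prom$end - prom$start < min_len) next
      if (any(fam_present$prom == j & fam_present$family == site$family)) {
        next  # canonical copy of this family present
      }
      prom_seq <- seq_region(genome, prom$chrom, prom$start, prom$end)
      hit <- dte_align_one(te_seq, te_seq_rc, prom_seq, tfbs_rel,
                           min_len, min_identity, min_score,
                           match, mismatch, gap_open, gap_ext, seed_k)
      if (is.null(hit)) next
      tstart <- prom$start + hit$subject_start - 1L
      tend <- prom$start + hit$subject_end
      if (overlaps_any(prom$chrom, tstart, tend, te_fp)) next
      out[[length(out) + 1]] <- tibble(
        triad_id = site$triad_id, tf_id = site$tf_id,
        source_subgenome = site$subgenome, target_subgenome = prom$subgenome,
        te_id = site$te_id, family = site$family,
        chrom = prom$chrom, start = tstart, end = tend,
        strand = hit$strand, score = hit$score,
        alignment_length = hit$alignment_length, identity = hit$identity,
        tfbs_coverage = hit$tfbs_coverage, tfbs_identity = hit$tfbs_identity,
        tfbs_conserved = hit$tfbs_conserved)
    }
  }
  if (length(out) == 0) {
    return(tibble(triad_id = character(), tf_id = character(),
                  source_subgenome = character(), target_subgenome = character(),
                  te_id = character(), family = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  score = integer(), alignment_length = integer(),
                  identity = double(), tfbs_coverage = double(),
                  tfbs_identity = double(), tfbs_conserved = logical()))
  }
  bind_rows(out)
}

#' Independently validate dTE hits
#'
#' Re-measures each reported hit from the genome: re-extracts the TE and the
#' target region, re-aligns them, and re-checks the defining invariants
#' (alignment length > 50 bp, no overlap with annotated TEs, identity above
#' the floor). Used as a post-hoc check that detection output satisfies its
#' own contract.
#'
#' @param hits Output of [find_dte()].
#' @param te_sites,genome,tes As passed to [find_dte()].
#' @param min_len,min_identity As passed to [find_dte()].
#' @return Logical vector, one entry per hit; `TRUE` when all invariants
#'   hold.
#' @export
validate_dte_hits <- function(hits, te_sites, genome, tes,
                              min_len = 51, min_identity = 60) {
  if (nrow(hits) == 0) return(logical(0))
  te_fp <- flatten_intervals(tes)
  vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    if (h$alignment_length < min_len) return(FALSE)
    if (overlaps_any(h$chrom, h$start, h$end, te_fp)) return(FALSE)
    site <- te_sites[te_sites$te_id == h$te_id &
                       te_sites$triad_id == h$triad_id &
                       te_sites$tf_id == h$tf_id &
                       te_sites$subgenome == h$source_subgenome, ][1, ]
    te_seq <- seq_region(genome, site$chrom, site$start, site$end)
    if (h$strand == "-") te_seq <- revcomp(te_seq)
    target <- seq_region(genome, h$chrom, h$start, h$end)
    al <- align_pair(te_seq, target, type = "local")
    al$length >= min_len && al$identity >= min_identity
  }, logical(1))
}

#' Per-triad TE / TE+dTE presence classes
#'
#' For each (triad, TF) with at least one TE-embedded TFBS, counts in how
#' many subgenomes the binding is supported by an annotated TE
#' (`n_subgenomes_te`) and by a TE or a detected dTE relic
#' (`n_subgenomes_te_dte`), joined with the triad's binding-balance pattern.
#'
#' @param patterns Output of [classify_patterns()] (rows with `pattern` not
#'   `NA`).
#' @param te_sites Output of [find_te_tfbs()].
#' @param dte_hits Output of [find_dte()].
#' @return Tibble `triad_id`, `tf_id`, `pattern`, `balanced`,
#'   `n_subgenomes_te`, `n_subgenomes_te_dte`.
#' @export
classify_te_presence <- function(patterns, te_sites, dte_hits) {
  te_pres <- summarise(group_by(te_sites, .data$triad_id, .data$tf_id),
                       te_subs = list(unique(.data$subgenome)), .groups = "drop")
  dte_pres <- summarise(group_by(dte_hits, .data$triad_id, .data$tf_id),
                        dte_subs = list(unique(.data$target_subgenome)),
                        .groups = "drop")
  x <- left_join(te_pres, dte_pres, by = c("triad_id", "tf_id"))
  x <- mutate(x,
              n_subgenomes_te = lengths(.data$te_subs),
              n_subgenomes_te_dte = purrr::map2_int(
                .data$te_subs, .data$dte_subs,
                ~ length(union(.x, .y %||% character(0)))))
  pat <- filter(select(patterns, "triad_id", "tf_id", "pattern"),
                !is.na(.data$pattern))
  x <- inner_join(x, pat, by = c("triad_id", "tf_id"))
  mutate(select(x, -"te_subs", -"dte_subs"),
         balanced = .data$pattern == "ABD")
}

#' Permutation control for dTE detection
#'
#' For each permutation, every TE-embedded TFBS sequence is paired with the
#' promoter of one randomly chosen *different* triad and the exact dTE
#' detection cutoffs of [find_dte()] are applied (both orientations,
#' TE-overlap exclusion, length/identity/score floors). The per-permutation
#' hit counts form the null distribution against which matched sister-pair
#' hits are compared; a fast score-only alignment pass screens pairs below
#' the score floor, which cannot qualify.
#'
#' @inheritParams find_dte
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; the run is reproducible given the same seed.
#' @return Object of class `dte_permutation`: tibble `perm`, `hits` with
#'   attributes `n_sites` and `n_perm`.
#' @export
dte_permutation_control <- function(te_sites, promoters, genome, tes,
                                    n_perm = 1000, seed = 1,
                                    min_len = 51, min_identity = 60,
                                    min_score = 20, match = 1L, mismatch = 2L,
                                    gap_open = 5L, gap_ext = 2L, seed_k = 12) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  n_sites <- nrow(te_sites)
  te_seqs <- character(n_sites); te_rcs <- character(n_sites)
  tfbs_rel <- matrix(0L, n_sites, 2)
  for (i in seq_len(n_sites)) {
    s <- te_sites[i, ]
    te_seqs[i] <- seq_region(genome, s$chrom, s$start, s$end)
    te_rcs[i] <- revcomp(te_seqs[i])
    tfbs_rel[i, ] <- c(s$tfbs_start - s$start + 1, s$tfbs_end - s$start)
  }
  prom_seqs <- vapply(seq_len(nrow(promoters)), function(j) {
    seq_region(genome, promoters$chrom[j], promoters$start[j], promoters$end[j])
  }, character(1))
  te_fp <- flatten_intervals(tes)
  run <- function() {
    hits <- integer(n_perm)
    for (p in seq_len(n_perm)) {
      cnt <- 0L
      for (i in seq_len(n_sites)) {
        pool <- which(promoters$triad_id != te_sites$triad_id[i])
        if (length(pool) == 0) abort("need promoters from at least two triads")
        j <- pool[sample.int(length(pool), 1)]
        fwd_seed <- shared_kmer(te_seqs[i], prom_seqs[j], seed_k)
        rev_seed <- shared_kmer(te_rcs[i], prom_seqs[j], seed_k)
        if (!fwd_seed && !rev_seed) next
        sc <- max(if (fwd_seed) align_score(te_seqs[i], prom_seqs[j], match,
                                            mismatch, gap_open, gap_ext) else 0L,
                  if (rev_seed) align_score(te_rcs[i], prom_seqs[j], match,
                                            mismatch, gap_open, gap_ext) else 0L)
        if (sc < min_score) next
        hit <- dte_align_one(te_seqs[i], te_rcs[i], prom_seqs[j], tfbs_rel[i, ],
                             min_len, min_identity, min_score,
                             match, mismatch, gap_open, gap_ext, seed_k)
        if (is.null(hit)) next
        tstart <- promoters$start[j] + hit$subject_start - 1L
        tend <- promoters$start[j] + hit$subject_end
        if (overlaps_any(promoters$chrom[j], tstart, tend, te_fp)) next
        cnt <- cnt + 1L
      }
      hits[p] <- cnt
    }
    hits
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hits <- run()
  structure(tibble(perm = seq_len(n_perm), hits = hits),
            n_sites = n_sites, n_perm = n_perm, class = c("dte_permutation",
                                                          "tbl_df", "tbl", "data.frame"))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
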