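#' Merge per-TF peaks into maximal binding sites
#'
#' Unions all peak intervals (any >= 1 bp overlap merges; bookended intervals
#' stay separate under the half-open convention) into maximal disjoint merged
#' TFBSs, recording the distinct TFs whose peaks overlap each one.
#'
#' @param peaks Peak tibble with `tf_id`, `chrom`, `start`, `end`.
#' @return Tibble `chrom`, `start`, `end`, `tf_count`, `tf_ids`
#'   (comma-separated sorted TF ids).
#' @export
merge_tfbs <- function(peaks) {
  peaks <- validate_intervals(peaks, "peaks")
  if (nrow(peaks) == 0) abort("merge_tfbs needs at least one peak")
  # min.gapwidth = 0: >= 1 bp of true overlap merges, bookended intervals
  # stay separate (half-open convention)
  merged <- GenomicRanges::reduce(as_gr(peaks), min.gapwidth = 0L)
  ov <- GenomicRanges::findOverlaps(merged, as_gr(peaks))
  tfs <- tibble(site = S4Vectors::queryHits(ov),
                tf_id = peaks$tf_id[S4Vectors::subjectHits(ov)])
  agg <- summarise(group_by(tfs, .data$site),
                   tf_count = dplyr::n_distinct(.data$tf_id),
                   tf_ids = paste(sort(unique(.data$tf_id)), collapse = ","),
                   .groups = "drop")
  out <- gr_tbl(merged)
  out$tf_count <- agg$tf_count[match(seq_len(nrow(out)), agg$site)]
  out$tf_ids <- agg$tf_ids[match(seq_len(nrow(out)), agg$site)]
  arrange(out, .data$chrom, .data$start)
}

#' Call high-occupancy target (HOT) regions
#'
#' A merged TFBS is HOT when it is bound by strictly more than `threshold`
#' distinct TFs (default 12, i.e. >= 13 TFs).
#'
#' @param sites Merged sites from [merge_tfbs()].
#' @param threshold Strict lower bound on the distinct-TF count (>= 1).
#' @return `sites` with an added logical `hot` column.
#' @export
call_hot <- function(sites, threshold = 12) {
  if (threshold < 1) abort("HOT threshold must be >= 1")
  mutate(sites, hot = .data$tf_count > threshold)
}

#' Binarized-bin correlation of TF binding profiles
#'
#' Tiles every chromosome into consecutive `bin_size` bins anchored at
#' coordinate 0 (trailing partial bin kept), marks for each TF whether each
#' bin overlaps at least one peak, and returns the Pearson correlation
#' matrix of these 0/1 profiles together with an average-linkage clustering
#' order on 1 - r distances. TFs whose profile is constant (all-zero or
#' all-one) have undefined correlations, reported as `NA`.
#'
#' @param peaks Peak tibble (`tf_id`, `chrom`, `start`, `end`).
#' @param sizes Chromosome sizes tibble (`chrom`, `length`).
#' @param bin_size Bin width in bp (default 2000).
#' @return Object of class `tf_cor`: list with `r` (correlation matrix),
#'   `order` (TF ids in clustering order), `n_bins`, `bin_size`.
#' @export
tf_binding_correlation <- function(peaks, sizes, bin_size = 2000) {
  tfs <- sort(unique(peaks$tf_id))
  if (length(tfs) < 2) abort("need peaks from at least two TFs")
  bins <- purrr::pmap_dfr(sizes, function(chrom, length) {
    s <- seq(0L, length - 1L, by = bin_size)
    tibble(chrom = chrom, start = s, end = pmin(s + bin_size, length))
  })
  bgr <- as_gr(bins)
  prof <- vapply(tfs, function(tf) {
    as.integer(GenomicRanges::countOverlaps(
      bgr, as_gr(peaks[peaks$tf_id == tf, ])) > 0)
  }, integer(length(bgr)))
  sds <- apply(prof, 2, stats::sd)
  r <- suppressWarnings(stats::cor(prof))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  usable <- which(sds > 0)
  ord <- tfs
  if (length(usable) > 2) {
    hc <- stats::hclust(stats::as.dist(1 - r[usable, usable]), method = "average")
    ord <- c(tfs[usable][hc$order], tfs[sds == 0])
  }
  structure(list(r = r, order = ord, n_bins = nrow(bins), bin_size = bin_size),
            class = "tf_cor")
}

#' @export
print.tf_cor <- function(x, ...) {
  cat(sprintf("TF binding correlation: %d TFs over %d bins of %d bp\n",
              ncol(x$r), x$n_bins, x$bin_size))
  invisible(x)
}

#' Fold enrichment of query intervals in annotation classes
#'
#' For each annotation class, enrichment is the fraction of query bp
#' overlapping the class divided by the class's fraction of the genome:
#' `(query bp in class / total query bp) / (class bp / genome bp)`.
#'
#' @param query Interval tibble (`chrom`, `start`, `end`); overlapping query
#'   intervals are flattened before measuring.
#' @param classes Labeled annotation tibble (`chrom`, `start`, `end`,
#'   `klass`); each class footprint is flattened.
#' @param genome_bp Total genome length in bp.
#' @return Tibble `klass`, `query_bp`, `class_bp`, `enrichment`.
#' @export
interval_enrichment <- function(query, classes, genome_bp) {
  query <- validate_intervals(query, "query")
  qbp <- interval_bp(query)
  if (qbp == 0) abort("empty query")
  kl <- unique(as.character(classes$klass))
  out <- purrr::map_dfr(kl, function(k) {
    cls <- classes[classes$klass == k, ]
    cbp <- interval_bp(cls)
    if (cbp == 0) abort(sprintf("zero-length background class %s", k))
    tibble(klass = k,
           query_bp = overlap_bp(query, cls),
           class_bp = cbp)
  })
  mutate(out, enrichment = (.data$query_bp / qbp) / (.data$class_bp / genome_bp))
}

#' TAD boundary windows and interior/non-TAD partition
#'
#' Builds fixed-width windows centered on every TAD start and end point
#' (default 20 kb), merges overlapping windows (adjacent TADs sharing a
#' boundary yield a single window), and partitions the rest of the genome
#' into TAD-interior and non-TAD regions. Windows clipped at a chromosome
#' end are flagged `truncated`.
#'
#' @param tads TAD interval tibble (`chrom`, `start`, `end`).
#' @param sizes Chromosome sizes tibble (`chrom`, `length`).
#' @param window Window width in bp (default 20000).
#' @return Tibble `chrom`, `start`, `end`, `klass`
#'   (`boundary`/`interior`/`non_tad`), `truncated` (boundary rows only).
#' @export
tad_boundary_windows <- function(tads, sizes, window = 20000) {
  half <- window %/% 2
  lens <- setNames(sizes$length, sizes$chrom)
  if (nrow(tads) > 0) {
    tads <- validate_intervals(tads, "TADs")
    pts <- bind_rows(select(tads, "chrom", pos = "start"),
                     select(tads, "chrom", pos = "end"))
    win <- mutate(pts,
                  raw_start = .data$pos - half, raw_end = .data$pos + half,
                  start = pmax(.data$raw_start, 0L),
                  end = pmin(.data$raw_end, lens[.data$chrom]),
                  truncated = .data$start != .data$raw_start | .data$end != .data$raw_end)
    wgr <- GenomicRanges::reduce(as_gr(win))
    trunc_flags <- GenomicRanges::countOverlaps(
      wgr, as_gr(win[win$truncated, , drop = FALSE])) > 0
    boundary <- mutate(gr_tbl(wgr), klass = "boundary", truncated = trunc_flags)
    tgr <- GenomicRanges::reduce(as_gr(tads))
    interior <- mutate(gr_tbl(GenomicRanges::setdiff(tgr, wgr)),
                       klass = "interior", truncated = NA)
  } else {
    boundary <- tibble(chrom = character(), start = integer(), end = integer(),
                       klass = character(), truncated = logical())
    interior <- boundary
    wgr <- GenomicRanges::GRanges()
    tgr <- GenomicRanges::GRanges()
  }
  ggr <- GenomicRanges::GRanges(sizes$chrom, IRanges::IRanges(1, sizes$length))
  covered <- GenomicRanges::reduce(c(GenomicRanges::granges(wgr),
                                     GenomicRanges::granges(tgr)))
  non_tad <- mutate(gr_tbl(GenomicRanges::setdiff(ggr, covered)),
                    klass = "non_tad", truncated = NA)
  out <- bind_rows(boundary, interior, non_tad)
  out$klass <- factor(out$klass, levels = c("boundary", "interior", "non_tad"))
  arrange(out, .data$chrom, .data$start)
}
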