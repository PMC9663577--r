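#' Select TE subfamilies by genome share
#'
#' Keeps TE subfamilies whose flattened footprint exceeds `min_fraction` of
#' the genome (default 0.1%).
#'
#' @param tes TE annotation tibble (see [read_te_table()]).
#' @param genome_bp Genome length in bp.
#' @param min_fraction Strict lower bound on genome fraction (default 0.001).
#' @return Tibble `subfamily`, `family`, `subfamily_bp`, `fraction` for
#'   selected subfamilies.
#' @export
select_subfamilies <- function(tes, genome_bp, min_fraction = 0.001) {
  fams <- distinct(tes, .data$subfamily, .data$family)
  bp <- purrr::map_dbl(fams$subfamily,
                       function(sf) interval_bp(tes[tes$subfamily == sf, ]))
  out <- mutate(fams, subfamily_bp = bp, fraction = bp / genome_bp)
  arrange(filter(out, .data$fraction > min_fraction), .data$subfamily)
}

#' TE-subfamily enrichment score of query intervals
#'
#' For query intervals (e.g. one TF's peaks) and each TE subfamily, the
#' enrichment score is
#' `ES = (query bp in subfamily / total query bp) /
#'       (subfamily bp / total TE bp)`,
#' all lengths measured in base pairs on flattened footprints. With
#' `background = "nondegenerated"` the denominator lengths (subfamily bp and
#' total TE bp) are computed from non-degenerated elements only -- the
#' background used when the query derives from degenerated-TE relics --
#' while the numerator still uses every element of the subfamily.
#'
#' @param query Interval tibble (`chrom`, `start`, `end`).
#' @param tes TE annotation tibble with `subfamily` and (optionally)
#'   `degenerated` columns.
#' @param subfamilies Character vector of subfamilies to score (default: all
#'   in `tes`).
#' @param background `"all"` or `"nondegenerated"`.
#' @param query_label Label copied into the output (e.g. the TF id).
#' @return Tibble `query_label`, `subfamily`, `es`, `query_bp_in_subfamily`,
#'   `query_bp_total`, `subfamily_bp`, `te_bp_total`. `es` is `NA` when a
#'   subfamily has no background footprint.
#' @export
enrichment_score <- function(query, tes, subfamilies = NULL,
                             background = c("all", "nondegenerated"),
                             query_label = "query") {
  background <- match.arg(background)
  query <- validate_intervals(query, "query")
  if (!"degenerated" %in% names(tes)) tes$degenerated <- FALSE
  if (is.null(subfamilies)) subfamilies <- sort(unique(tes$subfamily))
  bg <- if (background == "nondegenerated") tes[!tes$degenerated, ] else tes
  qbp <- interval_bp(query)
  if (qbp == 0) abort("empty query")
  te_bp_total <- interval_bp(bg)
  out <- purrr::map_dfr(subfamilies, function(sf) {
    num_fp <- tes[tes$subfamily == sf, ]
    bg_bp <- interval_bp(bg[bg$subfamily == sf, ])
    tibble(query_label = query_label,
           subfamily = sf,
           query_bp_in_subfamily = overlap_bp(query, num_fp),
           query_bp_total = qbp,
           subfamily_bp = bg_bp,
           te_bp_total = te_bp_total)
  })
  mutate(out, es = ifelse(
    .data$subfamily_bp > 0,
    (.data$query_bp_in_subfamily / .data$query_bp_total) /
      (.data$subfamily_bp / .data$te_bp_total),
    NA_real_))
}

#' Fraction of TFBSs overlapping TEs
#'
#' Midpoint rule (consistent with [locate_in_classes()]): a TFBS counts as
#' TE-overlapping when its midpoint lies inside the flattened TE footprint.
#'
#' @param tfbs Interval tibble (`chrom`, `start`, `end`).
#' @param tes TE annotation tibble.
#' @return Fraction in `[0, 1]` (`NaN` for an empty query).
#' @export
te_overlap_fraction <- function(tfbs, tes) {
  if (nrow(tfbs) == 0) return(NaN)
  mid <- tfbs$start + (tfbs$end - tfbs$start) %/% 2L
  mgr <- GenomicRanges::GRanges(tfbs$chrom, IRanges::IRanges(mid + 1, mid + 1))
  fp <- GenomicRanges::reduce(as_gr(tes))
  mean(GenomicRanges::countOverlaps(mgr, fp) > 0)
}
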