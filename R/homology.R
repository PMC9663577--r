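#' Classify genomic regions by subgenome homology
#'
#' From reciprocal whole-genome alignment blocks between the three
#' subgenomes, classifies every base of every chromosome as
#' subgenome-specific (`specific`, alignable to neither other subgenome),
#' `homo2` (reciprocally alignable to exactly one) or `homo3` (to both).
#' `homo3` runs falling inside a synteny block are additionally reported as
#' `homoeo3` (syntenic homo3); these rows overlap the `homo3` rows rather
#' than replacing them, so `specific`/`homo2`/`homo3` always partition the
#' genome.
#'
#' "Reciprocally alignable" between chromosomes of subgenomes X and Y is
#' operationalized as the intersection of the X->Y block footprint on X with
#' the subject footprint of the Y->X blocks on X; runs longer than `min_len`
#' bp (default 400) count.
#'
#' @param blocks Alignment-block tibble (see [read_alignment_blocks()])
#'   covering both directions of every subgenome pair.
#' @param sizes Chromosome sizes tibble (`chrom`, `length`), e.g. from
#'   [chrom_sizes()].
#' @param synteny Optional tibble of synteny-block intervals (`chrom`,
#'   `start`, `end`).
#' @param min_len Minimum reciprocal run length in bp; runs must be strictly
#'   longer to count (default 400).
#' @param subgenome_pattern Passed to [subgenome_of()].
#' @return Tibble `chrom`, `start`, `end`, `klass` with
#'   `klass` in `specific`, `homo2`, `homo3`, `homoeo3`.
#' @export
classify_regions <- function(blocks, sizes, synteny = NULL, min_len = 400,
                             subgenome_pattern = "([ABD])$") {
  blocks <- validate_alignment_blocks(blocks)
  qsub <- subgenome_of(blocks$query_chrom, subgenome_pattern)
  ssub <- subgenome_of(blocks$subject_chrom, subgenome_pattern)
  subs <- sort(unique(c(qsub, ssub, subgenome_of(sizes$chrom, subgenome_pattern))))
  dirs <- unique(paste(qsub, ssub))
  for (g in subs) for (h in subs) {
    if (g < h) {
      for (d in c(paste(g, h), paste(h, g))) {
        if (!d %in% dirs) {
          abort(sprintf("missing alignment direction %s -> %s",
                        sub(" .*", "", d), sub(".* ", "", d)))
        }
      }
    }
  }
  out <- list()
  for (ci in seq_len(nrow(sizes))) {
    cname <- sizes$chrom[ci]
    clen <- sizes$length[ci]
    g <- subgenome_of(cname, subgenome_pattern)
    others <- setdiff(subs, g)
    rec <- lapply(others, function(h) {
      fwd <- blocks[blocks$query_chrom == cname & ssub == h, ]
      rev <- blocks[qsub == h & blocks$subject_chrom == cname, ]
      fwd_ir <- IRanges::reduce(IRanges::IRanges(fwd$query_start + 1, fwd$query_end))
      rev_ir <- IRanges::reduce(IRanges::IRanges(rev$subject_start + 1, rev$subject_end))
      runs <- IRanges::intersect(fwd_ir, rev_ir)
      runs[IRanges::width(runs) > min_len]
    })
    homo3 <- IRanges::intersect(rec[[1]], rec[[2]])
    any_rec <- IRanges::reduce(c(rec[[1]], rec[[2]]))
    homo2 <- IRanges::setdiff(any_rec, homo3)
    chrom_ir <- IRanges::IRanges(1, clen)
    specific <- IRanges::setdiff(chrom_ir, any_rec)
    res <- bind_rows(
      ir_tbl(cname, specific, "specific"),
      ir_tbl(cname, homo2, "homo2"),
      ir_tbl(cname, homo3, "homo3"))
    if (!is.null(synteny) && nrow(synteny) > 0) {
      syn <- synteny[synteny$chrom == cname, ]
      if (nrow(syn) > 0) {
        syn_ir <- IRanges::reduce(IRanges::IRanges(syn$start + 1, syn$end))
        res <- bind_rows(res, ir_tbl(cname, IRanges::intersect(homo3, syn_ir),
                                     "homoeo3"))
      }
    }
    out[[ci]] <- res
  }
  res <- bind_rows(out)
  res$klass <- factor(res$klass, levels = c("specific", "homo2", "homo3", "homoeo3"))
  arrange(res, .data$chrom, .data$start, .data$klass)
}

ir_tbl <- function(chrom, ir, klass) {
  if (length(ir) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  klass = character()))
  }
  tibble(chrom = chrom, start = IRanges::start(ir) - 1L,
         end = IRanges::end(ir), klass = klass)
}

#' Locate query intervals in homology classes
#'
#' Labels each query interval (e.g. a TFBS) with the homology class of its
#' midpoint (default), or with the class holding the majority of its bases.
#' The `homoeo3` flag records whether the midpoint additionally falls in a
#' syntenic homo3 region.
#'
#' @param query Interval tibble (`chrom`, `start`, `end`).
#' @param classes Output of [classify_regions()].
#' @param method `"midpoint"` (deterministic for straddling features) or
#'   `"majority"` (largest bp overlap; ties to the earlier class level).
#' @return `query` with added `klass` (factor) and `homoeo3` (logical)
#'   columns; queries on chromosomes absent from `classes` raise an error.
#' @export
locate_in_classes <- function(query, classes, method = c("midpoint", "majority")) {
  method <- match.arg(method)
  query <- validate_intervals(query, "query")
  off <- setdiff(unique(query$chrom), unique(classes$chrom))
  if (length(off) > 0) {
    abort(sprintf("query chromosome(s) not covered by classes: %s",
                  paste(off, collapse = ", ")))
  }
  part_lv <- c("specific", "homo2", "homo3")
  part <- classes[classes$klass %in% part_lv, ]
  syn <- classes[classes$klass == "homoeo3", ]
  if (nrow(query) == 0) {
    return(mutate(query, klass = factor(character(), levels = part_lv),
                  homoeo3 = logical()))
  }
  if (method == "midpoint") {
    mid <- query$start + (query$end - query$start) %/% 2L
    mgr <- GenomicRanges::GRanges(query$chrom, IRanges::IRanges(mid + 1, mid + 1))
    hit <- GenomicRanges::findOverlaps(mgr, as_gr(part), select = "first")
    klass <- as.character(part$klass[hit])
    h3 <- rep(FALSE, nrow(query))
    if (nrow(syn) > 0) {
      h3 <- GenomicRanges::countOverlaps(mgr, as_gr(syn)) > 0
    }
  } else {
    qgr <- as_gr(query)
    ov <- GenomicRanges::findOverlaps(qgr, as_gr(part))
    w <- GenomicRanges::width(IRanges::pintersect(
      qgr[S4Vectors::queryHits(ov)], as_gr(part)[S4Vectors::subjectHits(ov)]))
    tab <- tibble(q = S4Vectors::queryHits(ov),
                  klass = factor(as.character(part$klass[S4Vectors::subjectHits(ov)]),
                                 levels = part_lv),
                  w = w)
    best <- summarise(group_by(arrange(tab, .data$q, .data$klass), .data$q),
                      klass = as.character(.data$klass[which.max(.data$w)]),
                      .groups = "drop")
    klass <- rep(NA_character_, nrow(query))
    klass[best$q] <- best$klass
    h3 <- rep(FALSE, nrow(query))
    if (nrow(syn) > 0) {
      h3 <- GenomicRanges::countOverlaps(qgr, as_gr(syn)) > 0
    }
  }
  mutate(query, klass = factor(klass, levels = part_lv), homoeo3 = h3)
}

#' Per-class fractions of located queries
#'
#' @param located Output of [locate_in_classes()].
#' @return Tibble `klass`, `n`, `fraction`.
#' @export
class_fractions <- function(located) {
  if (nrow(located) == 0) {
    return(tibble(klass = factor(character(), levels = c("specific", "homo2", "homo3")),
                  n = integer(), fraction = double()))
  }
  out <- count(located, .data$klass, .drop = FALSE)
  mutate(out, fraction = .data$n / sum(.data$n))
}
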