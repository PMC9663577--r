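#' Genomic interval conventions
#'
#' All positional data in polytereg live in plain tibbles with columns
#' `chrom`, `start`, `end` using 0-based half-open coordinates (the BED
#' convention). GFF3 input is converted at the boundary by [read_gff_genes()].
#' The subgenome of a feature is derived from the chromosome name suffix
#' (e.g. `"chr1A"` is subgenome `"A"`), configurable through the
#' `subgenome_pattern` argument of the functions that need it.
#'
#' @name interval-conventions
NULL

#' Validate an interval tibble
#'
#' Checks the core interval invariants: non-empty chromosome names,
#' `start >= 0` and `end > start`. Called by every reader; exported so that
#' synthetic datasets and hand-built tibbles can be checked the same way.
#'
#' @param x Data frame with `chrom`, `start`, `end` columns.
#' @param what Label used in error messages.
#' @return `x` invisibly, as a tibble.
#' @export
validate_intervals <- function(x, what = "interval") {
  x <- as_tibble(x)
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s table lacks column(s): %s", what,
                  paste(missing_cols, collapse = ", ")))
  }
  bad <- which(is.na(x$chrom) | !nzchar(x$chrom))
  if (length(bad) > 0) {
    abort(sprintf("%s: empty chromosome name at row(s) %s", what,
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(x$start < 0 | x$end <= x$start)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: invalid coordinates (need 0 <= start < end) at row(s) %s",
      what, paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(x)
}

#' Parse the subgenome letter from chromosome names
#'
#' @param chrom Character vector of chromosome names.
#' @param subgenome_pattern Regular expression whose first capture group is
#'   the subgenome label. The default takes the trailing A/B/D letter, which
#'   mirrors common polyploid naming (e.g. IWGSC "1A".."7D").
#' @return Character vector of subgenome labels; errors if any name does not
#'   match.
#' @export
#' @examples
#' subgenome_of(c("chr1A", "chr1B", "chr1D"))
subgenome_of <- function(chrom, subgenome_pattern = "([ABD])$") {
  m <- stringr::str_match(chrom, subgenome_pattern)[, 2]
  if (anyNA(m)) {
    abort(sprintf("cannot derive subgenome from chromosome name(s): %s",
                  paste(unique(chrom[is.na(m)]), collapse = ", ")))
  }
  m
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

# GRanges -> tibble (0-based half-open)
gr_tbl <- function(gr) {
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

# flatten (union) intervals of a tibble, per chromosome
flatten_intervals <- function(x) {
  if (nrow(x) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  gr_tbl(GenomicRanges::reduce(as_gr(x)))
}

# total bp of a flattened interval tibble
interval_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  f <- flatten_intervals(x)
  sum(f$end - f$start)
}

# does [start, end) on chrom overlap any interval of tbl? (plain arithmetic;
# avoids GRanges seqlevel bookkeeping in hot loops)
overlaps_any <- function(chrom, start, end, tbl) {
  if (nrow(tbl) == 0) return(FALSE)
  any(tbl$chrom == chrom & tbl$start < end & tbl$end > start)
}

# bp overlap between two interval sets (both flattened first)
overlap_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ov <- GenomicRanges::intersect(GenomicRanges::reduce(as_gr(a)),
                                 GenomicRanges::reduce(as_gr(b)))
  sum(GenomicRanges::width(ov))
}
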