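#' Read a narrowPeak or BED6+summit peak file
#'
#' Reads the ENCODE narrowPeak format (10 tab-separated columns) used for
#' DAP-seq peak sets. Coordinates are kept 0-based half-open. The absolute
#' summit position is `start + peak_offset`; an unknown summit (offset `-1`)
#' falls back to the interval midpoint so that downstream affinity scores
#' remain computable. The normalized read density (`rpkm`) is taken from the
#' signalValue column by default; which column feeds it is exposed because
#' peak callers differ in what they store there.
#'
#' @param path Path to a narrowPeak file.
#' @param tf_id Identifier of the transcription factor the peaks belong to.
#' @param signal_col Column used as normalized read density: `"signalValue"`
#'   (7th), `"pValue"` (8th), `"qValue"` (9th) or `"score"` (5th).
#' @return Tibble with columns `tf_id`, `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `rpkm`, `summit` (absolute bp).
#' @export
read_narrowpeak <- function(path, tf_id,
                            signal_col = c("signalValue", "pValue", "qValue", "score")) {
  signal_col <- match.arg(signal_col)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(tf_id = character(), chrom = character(), start = integer(),
                  end = integer(), name = character(), score = double(),
                  strand = character(), rpkm = double(), summit = integer()))
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  bad <- which(nf != 10)
  if (length(bad) > 0) {
    abort(sprintf("malformed narrowPeak line %d in %s: expected 10 fields, found %d",
                  bad[1], path, nf[bad[1]]))
  }
  m <- do.call(rbind, fields)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      abort(sprintf("malformed narrowPeak line %d in %s: non-numeric %s",
                    which(is.na(v))[1], path, what))
    }
    v
  }
  x <- tibble(
    tf_id = tf_id,
    chrom = m[, 1],
    start = as.integer(num(2, "start")),
    end = as.integer(num(3, "end")),
    name = m[, 4],
    score = num(5, "score"),
    strand = m[, 6],
    signalValue = num(7, "signalValue"),
    pValue = num(8, "pValue"),
    qValue = num(9, "qValue"),
    peak = as.integer(num(10, "summit offset"))
  )
  validate_intervals(x, what = sprintf("peaks[%s]", path))
  x$rpkm <- x[[signal_col]]
  if (any(x$rpkm < 0)) {
    abort(sprintf("negative signal (%s) at line %d of %s",
                  signal_col, which(x$rpkm < 0)[1], path))
  }
  x$summit <- ifelse(x$peak < 0,
                     x$start + (x$end - x$start) %/% 2L,
                     x$start + x$peak)
  bad <- which(x$summit < x$start | x$summit >= x$end)
  if (length(bad) > 0) {
    abort(sprintf("summit outside peak interval at line %d of %s", bad[1], path))
  }
  x$summit <- as.integer(x$summit)
  select(x, "tf_id", "chrom", "start", "end", "name", "score", "strand",
         "rpkm", "summit")
}

#' Write peaks as narrowPeak
#'
#' Inverse of [read_narrowpeak()] (with `rpkm` stored in signalValue);
#' rows are emitted in deterministic (chrom, start, name) order.
#'
#' @param peaks Peak tibble as returned by [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  peaks <- arrange(peaks, .data$chrom, .data$start, .data$name)
  out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t-1\t-1\t%d",
                 peaks$chrom, peaks$start, peaks$end, peaks$name,
                 format(peaks$score, trim = TRUE, scientific = FALSE),
                 peaks$strand,
                 format(peaks$rpkm, trim = TRUE, scientific = FALSE),
                 peaks$summit - peaks$start)
  readr::write_lines(out, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Extracts `gene` features, converting the 1-based inclusive GFF coordinates
#' to the package's 0-based half-open convention. The TSS is the `start` of
#' the converted interval on "+" genes and `end - 1` on "-" genes.
#'
#' @param path Path to a GFF3 file.
#' @param subgenome_pattern Passed to [subgenome_of()].
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`,
#'   `subgenome`.
#' @export
read_gff_genes <- function(path, subgenome_pattern = "([ABD])$") {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  bad <- which(nf != 9)
  if (length(bad) > 0) {
    abort(sprintf("malformed GFF3 line %d in %s: expected 9 fields", bad[1], path))
  }
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) {
    return(tibble(gene_id = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character(), tss = integer(),
                  subgenome = character()))
  }
  ids <- stringr::str_match(m[, 9], "(?:^|;)ID=([^;]+)")[, 2]
  if (anyNA(ids)) {
    i <- which(is.na(ids))[1]
    abort(sprintf("gene feature without ID attribute in %s: %s %s..%s",
                  path, m[i, 1], m[i, 4], m[i, 5]))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene ID(s) in %s: %s", path,
                  paste(unique(dup), collapse = ", ")))
  }
  start1 <- as.integer(m[, 4])
  end1 <- as.integer(m[, 5])
  strand <- m[, 7]
  if (!all(strand %in% c("+", "-"))) {
    abort(sprintf("gene with strand other than +/- in %s", path))
  }
  x <- tibble(
    gene_id = ids,
    chrom = m[, 1],
    start = start1 - 1L,
    end = end1,
    strand = strand,
    tss = ifelse(strand == "+", start1 - 1L, end1 - 1L)
  )
  validate_intervals(x, what = sprintf("genes[%s]", path))
  x$tss <- as.integer(x$tss)
  x$subgenome <- subgenome_of(x$chrom, subgenome_pattern)
  x
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff_genes()]: converts back to 1-based inclusive
#' coordinates exactly.
#'
#' @param genes Gene tibble as returned by [read_gff_genes()].
#' @param path Output path.
#' @param source Value of the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path, source = "polytereg") {
  genes <- arrange(genes, .data$chrom, .data$start, .data$gene_id)
  out <- c("##gff-version 3",
           sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, source, genes$start + 1L, genes$end,
                   genes$strand, genes$gene_id))
  readr::write_lines(out, path)
  invisible(path)
}

#' Read a transposable-element annotation table
#'
#' Tab-separated TE annotation with columns `chrom`, `start`, `end`,
#' `strand`, `family`, `subfamily`, `full_length`, `ltr5_start`, `ltr5_end`,
#' `ltr3_start`, `ltr3_end` (LTR columns empty/NA for non-full-length
#' elements) and optionally `te_id`. Enforces the structural invariants:
#' full-length elements carry both LTRs, non-overlapping and inside the
#' element; the subfamily name extends the family name.
#'
#' @param path Path to the TE table.
#' @return Tibble with a `te_id` column (generated when absent) and a
#'   `degenerated` column initialised to `FALSE` (annotated elements are by
#'   definition not degenerated relics).
#' @export
read_te_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         start = readr::col_integer(),
                         end = readr::col_integer(),
                         strand = readr::col_character(),
                         family = readr::col_character(),
                         subfamily = readr::col_character(),
                         full_length = readr::col_logical(),
                         ltr5_start = readr::col_integer(),
                         ltr5_end = readr::col_integer(),
                         ltr3_start = readr::col_integer(),
                         ltr3_end = readr::col_integer(),
                         .default = readr::col_guess()
                       ))
  validate_te_table(x, what = sprintf("TE table [%s]", path))
}

#' Validate a TE annotation tibble
#'
#' @param x TE tibble (see [read_te_table()] for columns).
#' @param what Label for error messages.
#' @return The validated tibble (with `te_id` and `degenerated` filled in).
#' @export
validate_te_table <- function(x, what = "TE table") {
  x <- validate_intervals(as_tibble(x), what = what)
  if (!"te_id" %in% names(x)) {
    x <- mutate(x, te_id = sprintf("TE%06d", dplyr::row_number()))
  }
  if (!"degenerated" %in% names(x)) x$degenerated <- FALSE
  bad <- which(!startsWith(x$subfamily, x$family))
  if (length(bad) > 0) {
    abort(sprintf("%s: subfamily name does not extend family name at row %d",
                  what, bad[1]))
  }
  fl <- which(x$full_length)
  if (length(fl) > 0) {
    y <- x[fl, ]
    miss <- is.na(y$ltr5_start) | is.na(y$ltr5_end) | is.na(y$ltr3_start) |
      is.na(y$ltr3_end)
    if (any(miss)) {
      abort(sprintf("%s: full-length element without both LTRs at row %d",
                    what, fl[which(miss)[1]]))
    }
    inside <- y$ltr5_start >= y$start & y$ltr5_end <= y$end &
      y$ltr3_start >= y$start & y$ltr3_end <= y$end &
      y$ltr5_start < y$ltr5_end & y$ltr3_start < y$ltr3_end
    if (any(!inside)) {
      abort(sprintf("%s: LTR outside element at row %d", what, fl[which(!inside)[1]]))
    }
    disjoint <- y$ltr5_end <= y$ltr3_start | y$ltr3_end <= y$ltr5_start
    if (any(!disjoint)) {
      abort(sprintf("%s: overlapping LTR pair at row %d", what, fl[which(!disjoint)[1]]))
    }
  }
  x
}

#' Read reciprocal alignment blocks
#'
#' Coords-style tabular alignment blocks with columns `query_chrom`,
#' `query_start`, `query_end`, `subject_chrom`, `subject_start`,
#' `subject_end`, `identity` (percent). Coordinates 0-based half-open.
#'
#' @param path Path to the block table.
#' @return Validated tibble.
#' @export
read_alignment_blocks <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_alignment_blocks(x, what = sprintf("alignment blocks [%s]", path))
}

#' Validate alignment blocks
#' @param x Block tibble.
#' @param what Label for error messages.
#' @return The validated tibble.
#' @export
validate_alignment_blocks <- function(x, what = "alignment blocks") {
  x <- as_tibble(x)
  validate_intervals(
    tibble(chrom = x$query_chrom, start = x$query_start, end = x$query_end),
    what = paste(what, "(query)"))
  validate_intervals(
    tibble(chrom = x$subject_chrom, start = x$subject_start, end = x$subject_end),
    what = paste(what, "(subject)"))
  if (any(x$identity < 0 | x$identity > 100)) {
    abort(sprintf("%s: identity outside [0, 100]", what))
  }
  x
}

#' Read a 1:1:1 triad table
#'
#' @param path TSV with columns `triad_id`, `gene_A`, `gene_B`, `gene_D`.
#' @return Tibble.
#' @export
read_triads <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("triad_id", "gene_A", "gene_B", "gene_D")
  if (!all(req %in% names(x))) {
    abort(sprintf("triad table %s lacks columns %s", path,
                  paste(setdiff(req, names(x)), collapse = ", ")))
  }
  as_tibble(x)
}

#' Read an expression (TPM) table
#'
#' @param path TSV with columns `gene_id`, `tpm`.
#' @return Tibble; errors on negative TPM.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (any(x$tpm < 0)) abort(sprintf("negative TPM in %s", path))
  as_tibble(x)
}

#' Read a BED3/BED6 file
#'
#' @param path Path to a BED file.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  names(x) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(x))]
  validate_intervals(as_tibble(x), what = sprintf("BED [%s]", path))
  as_tibble(x)
}

#' Write a result table deterministically
#'
#' TSV with header; rows sorted by `chrom`, `start` when present, then by all
#' remaining columns left to right, so repeated runs produce byte-identical
#' files.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  x <- as_tibble(x)
  keys <- c(intersect(c("chrom", "start", "end"), names(x)),
            setdiff(names(x), c("chrom", "start", "end")))
  x <- arrange(x, !!!rlang::syms(keys))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read genome sequences from FASTA files
#'
#' @param paths One or more FASTA paths; sequences are concatenated into one
#'   named set.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(paths) {
  seqs <- do.call(c, lapply(paths, Biostrings::readDNAStringSet))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Chromosome sizes of a genome
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @return Tibble with `chrom`, `length`.
#' @export
chrom_sizes <- function(genome) {
  if (is.character(genome)) {
    tibble(chrom = names(genome), length = nchar(genome))
  } else {
    tibble(chrom = names(genome), length = Biostrings::width(genome))
  }
}
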