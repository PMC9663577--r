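#' TF affinity score (TFAS) of genes from promoter peaks
#'
#' For each gene and transcription factor, TFAS is the sum over promoter
#' peaks of the peak's normalized read density weighted by an exponential
#' decay of the summit-to-TSS distance:
#' \deqn{\mathrm{TFAS} = \sum_{k=1}^{n} \mathrm{rpkm}_k \, e^{-d_k / 2000}}
#' The promoter is the 5-kb window centered on the TSS (summits with
#' \eqn{|d| \le} `half_width` qualify); genes with no qualifying peak score 0.
#'
#' @param genes Gene tibble (see [read_gff_genes()]): `gene_id`, `chrom`,
#'   `tss`.
#' @param peaks Peak tibble (see [read_narrowpeak()]): `tf_id`, `chrom`,
#'   `summit`, `rpkm`.
#' @param half_width Promoter half-width in bp (default 2500).
#' @param decay Exponential decay scale in bp (default 2000).
#' @return Tibble `tf_id`, `gene_id`, `tfas`, `n_peaks` with one row per
#'   (TF, gene) combination, including zero rows.
#' @export
compute_tfas <- function(genes, peaks, half_width = 2500, decay = 2000) {
  if (any(peaks$rpkm < 0)) abort("negative rpkm in peak table")
  g <- select(genes, "gene_id", "chrom", "tss")
  p <- select(peaks, "tf_id", "chrom", "summit", "rpkm")
  hits <- inner_join(g, p, by = "chrom", relationship = "many-to-many")
  hits <- filter(hits, abs(.data$summit - .data$tss) <= half_width)
  scored <- summarise(
    group_by(hits, .data$tf_id, .data$gene_id),
    tfas = sum(.data$rpkm * exp(-abs(.data$summit - .data$tss) / decay)),
    n_peaks = dplyr::n(), .groups = "drop")
  grid <- tidyr::expand_grid(tf_id = sort(unique(peaks$tf_id)),
                             gene_id = g$gene_id)
  out <- left_join(grid, scored, by = c("tf_id", "gene_id"))
  mutate(out,
         tfas = tidyr::replace_na(.data$tfas, 0),
         n_peaks = tidyr::replace_na(.data$n_peaks, 0L))
}

#' The seven standard triad binding patterns
#'
#' Standard TFAS proportion coordinates for balanced (`ABD`), one-suppressed
#' (`AB`, `AD`, `BD`) and one-dominant (`A`, `B`, `D`) triad binding.
#' Thirds are exact (1/3, not the displayed 0.33) so each row sums to 1.
#'
#' @return A 7 x 3 numeric matrix with rownames in tie-break priority order
#'   `ABD, AB, AD, BD, A, B, D` and columns `A`, `B`, `D`.
#' @export
pattern_standards <- function() {
  m <- rbind(
    ABD = c(1, 1, 1) / 3,
    AB = c(0.5, 0.5, 0),
    AD = c(0.5, 0, 0.5),
    BD = c(0, 0.5, 0.5),
    A = c(1, 0, 0),
    B = c(0, 1, 0),
    D = c(0, 0, 1)
  )
  colnames(m) <- c("A", "B", "D")
  m
}

#' Nearest standard pattern for proportion vectors
#'
#' Assigns each proportion triple to the closest of the seven standard
#' patterns by Euclidean distance. Exact ties are broken by the fixed
#' priority `ABD > AB > AD > BD > A > B > D`.
#'
#' @param props Numeric matrix (n x 3) or length-3 vector of nonnegative
#'   proportions (rows should sum to 1).
#' @return Tibble with `pattern` (factor in priority order) and `distance`.
#' @export
#' @examples
#' nearest_pattern(c(0.6, 0.3, 0.1))
nearest_pattern <- function(props) {
  if (is.null(dim(props))) props <- matrix(props, nrow = 1)
  stopifnot(ncol(props) == 3)
  if (any(props < 0)) abort("proportions must be nonnegative")
  std <- pattern_standards()
  d2 <- outer(rowSums(props^2), rep(1, 7)) -
    2 * props %*% t(std) +
    outer(rep(1, nrow(props)), rowSums(std^2))
  d2[d2 < 0] <- 0  # numerical noise
  idx <- max.col(-d2, ties.method = "first")
  tibble(pattern = factor(rownames(std)[idx], levels = rownames(std)),
         distance = sqrt(d2[cbind(seq_len(nrow(props)), idx)]))
}

#' Classify triads into the seven binding-balance patterns
#'
#' Joins per-gene TFAS onto triads, filters triads where all three genes
#' score below `min_tfas` for the TF, normalizes the remaining TFAS triples
#' to proportions and assigns the nearest standard pattern
#' ([nearest_pattern()]).
#'
#' @param tfas TFAS tibble from [compute_tfas()].
#' @param triads Triad tibble: `triad_id`, `gene_A`, `gene_B`, `gene_D`.
#' @param min_tfas Filter threshold (default 0.25): triads with all three
#'   TFAS below it are marked `filtered` and get no pattern.
#' @return Tibble with one row per (triad, TF): TFAS triple, `filtered`,
#'   proportions, `pattern`, `distance` (`NA` for filtered rows).
#' @export
classify_patterns <- function(tfas, triads, min_tfas = 0.25) {
  if (any(tfas$tfas < 0)) abort("negative TFAS")
  pull_sub <- function(gene_col, out) {
    x <- left_join(
      select(triads, "triad_id", gene_id = dplyr::all_of(gene_col)),
      select(tfas, "tf_id", "gene_id", "tfas"),
      by = "gene_id", relationship = "many-to-many")
    setNames(select(x, "triad_id", "tf_id", "tfas"),
             c("triad_id", "tf_id", out))
  }
  x <- inner_join(pull_sub("gene_A", "tfas_A"), pull_sub("gene_B", "tfas_B"),
                  by = c("triad_id", "tf_id"))
  x <- inner_join(x, pull_sub("gene_D", "tfas_D"), by = c("triad_id", "tf_id"))
  x <- filter(x, !is.na(.data$tf_id))
  x <- mutate(x, filtered = .data$tfas_A < min_tfas & .data$tfas_B < min_tfas &
                .data$tfas_D < min_tfas)
  tot <- with(x, tfas_A + tfas_B + tfas_D)
  props <- cbind(x$tfas_A, x$tfas_B, x$tfas_D) / ifelse(tot > 0, tot, 1)
  np <- nearest_pattern(props)
  x <- mutate(x,
              prop_A = props[, 1], prop_B = props[, 2], prop_D = props[, 3],
              pattern = dplyr::if_else(.data$filtered, factor(NA, levels = levels(np$pattern)),
                                       np$pattern),
              distance = dplyr::if_else(.data$filtered, NA_real_, np$distance))
  x
}

#' Regulatory divergence of homoeologous gene pairs
#'
#' For each 1:1 orthologous pair, sums over qualifying TFs the absolute
#' log2 fold-change of promoter binding density. A TF qualifies for a pair
#' when at least one of the two genes has TFAS above `min_tfas`. A symmetric
#' pseudocount is always added to both densities so the measure is defined
#' and bounded when one side is zero.
#'
#' @param pairs Tibble with one row per (pair, TF): `pair_id`, `tf_id`,
#'   `value_1`, `value_2` (promoter binding densities) and `tfas_1`,
#'   `tfas_2`.
#' @param eps Pseudocount (default 0.5) added to both values.
#' @param min_tfas Qualification threshold (default 0.25).
#' @return Tibble `pair_id`, `n_tfs`, `divergence`; pairs with no qualifying
#'   TF are excluded and reported via the `n_excluded` attribute.
#' @export
regulatory_divergence <- function(pairs, eps = 0.5, min_tfas = 0.25) {
  if (any(pairs$value_1 < 0 | pairs$value_2 < 0)) abort("negative densities")
  qual <- filter(pairs, pmax(.data$tfas_1, .data$tfas_2) > min_tfas)
  out <- summarise(
    group_by(qual, .data$pair_id),
    n_tfs = dplyr::n(),
    divergence = sum(abs(log2((.data$value_1 + eps) / (.data$value_2 + eps)))),
    .groups = "drop")
  attr(out, "n_excluded") <- length(setdiff(unique(pairs$pair_id), out$pair_id))
  out
}

#' Expression divergence of homoeologous gene pairs
#'
#' Absolute log2 fold-change of expression (TPM) between the two genes of a
#' 1:1 orthologous pair, with a symmetric pseudocount.
#'
#' @param pairs Tibble with `pair_id`, `tpm_1`, `tpm_2`.
#' @param eps Pseudocount (default 0.5).
#' @return Input with an added `divergence` column.
#' @export
expression_divergence <- function(pairs, eps = 0.5) {
  if (any(pairs$tpm_1 < 0 | pairs$tpm_2 < 0)) abort("negative TPM")
  mutate(pairs,
         divergence = abs(log2((.data$tpm_1 + eps) / (.data$tpm_2 + eps))))
}

#' Chromatin-openness (DHS) divergence of triads
#'
#' Normalizes a nonnegative triple of per-subgenome DHS densities to
#' proportions and returns its Euclidean distance to the balanced point
#' (1/3, 1/3, 1/3).
#'
#' @param x Tibble or data frame with columns `dhs_A`, `dhs_B`, `dhs_D`, or
#'   an n x 3 matrix.
#' @return Numeric vector of distances.
#' @export
#' @examples
#' dhs_divergence(matrix(c(5, 5, 5, 1, 0, 0), 2, byrow = TRUE))
dhs_divergence <- function(x) {
  m <- if (is.data.frame(x)) as.matrix(x[, c("dhs_A", "dhs_B", "dhs_D")]) else x
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  stopifnot(ncol(m) == 3)
  if (any(m < 0)) abort("negative DHS densities")
  tot <- rowSums(m)
  if (any(tot == 0)) abort("all-zero DHS triple")
  p <- m / tot
  sqrt(rowSums((p - 1 / 3)^2))
}
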