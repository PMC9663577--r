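gene1 <- tibble::tibble(gene_id = "g1", chrom = "chr1A", start = 10000L,
                        end = 11000L, strand = "+", tss = 10000L,
                        subgenome = "A")

test_that("TFAS evaluates the distance-decayed sum exactly", {
  # summit at TSS
  expect_equal(compute_tfas(gene1, peak_row("chr1A", 9900, 10100, 10000, 2))$tfas,
               2.0)
  # d = 2000
  expect_equal(compute_tfas(gene1, peak_row("chr1A", 11900, 12100, 12000, 1))$tfas,
               exp(-1), tolerance = 1e-9)
  # two peaks: d = 1000 (rpkm 1) and d = 2500 (rpkm 2)
  pk <- dplyr::bind_rows(peak_row("chr1A", 10900, 11100, 11000, 1),
                         peak_row("chr1A", 12400, 12600, 12500, 2))
  expect_equal(compute_tfas(gene1, pk)$tfas,
               exp(-0.5) + 2 * exp(-1.25), tolerance = 1e-9)
  expect_equal(compute_tfas(gene1, pk)$tfas, 1.179541, tolerance = 1e-6)
  # just outside the promoter
  out <- compute_tfas(gene1, peak_row("chr1A", 12400, 12600, 12501, 1))
  expect_equal(out$tfas, 0)
  expect_equal(out$n_peaks, 0L)
  expect_error(compute_tfas(gene1, peak_row("chr1A", 1, 10, 5, -1)), "negative")
})

test_that("TFAS is additive and order-invariant over peaks", {
  set.seed(31)
  pk <- dplyr::bind_rows(lapply(1:20, function(i) {
    s <- 10000 + sample(-3000:3000, 1)
    peak_row("chr1A", s - 100, s + 100, s, runif(1, 0, 5))
  }))
  a <- compute_tfas(gene1, pk)$tfas
  b <- compute_tfas(gene1, pk[sample(20), ])$tfas
  expect_equal(a, b)
  split_sum <- compute_tfas(gene1, pk[1:10, ])$tfas +
    compute_tfas(gene1, pk[11:20, ])$tfas
  expect_equal(a, split_sum)
})

test_that("pattern classification matches exhaustive distances and filters", {
  expect_equal(as.character(nearest_pattern(c(1, 1, 1) / 3)$pattern), "ABD")
  expect_equal(nearest_pattern(c(1, 1, 1) / 3)$distance, 0)
  r <- nearest_pattern(c(0.6, 0.3, 0.1))
  expect_equal(as.character(r$pattern), "AB")
  expect_equal(r$distance, sqrt(0.01 + 0.04 + 0.01), tolerance = 1e-9)
  expect_equal(as.character(nearest_pattern(c(0.9, 0.05, 0.05))$pattern), "A")
  # all-below-threshold triads are filtered
  tfas <- tibble::tibble(tf_id = "TF01", gene_id = c("a", "b", "d"),
                         tfas = c(0.2, 0.2, 0.2), n_peaks = 1L)
  triads <- tibble::tibble(triad_id = "t1", gene_A = "a", gene_B = "b",
                           gene_D = "d")
  out <- classify_patterns(tfas, triads)
  expect_true(out$filtered)
  expect_true(is.na(out$pattern))
  tfas$tfas <- c(0.3, 0.2, 0.2)
  out2 <- classify_patterns(tfas, triads)
  expect_false(out2$filtered)
  expect_equal(out2$prop_A, 0.3 / 0.7, tolerance = 1e-12)
})

test_that("equidistant ties break by the documented priority", {
  # (0.75, 0.25, 0) is exactly equidistant from A and AB (squared distance
  # 0.125 each, dyadic so exact in floating point); AB precedes A
  expect_equal(as.character(nearest_pattern(c(0.75, 0.25, 0))$pattern), "AB")
  # (0.5, 0.25, 0.25) ties AB with AD but ABD is strictly closer
  expect_equal(as.character(nearest_pattern(c(0.5, 0.25, 0.25))$pattern), "ABD")
})

test_that("pattern assignment is equivariant under subgenome permutation", {
  set.seed(32)
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  labels <- c("A", "B", "D")
  relabel <- function(pat, perm) {
    idx <- match(strsplit(pat, "")[[1]], labels)
    paste(labels[sort(which(perm %in% idx))], collapse = "")
  }
  for (i in 1:50) {
    v <- as.vector(perturb_proportions(sample(rownames(pattern_standards()), 1),
                                       0.3))
    base <- as.character(nearest_pattern(v)$pattern)
    for (perm in perms) {
      # v[perm] puts old axis perm[j] on new axis j, so the winning axis set
      # S becomes {j : perm[j] in S}
      permuted <- as.character(nearest_pattern(v[perm])$pattern)
      expect_equal(permuted, relabel(base, perm))
    }
  }
})

test_that("regulatory and expression divergence follow the |log2 FC| formula", {
  pairs <- tibble::tibble(pair_id = "p1", tf_id = c("TF01", "TF02"),
                          value_1 = c(8, 3), value_2 = c(2, 3),
                          tfas_1 = c(1, 1), tfas_2 = c(0, 1))
  expect_equal(regulatory_divergence(pairs, eps = 0)$divergence, 2.0)
  one <- tibble::tibble(pair_id = "p", tf_id = "TF01", value_1 = 4,
                        value_2 = 0, tfas_1 = 1, tfas_2 = 0)
  expect_equal(regulatory_divergence(one, eps = 0.5)$divergence,
               log2(9), tolerance = 1e-12)
  # no qualifying TF -> pair excluded and reported
  low <- dplyr::mutate(one, tfas_1 = 0.1)
  out <- regulatory_divergence(low)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_excluded"), 1)
  ex <- expression_divergence(tibble::tibble(pair_id = c("a", "b"),
                                             tpm_1 = c(10, 16),
                                             tpm_2 = c(10, 1)), eps = 0)
  expect_equal(ex$divergence, c(0, 4))
})

test_that("DHS divergence is the distance to the balanced point", {
  expect_equal(dhs_divergence(matrix(c(5, 5, 5), 1)), 0)
  expect_equal(dhs_divergence(matrix(c(1, 0, 0), 1)), sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(dhs_divergence(matrix(c(0.5, 0.5, 0), 1)), sqrt(1 / 6),
               tolerance = 1e-12)
  expect_error(dhs_divergence(matrix(c(0, 0, 0), 1)), "all-zero")
})
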