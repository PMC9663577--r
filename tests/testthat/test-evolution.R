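test_that("identical LTRs date to age zero and age is linear in distance", {
  fx <- make_ltr_genome(ages = 0, ltr_len = 500)
  out <- te_insertion_age(fx$tes, fx$genome)
  expect_equal(out$ltr_distance, 0)
  expect_equal(out$age_years, 0)
  # distance 0.026 at the default rate -> 1 Myr; doubling mu halves the age
  pair <- make_k2p_pair(1000, 20, 6)  # p+q = 0.026
  d <- k2p_distance(pair$x, pair$y)$distance
  expect_equal(d / (2 * 1.3e-8) / 1e6, d / 0.026, tolerance = 1e-9)
  fx2 <- make_ltr_genome(ages = 1e6, ltr_len = 2000, seed = 82)
  a1 <- te_insertion_age(fx2$tes, fx2$genome, mutation_rate = 1.3e-8)$age_years
  a2 <- te_insertion_age(fx2$tes, fx2$genome, mutation_rate = 2.6e-8)$age_years
  expect_equal(a2, a1 / 2)
  expect_error(te_insertion_age(fx$tes[0, ], fx$genome), "full-length")
})

test_that("simulated insertion ages are recovered without bias", {
  fx <- make_ltr_genome(ages = rep(1e6, 40), seed = 83)
  out <- te_insertion_age(fx$tes, fx$genome)
  expect_false(any(out$saturated))
  expect_lt(abs(median(out$age_years) - 1e6) / 1e6, 0.1)
})

test_that("expansion profile finds one mode for a single clonal burst", {
  set.seed(84)
  anc <- random_dna(300)
  clones <- vapply(1:25, function(i) evolve_sequence(anc, 0.05),
                   character(1))
  prof <- tfbs_expansion_profile(clones, n_sample = 25, seed = 1)
  expect_s3_class(prof, "expansion_profile")
  expect_equal(nrow(prof$distances), choose(25, 2))
  expect_equal(prof$n_saturated, 0)
  main <- prof$modes$location[which.max(prof$modes$density)]
  expect_lt(abs(main - 0.10), prof$bandwidth + 0.02)  # 2x branch length
  g <- glance(prof)
  expect_equal(g$n_pairs, choose(25, 2))
  expect_equal(tidy(prof), prof$distances)
})

test_that("two planted expansion waves give two separated modes", {
  set.seed(85)
  anc <- random_dna(300)
  old_master <- evolve_sequence(anc, 0.18)
  young <- vapply(1:15, function(i) evolve_sequence(anc, 0.01), character(1))
  old <- vapply(1:15, function(i) evolve_sequence(old_master, 0.01),
                character(1))
  prof <- tfbs_expansion_profile(c(young, old), n_sample = 30, seed = 2)
  # within-wave pairs near 0.02, across-wave pairs near 0.20
  expect_gte(nrow(prof$modes), 2)
  locs <- sort(prof$modes$location)
  expect_lt(locs[1], 0.08)
  expect_gt(locs[length(locs)], 0.12)
})

test_that("unrelated random sequences yield no mode below 0.5", {
  set.seed(86)
  rand <- vapply(1:15, function(i) random_dna(250), character(1))
  prof <- tfbs_expansion_profile(rand, n_sample = 15, seed = 3)
  ok <- nrow(prof$modes) == 0 || all(prof$modes$location >= 0.5)
  expect_true(ok)
})

test_that("similar TFBS pairs respect identity, coverage and score floors", {
  set.seed(87)
  a <- random_dna(200)
  dup <- a
  half <- paste0(substr(a, 1, 100), random_dna(100))  # 50% shared segment
  unrelated <- random_dna(200)
  out <- find_similar_tfbs_pairs(c(s1 = a, s2 = dup, s3 = half,
                                   s4 = unrelated))
  expect_equal(nrow(out), 1)
  expect_equal(c(out$query, out$subject), c("s1", "s2"))
  expect_equal(out$identity, 100)
  expect_equal(out$coverage, 100)
})

test_that("a planted expansion is recovered among decoys with no false pairs", {
  set.seed(88)
  anc <- random_dna(200)
  fam <- vapply(1:10, function(i) evolve_sequence(anc, 0.05), character(1))
  decoys <- vapply(1:40, function(i) random_dna(200), character(1))
  seqs <- setNames(c(fam, decoys),
                   c(sprintf("fam%02d", 1:10), sprintf("dec%02d", 1:40)))
  out <- find_similar_tfbs_pairs(seqs)
  expect_true(all(grepl("^fam", out$query) & grepl("^fam", out$subject)))
  expect_gte(nrow(out), 0.9 * choose(10, 2))
})

test_that("cross-lineage distances skip sparse lineages and need a subfamily", {
  sim <- small_sim()
  expect_error(cross_lineage_te_distance(sim$tes, sim$genome),
               "subfamily")
  # thin out one lineage below the copy floor: it is skipped with a warning
  fl <- sim$tes[sim$tes$full_length & sim$tes$subfamily == "RLC_fama.1", ]
  d_rows <- which(subgenome_of(fl$chrom) == "D")
  thin <- fl[-d_rows[-seq_len(2)], ]
  expect_warning(
    out <- cross_lineage_te_distance(thin, sim$genome,
                                     subfamily = "RLC_fama.1",
                                     n_sample = 8, seed = 1, min_copies = 5,
                                     max_pairs = 50),
    regexp = "skipped")
  expect_equal(out$skipped$lineage, "D")
  expect_false("D" %in% c(out$distances$lineage_1, out$distances$lineage_2))
  # all lineages sparse -> error
  expect_error(suppressWarnings(
    cross_lineage_te_distance(sim$tes, sim$genome, subfamily = "RLC_fama.1",
                              min_copies = 1e6)),
    "at least two lineages")
})

test_that("ancestral vs lineage-specific expansions separate across lineages", {
  sim <- small_sim()
  anc <- suppressWarnings(cross_lineage_te_distance(
    sim$tes, sim$genome, subfamily = "RLC_fama.1", n_sample = 12, seed = 4,
    min_copies = 5, max_pairs = 120))
  neo <- suppressWarnings(cross_lineage_te_distance(
    sim$tes, sim$genome, subfamily = "RLG_famb.1", n_sample = 12, seed = 4,
    min_copies = 5, max_pairs = 120))
  main_modes <- function(x, within) {
    m <- x$modes[x$modes$within == within, ]
    vapply(split(m, paste(m$lineage_1, m$lineage_2)),
           function(g) g$location[which.max(g$density)], double(1))
  }
  anc_between <- main_modes(anc, within = FALSE)
  expect_equal(length(anc_between), 3)
  expect_lt((max(anc_between) - min(anc_between)) / mean(anc_between), 0.2)
  neo_between <- main_modes(neo, within = FALSE)
  neo_within <- main_modes(neo, within = TRUE)
  expect_gt(min(neo_between), 1.5 * max(neo_within))
})
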