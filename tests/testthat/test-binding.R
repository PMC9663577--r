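test_that("peak merging unions overlaps but not bookended intervals", {
  pk <- dplyr::bind_rows(
    peak_row("chr1A", 100, 300, 200, 1, tf = "TF1"),
    peak_row("chr1A", 250, 500, 300, 1, tf = "TF2"),
    peak_row("chr1A", 500, 700, 600, 1, tf = "TF1"))  # bookended at 500
  m <- merge_tfbs(pk)
  expect_equal(nrow(m), 2)
  expect_equal(m$tf_count, c(2L, 1L))
  expect_equal(m$tf_ids, c("TF1,TF2", "TF1"))
  # idempotence: merging the merged footprint changes nothing
  m2 <- merge_tfbs(dplyr::mutate(m, tf_id = "X"))
  expect_equal(m2[, c("chrom", "start", "end")], m[, c("chrom", "start", "end")])
})

test_that("HOT calling applies the strict >12 rule", {
  mk <- function(n) tibble::tibble(chrom = "c1A", start = 0L, end = 100L,
                                   tf_count = n, tf_ids = "x")
  expect_true(call_hot(mk(13L))$hot)
  expect_false(call_hot(mk(12L))$hot)
  expect_error(call_hot(mk(5L), threshold = 0), ">= 1")
})

test_that("merged TF membership equals a per-base brute-force count", {
  set.seed(51)
  for (rep in 1:3) {
    L <- 4000L
    pk <- dplyr::bind_rows(lapply(1:500, function(i) {
      s <- sample.int(L - 60, 1)
      w <- sample(10:50, 1)
      peak_row("c1A", s, s + w, s + w %/% 2, 1,
               tf = sprintf("TF%02d", sample.int(18, 1)))
    }))
    m <- merge_tfbs(pk)
    # brute force: per-base list of TFs
    per_base <- vector("list", L)
    for (i in seq_len(nrow(pk))) {
      rng <- (pk$start[i] + 1):pk$end[i]
      for (b in rng) per_base[[b]] <- union(per_base[[b]], pk$tf_id[i])
    }
    covered <- lengths(per_base) > 0
    # merged output is disjoint and covers exactly the peak-covered bases
    covered_by_m <- rep(FALSE, L)
    for (i in seq_len(nrow(m))) {
      expect_false(any(covered_by_m[(m$start[i] + 1):m$end[i]]))
      covered_by_m[(m$start[i] + 1):m$end[i]] <- TRUE
    }
    expect_equal(covered_by_m, covered)
    # per-site distinct-TF sets equal the union of per-base TF sets
    for (i in seq_len(nrow(m))) {
      tf_union <- sort(unique(unlist(per_base[(m$start[i] + 1):m$end[i]])))
      expect_equal(m$tf_count[i], length(tf_union))
      expect_equal(m$tf_ids[i], paste(tf_union, collapse = ","))
    }
    # a planted 20-TF pileup is the only HOT site over an 8-TF background
    bg <- dplyr::mutate(pk, tf_id = sprintf("TF%02d",
                                            as.integer(factor(tf_id)) %% 8 + 1))
    pile <- dplyr::bind_rows(lapply(sprintf("H%02d", 1:20), function(tf) {
      peak_row("c1B", 1000, 1100, 1050, 1, tf = tf)
    }))
    hot <- call_hot(merge_tfbs(dplyr::bind_rows(bg, pile)))
    expect_equal(sum(hot$hot), 1)
    expect_equal(hot$chrom[hot$hot], "c1B")
    expect_equal(sum(hot$end - hot$start),
                 sum(hot$end[hot$hot] - hot$start[hot$hot]) +
                   sum(hot$end[!hot$hot] - hot$start[!hot$hot]))
  }
})

test_that("binarized-bin correlations behave at the extremes", {
  sizes <- tibble::tibble(chrom = "c1A", length = 20000L)
  # TF A occupies odd bins, TF B even bins -> r = -1; A vs A -> 1
  odd <- dplyr::bind_rows(lapply(seq(0, 9, by = 2), function(b) {
    peak_row("c1A", b * 2000 + 100, b * 2000 + 200, b * 2000 + 150, 1, tf = "A")
  }))
  even <- dplyr::bind_rows(lapply(seq(1, 9, by = 2), function(b) {
    peak_row("c1A", b * 2000 + 100, b * 2000 + 200, b * 2000 + 150, 1, tf = "B")
  }))
  tc <- tf_binding_correlation(dplyr::bind_rows(odd, even), sizes)
  expect_equal(tc$r["A", "A"], 1)
  expect_equal(tc$r["A", "B"], -1)
  expect_true(isSymmetric(tc$r))
  # constant (all-one) profile -> NA, not 0
  full <- dplyr::bind_rows(lapply(0:9, function(b) {
    peak_row("c1A", b * 2000 + 100, b * 2000 + 200, b * 2000 + 150, 1, tf = "C")
  }))
  tc2 <- tf_binding_correlation(dplyr::bind_rows(odd, even, full), sizes)
  expect_true(is.na(tc2$r["C", "A"]))
  expect_true(is.na(tc2$r["C", "C"]))
})

test_that("independent random TFs are uncorrelated over many bins", {
  set.seed(52)
  sizes <- tibble::tibble(chrom = "c1A", length = 2e7)  # 1e4 bins
  rand_tf <- function(tf) {
    bins <- sample(0:9999, 2000)
    tibble::tibble(tf_id = tf, chrom = "c1A", start = bins * 2000 + 500,
                   end = bins * 2000 + 700)
  }
  tc <- tf_binding_correlation(dplyr::bind_rows(rand_tf("X"), rand_tf("Y")),
                               sizes)
  expect_lt(abs(tc$r["X", "Y"]), 0.05)
})

test_that("interval enrichment follows the genome-fraction formula", {
  classes <- tibble::tibble(chrom = "c1A",
                            start = c(0L, 1000L, 10000L),
                            end = c(1000L, 10000L, 100000L),
                            klass = c("x", "y", "z"))
  # all query inside class x, which covers 1% of a 100-kb genome
  q <- tibble::tibble(chrom = "c1A", start = 200L, end = 700L)
  e <- interval_enrichment(q, classes, genome_bp = 100000)
  expect_equal(e$enrichment[e$klass == "x"], 100)
  expect_equal(e$enrichment[e$klass == "y"], 0)
  # query proportional to class footprints -> enrichment 1 everywhere
  qp <- tibble::tibble(chrom = "c1A", start = c(0L, 1000L, 10000L),
                       end = c(1000L, 10000L, 100000L))
  ep <- interval_enrichment(qp, classes, genome_bp = 100000)
  expect_equal(ep$enrichment, rep(1, 3))
  expect_error(interval_enrichment(q[0, ], classes, 1e5), "empty query")
})

test_that("planted query concentration is recovered by enrichment", {
  set.seed(53)
  classes <- tibble::tibble(chrom = "c1A", start = c(0L, 50000L),
                            end = c(50000L, 100000L), klass = c("hot", "cold"))
  folds <- replicate(100, {
    n_hot <- stats::rbinom(1, 300, 2 / 3)  # 2x concentration in 'hot'
    pos <- c(sample(0:49900, n_hot), sample(50000:99900, 300 - n_hot))
    q <- tibble::tibble(chrom = "c1A", start = pos, end = pos + 50L)
    interval_enrichment(q, classes, 1e5)$enrichment[1]
  })
  expect_lt(abs(mean(folds) - 4 / 3), 4 / 3 * 0.1)
})

test_that("TAD boundary windows are centered, merged and truncated", {
  sizes <- tibble::tibble(chrom = "c1A", length = 400000L)
  tads <- tibble::tibble(chrom = "c1A", start = 100000L, end = 300000L)
  w <- tad_boundary_windows(tads, sizes)
  b <- w[w$klass == "boundary", ]
  expect_equal(b$start, c(90000L, 290000L))
  expect_equal(b$end, c(110000L, 310000L))
  expect_false(any(b$truncated))
  i <- w[w$klass == "interior", ]
  expect_equal(i$start, 110000L); expect_equal(i$end, 290000L)
  # adjacent TADs sharing a boundary point -> single merged window
  tads2 <- tibble::tibble(chrom = "c1A", start = c(100000L, 200000L),
                          end = c(200000L, 300000L))
  b2 <- tad_boundary_windows(tads2, sizes)
  expect_equal(sum(b2$klass == "boundary"), 3)
  # boundary window at a chromosome end is clipped and flagged
  tads3 <- tibble::tibble(chrom = "c1A", start = 5000L, end = 100000L)
  b3 <- tad_boundary_windows(tads3, sizes)
  first <- b3[b3$klass == "boundary", ][1, ]
  expect_equal(first$start, 0L)
  expect_true(first$truncated)
  # empty TAD list -> everything non-TAD
  e <- tad_boundary_windows(tads[0, ], sizes)
  expect_equal(as.character(e$klass), "non_tad")
  expect_equal(e$end - e$start, 400000L)
})
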