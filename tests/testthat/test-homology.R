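# minimal block builder: reciprocal blocks between chrom pairs
blk <- function(qc, qs, qe, sc, ss = qs, se = qe, id = 95) {
  tibble::tibble(query_chrom = qc, query_start = as.integer(qs),
                 query_end = as.integer(qe), subject_chrom = sc,
                 subject_start = as.integer(ss), subject_end = as.integer(se),
                 identity = id)
}
both_dirs <- function(...) {
  x <- dplyr::bind_rows(...)
  dplyr::bind_rows(x, dplyr::rename(x, query_chrom = "subject_chrom",
                                    query_start = "subject_start",
                                    query_end = "subject_end",
                                    subject_chrom = "query_chrom",
                                    subject_start = "query_start",
                                    subject_end = "query_end"))
}
sizes3 <- tibble::tibble(chrom = c("chr1A", "chr1B", "chr1D"),
                         length = 10000L)
# every pair needs at least a token reciprocal block somewhere
token <- both_dirs(blk("chr1A", 9900, 9950, "chr1B"),
                   blk("chr1A", 9900, 9950, "chr1D"),
                   blk("chr1B", 9800, 9850, "chr1D"))

test_that("the 400-bp reciprocal rule separates homo3, homo2 and specific", {
  blocks <- dplyr::bind_rows(
    both_dirs(blk("chr1A", 1000, 1500, "chr1B"),   # 500 bp vs both others
              blk("chr1A", 1000, 1500, "chr1D"),
              blk("chr1A", 3000, 3300, "chr1B"),   # 300 bp: below threshold
              blk("chr1A", 5000, 5600, "chr1B")),  # homo2: only vs B
    token)
  cls <- classify_regions(blocks, sizes3)
  a <- cls[cls$chrom == "chr1A", ]
  k_at <- function(pos) as.character(a$klass[a$start <= pos & a$end > pos &
                                               a$klass != "homoeo3"])
  expect_equal(k_at(1200), "homo3")
  expect_equal(k_at(3100), "specific")  # 300 bp run is not > 400
  expect_equal(k_at(5300), "homo2")
  expect_equal(k_at(8000), "specific")
})

test_that("homo3 runs inside synteny blocks are additionally homoeo3", {
  blocks <- dplyr::bind_rows(
    both_dirs(blk("chr1A", 1000, 2000, "chr1B"),
              blk("chr1A", 1000, 2000, "chr1D")),
    token)
  syn <- tibble::tibble(chrom = "chr1A", start = 0L, end = 1600L)
  cls <- classify_regions(blocks, sizes3, synteny = syn)
  h3 <- cls[cls$chrom == "chr1A" & cls$klass == "homo3", ]
  he <- cls[cls$chrom == "chr1A" & cls$klass == "homoeo3", ]
  expect_equal(h3$start, 1000L)
  expect_equal(he$start, 1000L)
  expect_equal(he$end, 1600L)  # homoeo3 is contained in homo3
})

test_that("a missing alignment direction is reported by pair", {
  one_dir <- dplyr::bind_rows(blk("chr1A", 1000, 1500, "chr1B"), token)
  expect_error(classify_regions(one_dir, sizes3), NA)  # token covers all
  no_bd <- dplyr::filter(token, !(query_chrom == "chr1B" &
                                    subject_chrom == "chr1D"))
  expect_error(classify_regions(no_bd, sizes3), "B -> D")
})

test_that("classification equals per-base brute force on a random mosaic", {
  set.seed(41)
  L <- 10000L
  mk <- function() {
    s <- sort(sample(seq(0, L - 600, by = 50), 12))
    tibble::tibble(start = s, end = pmin(s + sample(c(300, 450, 700), 12,
                                                    replace = TRUE), L))
  }
  ab <- mk(); ad <- mk(); bd <- mk()
  blocks <- dplyr::bind_rows(
    both_dirs(blk("chr1A", ab$start, ab$end, "chr1B"),
              blk("chr1A", ad$start, ad$end, "chr1D"),
              blk("chr1B", bd$start, bd$end, "chr1D")))
  cls <- classify_regions(blocks, sizes3)
  # brute force for chr1A: per-base membership in >400 bp runs
  base_cov <- function(tab) {
    runs <- tab[tab$end - tab$start > 400, ]
    cov <- rep(FALSE, L)
    for (i in seq_len(nrow(runs))) cov[(runs$start[i] + 1):runs$end[i]] <- TRUE
    cov
  }
  # merge overlapping intervals first, then apply the length rule
  merge_tab <- function(tab) {
    ir <- IRanges::reduce(IRanges::IRanges(tab$start + 1, tab$end))
    tibble::tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }
  covB <- base_cov(merge_tab(ab)); covD <- base_cov(merge_tab(ad))
  truth <- ifelse(covB & covD, "homo3", ifelse(covB | covD, "homo2", "specific"))
  a <- cls[cls$chrom == "chr1A" & cls$klass != "homoeo3", ]
  called <- rep(NA_character_, L)
  for (i in seq_len(nrow(a))) {
    called[(a$start[i] + 1):a$end[i]] <- as.character(a$klass[i])
  }
  expect_equal(called, truth)
  # per-base fractions sum to 1 over the analyzed length
  fr <- sum(a$end - a$start)
  expect_equal(fr, L)
})

test_that("query location uses the midpoint and supports empty input", {
  blocks <- dplyr::bind_rows(
    both_dirs(blk("chr1A", 1000, 2000, "chr1B"),
              blk("chr1A", 1000, 2000, "chr1D")),
    token)
  cls <- classify_regions(blocks, sizes3)
  q <- tibble::tibble(chrom = "chr1A", start = c(1400L, 1900L, 5000L),
                      end = c(1600L, 2300L, 5100L))
  loc <- locate_in_classes(q, cls)
  expect_equal(as.character(loc$klass), c("homo3", "specific", "specific"))
  # straddling query (1900..2300): midpoint 2100 -> specific
  q2 <- tibble::tibble(chrom = "chr1A", start = 1900L, end = 2300L)
  expect_equal(as.character(locate_in_classes(q2, cls)$klass), "specific")
  # majority rule alternative gives homo3 when most bases fall inside
  q3 <- tibble::tibble(chrom = "chr1A", start = 1700L, end = 2100L)
  expect_equal(as.character(locate_in_classes(q3, cls, "majority")$klass),
               "homo3")
  empty <- locate_in_classes(q[0, ], cls)
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(class_fractions(empty)), 0)
  expect_error(locate_in_classes(tibble::tibble(chrom = "chrX", start = 1L,
                                                end = 2L), cls),
               "not covered")
})

test_that("synthetic-data region classes are recovered exactly", {
  sim <- small_sim()
  cls <- classify_regions(sim$blocks, sim$sizes, synteny = sim$synteny)
  rep <- truth_check(sim, list(regions = cls))
  expect_equal(rep$value[rep$metric == "base_accuracy"], 1)
  # subgenome relabeling leaves class footprints unchanged
  swap <- function(x) dplyr::mutate(x, chrom = chartr("AB", "BA", .data$chrom))
  blocks2 <- dplyr::mutate(sim$blocks,
                           query_chrom = chartr("AB", "BA", query_chrom),
                           subject_chrom = chartr("AB", "BA", subject_chrom))
  cls2 <- classify_regions(blocks2, swap(sim$sizes))
  tally <- function(cl) {
    x <- cl[cl$klass != "homoeo3", ]
    tapply(x$end - x$start, as.character(x$klass), sum)
  }
  expect_equal(tally(cls2), tally(cls))
})
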