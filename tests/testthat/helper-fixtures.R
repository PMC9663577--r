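# Shared fixtures, built once per test run.

peak_row <- function(chrom, start, end, summit, rpkm, tf = "TF01",
                     name = "p", strand = ".") {
  tibble::tibble(tf_id = tf, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), name = name, score = 0,
                 strand = strand, rpkm = rpkm, summit = as.integer(summit))
}

# small two-family simulation reused by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        subgenome_length = 6e5, n_triads = 40, n_tfs = 3,
        te_families = list(
          list(name = "RLC_fama.1", family = "RLC_fama", copies = 12,
               epoch = "ancestral", ltr_length = 300, element_length = 1500,
               motif = "TGACGTCAGGCTAAGCTAGC", tf = "TF01"),
          list(name = "RLG_famb.1", family = "RLG_famb", copies = 10,
               epoch = "lineage", ltr_length = 300, element_length = 1500,
               motif = "CACGTGACCTAGGTCAATGC", tf = "TF02")),
        seed = 7)
      cache <<- simulate_polyploid(cfg)
    }
    cache
  }
})

# independent brute-force TFAS oracle: plain double loop over peaks
tfas_oracle <- function(tss, summits, rpkms, half_width = 2500, decay = 2000) {
  total <- 0
  for (k in seq_along(summits)) {
    d <- abs(summits[k] - tss)
    if (d <= half_width) total <- total + rpkms[k] * exp(-d / decay)
  }
  total
}

# independent nearest-standard oracle with the documented priority order
pattern_oracle <- function(props) {
  std <- pattern_standards()
  apply(props, 1, function(v) {
    d <- sqrt(colSums((t(std) - v)^2))
    rownames(std)[which.min(d)]  # which.min takes the first = priority order
  })
}

# Planted-relic fixture: one or more triads, promoters of 5 kb per subgenome
# laid side by side on three chromosomes; the TE with its TFBS sits in
# promoter A, relics are planted in the `relic_subs` promoters. relic_len
# and relic_rate may be length-1 or ranges (sampled per triad).

make_dte_fixture <- function(n_triads = 1, relic_len = 120, relic_rate = 0.2,
                             window_intact = TRUE, relic_subs = c("B", "D"),
                             revcomp_target = FALSE, te_len = 200L,
                             seed = 71) {
  set.seed(seed)
  prom_w <- 5000L
  chroms <- c(A = "p1A", B = "p1B", D = "p1D")
  seqs <- list(A = character(n_triads), B = character(n_triads),
               D = character(n_triads))
  te_sites <- list(); tes <- list(); relics <- list()
  for (ti in seq_len(n_triads)) {
    base <- lapply(chroms, function(x) random_dna(prom_w))
    te_seq <- random_dna(te_len)
    te_off <- 2000L
    wc <- te_len %/% 2
    win_rel <- c(wc - 29L, wc + 30L)  # 60-bp window, 1-based within TE
    base$A <- paste0(substr(base$A, 1, te_off), te_seq,
                     substr(base$A, te_off + te_len + 1, prom_w))
    tid <- sprintf("t%03d", ti)
    fam <- sprintf("RLX_fix%d", ti)
    off0 <- (ti - 1L) * prom_w
    te_sites[[ti]] <- tibble::tibble(
      triad_id = tid, tf_id = "TF01", subgenome = "A", chrom = "p1A",
      start = off0 + te_off, end = off0 + te_off + te_len,
      tfbs_start = off0 + te_off + win_rel[1] - 1L,
      tfbs_end = off0 + te_off + win_rel[2],
      te_id = sprintf("TE_%s", tid), family = fam,
      subfamily = paste0(fam, ".1"))
    tes[[ti]] <- tibble::tibble(
      chrom = "p1A", start = off0 + te_off, end = off0 + te_off + te_len,
      strand = "+", family = fam, subfamily = paste0(fam, ".1"),
      full_length = FALSE, ltr5_start = NA_integer_, ltr5_end = NA_integer_,
      ltr3_start = NA_integer_, ltr3_end = NA_integer_,
      te_id = sprintf("TE_%s", tid), degenerated = FALSE)
    rlen <- if (length(relic_len) > 1) sample(relic_len[1]:relic_len[2], 1) else
      relic_len
    rrate <- if (length(relic_rate) > 1) runif(1, relic_rate[1], relic_rate[2]) else
      relic_rate
    # relic: substring of the TE containing the window, flanks degenerated
    span_rel <- c(max(1L, win_rel[1] - (rlen - 60L) %/% 2), 0L)
    span_rel[2] <- min(te_len, span_rel[1] + rlen - 1L)
    relic_seq <- substr(te_seq, span_rel[1], span_rel[2])
    if (window_intact) {
      w1 <- win_rel[1] - span_rel[1] + 1L
      w2 <- min(win_rel[2] - span_rel[1] + 1L, nchar(relic_seq))
      left <- if (w1 > 1) degenerate_sequence(substr(relic_seq, 1, w1 - 1),
                                              rrate) else ""
      right <- if (w2 < nchar(relic_seq))
        degenerate_sequence(substr(relic_seq, w2 + 1, nchar(relic_seq)),
                            rrate) else ""
      relic_seq <- paste0(left, substr(relic_seq, w1, w2), right)
    } else {
      relic_seq <- degenerate_sequence(relic_seq, rrate)
    }
    for (g in relic_subs) {
      target_off <- 3000L
      planted <- if (revcomp_target) revcomp(relic_seq) else relic_seq
      base[[g]] <- paste0(substr(base[[g]], 1, target_off), planted,
                          substr(base[[g]], target_off + nchar(planted) + 1,
                                 prom_w))
      relics[[length(relics) + 1]] <- tibble::tibble(
        triad_id = tid, subgenome = g, chrom = unname(chroms[g]),
        start = off0 + target_off, end = off0 + target_off + nchar(planted))
    }
    for (g in names(seqs)) seqs[[g]][ti] <- base[[g]]
  }
  genome <- Biostrings::DNAStringSet(c(
    p1A = paste(seqs$A, collapse = ""), p1B = paste(seqs$B, collapse = ""),
    p1D = paste(seqs$D, collapse = "")))
  promoters <- dplyr::bind_rows(lapply(seq_len(n_triads), function(ti) {
    tibble::tibble(triad_id = sprintf("t%03d", ti), subgenome = names(chroms),
                   chrom = unname(chroms),
                   start = (ti - 1L) * prom_w, end = ti * prom_w)
  }))
  list(genome = genome, promoters = promoters,
       te_sites = dplyr::bind_rows(te_sites), tes = dplyr::bind_rows(tes),
       relics = dplyr::bind_rows(relics))
}

# build a genome of full-length TEs with planted LTR divergence
make_ltr_genome <- function(ages, mutation_rate = 1.3e-8, ltr_len = 2000,
                            internal_len = 200, seed = 81) {
  set.seed(seed)
  n <- length(ages)
  seqs <- character(n)
  tes <- vector("list", n)
  for (i in seq_len(n)) {
    d <- mutation_rate * ages[i]
    ltr <- random_dna(ltr_len)
    l5 <- evolve_sequence(ltr, d)   # each LTR drifts independently since
    l3 <- evolve_sequence(ltr, d)   # insertion, so the pair diverges 2*mu*age
    seqs[i] <- paste0(l5, random_dna(internal_len), l3)
    tes[[i]] <- tibble::tibble(
      chrom = sprintf("te%03dA", i), start = 0L,
      end = nchar(seqs[i]), strand = "+", family = "RLC_x",
      subfamily = "RLC_x.1", full_length = TRUE,
      ltr5_start = 0L, ltr5_end = ltr_len,
      ltr3_start = nchar(seqs[i]) - ltr_len, ltr3_end = nchar(seqs[i]),
      te_id = sprintf("te%03d", i), degenerated = FALSE)
  }
  list(genome = Biostrings::DNAStringSet(setNames(seqs, sprintf("te%03dA",
                                                                seq_len(n)))),
       tes = dplyr::bind_rows(tes))
}

# build an aligned sequence pair with exact transition/transversion counts
make_k2p_pair <- function(sites, transitions, transversions) {
  stopifnot(transitions + transversions <= sites)
  x <- rep("A", sites)
  y <- x
  if (transitions > 0) y[seq_len(transitions)] <- "G"
  if (transversions > 0) {
    y[transitions + seq_len(transversions)] <- "C"
  }
  list(x = paste(x, collapse = ""), y = paste(y, collapse = ""))
}
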