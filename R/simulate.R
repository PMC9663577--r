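DEFAULT_MOTIFS <- c("TGACGTCAGGCTAAGCTAGC", "CACGTGACCTAGGTCAATGC",
                    "GGCCCAATTGGGCCTAGCTA", "TTGACCGATCGGTCAAGGCC",
                    "AACCGGTTAACCGGTTAAGG")

#' Configuration for the synthetic polyploid generator
#'
#' Assembles and validates the parameter set of [simulate_polyploid()]. The
#' defaults describe a toy hexaploid: three 2-Mb subgenomes that diverged
#' from a common ancestor 5 million years ago at 1.3e-8 substitutions per
#' site per year, carrying 1:1:1 gene triads, an ancestrally expanded
#' motif-bearing LTR retrotransposon family, an independently
#' (per-lineage) expanded family, TE relics conserved only around their
#' TFBS, and DAP-seq-like peak sets whose triad-promoter proportions follow
#' a planted mixture of the seven balance patterns.
#'
#' @param subgenome_length Chromosome length per subgenome in bp.
#' @param n_triads Number of 1:1:1 gene triads.
#' @param n_tfs Number of TFs with peak sets.
#' @param segment_length Homology mosaic segment size in bp.
#' @param class_probs Segment class proportions, named `homo3`, `homo2`,
#'   `specific` (sum 1). Segment counts are rounded deterministically.
#' @param te_families List of family descriptors; each a list with `name`
#'   (subfamily label), `family`, `copies` (per subgenome), `epoch`
#'   (`"ancestral"`, `"lineage"`, or `"lineage_A"`/`"_B"`/`"_D"`),
#'   `ltr_length`, `element_length`, `motif` (IUPAC-free string or `NULL`)
#'   and `tf` (bound TF id or `NULL`).
#' @param mutation_rate Substitutions/site/year (default 1.3e-8).
#' @param divergence_time Years since the subgenomes split (default 5e6).
#' @param promoter_te_fraction Fraction of triads whose ancestral promoter
#'   carried a motif-bearing TE fragment.
#' @param relic_fraction Among those, fraction where the copy survives
#'   annotated in one subgenome only and is degenerated to a relic in the
#'   two sisters.
#' @param tfbs_window TFBS window width in bp (default 60) kept intact in
#'   relics.
#' @param degeneration_rate Per-site substitution probability applied to
#'   relic bases outside the TFBS window (default 0.35).
#' @param relic_span Length range (bp) of the surviving alignable relic
#'   span.
#' @param promoter_te_length Length of the promoter TE fragment (bp). Each
#'   triad's promoter copy is an independent sequence sharing only the bound
#'   motif with other copies, modelling insertions so anciently diverged
#'   that only the binding site is conserved between family members:
#'   homoeologous copies within a triad stay alignable (they descend from
#'   one ancestral insertion) while copies of different triads share no
#'   alignable stretch.
#' @param balance_mixture Named 7-vector of planted pattern proportions
#'   (order `ABD, AB, AD, BD, A, B, D`; sums to 1).
#' @param noise_radius Maximum Euclidean perturbation of planted
#'   proportions; must stay below 0.2041 (half the minimum distance between
#'   standards) so planted patterns remain recoverable.
#' @param peak_width Peak interval width in bp.
#' @param promoter_half_width Promoter half-width in bp (default 2500).
#' @param signal_meanlog,signal_sdlog Lognormal total promoter signal per
#'   (TF, triad).
#' @param te_peak_meanlog,te_peak_sdlog Lognormal signal of genome-wide
#'   TE-copy peaks.
#' @param n_background_peaks Random non-promoter peaks per TF per
#'   subgenome.
#' @param expression_scale,expression_exponent,expression_sdlog TPM model:
#'   `tpm = scale * signal^exponent * lognormal(0, sdlog)` (monotone in
#'   promoter signal with multiplicative noise).
#' @param gene_length,gene_spacing Gene body length and TSS spacing in bp.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(subgenome_length = 2e6,
                       n_triads = 300,
                       n_tfs = 5,
                       segment_length = 25000,
                       class_probs = c(homo3 = 0.70, homo2 = 0.12, specific = 0.18),
                       te_families = NULL,
                       mutation_rate = 1.3e-8,
                       divergence_time = 5e6,
                       promoter_te_fraction = 0.5,
                       relic_fraction = 0.6,
                       tfbs_window = 60,
                       degeneration_rate = 0.35,
                       relic_span = c(80, 300),
                       promoter_te_length = 400,
                       balance_mixture = c(ABD = 0.4, AB = 0.1, AD = 0.1,
                                           BD = 0.1, A = 0.1, B = 0.1, D = 0.1),
                       noise_radius = 0.15,
                       peak_width = 200,
                       promoter_half_width = 2500,
                       signal_meanlog = log(8), signal_sdlog = 0.25,
                       te_peak_meanlog = log(3), te_peak_sdlog = 0.4,
                       n_background_peaks = 100,
                       expression_scale = 2, expression_exponent = 0.9,
                       expression_sdlog = 0.4,
                       gene_length = 1000, gene_spacing = 3800,
                       seed = 1) {
  if (is.null(te_families)) {
    te_families <- list(
      list(name = "RLC_fama.1", family = "RLC_fama", copies = 40,
           epoch = "ancestral", ltr_length = 300, element_length = 1500,
           motif = DEFAULT_MOTIFS[1], tf = "TF01"),
      list(name = "RLG_famb.1", family = "RLG_famb", copies = 40,
           epoch = "lineage", ltr_length = 300, element_length = 1500,
           motif = DEFAULT_MOTIFS[2], tf = "TF02"),
      list(name = "DTC_famc.1", family = "DTC_famc", copies = 30,
           epoch = "ancestral", ltr_length = 0, element_length = 800,
           motif = NULL, tf = NULL)
    )
  }
  cfg <- as.list(environment())
  stopifnot(abs(sum(class_probs) - 1) < 1e-9,
            abs(sum(balance_mixture) - 1) < 1e-9,
            all(balance_mixture >= 0),
            promoter_te_fraction >= 0, promoter_te_fraction <= 1,
            relic_fraction >= 0, relic_fraction <= 1,
            degeneration_rate >= 0, degeneration_rate <= 1,
            mutation_rate > 0, divergence_time >= 0, n_tfs >= 1)
  if (noise_radius >= 0.2041) {
    abort("noise_radius must stay below 0.2041 for planted patterns to be recoverable")
  }
  if (!identical(names(balance_mixture),
                 c("ABD", "AB", "AD", "BD", "A", "B", "D"))) {
    abort("balance_mixture must be named ABD, AB, AD, BD, A, B, D in order")
  }
  structure(cfg, class = "sim_config")
}

#' Project a vector onto the probability simplex
#'
#' Euclidean projection onto `{p : p >= 0, sum(p) = 1}` (sort-based
#' algorithm). Projection is non-expansive, so a point within radius r of a
#' simplex point stays within r after projection -- the property that makes
#' noise-ball perturbations of the standard patterns provably recoverable.
#'
#' @param v Numeric vector.
#' @return Projected vector of the same length.
#' @export
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  tau <- (1 - css[rho]) / rho
  pmax(v + tau, 0)
}

#' Perturb standard pattern proportions inside a noise ball
#'
#' Draws points uniformly in the Euclidean ball of radius `radius` around a
#' standard pattern's proportion vector and projects them back onto the
#' simplex.
#'
#' @param pattern Pattern name (`"ABD"`, ..., `"D"`) or a length-3
#'   proportion vector.
#' @param radius Ball radius.
#' @param n Number of draws.
#' @return `n` x 3 matrix of proportion vectors.
#' @export
perturb_proportions <- function(pattern, radius, n = 1) {
  std <- if (is.character(pattern)) pattern_standards()[pattern, ] else pattern
  g <- matrix(rnorm(3 * n), n, 3)
  g <- g / sqrt(rowSums(g^2))
  r <- radius * runif(n)^(1 / 3)
  pts <- sweep(g * r, 2, std, "+")
  t(apply(pts, 1, project_simplex))
}

# Write a replacement string into a character-vector sequence at 0-based pos.
write_at <- function(chars, pos0, s) {
  chars[(pos0 + 1):(pos0 + nchar(s))] <- strsplit(s, "", fixed = TRUE)[[1]]
  chars
}

#' Generate a synthetic three-subgenome dataset with planted ground truth
#'
#' Builds three equal-length subgenome chromosomes from a shared segment
#' mosaic (segments present in three, two or one subgenome give planted
#' homo3/homo2/specific homology classes), plants gene triads, TE families
#' expanded before or after the subgenome split, TE relics degenerated
#' outside a conserved TFBS window, per-TF peak sets following a planted
#' mixture of the seven balance patterns, DHS and expression coupled to
#' binding, and emits alignment/synteny blocks from the known homologous
#' coordinates together with full truth tables.
#'
#' Sequence divergence uses the exact finite-time K2P process
#' ([evolve_sequence()], transition:transversion rate ratio 2) with no
#' indels, so distance estimators can be validated against closed-form
#' expectations. Ancestral-epoch TE copies ride in the ancestor and diverge
#' for `divergence_time` in each lineage; lineage-epoch copies burst from a
#' per-lineage master at ages drawn uniformly from `[0, divergence_time]`,
#' with LTR pairs homogenized at insertion so 5'/3' LTR divergence encodes
#' the copy's age.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional directory; when given, the full dataset (FASTA
#'   per subgenome, GFF3, TE table, per-TF narrowPeak, DHS BED, TPM TSV,
#'   alignment-block and synteny TSVs, triad TSV, truth tables) is written
#'   there deterministically.
#' @return Object of class `polyploid_sim`: list of tibbles (`genes`,
#'   `triads`, `promoters`, `tes`, `te_truth`, `peaks`, `dhs`,
#'   `expression`, `blocks`, `synteny`, `region_truth`, `pattern_truth`,
#'   `relic_truth`, `presence_truth`), the `genome`
#'   ([Biostrings::DNAStringSet]), `sizes` and the `config`.
#' @export
simulate_polyploid <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  subs <- c("A", "B", "D")
  chroms <- setNames(paste0("chr1", subs), subs)
  seg_len <- config$segment_length
  n_seg <- floor(config$subgenome_length / seg_len)
  L <- n_seg * seg_len
  mu <- config$mutation_rate
  Tdiv <- config$divergence_time
  d_branch <- mu * Tdiv

  ## --- segment classes -------------------------------------------------
  n3 <- round(config$class_probs[["homo3"]] * n_seg)
  n2 <- round(config$class_probs[["homo2"]] * n_seg)
  n1 <- n_seg - n3 - n2
  klass <- sample(c(rep("homo3", n3), rep("homo2", n2), rep("specific", n1)))
  # balanced partner/owner assignment so every subgenome owns its share of
  # homo2 and specific segments even in small genomes
  pairs2 <- list(c("A", "B"), c("A", "D"), c("B", "D"))
  pair_seq <- sample(rep(seq_len(3), length.out = n2))
  owner_seq <- sample(rep(subs, length.out = n1))
  i2 <- 0; i1 <- 0
  share <- lapply(seq_len(n_seg), function(i) {
    switch(klass[i],
           homo3 = subs,
           homo2 = { i2 <<- i2 + 1; pairs2[[pair_seq[i2]]] },
           specific = { i1 <<- i1 + 1; owner_seq[i1] })
  })
  seg_start <- (seq_len(n_seg) - 1L) * seg_len

  ## --- gene layout ------------------------------------------------------
  margin <- config$promoter_half_width + 100
  slots_per_seg <- floor((seg_len - 2 * margin) / config$gene_spacing) + 1
  need_segs <- ceiling(config$n_triads / slots_per_seg)
  homo3_segs <- which(klass == "homo3")
  if (length(homo3_segs) < need_segs) {
    abort(sprintf(
      "infeasible packing: %d triads need %d homo3 segments, only %d available",
      config$n_triads, need_segs, length(homo3_segs)))
  }
  gene_segs <- homo3_segs[seq_len(need_segs)]
  tss_rel <- margin + (seq_len(slots_per_seg) - 1L) * config$gene_spacing
  tss_all <- as.vector(outer(tss_rel, seg_start[gene_segs], "+"))[seq_len(config$n_triads)]
  triad_strand <- sample(c("+", "-"), config$n_triads, replace = TRUE)
  triad_ids <- sprintf("triad%04d", seq_len(config$n_triads))
  tfs <- sprintf("TF%02d", seq_len(config$n_tfs))

  ## --- TE consensus sequences ------------------------------------------
  fams <- config$te_families
  for (k in seq_along(fams)) {
    f <- fams[[k]]
    el <- strsplit(random_dna(f$element_length), "", fixed = TRUE)[[1]]
    if (f$ltr_length > 0) {
      el[(f$element_length - f$ltr_length + 1):f$element_length] <-
        el[seq_len(f$ltr_length)]
    }
    if (!is.null(f$motif)) {
      mstart <- floor((f$element_length - nchar(f$motif)) / 2)
      el <- write_at(el, mstart, f$motif)
      fams[[k]]$motif_offset <- mstart  # 0-based within element
    }
    fams[[k]]$consensus <- paste(el, collapse = "")
  }

  ## --- ancestral TE placement ------------------------------------------
  te_slots_segs <- c(setdiff(homo3_segs, gene_segs), which(klass == "homo2"))
  slot_cursor <- setNames(rep(100L, length(te_slots_segs)), te_slots_segs)
  anc_tes <- list()
  for (k in seq_along(fams)) {
    f <- fams[[k]]
    if (f$epoch != "ancestral") next
    placed <- 0
    for (si in te_slots_segs) {
      while (placed < f$copies &&
             slot_cursor[[as.character(si)]] + f$element_length + 100 < seg_len) {
        pos <- seg_start[si] + slot_cursor[[as.character(si)]]
        anc_tes[[length(anc_tes) + 1]] <- list(fam = k, pos = pos, seg = si)
        slot_cursor[[as.character(si)]] <-
          slot_cursor[[as.character(si)]] + f$element_length + 200L
        placed <- placed + 1
      }
      if (placed >= f$copies) break
    }
    if (placed < f$copies) {
      abort(sprintf("infeasible packing: no room for %d copies of %s",
                    f$copies, f$name))
    }
  }

  ## --- promoter TEs and relic plan --------------------------------------
  anc_motif_fam <- which(vapply(fams, function(f)
    f$epoch == "ancestral" && !is.null(f$motif), logical(1)))[1]
  prom_te_triads <- integer(0)
  relic_triads <- integer(0)
  if (!is.na(anc_motif_fam) && config$promoter_te_fraction > 0) {
    n_pt <- round(config$promoter_te_fraction * config$n_triads)
    prom_te_triads <- sort(sample.int(config$n_triads, n_pt))
    n_relic <- round(config$relic_fraction * n_pt)
    relic_triads <- sort(sample(prom_te_triads, n_relic))
  }
  relic_source <- setNames(subs[(seq_along(relic_triads) - 1) %% 3 + 1],
                           relic_triads)
  ptl <- config$promoter_te_length
  f_anc <- if (!is.na(anc_motif_fam)) fams[[anc_motif_fam]] else NULL
  # promoter TE fragments carry the family motif at their center; the rest
  # of each fragment is triad-specific (see promoter_te_length docs)
  prom_te_info <- NULL
  if (!is.null(f_anc)) {
    motif_rel <- ptl %/% 2 - nchar(f_anc$motif) %/% 2  # 0-based within fragment
    prom_te_info <- list(motif_rel = motif_rel,
                         motif_len = nchar(f_anc$motif),
                         motif = f_anc$motif)
  }
  # absolute promoter-TE coordinates per triad (same in all subgenomes)
  prom_te_pos <- rep(NA_integer_, config$n_triads)
  for (ti in prom_te_triads) {
    prom_te_pos[ti] <- if (triad_strand[ti] == "+") {
      tss_all[ti] - 1400L
    } else {
      tss_all[ti] + 1001L
    }
  }

  ## --- ancestral segment sequences --------------------------------------
  anc_seq <- vector("list", n_seg)
  for (si in seq_len(n_seg)) {
    if (length(share[[si]]) >= 2) {
      anc_seq[[si]] <- strsplit(random_dna(seg_len), "", fixed = TRUE)[[1]]
    }
  }
  for (te in anc_tes) {
    rel <- te$pos - seg_start[te$seg]
    anc_seq[[te$seg]] <- write_at(anc_seq[[te$seg]], rel, fams[[te$fam]]$consensus)
  }
  seg_of <- function(pos) pos %/% seg_len + 1L
  for (ti in prom_te_triads) {
    si <- seg_of(prom_te_pos[ti])
    frag <- paste0(random_dna(prom_te_info$motif_rel), prom_te_info$motif,
                   random_dna(ptl - prom_te_info$motif_rel -
                                prom_te_info$motif_len))
    anc_seq[[si]] <- write_at(anc_seq[[si]], prom_te_pos[ti] - seg_start[si],
                              frag)
  }

  ## --- per-subgenome assembly -------------------------------------------
  genome_chars <- list()
  for (g in subs) {
    segs <- vector("list", n_seg)
    for (si in seq_len(n_seg)) {
      if (g %in% share[[si]] && length(share[[si]]) >= 2) {
        segs[[si]] <- strsplit(
          evolve_sequence(paste(anc_seq[[si]], collapse = ""), d_branch),
          "", fixed = TRUE)[[1]]
      } else {
        segs[[si]] <- strsplit(random_dna(seg_len), "", fixed = TRUE)[[1]]
      }
    }
    genome_chars[[g]] <- unlist(segs, use.names = FALSE)
  }

  ## --- lineage TE insertions --------------------------------------------
  lin_tes <- list()
  for (k in seq_along(fams)) {
    f <- fams[[k]]
    if (!startsWith(f$epoch, "lineage")) next
    targets <- if (f$epoch == "lineage") subs else sub("lineage_", "", f$epoch)
    for (g in targets) {
      master <- evolve_sequence(f$consensus, d_branch)
      if (f$ltr_length > 0) {
        mch <- strsplit(master, "", fixed = TRUE)[[1]]
        mch[(f$element_length - f$ltr_length + 1):f$element_length] <-
          mch[seq_len(f$ltr_length)]
        master <- paste(mch, collapse = "")
      }
      own_segs <- which(klass == "specific" &
                          vapply(share, function(s) identical(s, g), logical(1)))
      if (length(own_segs) == 0) {
        abort(sprintf("infeasible packing: no specific segments in subgenome %s for %s",
                      g, f$name))
      }
      cursor <- setNames(rep(100L, length(own_segs)), own_segs)
      placed <- 0
      ages <- runif(f$copies, 0, Tdiv)
      for (si in own_segs) {
        while (placed < f$copies &&
               cursor[[as.character(si)]] + f$element_length + 100 < seg_len) {
          pos <- seg_start[si] + cursor[[as.character(si)]]
          age <- ages[placed + 1]
          copy <- evolve_sequence(master, mu * age)
          genome_chars[[g]] <- write_at(genome_chars[[g]], pos, copy)
          lin_tes[[length(lin_tes) + 1]] <-
            list(fam = k, sub = g, pos = pos, age = age)
          cursor[[as.character(si)]] <-
            cursor[[as.character(si)]] + f$element_length + 200L
          placed <- placed + 1
        }
        if (placed >= f$copies) break
      }
      if (placed < f$copies) {
        abort(sprintf("infeasible packing: no room for %d copies of %s in %s",
                      f$copies, f$name, g))
      }
    }
  }

  ## --- relic degeneration -----------------------------------------------
  relic_rows <- list()
  win <- config$tfbs_window
  for (ti in relic_triads) {
    src <- relic_source[[as.character(ti)]]
    te_s <- prom_te_pos[ti]; te_e <- te_s + ptl
    motif_center <- te_s + prom_te_info$motif_rel + prom_te_info$motif_len %/% 2
    w_s <- motif_center - win %/% 2; w_e <- w_s + win
    span_len <- sample(seq(config$relic_span[1], config$relic_span[2]), 1)
    span_s <- max(te_s, motif_center - span_len %/% 2)
    span_e <- min(te_e, span_s + span_len)
    for (g in setdiff(subs, src)) {
      ch <- genome_chars[[g]]
      # outside the surviving span: erase to random background
      if (span_s > te_s) ch <- write_at(ch, te_s, random_dna(span_s - te_s))
      if (te_e > span_e) ch <- write_at(ch, span_e, random_dna(te_e - span_e))
      # span flanks outside the TFBS window: heavy substitution decay
      for (reg in list(c(span_s, w_s), c(w_e, span_e))) {
        if (reg[2] > reg[1]) {
          seg <- paste(ch[(reg[1] + 1):reg[2]], collapse = "")
          ch <- write_at(ch, reg[1], degenerate_sequence(seg, config$degeneration_rate))
        }
      }
      genome_chars[[g]] <- ch
      relic_rows[[length(relic_rows) + 1]] <- tibble(
        triad_id = triad_ids[ti], subgenome = g, chrom = chroms[[g]],
        start = span_s, end = span_e, motif_start = w_s, motif_end = w_e,
        source_subgenome = src)
    }
  }
  relic_truth <- if (length(relic_rows) > 0) bind_rows(relic_rows) else
    tibble(triad_id = character(), subgenome = character(), chrom = character(),
           start = integer(), end = integer(), motif_start = integer(),
           motif_end = integer(), source_subgenome = character())

  ## --- gene / triad / promoter tables -----------------------------------
  genes <- purrr::map_dfr(seq_len(config$n_triads), function(ti) {
    tibble(triad_id = triad_ids[ti], subgenome = subs,
           gene_id = sprintf("%s_%s", triad_ids[ti], subs),
           chrom = unname(chroms[subs]), strand = triad_strand[ti],
           tss = tss_all[ti],
           start = if (triad_strand[ti] == "+") tss_all[ti] else
             tss_all[ti] - config$gene_length + 1L,
           end = if (triad_strand[ti] == "+") tss_all[ti] + config$gene_length else
             tss_all[ti] + 1L)
  })
  genes <- mutate(genes, start = as.integer(start), end = as.integer(end),
                  tss = as.integer(tss))
  triads <- tibble(triad_id = triad_ids,
                   gene_A = sprintf("%s_A", triad_ids),
                   gene_B = sprintf("%s_B", triad_ids),
                   gene_D = sprintf("%s_D", triad_ids))
  promoters <- mutate(select(genes, "triad_id", "subgenome", "chrom", "tss"),
                      start = as.integer(pmax(.data$tss - config$promoter_half_width, 0)),
                      end = as.integer(.data$tss + config$promoter_half_width + 1))
  promoters <- select(promoters, -"tss")

  ## --- TE truth and annotation tables -----------------------------------
  te_rows <- list()
  add_te <- function(fam, g, pos, age, full_length, annotated, degenerated) {
    f <- fams[[fam]]
    te_rows[[length(te_rows) + 1]] <<- tibble(
      chrom = chroms[[g]], start = pos, end = pos + f$element_length,
      strand = "+", family = f$family, subfamily = f$name,
      full_length = full_length,
      ltr5_start = if (full_length) pos else NA_integer_,
      ltr5_end = if (full_length) pos + f$ltr_length else NA_integer_,
      ltr3_start = if (full_length) pos + f$element_length - f$ltr_length else NA_integer_,
      ltr3_end = if (full_length) pos + f$element_length else NA_integer_,
      epoch = f$epoch, age_years = age, annotated = annotated,
      degenerated = degenerated)
  }
  for (te in anc_tes) {
    f <- fams[[te$fam]]
    present <- share[[te$seg]]
    for (g in present) add_te(te$fam, g, te$pos, Tdiv, f$ltr_length > 0, TRUE, FALSE)
  }
  for (te in lin_tes) {
    add_te(te$fam, te$sub, te$pos, te$age, fams[[te$fam]]$ltr_length > 0,
           TRUE, FALSE)
  }
  # promoter TE fragments (truncated: not full length, no LTRs)
  for (ti in prom_te_triads) {
    pos <- prom_te_pos[ti]
    is_relic <- ti %in% relic_triads
    for (g in subs) {
      annotated <- !is_relic || g == relic_source[[as.character(ti)]]
      te_rows[[length(te_rows) + 1]] <- tibble(
        chrom = chroms[[g]], start = pos, end = pos + ptl, strand = "+",
        family = f_anc$family, subfamily = f_anc$name, full_length = FALSE,
        ltr5_start = NA_integer_, ltr5_end = NA_integer_,
        ltr3_start = NA_integer_, ltr3_end = NA_integer_,
        epoch = "ancestral", age_years = Tdiv, annotated = annotated,
        degenerated = !annotated)
    }
  }
  te_truth <- bind_rows(te_rows)
  te_truth <- mutate(te_truth,
                     te_id = sprintf("TE%05d", seq_len(nrow(te_truth))))
  tes <- validate_te_table(filter(te_truth, .data$annotated))

  ## --- planted patterns and peaks ---------------------------------------
  std <- pattern_standards()
  pat_names <- rownames(std)
  # the balance pattern is planted per triad (promoter divergence biases all
  # TFs the same way, which is what couples binding to expression bias);
  # relic-completed triads are balanced by construction
  triad_pattern <- vapply(seq_len(config$n_triads), function(ti) {
    if (ti %in% relic_triads) "ABD" else
      sample(pat_names, 1, prob = config$balance_mixture)
  }, character(1))
  pattern_truth <- purrr::map_dfr(seq_len(config$n_triads), function(ti) {
    purrr::map_dfr(tfs, function(tf) {
      pat <- triad_pattern[ti]
      props <- perturb_proportions(pat, config$noise_radius)[1, ]
      tibble(triad_id = triad_ids[ti], tf_id = tf, pattern = pat,
             prop_A = props[1], prop_B = props[2], prop_D = props[3],
             signal = rlnorm(1, config$signal_meanlog, config$signal_sdlog))
    })
  })
  half_pk <- config$peak_width %/% 2
  anc_tf <- if (!is.null(f_anc)) f_anc$tf else NA_character_
  peak_rows <- purrr::map_dfr(seq_len(config$n_triads), function(ti) {
    offs <- setNames(as.integer(round(runif(length(tfs), -1000, 1000))), tfs)
    rows <- pattern_truth[pattern_truth$triad_id == triad_ids[ti], ]
    purrr::map_dfr(seq_len(nrow(rows)), function(ri) {
      r <- rows[ri, ]
      has_pt <- ti %in% prom_te_triads && identical(r$tf_id, anc_tf)
      summit <- if (has_pt) {
        prom_te_pos[ti] + prom_te_info$motif_rel + prom_te_info$motif_len %/% 2
      } else {
        tss_all[ti] + offs[[r$tf_id]]
      }
      props <- c(A = r$prop_A, B = r$prop_B, D = r$prop_D)
      keep <- props * r$signal >= 0.02
      if (!any(keep)) return(tibble())
      tibble(tf_id = r$tf_id, chrom = unname(chroms[subs[keep]]),
             start = summit - half_pk, end = summit + half_pk,
             summit = summit, rpkm = unname(props[keep] * r$signal))
    })
  })
  # genome-wide peaks on intact TE-copy motifs outside promoters
  te_copy_peaks <- list()
  motif_center_of <- function(famk, pos) {
    pos + fams[[famk]]$motif_offset + nchar(fams[[famk]]$motif) %/% 2
  }
  for (te in anc_tes) {
    f <- fams[[te$fam]]
    if (is.null(f$motif)) next
    for (g in share[[te$seg]]) {
      te_copy_peaks[[length(te_copy_peaks) + 1]] <- tibble(
        tf_id = f$tf, chrom = chroms[[g]],
        summit = motif_center_of(te$fam, te$pos),
        rpkm = rlnorm(1, config$te_peak_meanlog, config$te_peak_sdlog))
    }
  }
  for (te in lin_tes) {
    f <- fams[[te$fam]]
    if (is.null(f$motif)) next
    te_copy_peaks[[length(te_copy_peaks) + 1]] <- tibble(
      tf_id = f$tf, chrom = chroms[[te$sub]],
      summit = motif_center_of(te$fam, te$pos),
      rpkm = rlnorm(1, config$te_peak_meanlog, config$te_peak_sdlog))
  }
  te_peaks <- if (length(te_copy_peaks) > 0) {
    mutate(bind_rows(te_copy_peaks), start = .data$summit - half_pk,
           end = .data$summit + half_pk)
  } else tibble()
  # random background peaks in non-gene segments
  bg_segs <- setdiff(seq_len(n_seg), gene_segs)
  bg_rows <- purrr::map_dfr(tfs, function(tf) {
    purrr::map_dfr(subs, function(g) {
      si <- sample(bg_segs, config$n_background_peaks, replace = TRUE)
      summit <- seg_start[si] + as.integer(round(runif(length(si), half_pk + 1,
                                                       seg_len - half_pk - 1)))
      tibble(tf_id = tf, chrom = chroms[[g]], summit = summit,
             start = summit - half_pk, end = summit + half_pk,
             rpkm = rlnorm(length(si), config$te_peak_meanlog,
                           config$te_peak_sdlog))
    })
  })
  peaks <- bind_rows(peak_rows, te_peaks, bg_rows)
  peaks <- mutate(peaks,
                  start = as.integer(pmax(.data$start, 0)),
                  end = as.integer(pmin(.data$end, L)),
                  summit = as.integer(.data$summit),
                  strand = ".", score = 0)
  peaks <- arrange(peaks, .data$tf_id, .data$chrom, .data$start, .data$summit)
  peaks <- mutate(peaks, name = sprintf("peak%06d", seq_len(nrow(peaks))))

  ## --- DHS and expression -----------------------------------------------
  prom_sig <- summarise(
    group_by(inner_join(select(peaks, "tf_id", "chrom", "summit", "rpkm"),
                        select(genes, "triad_id", "subgenome", "chrom", "tss"),
                        by = "chrom", relationship = "many-to-many"),
             .data$triad_id, .data$subgenome),
    signal = sum(.data$rpkm[abs(.data$summit - .data$tss) <=
                              config$promoter_half_width]),
    .groups = "drop")
  dhs <- mutate(inner_join(select(genes, "triad_id", "subgenome", "chrom", "tss"),
                           prom_sig, by = c("triad_id", "subgenome")),
                start = as.integer(.data$tss - 200), end = as.integer(.data$tss + 200),
                name = sprintf("%s_%s", .data$triad_id, .data$subgenome),
                score = .data$signal, strand = ".")
  dhs <- select(dhs, "chrom", "start", "end", "name", "score", "strand")
  expression <- mutate(
    inner_join(select(genes, "gene_id", "triad_id", "subgenome"),
               prom_sig, by = c("triad_id", "subgenome")),
    tpm = config$expression_scale * .data$signal^config$expression_exponent *
      rlnorm(dplyr::n(), 0, config$expression_sdlog))
  expression <- select(expression, "gene_id", "tpm")

  ## --- alignment and synteny blocks -------------------------------------
  block_rows <- list()
  for (si in seq_len(n_seg)) {
    mem <- share[[si]]
    if (length(mem) < 2) next
    idx <- (seg_start[si] + 1):(seg_start[si] + seg_len)
    for (a in seq_along(mem)) {
      for (b in seq_along(mem)) {
        if (a == b) next
        ident <- 100 * mean(genome_chars[[mem[a]]][idx] ==
                              genome_chars[[mem[b]]][idx])
        block_rows[[length(block_rows) + 1]] <- tibble(
          query_chrom = chroms[[mem[a]]], query_start = seg_start[si],
          query_end = seg_start[si] + seg_len,
          subject_chrom = chroms[[mem[b]]], subject_start = seg_start[si],
          subject_end = seg_start[si] + seg_len, identity = round(ident, 2))
      }
    }
  }
  blocks <- bind_rows(block_rows)
  synteny <- purrr::map_dfr(subs, function(g) {
    tibble(chrom = chroms[[g]], start = seg_start[gene_segs],
           end = seg_start[gene_segs] + seg_len,
           block_id = sprintf("syn%03d", seq_along(gene_segs)))
  })

  ## --- region truth ------------------------------------------------------
  region_truth <- purrr::map_dfr(subs, function(g) {
    kl <- vapply(seq_len(n_seg), function(si) {
      if (!(g %in% share[[si]])) "specific"
      else if (length(share[[si]]) == 3) "homo3"
      else if (length(share[[si]]) == 2) "homo2"
      else "specific"
    }, character(1))
    tibble(chrom = chroms[[g]], start = seg_start, end = seg_start + seg_len,
           klass = kl)
  })

  ## --- presence truth ----------------------------------------------------
  presence_truth <- purrr::map_dfr(seq_len(config$n_triads), function(ti) {
    is_pt <- ti %in% prom_te_triads
    is_relic <- ti %in% relic_triads
    src <- if (is_relic) relic_source[[as.character(ti)]] else NA_character_
    tibble(triad_id = triad_ids[ti], subgenome = subs,
           has_te = is_pt & (!is_relic | subs == src),
           has_dte = is_relic & subs != src)
  })

  genome <- Biostrings::DNAStringSet(
    setNames(vapply(subs, function(g) paste(genome_chars[[g]], collapse = ""),
                    character(1)), unname(chroms[subs])))
  sizes <- tibble(chrom = unname(chroms[subs]), length = L)

  sim <- structure(list(
    config = config, genome = genome, sizes = sizes,
    genes = genes, triads = triads, promoters = promoters,
    tes = tes, te_truth = te_truth, peaks = peaks, dhs = dhs,
    expression = expression, blocks = blocks, synteny = synteny,
    region_truth = region_truth, pattern_truth = pattern_truth,
    relic_truth = relic_truth, presence_truth = presence_truth),
    class = "polyploid_sim")
  if (!is.null(out_dir)) write_sim_dataset(sim, out_dir)
  sim
}

#' @export
print.polyploid_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic polyploid: 3 x %s bp, %d triads, %d TFs, %d annotated TEs, %d relics\n",
    format(x$sizes$length[1], big.mark = ",", scientific = FALSE),
    nrow(x$triads),
    length(unique(x$peaks$tf_id)), nrow(x$tes),
    nrow(x$relic_truth)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the standard-format files of a [simulate_polyploid()] dataset:
#' one FASTA per subgenome, GFF3 gene models, the TE annotation TSV, one
#' narrowPeak file per TF, DHS BED, expression TSV, alignment-block,
#' synteny and triad TSVs, and the truth tables under `truth/`. Output is
#' deterministic (byte-identical for identical simulations).
#'
#' @param sim A `polyploid_sim` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  for (i in seq_along(sim$genome)) {
    chrom <- names(sim$genome)[i]
    sub <- subgenome_of(chrom)
    Biostrings::writeXStringSet(sim$genome[i],
                                file.path(out_dir, sprintf("genome_%s.fa", sub)),
                                width = 80L)
  }
  write_gff_genes(sim$genes, file.path(out_dir, "genes.gff3"))
  write_table(select(sim$tes, "chrom", "start", "end", "strand", "family",
                     "subfamily", "full_length", "ltr5_start", "ltr5_end",
                     "ltr3_start", "ltr3_end", "te_id"),
              file.path(out_dir, "te_annotations.tsv"))
  for (tf in unique(sim$peaks$tf_id)) {
    write_narrowpeak(filter(sim$peaks, .data$tf_id == tf),
                     file.path(out_dir, "peaks", paste0(tf, ".narrowPeak")))
  }
  dhs <- arrange(sim$dhs, .data$chrom, .data$start)
  readr::write_lines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", dhs$chrom, dhs$start,
                             dhs$end, dhs$name,
                             format(dhs$score, trim = TRUE, scientific = FALSE),
                             dhs$strand),
                     file.path(out_dir, "dhs.bed"))
  write_table(sim$expression, file.path(out_dir, "expression.tsv"))
  write_table(sim$blocks, file.path(out_dir, "alignment_blocks.tsv"))
  write_table(sim$synteny, file.path(out_dir, "synteny.tsv"))
  write_table(sim$triads, file.path(out_dir, "triads.tsv"))
  write_table(sim$te_truth, file.path(out_dir, "truth", "te_truth.tsv"))
  write_table(sim$region_truth, file.path(out_dir, "truth", "region_truth.tsv"))
  write_table(sim$pattern_truth, file.path(out_dir, "truth", "pattern_truth.tsv"))
  write_table(sim$relic_truth, file.path(out_dir, "truth", "relic_truth.tsv"))
  write_table(sim$presence_truth,
              file.path(out_dir, "truth", "presence_truth.tsv"))
  invisible(out_dir)
}
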