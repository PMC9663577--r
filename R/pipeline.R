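#' Run the full analysis pipeline on a dataset
#'
#' Executes every analysis stage of the package on a simulated (or
#' equivalently structured) dataset: region homology classification and
#' TFBS localization, merged-site/HOT calling, binarized-bin TF correlation,
#' TFAS and triad balance patterns, TE-subfamily enrichment, TE-embedded
#' TFBS and degenerated-TE detection with presence classification, LTR
#' insertion dating and cross-lineage expansion profiling.
#'
#' @param sim A `polyploid_sim` object (or a list with the same elements
#'   built from files via the readers).
#' @param hot_threshold HOT strict TF-count bound (default 12).
#' @param min_region_len Reciprocal-run threshold in bp (default 400).
#' @param n_perm Permutations for the dTE control (default 100 here; raise
#'   to 1000 for a paper-scale control).
#' @param seed Seed for the sampling stages.
#' @return Named list with each stage's result tables plus a
#'   `truth_report` from [truth_check()].
#' @export
run_pipeline <- function(sim, hot_threshold = 12, min_region_len = 400,
                         n_perm = 100, seed = 1) {
  genome_bp <- sum(sim$sizes$length)
  regions <- classify_regions(sim$blocks, sim$sizes, synteny = sim$synteny,
                              min_len = min_region_len)
  merged <- merge_tfbs(sim$peaks)
  hot <- call_hot(merged, threshold = hot_threshold)
  located <- locate_in_classes(merged, regions)
  tf_cor <- tf_binding_correlation(sim$peaks, sim$sizes)
  tfas <- compute_tfas(sim$genes, sim$peaks)
  patterns <- classify_patterns(tfas, sim$triads)
  subfams <- select_subfamilies(sim$tes, genome_bp)
  es <- purrr::map_dfr(unique(sim$peaks$tf_id), function(tf) {
    enrichment_score(filter(sim$peaks, .data$tf_id == tf), sim$tes,
                     subfamilies = subfams$subfamily, query_label = tf)
  })
  te_sites <- find_te_tfbs(sim$peaks, sim$tes, sim$promoters)
  dte_hits <- find_dte(te_sites, sim$promoters, sim$genome, sim$tes)
  presence <- classify_te_presence(patterns, te_sites, dte_hits)
  perm <- dte_permutation_control(te_sites, sim$promoters, sim$genome,
                                  sim$tes, n_perm = n_perm, seed = seed)
  ages <- te_insertion_age(sim$tes, sim$genome)
  fl_subfams <- unique(sim$tes$subfamily[sim$tes$full_length])
  lineage <- purrr::map(setNames(fl_subfams, fl_subfams), function(sf) {
    tryCatch(suppressWarnings(
      cross_lineage_te_distance(sim$tes, sim$genome, subfamily = sf,
                                n_sample = 40, seed = seed, min_copies = 10,
                                max_pairs = 400)),
      error = function(e) NULL)
  })
  report <- truth_check(sim, list(patterns = patterns, regions = regions,
                                  dte_hits = dte_hits, te_ages = ages))
  list(regions = regions, merged_sites = hot, located_tfbs = located,
       tf_cor = tf_cor, tfas = tfas, patterns = patterns,
       subfamilies = subfams, enrichment = es, te_sites = te_sites,
       dte_hits = dte_hits, presence = presence, dte_permutation = perm,
       te_ages = ages, lineage_distance = lineage, truth_report = report)
}
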