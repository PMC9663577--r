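#' Compare pipeline results against planted ground truth
#'
#' Scores any subset of pipeline outputs against the truth tables of a
#' [simulate_polyploid()] dataset. Stages are matched by id, so shuffled or
#' partial results are scored honestly (missing entries count against
#' recovery).
#'
#' @param sim A `polyploid_sim` object.
#' @param results Named list with any of:
#'   * `patterns` -- output of [classify_patterns()];
#'   * `regions` -- output of [classify_regions()];
#'   * `dte_hits` -- output of [find_dte()];
#'   * `te_ages` -- output of [te_insertion_age()].
#' @return Tibble `stage`, `metric`, `value`, `n` (`n` = truth entities
#'   scored). Pattern confusion counts are attached as the
#'   `pattern_confusion` attribute.
#' @export
truth_check <- function(sim, results) {
  out <- list()
  if (!is.null(results$patterns)) {
    truth <- select(sim$pattern_truth, "triad_id", "tf_id", truth = "pattern")
    res <- select(filter(results$patterns, !.data$filtered),
                  "triad_id", "tf_id", called = "pattern")
    j <- left_join(truth, res, by = c("triad_id", "tf_id"))
    acc <- mean(as.character(j$called) == j$truth, na.rm = FALSE)
    acc[is.na(acc)] <- 0
    out$patterns <- tibble(
      stage = "patterns",
      metric = c("accuracy", "missing"),
      value = c(sum(as.character(j$called) == j$truth, na.rm = TRUE) / nrow(j),
                sum(is.na(j$called))),
      n = nrow(j))
    attr_conf <- table(truth = j$truth, called = addNA(j$called))
  } else attr_conf <- NULL
  if (!is.null(results$regions)) {
    part <- results$regions[results$regions$klass %in%
                              c("specific", "homo2", "homo3"), ]
    agree <- sum(purrr::map_dbl(c("specific", "homo2", "homo3"), function(k) {
      overlap_bp(part[part$klass == k, ],
                 sim$region_truth[sim$region_truth$klass == k, ])
    }))
    total <- sum(sim$region_truth$end - sim$region_truth$start)
    out$regions <- tibble(stage = "regions", metric = "base_accuracy",
                          value = agree / total, n = total)
  }
  if (!is.null(results$dte_hits)) {
    truth <- sim$relic_truth
    hits <- results$dte_hits
    recovered <- vapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      any(hits$triad_id == tr$triad_id &
            hits$target_subgenome == tr$subgenome &
            hits$chrom == tr$chrom &
            hits$start < tr$end & hits$end > tr$start)
    }, logical(1))
    matched_hits <- vapply(seq_len(nrow(hits)), function(i) {
      h <- hits[i, ]
      any(truth$triad_id == h$triad_id & truth$subgenome == h$target_subgenome &
            truth$chrom == h$chrom & truth$start < h$end & truth$end > h$start)
    }, logical(1))
    out$dte <- tibble(stage = "dte",
                      metric = c("recall", "precision", "missing"),
                      value = c(mean(recovered),
                                if (nrow(hits) > 0) mean(matched_hits) else NA,
                                sum(!recovered)),
                      n = nrow(truth))
  }
  if (!is.null(results$te_ages)) {
    truth <- select(sim$te_truth, "te_id", true_age = "age_years")
    j <- inner_join(results$te_ages, truth, by = "te_id")
    j <- filter(j, !.data$saturated, .data$true_age > 0)
    out$ages <- tibble(
      stage = "te_ages",
      metric = c("median_relative_error", "n_dated"),
      value = c(median(abs(j$age_years - j$true_age) / j$true_age),
                nrow(j)),
      n = nrow(j))
  }
  res <- bind_rows(out)
  if (!is.null(attr_conf)) attr(res, "pattern_confusion") <- attr_conf
  res
}
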