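#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an expansion profile
#'
#' @param x An `expansion_profile` object.
#' @param ... Unused.
#' @return Tibble of pairwise distances (`i`, `j`, `distance`).
#' @export
tidy.expansion_profile <- function(x, ...) x$distances

#' One-row summary of an expansion profile
#'
#' @param x An `expansion_profile` object.
#' @param ... Unused.
#' @return Tibble with `n_sequences`, `n_pairs`, `n_saturated`, `n_modes`,
#'   `bandwidth`, `main_mode`.
#' @export
glance.expansion_profile <- function(x, ...) {
  tibble(n_sequences = x$n_sequences, n_pairs = nrow(x$distances),
         n_saturated = x$n_saturated, n_modes = nrow(x$modes),
         bandwidth = x$bandwidth,
         main_mode = if (nrow(x$modes) > 0)
           x$modes$location[which.max(x$modes$density)] else NA_real_)
}

#' Tidy cross-lineage TE distances
#'
#' @param x A `lineage_distance` object.
#' @param ... Unused.
#' @return Tibble `lineage_1`, `lineage_2`, `within`, `distance`.
#' @export
tidy.lineage_distance <- function(x, ...) x$distances

#' One-row-per-lineage-pair summary of cross-lineage TE distances
#'
#' @param x A `lineage_distance` object.
#' @param ... Unused.
#' @return Tibble with pair labels, pair counts, and main mode location.
#' @export
glance.lineage_distance <- function(x, ...) {
  summarise(group_by(x$distances, .data$lineage_1, .data$lineage_2,
                     .data$within),
            n_pairs = dplyr::n(), median_distance = median(.data$distance),
            .groups = "drop")
}

#' Tidy a dTE permutation control
#'
#' @param x A `dte_permutation` object.
#' @param ... Unused.
#' @return Tibble `perm`, `hits`.
#' @export
tidy.dte_permutation <- function(x, ...) tibble(perm = x$perm, hits = x$hits)

#' One-row summary of a dTE permutation control
#'
#' @param x A `dte_permutation` object.
#' @param ... Unused.
#' @return Tibble `n_perm`, `n_sites`, `mean_hits`, `max_hits`.
#' @export
glance.dte_permutation <- function(x, ...) {
  tibble(n_perm = attr(x, "n_perm"), n_sites = attr(x, "n_sites"),
         mean_hits = mean(x$hits), max_hits = max(x$hits))
}

#' Tidy a TF binding correlation
#'
#' @param x A `tf_cor` object.
#' @param ... Unused.
#' @return Long tibble `tf_1`, `tf_2`, `r`.
#' @export
tidy.tf_cor <- function(x, ...) {
  m <- x$r
  tibble(tf_1 = rep(rownames(m), times = ncol(m)),
         tf_2 = rep(colnames(m), each = nrow(m)),
         r = as.vector(m))
}
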