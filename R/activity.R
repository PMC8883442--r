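#' Per-strain condition counts for each kinase
#'
#' After QC, a kinase's activity in a strain is summarised as the number of
#' retained conditions in which it caused a growth phenotype.
#'
#' @param matrix Kinase-condition score tibble.
#' @param retained Flagged tibble from [filter_conditions()] or a tibble of
#'   retained `condition_id`, `strain` pairs.
#' @param defect_min_score Minimum score counted as a phenotype (default 1).
#'
#' @return Tibble `protein_id`, `strain`, `n_conditions_defect`. Every
#'   protein x strain present in the (retained part of the) matrix gets a
#'   row, zero counts included.
#' @export
condition_counts <- function(matrix, retained, defect_min_score = 1L) {
  if ("excluded" %in% names(retained)) {
    retained <- filter(retained, !.data$excluded)
  }
  m <- semi_join(matrix, retained, by = c("condition_id", "strain"))
  m %>%
    group_by(.data$protein_id, .data$strain) %>%
    summarise(n_conditions_defect = sum(.data$score >= defect_min_score),
              .groups = "drop")
}

#' Bin per-strain condition counts on a 0-4 scale
#'
#' Bin 0 encodes "no phenotype in any condition". Kinases with positive
#' counts are split into bins 1-4. Under the default `zero_plus_quartiles`
#' scheme the split points are the quartiles of that strain's positive-count
#' distribution, with ties assigned to the lower bin so equal counts always
#' share a bin. `fixed_edges` uses four user-supplied upper edges instead
#' (bin = 1 + number of edges strictly below the count, capped at 4).
#'
#' @param counts Tibble from [condition_counts()].
#' @param scheme `"zero_plus_quartiles"` (default) or `"fixed_edges"`.
#' @param edges Numeric length 4, required for `"fixed_edges"`: counts in
#'   `(0, e1]` map to bin 1, `(e1, e2]` to 2, etc.
#' @return The input tibble with an integer `bin` column in `0:4`.
#' @export
bin_counts <- function(counts, scheme = c("zero_plus_quartiles", "fixed_edges"),
                       edges = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "fixed_edges") {
    if (is.null(edges) || length(edges) != 4L) {
      abort("fixed_edges scheme requires exactly 4 edges.",
            class = "kinarray_parameter_error")
    }
    return(mutate(counts, bin = ifelse(
      .data$n_conditions_defect == 0L, 0L,
      pmin(1L + (.data$n_conditions_defect > edges[1]) +
             (.data$n_conditions_defect > edges[2]) +
             (.data$n_conditions_defect > edges[3]), 4L))))
  }
  counts %>%
    group_by(.data$strain) %>%
    mutate(bin = {
      pos <- .data$n_conditions_defect[.data$n_conditions_defect > 0L]
      if (length(pos) == 0L) {
        rep(0L, n())
      } else {
        q <- quantile(pos, c(0.25, 0.5, 0.75), names = FALSE)
        ifelse(.data$n_conditions_defect == 0L, 0L,
               1L + (.data$n_conditions_defect > q[1]) +
                 (.data$n_conditions_defect > q[2]) +
                 (.data$n_conditions_defect > q[3]))
      }
    }) %>%
    ungroup() %>%
    mutate(bin = as.integer(.data$bin))
}

#' Cluster kinases into activity tiers from their bin profiles
#'
#' Agglomerative hierarchical clustering of the kinases' per-strain bin
#' vectors (Euclidean distance), cut into `k` groups. Tier labels are
#' assigned by descending cluster mean bin, so labelling does not depend on
#' cluster indices: with `k = 3` the tiers are `topmost`, `highly`,
#' `moderately` (active); `k = 4` appends `inactive`.
#'
#' @param bins Tibble from [bin_counts()] (`protein_id`, `strain`, `bin`).
#'   Strains missing for a kinase are imputed as bin 0.
#' @param k Number of tiers (default 3).
#' @param linkage `"ward"` (default, Ward linkage on Euclidean distances),
#'   `"average"`, or `"complete"`.
#'
#' @return Object of class `"tier_clustering"`: list with `tiers` (tibble
#'   `protein_id`, `tier`), `bin_matrix`, the `hclust` tree, `k`, `linkage`,
#'   and `cluster_means`. [tidy()] returns the tier table, [glance()] the
#'   tier sizes and mean bins.
#' @export
cluster_tiers <- function(bins, k = 3L, linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  wide <- bins %>%
    select("protein_id", "strain", "bin") %>%
    tidyr::pivot_wider(names_from = "strain", values_from = "bin",
                       values_fill = 0L) %>%
    arrange(.data$protein_id)
  bm <- as.matrix(wide[-1L])
  rownames(bm) <- wide$protein_id
  n_distinct_vec <- nrow(unique(bm))
  if (k > n_distinct_vec) {
    abort(sprintf("k = %d exceeds the %d distinct bin vector(s).",
                  k, n_distinct_vec),
          class = "kinarray_clustering_error")
  }
  method <- switch(linkage, ward = "ward.D2", average = "average",
                   complete = "complete")
  hc <- hclust(dist(bm, method = "euclidean"), method = method)
  raw <- cutree(hc, k = k)
  means <- tapply(rowMeans(bm), raw, mean)
  ord <- order(means, decreasing = TRUE)  # cluster ids by descending mean
  labels <- tier_labels(k)
  tier_of <- setNames(labels, names(means)[ord])
  tiers <- tibble(protein_id = rownames(bm),
                  tier = factor(unname(tier_of[as.character(raw)]),
                                levels = labels))
  structure(list(tiers = tiers, bin_matrix = bm, hclust = hc, k = k,
                 linkage = linkage,
                 cluster_means = tibble(tier = labels,
                                        mean_bin = as.numeric(means[ord]))),
            class = "tier_clustering")
}

tier_labels <- function(k) {
  base <- c("topmost", "highly", "moderately", "inactive")
  if (k <= 4L) base[seq_len(k)] else sprintf("tier_%d", seq_len(k))
}

#' @export
print.tier_clustering <- function(x, ...) {
  cat("Activity tiers (", x$linkage, " linkage, k = ", x$k, "):\n", sep = "")
  print(glance(x), ...)
  invisible(x)
}

#' @rdname cluster_tiers
#' @param x A `tier_clustering` object.
#' @param ... Unused.
#' @method tidy tier_clustering
#' @export
tidy.tier_clustering <- function(x, ...) x$tiers

#' @rdname cluster_tiers
#' @method glance tier_clustering
#' @export
glance.tier_clustering <- function(x, ...) {
  x$tiers %>%
    count(.data$tier, name = "n_kinases") %>%
    left_join(x$cluster_means, by = "tier")
}

#' Rank kinases by overall activity
#'
#' Orders kinases by total bin score across strains, breaking ties by total
#' raw condition count and then by identifier, and returns the top `n` —
#' the "most phenotypes across all condition-strain pairs" list.
#'
#' @param binned Tibble from [bin_counts()] (`protein_id`, `strain`,
#'   `n_conditions_defect`, `bin`).
#' @param n How many kinases to return (default 30).
#' @return Tibble `rank`, `protein_id`, `bin_sum`, `count_sum`.
#' @export
rank_top <- function(binned, n = 30L) {
  if (!is.numeric(n) || n <= 0) {
    abort("n must be a positive integer.", class = "kinarray_parameter_error")
  }
  binned %>%
    group_by(.data$protein_id) %>%
    summarise(bin_sum = sum(.data$bin),
              count_sum = sum(.data$n_conditions_defect), .groups = "drop") %>%
    arrange(dplyr::desc(.data$bin_sum), dplyr::desc(.data$count_sum),
            .data$protein_id) %>%
    head(n) %>%
    mutate(rank = row_number(), .before = 1L)
}
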