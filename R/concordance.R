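#' Per-strain sets of kinase-condition defect pairs
#'
#' For cross-strain concordance: in each strain, which (kinase, condition)
#' pairs showed a growth defect? Only conditions evaluated and retained in
#' that strain can contribute, so a condition absent in one strain never
#' creates disagreement.
#'
#' @param matrix Kinase-condition score tibble.
#' @param retained Flagged tibble from [filter_conditions()] or retained
#'   pairs (`condition_id`, `strain`).
#' @param defect_min_score Minimum defect score (default 1).
#' @return Tibble `strain`, `protein_id`, `condition_id` — the long form of
#'   the per-strain defect-pair sets.
#' @export
defect_pair_sets <- function(matrix, retained, defect_min_score = 1L) {
  if ("excluded" %in% names(retained)) {
    retained <- filter(retained, !.data$excluded)
  }
  matrix %>%
    semi_join(retained, by = c("condition_id", "strain")) %>%
    filter(.data$score >= defect_min_score) %>%
    select("strain", "protein_id", "condition_id") %>%
    arrange(.data$strain, .data$protein_id, .data$condition_id)
}

#' Upset counts: exact strain-combination membership of defect pairs
#'
#' Counts every (kinase, condition) pair defective in at least one strain
#' under the exact combination of strains in which it is defective — the
#' numbers behind an upset plot. Combination counts therefore partition the
#' union: they sum to the number of distinct defective pairs.
#'
#' @param sets Tibble from [defect_pair_sets()].
#' @return Tibble `combination` (strain names joined by `+`, sorted),
#'   `degree` (number of strains), `count`, ordered by descending count.
#' @export
upset_counts <- function(sets) {
  if (nrow(sets) == 0L) {
    return(tibble(combination = character(), degree = integer(),
                  count = integer()))
  }
  sets %>%
    group_by(.data$protein_id, .data$condition_id) %>%
    summarise(combination = paste(sort(unique(.data$strain)), collapse = "+"),
              degree = n_distinct(.data$strain), .groups = "drop") %>%
    count(.data$combination, .data$degree, name = "count") %>%
    arrange(dplyr::desc(.data$count), .data$combination)
}

#' Histogram of severe-defect strain breadth per kinase
#'
#' A kinase is "severe" in a strain if it scores 3 (severe growth
#' reduction) in at least one retained condition of that strain. This
#' tallies how many kinases are severe in exactly `k` strains; kinases with
#' no severe defect anywhere are omitted.
#'
#' @inheritParams defect_pair_sets
#' @return Tibble `n_strains`, `n_kinases`, descending in `n_strains`.
#' @export
severe_strain_histogram <- function(matrix, retained) {
  severe <- defect_pair_sets(matrix, retained, defect_min_score = 3L)
  if (nrow(severe) == 0L) {
    return(tibble(n_strains = integer(), n_kinases = integer()))
  }
  severe %>%
    distinct(.data$protein_id, .data$strain) %>%
    count(.data$protein_id, name = "n_strains") %>%
    count(.data$n_strains, name = "n_kinases") %>%
    arrange(dplyr::desc(.data$n_strains))
}
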