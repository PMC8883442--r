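#' Count kinases with a growth defect per condition-strain pair
#'
#' The screen's QC statistic: for each condition evaluated in each strain,
#' how many kinases show a growth-reduction score at or above a cutoff.
#' Conditions that suppress growth of a large fraction of the array are
#' globally toxic rather than kinase-specific and are excluded downstream.
#'
#' @param matrix Kinase-condition score tibble (`protein_id`, `strain`,
#'   `condition_id`, `score`), e.g. from [aggregate_to_kinase()].
#' @param defect_min_score Minimum score counted as a defect (1-3; default 1,
#'   any growth reduction).
#' @param restrict_to `"kinases_only"` (default) counts only non-control
#'   proteins and requires `annotations`; `"all_constructs"` counts every
#'   protein in the matrix.
#' @param annotations Annotation tibble with `protein_id`, `is_control`;
#'   required for `"kinases_only"`.
#'
#' @return Tibble with `condition_id`, `strain`, `n_defect`, `n_evaluated`.
#'   Missing entries contribute to neither numerator nor denominator;
#'   condition-strain pairs with no observations produce no row.
#' @export
defect_counts <- function(matrix, defect_min_score = 1L,
                          restrict_to = c("kinases_only", "all_constructs"),
                          annotations = NULL) {
  restrict_to <- match.arg(restrict_to)
  if (!is.numeric(defect_min_score) || length(defect_min_score) != 1L ||
      defect_min_score < 1 || defect_min_score > 3) {
    abort("defect_min_score must be a single value in 1-3.",
          class = "kinarray_parameter_error")
  }
  if (nrow(matrix) == 0L) abort("Score matrix is empty.", class = "kinarray_parameter_error")
  m <- matrix
  if (restrict_to == "kinases_only") {
    if (is.null(annotations)) {
      abort("annotations are required for restrict_to = 'kinases_only'.",
            class = "kinarray_parameter_error")
    }
    kin <- annotations$protein_id[!annotations$is_control]
    m <- filter(m, .data$protein_id %in% kin)
  }
  m %>%
    filter(!is.na(.data$score)) %>%
    group_by(.data$condition_id, .data$strain) %>%
    summarise(n_defect = sum(.data$score >= defect_min_score),
              n_evaluated = n(), .groups = "drop")
}

#' Locate the valley of a bimodal defect-count distribution
#'
#' When per-condition defect counts are histogrammed, specific conditions
#' form a low mode and globally toxic conditions a high mode, with a sparse
#' valley between them. This finds the minimum-density point of the
#' histogram inside a search window, as a data-driven alternative to a fixed
#' exclusion threshold.
#'
#' @param counts Integer vector of per-condition defect counts (>= 10 values).
#' @param bin_width Histogram bin width.
#' @param search_range Length-2 numeric `(low, high)`: midpoints outside this
#'   window are not considered.
#'
#' @return The valley midpoint. Tied minimum-density bins that form a
#'   contiguous run return the run's central midpoint (so a wide empty gap
#'   yields its centre); among several runs the lowest is chosen. If the
#'   in-range histogram has no interior minimum (unimodal), `NA` is returned
#'   with a warning.
#' @export
detect_valley <- function(counts, bin_width = 10,
                          search_range = c(0, max(counts))) {
  if (length(counts) == 0L) {
    abort("counts must be non-empty.", class = "kinarray_parameter_error")
  }
  if (length(counts) < 10L) {
    abort("Valley detection needs at least 10 count values.",
          class = "kinarray_parameter_error")
  }
  breaks <- seq(floor(min(counts) / bin_width) * bin_width,
                max(counts) + bin_width, by = bin_width)
  h <- graphics::hist(counts, breaks = breaks, plot = FALSE)
  mids <- h$mids
  dens <- h$counts
  in_range <- mids >= search_range[1] & mids <= search_range[2]
  if (!any(in_range)) {
    warn("Search range contains no histogram bins; no valley found.")
    return(NA_real_)
  }
  cand <- which(in_range)
  min_d <- min(dens[cand])
  # unimodal in range: the in-range minimum has no higher-density bin on
  # both sides anywhere in the histogram
  at_min <- cand[dens[cand] == min_d]
  has_flank <- vapply(at_min, function(i) {
    any(dens[seq_len(i - 1L)] > min_d) && any(dens[-seq_len(i)] > min_d)
  }, logical(1))
  if (!any(has_flank)) {
    warn("Defect-count histogram is unimodal in the search range; no valley.")
    return(NA_real_)
  }
  at_min <- at_min[has_flank]
  runs <- split(at_min, cumsum(c(1L, diff(at_min) != 1L)))
  run <- runs[[1L]]  # lowest run
  (mids[run[1L]] + mids[run[length(run)]]) / 2
}

#' Flag globally toxic condition-strain pairs
#'
#' Excludes condition-strain pairs whose defect count exceeds a cutoff
#' (strictly more than `max_defect` kinases with reduced growth; the
#' reference screen used 175). A fractional cutoff relative to the number of
#' kinases evaluated in the pair is available as an alternative.
#'
#' @param counts Defect-count tibble from [defect_counts()].
#' @param max_defect Absolute cutoff (default 175); exclusion is strict
#'   (`n_defect > max_defect`).
#' @param max_defect_frac Optional fraction in (0, 1]; when given it
#'   overrides `max_defect` with `max_defect_frac * n_evaluated` per pair.
#'
#' @return The input tibble with a logical `excluded` column. Retained pairs
#'   are `filter(x, !excluded)`.
#' @export
filter_conditions <- function(counts, max_defect = 175, max_defect_frac = NULL) {
  cutoff <- if (is.null(max_defect_frac)) max_defect else
    max_defect_frac * counts$n_evaluated
  mutate(counts, excluded = .data$n_defect > cutoff)
}

#' Evaluable condition-strain accounting after QC
#'
#' Summarises the retained screen: total condition-strain pairs, conditions
#' per strain, and conditions retained in every strain of the dataset.
#'
#' @param conditions Condition tibble with `evaluated_<strain>` flags (used
#'   to define the dataset's strain set).
#' @param retained Either the flagged tibble from [filter_conditions()] or a
#'   tibble of retained pairs with `condition_id`, `strain`.
#'
#' @return List of class `"evaluable_accounting"`: `n_pairs`, `per_strain`
#'   (tibble `strain`, `n_conditions`), `n_shared`, `strains`.
#' @export
evaluable_accounting <- function(conditions, retained) {
  if ("excluded" %in% names(retained)) {
    retained <- filter(retained, !.data$excluded)
  }
  strains <- sub("^evaluated_", "",
                 grep("^evaluated_", names(conditions), value = TRUE))
  pairs <- distinct(retained, .data$condition_id, .data$strain)
  per_strain <- pairs %>%
    count(.data$strain, name = "n_conditions") %>%
    tidyr::complete(strain = strains, fill = list(n_conditions = 0L))
  shared <- pairs %>%
    filter(.data$strain %in% strains) %>%
    count(.data$condition_id) %>%
    filter(.data$n == length(strains)) %>%
    nrow()
  structure(list(n_pairs = nrow(pairs), per_strain = per_strain,
                 n_shared = shared, strains = strains),
            class = "evaluable_accounting")
}

#' @export
print.evaluable_accounting <- function(x, ...) {
  cat(x$n_pairs, "condition-strain pairs retained;",
      x$n_shared, "condition(s) retained in all", length(x$strains), "strains\n")
  print(x$per_strain, ...)
  invisible(x)
}
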