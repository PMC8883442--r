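#' Aggregate spot observations to the kinase level
#'
#' Most proteins in the array are covered by several ORF clones, two vectors
#' (with / without a nuclear localization sequence) and replicate spots.
#' Downstream analysis works on one ordinal score per protein x strain x
#' condition; this collapses clones, vectors and replicates under a stated
#' rule.
#'
#' @param observations Tibble of spot observations (see [read_screen_long()]).
#' @param constructs Tibble of construct records with columns `construct_id`,
#'   `protein_id`, and optionally `is_control`, `is_kinase_dead`.
#' @param rule Aggregation rule. `"max"` (default): the maximum score over
#'   all spots of the protein — any active clone is taken as evidence of
#'   activity. `"median"`: the median spot score, half-integer medians
#'   rounded down to stay on the ordinal scale.
#'
#' @return A tibble with columns `protein_id`, `strain`, `condition_id`,
#'   `score` — one row per combination with at least one observation — and
#'   an `"aggregation"` attribute recording the rule. Kinase-dead constructs
#'   never merge into their wild-type kinase: when a kinase-dead construct
#'   shares its `protein_id` with a non-dead construct it is aggregated
#'   under `<protein_id>-KD`.
#'
#' @details Observations referencing a construct absent from `constructs`
#'   raise an integrity error. The rule `"max"` is idempotent and invariant
#'   to row order, and the aggregated value is an upper bound on every
#'   contributing spot score.
#' @export
aggregate_to_kinase <- function(observations, constructs,
                                rule = c("max", "median")) {
  rule <- match.arg(rule)
  constructs <- tibble::as_tibble(constructs)
  if (!"is_kinase_dead" %in% names(constructs)) constructs$is_kinase_dead <- FALSE
  orphans <- setdiff(unique(observations$construct_id), constructs$construct_id)
  if (length(orphans) > 0L) {
    abort(paste0("Observations reference undeclared construct(s): ",
                 paste(head(orphans, 5L), collapse = ", "),
                 if (length(orphans) > 5L) " ..." else ""),
          class = "kinarray_integrity_error")
  }
  wt_proteins <- unique(constructs$protein_id[!constructs$is_kinase_dead])
  constructs$agg_protein <- ifelse(
    constructs$is_kinase_dead & constructs$protein_id %in% wt_proteins,
    paste0(constructs$protein_id, "-KD"), constructs$protein_id)
  agg_fun <- switch(rule,
    max = function(x) max(x),
    median = function(x) as.integer(floor(median(x))))
  out <- observations %>%
    inner_join(constructs[c("construct_id", "agg_protein")], by = "construct_id") %>%
    group_by(protein_id = .data$agg_protein, .data$strain, .data$condition_id) %>%
    summarise(score = as.integer(agg_fun(.data$score)), .groups = "drop") %>%
    arrange(.data$protein_id, .data$strain, .data$condition_id)
  attr(out, "aggregation") <- rule
  out
}

#' Cross-check a screen dataset for referential consistency
#'
#' Report-only validation: no error is ever raised. Checks observations,
#' construct records, condition metadata and protein annotations against
#' each other.
#'
#' @param observations Spot observation tibble.
#' @param constructs Construct record tibble.
#' @param conditions Condition tibble (with `evaluated_<strain>` flags).
#' @param annotations Protein annotation tibble.
#'
#' @return A list of class `"screen_validation"` with `issues` (tibble:
#'   `type`, `key`, `message`) and `per_strain` observation counts. A fully
#'   consistent dataset yields zero issues.
#' @export
validate_dataset <- function(observations, constructs, conditions, annotations) {
  issues <- list()
  add <- function(type, key, message) {
    issues[[length(issues) + 1L]] <<- tibble(type = type, key = key, message = message)
  }
  orphan_con <- setdiff(unique(observations$construct_id), constructs$construct_id)
  for (k in orphan_con) add("orphan_construct", k, "observation references undeclared construct")
  orphan_cond <- setdiff(unique(observations$condition_id), conditions$condition_id)
  for (k in orphan_cond) add("orphan_condition", k, "observation references undeclared condition")
  orphan_prot <- setdiff(unique(constructs$protein_id), annotations$protein_id)
  for (k in orphan_prot) add("orphan_protein", k, "construct references unannotated protein")

  dup_obs <- observations %>%
    count(across(all_of(.spot_key))) %>% filter(.data$n > 1L)
  for (i in seq_len(nrow(dup_obs))) {
    add("duplicate_observation",
        paste(dup_obs$construct_id[i], dup_obs$strain[i],
              dup_obs$condition_id[i], dup_obs$replicate[i], sep = "/"),
        "duplicated (construct, strain, condition, replicate) key")
  }
  for (tab in list(c("construct_id", "constructs"), c("condition_id", "conditions"),
                   c("protein_id", "annotations"))) {
    d <- switch(tab[2], constructs = constructs, conditions = conditions,
                annotations = annotations)
    dups <- d[[tab[1]]][duplicated(d[[tab[1]]])]
    for (k in unique(dups)) add(paste0("duplicate_", tab[1]), k,
                                paste("duplicated key in", tab[2], "table"))
  }
  ev <- condition_strains(conditions)
  not_eval <- observations %>%
    distinct(.data$strain, .data$condition_id) %>%
    left_join(ev, by = c("strain", "condition_id")) %>%
    filter(is.na(.data$evaluated) | !.data$evaluated)
  for (i in seq_len(nrow(not_eval))) {
    add("not_evaluated", paste(not_eval$condition_id[i], not_eval$strain[i], sep = "/"),
        "scores present for a condition not evaluated in that strain")
  }
  per_strain <- count(observations, .data$strain, name = "n_observations")
  structure(list(
    issues = if (length(issues)) bind_rows(issues) else
      tibble(type = character(), key = character(), message = character()),
    per_strain = per_strain
  ), class = "screen_validation")
}

#' @export
print.screen_validation <- function(x, ...) {
  cat("Screen dataset validation:", nrow(x$issues), "issue(s)\n")
  if (nrow(x$issues) > 0L) print(count(x$issues, .data$type), ...)
  cat("Observations per strain:\n")
  print(x$per_strain, ...)
  invisible(x)
}
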