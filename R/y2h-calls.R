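#' Ordinal dilution score of a spotted growth series
#'
#' Summarises a 1:10 dilution series as `1 + deepest dilution step with any
#' growth` (growth >= 1), or 0 if no step grows. Missing steps are skipped.
#' Growth is expected to be non-increasing along the series; a violation is
#' reported as a data-quality warning, not an error, and the rule is applied
#' literally.
#'
#' @param growth Ordinal growth values (0-3) along the series.
#' @param dilution_step Integer steps (0 = undiluted); defaults to
#'   `0, 1, ...` in input order.
#' @return Integer dilution score in `0:(max step + 1)`.
#' @examples
#' dilution_score(c(3, 2, 0))  # 2
#' @export
dilution_score <- function(growth, dilution_step = seq_along(growth) - 1L) {
  keep <- !is.na(growth)
  growth <- growth[keep]; dilution_step <- dilution_step[keep]
  if (length(growth) == 0L) {
    abort("Dilution series is empty.", class = "kinarray_parameter_error")
  }
  ord <- order(dilution_step)
  g <- growth[ord]
  if (any(diff(g) > 0)) {
    warn("Growth increases along the dilution series; check spotting order.")
  }
  grown <- dilution_step[growth >= 1]
  if (length(grown) == 0L) 0L else as.integer(1L + max(grown))
}

# per (kinase, construct_type, media, replicate) dilution scores of a plate
plate_dilution_scores <- function(plate) {
  obs <- if (inherits(plate, "y2h_plate")) plate$observations else plate
  obs %>%
    group_by(.data$kinase, .data$construct_type, .data$media, .data$replicate) %>%
    summarise(dilution_score = {
      grown <- .data$dilution_step[.data$growth >= 1 & !is.na(.data$growth)]
      if (length(grown) == 0L) 0L else as.integer(1L + max(grown))
    }, .groups = "drop")
}

#' Baseline dilution score per media
#'
#' The reference growth level against which modulation shifts are measured:
#' the median dilution score of a designated spot set, per media, pooling
#' replicates by median.
#'
#' @param plate A `y2h_plate` or its long observation tibble (columns
#'   `kinase`, `construct_type`, `media`, `dilution_step`, `replicate`,
#'   `growth`).
#' @param strategy `"control_kinases"` (default): use spots with
#'   `construct_type == "control"` (the unrelated-kinase controls); falls
#'   back to `"plate_median"` with a warning when no controls are annotated.
#'   `"plate_median"`: median over all spots.
#' @return Tibble `media`, `baseline`.
#' @export
baseline_estimate <- function(plate, strategy = c("control_kinases", "plate_median")) {
  strategy <- match.arg(strategy)
  scores <- plate_dilution_scores(plate)
  if (strategy == "control_kinases") {
    ctrl <- filter(scores, .data$construct_type == "control")
    if (nrow(ctrl) == 0L) {
      warn("No control spots annotated; falling back to plate median.")
      ctrl <- scores
    }
    scores <- ctrl
  }
  scores %>%
    group_by(.data$media) %>%
    summarise(baseline = median(.data$dilution_score), .groups = "drop")
}

#' Call interaction-modulating kinases from a phospho-Y2H plate
#'
#' A kinase is called a loss-of-interaction modulator when its selective
#' media (SD5) dilution score drops at least `min_shift` steps below the
#' SD5 baseline in at least `replicate_rule` of the replicates, while its
#' control-media (SD3) growth stays within `viability_max_drop` of the SD3
#' baseline — the viability gate that keeps growth-toxic kinases (the most
#' active ones, precisely the confound of this assay) from being miscalled.
#' Gain calls are the mirrored rule (SD5 at least `min_shift` above a low
#' baseline). Loss and gain are mutually exclusive; kinases failing the
#' viability gate are reported as `none` with `toxic = TRUE`.
#'
#' @inheritParams baseline_estimate
#' @param baseline Optional tibble `media`, `baseline`; computed with
#'   [baseline_estimate()] when `NULL`.
#' @param min_shift Minimum dilution-score shift (default 2 steps; one step
#'   is within scoring noise of a 1:10 series).
#' @param replicate_rule Minimum fraction of replicates supporting the
#'   shift (default 2/3, i.e. 2 of 3 biological replicates).
#' @param viability_max_drop Maximum tolerated SD3 drop below baseline
#'   (default 1 step), assessed on the median SD3 score across replicates.
#' @param baseline_strategy Passed to [baseline_estimate()] when `baseline`
#'   is `NULL`.
#'
#' @return Tibble of class `"y2h_calls"`, one row per kinase x construct
#'   type: `kinase`, `construct_type`, `mode` (`loss`/`gain`/`none`),
#'   `effect_size` (absolute median shift, dilution steps),
#'   `replicate_support`, `viability_ok`, `toxic`, `sd5_median`,
#'   `sd3_median`. Calling thresholds are recorded in the `"parameters"`
#'   attribute.
#' @export
call_modulators <- function(plate, baseline = NULL, min_shift = 2L,
                            replicate_rule = 2 / 3, viability_max_drop = 1L,
                            baseline_strategy = "control_kinases") {
  scores <- plate_dilution_scores(plate)
  if (is.null(baseline)) {
    baseline <- baseline_estimate(plate, strategy = baseline_strategy)
  }
  if (!all(c("SD3", "SD5") %in% baseline$media)) {
    abort("Baseline must cover both SD3 and SD5.",
          class = "kinarray_parameter_error")
  }
  base5 <- baseline$baseline[baseline$media == "SD5"]
  base3 <- baseline$baseline[baseline$media == "SD3"]
  wide <- scores %>%
    tidyr::pivot_wider(names_from = "media", values_from = "dilution_score") %>%
    group_by(.data$kinase, .data$construct_type) %>%
    summarise(
      sd5_median = median(.data$SD5),
      sd3_median = median(.data$SD3),
      loss_support = mean(.data$SD5 <= base5 - min_shift),
      gain_support = mean(.data$SD5 >= base5 + min_shift),
      .groups = "drop")
  calls <- wide %>%
    mutate(
      viability_ok = .data$sd3_median >= base3 - viability_max_drop,
      loss_ok = .data$viability_ok & .data$loss_support >= replicate_rule,
      gain_ok = .data$viability_ok & .data$gain_support >= replicate_rule,
      mode = dplyr::case_when(
        .data$loss_ok & (!.data$gain_ok | .data$loss_support > .data$gain_support) ~ "loss",
        .data$gain_ok & (!.data$loss_ok | .data$gain_support > .data$loss_support) ~ "gain",
        TRUE ~ "none"),
      toxic = !.data$viability_ok,
      effect_size = ifelse(.data$mode == "none", 0L,
                           as.integer(abs(.data$sd5_median - base5))),
      replicate_support = dplyr::case_when(
        .data$mode == "loss" ~ .data$loss_support,
        .data$mode == "gain" ~ .data$gain_support,
        TRUE ~ 0)) %>%
    select("kinase", "construct_type", "mode", "effect_size",
           "replicate_support", "viability_ok", "toxic",
           "sd5_median", "sd3_median") %>%
    arrange(.data$kinase, .data$construct_type)
  attr(calls, "parameters") <- list(
    min_shift = min_shift, replicate_rule = replicate_rule,
    viability_max_drop = viability_max_drop,
    baseline_sd5 = base5, baseline_sd3 = base3)
  class(calls) <- c("y2h_calls", class(calls))
  calls
}

#' @export
print.y2h_calls <- function(x, ...) {
  p <- attr(x, "parameters")
  cat(sprintf(
    "Phospho-Y2H calls (min_shift = %s, replicate_rule = %.2f, viability_max_drop = %s; baselines SD5 = %s, SD3 = %s)\n",
    p$min_shift, p$replicate_rule, p$viability_max_drop,
    p$baseline_sd5, p$baseline_sd3))
  NextMethod()
}

#' Phospho-dependence of a modulation call
#'
#' A modulation is phospho-dependent when the wild-type kinase modulates the
#' interaction but its kinase-dead variant does not. A kinase-dead variant
#' that reproduces the wild-type mode flags a possible scaffold or
#' ternary-complex effect instead, and yields `FALSE`.
#'
#' @param wt_call,kd_call One-row subsets of a [call_modulators()] result
#'   (or any list/rows with `kinase` and `mode`), for the wild-type and
#'   kinase-dead constructs of the same kinase.
#' @return Logical flag.
#' @export
phospho_dependence <- function(wt_call, kd_call) {
  wt_kin <- wt_call$kinase[1]; kd_kin <- kd_call$kinase[1]
  if (!identical(wt_kin, kd_kin)) {
    abort(sprintf("Kinase mismatch: wild-type '%s' vs kinase-dead '%s'.",
                  wt_kin, kd_kin),
          class = "kinarray_integrity_error")
  }
  wt_mode <- as.character(wt_call$mode[1])
  kd_mode <- as.character(kd_call$mode[1])
  wt_mode != "none" && kd_mode == "none"
}

#' Pair wild-type and kinase-dead calls into phospho-dependence flags
#'
#' @param calls A [call_modulators()] result containing both `kinase` and
#'   `kinase_dead` construct types for at least one kinase.
#' @return Tibble `kinase`, `wt_mode`, `kd_mode`, `phospho_dependent`.
#' @export
phospho_dependence_table <- function(calls) {
  wt <- filter(calls, .data$construct_type == "kinase")
  kd <- filter(calls, .data$construct_type == "kinase_dead")
  paired <- inner_join(
    select(wt, "kinase", wt_mode = "mode"),
    select(kd, "kinase", kd_mode = "mode"), by = "kinase")
  mutate(paired, phospho_dependent =
           .data$wt_mode != "none" & .data$kd_mode == "none")
}
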