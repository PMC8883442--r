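#' Configuration for the synthetic colony-screen generator
#'
#' Builds and checks the parameter set of [simulate_screen()]. The defaults
#' reproduce the scale and regime of the reference array: 266 kinases split
#' into 41 tyrosine, 179 serine/threonine with a yeast ortholog and 46
#' without, 80 control proteins, four strains, 73 conditions of which about
#' 17% are globally toxic, multi-clone coverage and duplicate spots —
#' roughly 350,000 spots in total.
#'
#' Scores follow an ordinal cumulative-logit model. For a spot of protein
#' `k` in strain `s` under condition `c`, the linear predictor is
#' `eta = a * activity_k + b * severity_c + gamma_s + d_class(k)` and
#' `P(score >= j) = plogis(eta - theta_j)` for `j` in 1..3. Controls and
#' kinase-dead constructs have activity 0. Latent activity tiers (inactive,
#' moderate, high, topmost) carry activities 0, 1, 2, 3; toxic conditions
#' draw their severity from a separate, much higher distribution, which is
#' what produces the bimodal per-condition defect counts used by the QC
#' stage.
#'
#' @param n_tyrosine,n_st_ortholog,n_st_non_ortholog Kinase counts per class.
#' @param n_controls Control proteins without kinase activity.
#' @param n_kinase_dead Kinase-dead variants (activity 0, `is_control` set),
#'   attached to the first `n_kinase_dead` kinases.
#' @param strains Named numeric vector: strain sensitivity offsets `gamma_s`.
#' @param n_conditions Total conditions.
#' @param fraction_toxic Fraction of conditions that are globally toxic.
#' @param severity_mean,severity_sd Normal-condition severity distribution.
#' @param toxic_severity_mean,toxic_severity_sd Toxic-condition severity.
#' @param tier_props Proportions (summing to 1) of inactive / moderate /
#'   high / topmost activity tiers among kinases.
#' @param a,b Coefficients on activity and severity.
#' @param d_class Named numeric: class offsets for `tyrosine`,
#'   `st_ortholog`, `st_non_ortholog`.
#' @param theta Strictly increasing ordinal thresholds, length 3.
#' @param clones_per_protein,replicates Coverage per protein.
#' @param prob_evaluated Probability a condition is evaluated in a given
#'   strain (each condition is forced to be evaluated in at least one).
#' @param seed Integer seed; all generation is deterministic given it.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_tyrosine = 41L, n_st_ortholog = 179L,
                       n_st_non_ortholog = 46L,
                       n_controls = 80L, n_kinase_dead = 10L,
                       strains = c(BY4742 = 0, L40c = 0.3, W303 = -0.3, Y258 = 0.5),
                       n_conditions = 73L, fraction_toxic = 0.17,
                       severity_mean = 0, severity_sd = 0.4,
                       toxic_severity_mean = 4, toxic_severity_sd = 0.4,
                       tier_props = c(inactive = 0.10, moderate = 0.40,
                                      high = 0.35, topmost = 0.15),
                       a = 2, b = 1,
                       d_class = c(tyrosine = 1, st_ortholog = 0.4,
                                   st_non_ortholog = 0),
                       theta = c(7, 9, 11),
                       clones_per_protein = 2L, replicates = 2L,
                       prob_evaluated = 0.85, seed = 1L) {
  cfg <- list(
    n_tyrosine = as.integer(n_tyrosine),
    n_st_ortholog = as.integer(n_st_ortholog),
    n_st_non_ortholog = as.integer(n_st_non_ortholog),
    n_controls = as.integer(n_controls),
    n_kinase_dead = as.integer(n_kinase_dead),
    strains = strains, n_conditions = as.integer(n_conditions),
    fraction_toxic = fraction_toxic,
    severity_mean = severity_mean, severity_sd = severity_sd,
    toxic_severity_mean = toxic_severity_mean,
    toxic_severity_sd = toxic_severity_sd,
    tier_props = tier_props, a = a, b = b, d_class = d_class,
    theta = theta, clones_per_protein = as.integer(clones_per_protein),
    replicates = as.integer(replicates),
    prob_evaluated = prob_evaluated, seed = as.integer(seed))
  counts <- c(cfg$n_tyrosine, cfg$n_st_ortholog, cfg$n_st_non_ortholog,
              cfg$n_controls, cfg$n_kinase_dead, cfg$n_conditions,
              cfg$clones_per_protein, cfg$replicates)
  if (any(counts < 0L) || cfg$clones_per_protein < 1L || cfg$replicates < 1L ||
      cfg$n_conditions < 1L) {
    abort("All counts must be non-negative (coverage and conditions >= 1).",
          class = "kinarray_config_error")
  }
  if (length(cfg$theta) != 3L || any(diff(cfg$theta) <= 0)) {
    abort("theta must be three strictly increasing thresholds.",
          class = "kinarray_config_error")
  }
  if (abs(sum(cfg$tier_props) - 1) > 1e-8 || any(cfg$tier_props < 0) ||
      length(cfg$tier_props) != 4L) {
    abort("tier_props must be four non-negative proportions summing to 1.",
          class = "kinarray_config_error")
  }
  if (cfg$fraction_toxic < 0 || cfg$fraction_toxic > 1) {
    abort("fraction_toxic must be in [0, 1].", class = "kinarray_config_error")
  }
  if (is.null(names(cfg$strains)) || any(names(cfg$strains) == "") ||
      anyDuplicated(names(cfg$strains))) {
    abort("strains must be a uniquely named numeric vector of offsets.",
          class = "kinarray_config_error")
  }
  if (!setequal(names(cfg$d_class),
                c("tyrosine", "st_ortholog", "st_non_ortholog"))) {
    abort("d_class must name tyrosine, st_ortholog, st_non_ortholog.",
          class = "kinarray_config_error")
  }
  if (cfg$n_kinase_dead > cfg$n_tyrosine + cfg$n_st_ortholog + cfg$n_st_non_ortholog) {
    abort("n_kinase_dead cannot exceed the number of kinases.",
          class = "kinarray_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a full colony screen with planted truth
#'
#' Generates spot observations plus the matching construct, condition and
#' annotation tables, and the planted truth (latent activity tiers, toxic
#' conditions, severities, strain offsets) used to create them. See
#' [sim_config()] for the score model.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"screen_dataset"` with elements `observations`,
#'   `constructs`, `conditions`, `annotations`, and `truth` (a list with
#'   `proteins`, `conditions`, `strains` tibbles). Deterministic given
#'   `config$seed`; the caller's RNG state is left untouched.
#' @examples
#' sim <- simulate_screen(sim_config(
#'   n_tyrosine = 5, n_st_ortholog = 10, n_st_non_ortholog = 5,
#'   n_controls = 5, n_kinase_dead = 2, n_conditions = 10, seed = 42))
#' dplyr::count(sim$observations, strain)
#' @export
simulate_screen <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    abort("config must be built with sim_config().",
          class = "kinarray_config_error")
  }
  withr::with_seed(config$seed, simulate_screen_impl(config))
}

simulate_screen_impl <- function(cfg) {
  classes <- rep(c("tyrosine", "st_ortholog", "st_non_ortholog"),
                 c(cfg$n_tyrosine, cfg$n_st_ortholog, cfg$n_st_non_ortholog))
  n_kin <- length(classes)
  kin_ids <- sprintf("KIN%03d", seq_len(n_kin))
  ctrl_ids <- if (cfg$n_controls > 0L) sprintf("CTRL%03d", seq_len(cfg$n_controls)) else character()
  kd_of <- kin_ids[seq_len(cfg$n_kinase_dead)]
  kd_ids <- if (length(kd_of)) paste0(kd_of, "-KD") else character()

  tier_levels <- c("inactive", "moderate", "high", "topmost")
  tiers <- sample(tier_levels, n_kin, replace = TRUE, prob = cfg$tier_props)
  activity <- match(tiers, tier_levels) - 1

  proteins <- tibble(
    protein_id = c(kin_ids, ctrl_ids, kd_ids),
    class = c(classes, rep(NA_character_, length(ctrl_ids) + length(kd_ids))),
    tier = c(tiers, rep(NA_character_, length(ctrl_ids) + length(kd_ids))),
    activity = c(activity, rep(0, length(ctrl_ids) + length(kd_ids))),
    is_control = c(rep(FALSE, n_kin), rep(TRUE, length(ctrl_ids) + length(kd_ids))),
    is_kinase_dead = c(rep(FALSE, n_kin + length(ctrl_ids)), rep(TRUE, length(kd_ids)))
  )

  n_toxic <- round(cfg$fraction_toxic * cfg$n_conditions)
  toxic <- c(rep(TRUE, n_toxic), rep(FALSE, cfg$n_conditions - n_toxic))
  severity <- ifelse(
    toxic,
    rnorm(cfg$n_conditions, cfg$toxic_severity_mean, cfg$toxic_severity_sd),
    rnorm(cfg$n_conditions, cfg$severity_mean, cfg$severity_sd))
  cond_ids <- sprintf("C%02d", seq_len(cfg$n_conditions))
  strains <- names(cfg$strains)

  # evaluated pattern; every condition evaluated in >= 1 strain
  ev <- matrix(runif(cfg$n_conditions * length(strains)) < cfg$prob_evaluated,
               nrow = cfg$n_conditions)
  none <- which(rowSums(ev) == 0L)
  if (length(none) > 0L) ev[cbind(none, sample.int(length(strains), length(none), replace = TRUE))] <- TRUE
  conditions <- tibble(
    condition_id = cond_ids,
    treatment = sprintf("treatment_%02d", ceiling(seq_len(cfg$n_conditions) / 2)),
    additive = "synthetic",
    concentration = ((seq_len(cfg$n_conditions) - 1L) %% 2L) + 1L,
    unit = "x", temperature = 30)
  for (j in seq_along(strains)) {
    conditions[[paste0("evaluated_", strains[j])]] <- ev[, j]
  }

  constructs <- tidyr::expand_grid(
    protein_id = proteins$protein_id,
    clone = seq_len(cfg$clones_per_protein)) %>%
    left_join(proteins[c("protein_id", "is_control", "is_kinase_dead")],
              by = "protein_id") %>%
    mutate(construct_id = sprintf("%s_c%d", .data$protein_id, .data$clone),
           orf_clone = sprintf("ORF_%s_%d", .data$protein_id, .data$clone),
           vector = ifelse(.data$clone %% 2L == 1L, "nls", "no_nls")) %>%
    select("construct_id", "protein_id", "orf_clone", "vector",
           "is_control", "is_kinase_dead")

  annotations <- proteins %>%
    mutate(
      family_group = dplyr::case_when(
        is.na(.data$class) ~ "control",
        .data$class == "tyrosine" ~ "TK",
        TRUE ~ "STK"),
      residue_class = dplyr::case_when(
        is.na(.data$class) ~ NA_character_,
        .data$class == "tyrosine" ~ "tyrosine",
        TRUE ~ "serine_threonine"),
      yeast_ortholog = !is.na(.data$class) & .data$class == "st_ortholog",
      is_dark = .data$protein_id %in% sample(kin_ids, round(0.27 * n_kin)),
      is_cancer = .data$protein_id %in% sample(kin_ids, round(0.5 * n_kin))) %>%
    select("protein_id", "family_group", "residue_class", "yeast_ortholog",
           "is_control", "is_kinase_dead", "is_dark", "is_cancer")

  ev_long <- condition_strains(conditions) %>% filter(.data$evaluated)
  grid <- tidyr::expand_grid(
    construct_id = constructs$construct_id,
    strain_condition = seq_len(nrow(ev_long)),
    replicate = seq_len(cfg$replicates)) %>%
    mutate(strain = ev_long$strain[.data$strain_condition],
           condition_id = ev_long$condition_id[.data$strain_condition]) %>%
    select(-"strain_condition") %>%
    left_join(constructs[c("construct_id", "protein_id")], by = "construct_id") %>%
    left_join(proteins[c("protein_id", "activity", "class")], by = "protein_id")

  d_cls <- ifelse(is.na(grid$class), 0, cfg$d_class[grid$class])
  eta <- cfg$a * grid$activity +
    cfg$b * severity[match(grid$condition_id, cond_ids)] +
    cfg$strains[grid$strain] + d_cls
  u <- runif(nrow(grid))
  score <- (u < plogis(eta - cfg$theta[1])) +
    (u < plogis(eta - cfg$theta[2])) +
    (u < plogis(eta - cfg$theta[3]))

  observations <- tibble(
    protein_id = grid$protein_id,
    construct_id = grid$construct_id,
    vector = constructs$vector[match(grid$construct_id, constructs$construct_id)],
    strain = grid$strain,
    condition_id = grid$condition_id,
    replicate = as.integer(grid$replicate),
    score = as.integer(score)) %>%
    arrange(.data$protein_id, .data$construct_id, .data$strain,
            .data$condition_id, .data$replicate)

  truth <- list(
    proteins = proteins,
    conditions = tibble(condition_id = cond_ids, toxic = toxic,
                        severity = severity),
    strains = tibble(strain = strains, offset = unname(cfg$strains)))
  structure(list(observations = observations, constructs = constructs,
                 conditions = conditions, annotations = annotations,
                 truth = truth, config = cfg),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("Synthetic colony screen:",
      nrow(x$observations), "spots;",
      n_distinct(x$constructs$protein_id), "proteins;",
      length(unique(x$observations$strain)), "strains;",
      nrow(x$conditions), "conditions",
      sprintf("(%d toxic)\n", sum(x$truth$conditions$toxic)))
  invisible(x)
}
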