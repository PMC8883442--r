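#' Simulate a phospho-Y2H kinase plate with planted modulators
#'
#' Emulates one bait-prey pair mated against a kinase array and spotted as a
#' 1:10 dilution series on control (SD3) and selective (SD5) media, in
#' replicates. Growth per dilution step is ordinal 0-3. A kinase's latent
#' "dilution score" (1 + deepest growing step; 0 if nothing grows) is the
#' baseline for its media, shifted down for planted loss-of-interaction
#' modulators and up for gain modulators, jittered with Gaussian noise,
#' rounded and clipped to the valid range. SD3 growth is always strong
#' unless the kinase is growth-toxic.
#'
#' Kinase-dead partner constructs are emitted for every planted modulator:
#' phospho-dependent modulators lose their shift in the kinase-dead version;
#' non-phospho-dependent ones (scaffold-type effects) keep it.
#'
#' @param n_kinases Number of array kinases on the plate.
#' @param true_modulators Named character vector, kinase id -> `"loss"` or
#'   `"gain"` (e.g. `c(KIN001 = "loss")`). Ids not of the form `KIN<i>` are
#'   accepted as long as they are among the plate's kinases when numeric ids
#'   are generated; by default kinases are `KIN001..KINn`.
#' @param baseline_interaction Does the bait-prey pair interact without any
#'   kinase? `TRUE` gives a high SD5 baseline (loss screens), `FALSE` a zero
#'   SD5 baseline (gain screens).
#' @param dilutions Number of dilution steps (>= 2), steps `0:(dilutions-1)`.
#' @param replicates Biological replicates (>= 1).
#' @param noise Standard deviation of the Gaussian jitter added to the
#'   latent dilution score before rounding.
#' @param shift Dilution-score shift of a true modulator (default 2 steps).
#' @param n_controls Unrelated-kinase control spots included on the plate.
#' @param toxic_kinases Character vector of kinases whose expression is
#'   growth-toxic (SD3 and SD5 both collapse to 0).
#' @param phospho_dependent Logical, recycled over `true_modulators`: is the
#'   modulation phospho-dependent (kinase-dead loses the effect)?
#' @param cu_um Copper induction level recorded as metadata (20 or 100).
#' @param bait,prey Identifier labels.
#' @param seed Integer seed.
#'
#' @return List of class `"y2h_plate"` with `observations` (tibble: `bait`,
#'   `prey`, `kinase`, `construct_type`, `media`, `cu_um`, `dilution_step`,
#'   `replicate`, `growth`) and `truth` (tibble of planted modulators with
#'   `mode`, `phospho_dependent`, plus toxic kinases).
#' @export
simulate_y2h_plate <- function(n_kinases = 100L, true_modulators = character(),
                               baseline_interaction = TRUE,
                               dilutions = 4L, replicates = 3L, noise = 0.4,
                               shift = 2L, n_controls = 4L,
                               toxic_kinases = character(),
                               phospho_dependent = TRUE,
                               cu_um = 100, bait = "BAIT", prey = "PREY",
                               seed = 1L) {
  if (dilutions < 2L) abort("dilutions must be >= 2.", class = "kinarray_config_error")
  if (replicates < 1L) abort("replicates must be >= 1.", class = "kinarray_config_error")
  modes <- unname(unlist(true_modulators))
  if (length(modes) > 0 && !all(modes %in% c("loss", "gain"))) {
    abort(paste0("Unknown modulation mode(s): ",
                 paste(setdiff(modes, c("loss", "gain")), collapse = ", ")),
          class = "kinarray_config_error")
  }
  withr::with_seed(seed, {
    kinases <- sprintf("KIN%03d", seq_len(n_kinases))
    if (length(true_modulators) > 0 && is.null(names(true_modulators))) {
      # unnamed: plant on the first k kinases
      names(true_modulators) <- kinases[seq_along(true_modulators)]
    }
    unknown <- setdiff(names(true_modulators), kinases)
    if (length(unknown) > 0L) {
      abort(paste0("true_modulators not on the plate: ",
                   paste(unknown, collapse = ", ")),
            class = "kinarray_config_error")
    }
    phospho <- rep_len(phospho_dependent, length(true_modulators))
    controls <- if (n_controls > 0L) sprintf("CTRL%02d", seq_len(n_controls)) else character()

    base5 <- if (isTRUE(baseline_interaction)) dilutions - 1L else 0L
    base3 <- dilutions

    spots <- bind_rows(
      tibble(kinase = kinases, construct_type = "kinase"),
      tibble(kinase = controls, construct_type = "control"),
      tibble(kinase = names(true_modulators), construct_type = "kinase_dead"))
    spots <- tidyr::expand_grid(spots, media = c("SD3", "SD5"),
                                replicate = seq_len(replicates))

    mod_mode <- true_modulators[spots$kinase]
    is_kd <- spots$construct_type == "kinase_dead"
    keeps_shift <- !is.na(mod_mode) & spots$construct_type == "kinase"
    # kinase-dead constructs of non-phospho-dependent modulators keep the shift
    kd_keeps <- !is.na(mod_mode) & is_kd &
      !phospho[match(spots$kinase, names(true_modulators))]
    eff <- ifelse((keeps_shift | kd_keeps) & spots$media == "SD5",
                  ifelse(mod_mode == "loss", -shift, shift), 0)
    latent_base <- ifelse(spots$media == "SD5", base5, base3)
    latent <- latent_base + eff + rnorm(nrow(spots), 0, noise)
    is_toxic <- spots$kinase %in% toxic_kinases & !is_kd
    latent[is_toxic] <- 0
    score <- pmin(pmax(round(latent), 0L), dilutions)

    obs <- tidyr::expand_grid(
      idx = seq_len(nrow(spots)), dilution_step = 0:(dilutions - 1L)) %>%
      mutate(growth = pmin(pmax(score[.data$idx] - .data$dilution_step, 0L), 3L))
    observations <- tibble(
      bait = bait, prey = prey,
      kinase = spots$kinase[obs$idx],
      construct_type = spots$construct_type[obs$idx],
      media = spots$media[obs$idx],
      cu_um = cu_um,
      dilution_step = obs$dilution_step,
      replicate = as.integer(spots$replicate[obs$idx]),
      growth = as.integer(obs$growth))

    truth <- tibble(
      kinase = names(true_modulators),
      mode = unname(true_modulators),
      phospho_dependent = phospho)
    structure(list(observations = observations, truth = truth,
                   toxic_kinases = toxic_kinases,
                   baseline = tibble(media = c("SD3", "SD5"),
                                     dilution_score = c(base3, base5))),
              class = "y2h_plate")
  })
}

#' Simulate a logistic OD595 growth curve
#'
#' `OD(t) = baseline + (K - baseline) / (1 + exp(-r (t - t0))) + eps`,
#' with `eps ~ Normal(0, noise_sd)`, sampled on a fixed grid (default every
#' 10 minutes over 24 hours, as in a plate-reader run).
#'
#' @param K Carrying capacity (OD595); must exceed `baseline`.
#' @param r Growth rate per hour; must be positive.
#' @param t0 Inflection time in hours.
#' @param baseline Starting OD595 (>= 0).
#' @param noise_sd Measurement noise standard deviation (OD units).
#' @param t_grid Time grid in hours.
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @return Tibble with columns `time_h`, `od`.
#' @export
simulate_growth_curve <- function(K, r, t0, baseline = 0.1, noise_sd = 0,
                                  t_grid = seq(0, 24, by = 1 / 6), seed = 1L) {
  if (r <= 0) abort("Growth rate r must be positive.", class = "kinarray_config_error")
  if (K <= baseline || baseline < 0) {
    abort("Require K > baseline >= 0.", class = "kinarray_config_error")
  }
  od <- baseline + (K - baseline) / (1 + exp(-r * (t_grid - t0)))
  if (noise_sd > 0) {
    od <- od + withr::with_seed(seed, rnorm(length(t_grid), 0, noise_sd))
  }
  tibble(time_h = t_grid, od = od)
}
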