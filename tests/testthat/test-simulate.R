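small_cfg <- function(n_conditions = 8L, ...) {
  sim_config(n_tyrosine = 4L, n_st_ortholog = 8L, n_st_non_ortholog = 4L,
             n_controls = 4L, n_kinase_dead = 2L,
             n_conditions = n_conditions,
             clones_per_protein = 1L, replicates = 1L, ...)
}

test_that("screen generation is deterministic given the seed", {
  a <- simulate_screen(small_cfg(seed = 5L))
  b <- simulate_screen(small_cfg(seed = 5L))
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  c <- simulate_screen(small_cfg(seed = 6L))
  expect_false(identical(a$observations$score, c$observations$score))
})

test_that("saturated thresholds with null effects give all-zero scores", {
  cfg <- small_cfg(a = 0, b = 0,
                   strains = c(S1 = 0, S2 = 0),
                   d_class = c(tyrosine = 0, st_ortholog = 0,
                               st_non_ortholog = 0),
                   severity_mean = 0, severity_sd = 0,
                   toxic_severity_mean = 0, toxic_severity_sd = 0,
                   theta = c(10, 11, 12), seed = 2L)
  sim <- simulate_screen(cfg)
  expect_true(all(sim$observations$score == 0L))
})

test_that("empirical score probabilities match the closed-form cumulative logit", {
  # all kinases topmost (activity 3), no class/strain/severity effects:
  # every spot has eta = 3a and P(score >= j) = plogis(3a - theta_j)
  cfg <- sim_config(
    n_tyrosine = 0L, n_st_ortholog = 100L, n_st_non_ortholog = 0L,
    n_controls = 0L, n_kinase_dead = 0L,
    strains = c(S1 = 0), n_conditions = 100L, fraction_toxic = 0,
    severity_mean = 0, severity_sd = 0,
    tier_props = c(inactive = 0, moderate = 0, high = 0, topmost = 1),
    a = 1, b = 0,
    d_class = c(tyrosine = 0, st_ortholog = 0, st_non_ortholog = 0),
    theta = c(2, 4, 6), clones_per_protein = 1L, replicates = 1L,
    prob_evaluated = 1, seed = 9L)
  sim <- simulate_screen(cfg)
  n <- nrow(sim$observations)
  expect_equal(n, 10000L)
  for (j in 1:3) {
    p_theory <- plogis(3 - cfg$theta[j])
    p_hat <- mean(sim$observations$score >= j)
    se <- sqrt(p_theory * (1 - p_theory) / n)
    expect_lt(abs(p_hat - p_theory), 3 * se + 1e-12)
  }
})

test_that("raising the activity coefficient raises expected scores of active kinases", {
  mean_active_score <- function(a) {
    sim <- simulate_screen(small_cfg(
      a = a, n_conditions = 30L, fraction_toxic = 0, seed = 13L))
    active <- sim$truth$proteins$protein_id[
      !sim$truth$proteins$is_control & sim$truth$proteins$activity > 0]
    mean(sim$observations$score[sim$observations$protein_id %in% active])
  }
  m <- vapply(c(1, 2, 3), mean_active_score, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("invalid configurations fail before any sampling", {
  expect_error(sim_config(theta = c(3, 2, 1)), class = "kinarray_config_error")
  expect_error(sim_config(tier_props = c(0.5, 0.5, 0, 0.5)),
               class = "kinarray_config_error")
  expect_error(sim_config(fraction_toxic = 1.2), class = "kinarray_config_error")
  expect_error(sim_config(n_conditions = 0), class = "kinarray_config_error")
  expect_error(simulate_screen(list(seed = 1)), class = "kinarray_config_error")
})

test_that("zero-noise Y2H plates follow the planted shifts exactly", {
  pl <- simulate_y2h_plate(n_kinases = 10L,
                           true_modulators = c(KIN004 = "loss"),
                           noise = 0, seed = 3L)
  sc <- dplyr::filter(
    kinarray:::plate_dilution_scores(pl),
    kinase == "KIN004", construct_type == "kinase", media == "SD5")
  expect_equal(sc$dilution_score, rep(1L, 3L))  # baseline 3 shifted by 2
  # everything else sits at baseline
  others <- dplyr::filter(
    kinarray:::plate_dilution_scores(pl),
    kinase != "KIN004" | construct_type == "kinase_dead")
  expect_true(all(others$dilution_score[others$media == "SD5"] == 3L))
  expect_true(all(others$dilution_score[others$media == "SD3"] == 4L))
})

test_that("without baseline interaction and modulators, SD5 shows no growth", {
  pl <- simulate_y2h_plate(n_kinases = 6L, baseline_interaction = FALSE,
                           noise = 0, seed = 4L)
  sd5 <- dplyr::filter(pl$observations, media == "SD5")
  expect_true(all(sd5$growth == 0L))
})

test_that("unknown modulation modes and bad dimensions are rejected", {
  expect_error(simulate_y2h_plate(true_modulators = c(KIN001 = "boost")),
               class = "kinarray_config_error")
  expect_error(simulate_y2h_plate(dilutions = 1L),
               class = "kinarray_config_error")
})

test_that("noiseless growth curves equal the logistic closed form", {
  cv <- simulate_growth_curve(K = 1, r = 0.5, t0 = 12, baseline = 0.1)
  expect_equal(nrow(cv), 145L)  # 24 h every 10 min
  closed <- 0.1 + 0.9 / (1 + exp(-0.5 * (cv$time_h - 12)))
  expect_equal(cv$od, closed)
  # midpoint symmetry at t0
  expect_equal(cv$od[cv$time_h == 12], 0.1 + 0.9 / 2)
  expect_error(simulate_growth_curve(K = 1, r = -1, t0 = 2),
               class = "kinarray_config_error")
  expect_error(simulate_growth_curve(K = 0.05, r = 1, t0 = 2, baseline = 0.1),
               class = "kinarray_config_error")
})
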