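test_that("dilution scoring applies the deepest-growing-step rule", {
  expect_equal(dilution_score(c(3, 2, 0)), 2L)
  expect_equal(dilution_score(c(0, 0, 0)), 0L)
  expect_equal(dilution_score(c(3, 3, 2, 1)), 4L)
  # missing steps are skipped
  expect_equal(dilution_score(c(3, NA, 1), dilution_step = 0:2), 3L)
  expect_error(dilution_score(numeric()), class = "kinarray_parameter_error")
})

test_that("non-monotone series warn but are scored literally", {
  expect_warning(s <- dilution_score(c(0, 2), dilution_step = 0:1),
                 "dilution series")
  expect_equal(s, 2L)
})

test_that("baselines come from controls, with plate-median fallback", {
  mk_obs <- function(kinase, type, media, score) {
    tidyr::expand_grid(kinase = kinase, construct_type = type, media = media,
                       replicate = 1L, dilution_step = 0:3) |>
      dplyr::mutate(growth = pmin(pmax(score - dilution_step, 0L), 3L),
                    bait = "b", prey = "p", cu_um = 100)
  }
  plate <- dplyr::bind_rows(
    mk_obs(c("CT1", "CT2", "CT3"), "control", "SD5", 3L),
    mk_obs(c("CT1", "CT2", "CT3"), "control", "SD3", 4L),
    mk_obs("K1", "kinase", "SD5", 0L), mk_obs("K1", "kinase", "SD3", 4L))
  b <- baseline_estimate(plate)
  expect_equal(b$baseline[b$media == "SD5"], 3)
  expect_equal(b$baseline[b$media == "SD3"], 4)

  # median over controls {3, 3, 2} is 3
  plate2 <- dplyr::bind_rows(
    mk_obs("CT1", "control", "SD5", 3L), mk_obs("CT2", "control", "SD5", 3L),
    mk_obs("CT3", "control", "SD5", 2L))
  expect_equal(baseline_estimate(plate2)$baseline, 3)

  # no controls: warn and fall back to the plate median
  noctrl <- dplyr::bind_rows(mk_obs(c("K1", "K2", "K3"), "kinase", "SD5", 2L))
  expect_warning(b3 <- baseline_estimate(noctrl), "plate median")
  expect_equal(b3$baseline, 2)
  pm <- baseline_estimate(noctrl, "plate_median")
  expect_equal(pm$baseline, 2)
})

test_that("plate medians equal a brute-force median on a synthetic plate", {
  pl <- simulate_y2h_plate(n_kinases = 96L, noise = 0.6, seed = 12L)
  pm <- baseline_estimate(pl, "plate_median")
  scores <- kinarray:::plate_dilution_scores(pl)
  for (md in c("SD3", "SD5")) {
    expect_equal(pm$baseline[pm$media == md],
                 median(scores$dilution_score[scores$media == md]))
  }
})

test_that("loss calls require the shift, replicate support and viability", {
  pl <- simulate_y2h_plate(n_kinases = 12L,
                           true_modulators = c(KIN003 = "loss"),
                           noise = 0, seed = 2L,
                           toxic_kinases = "KIN007")
  calls <- call_modulators(pl)
  wt <- dplyr::filter(calls, construct_type == "kinase")
  expect_equal(wt$mode[wt$kinase == "KIN003"], "loss")
  expect_equal(wt$effect_size[wt$kinase == "KIN003"], 2L)
  expect_equal(wt$replicate_support[wt$kinase == "KIN003"], 1)
  # the toxic kinase is flagged, never called
  expect_equal(wt$mode[wt$kinase == "KIN007"], "none")
  expect_true(wt$toxic[wt$kinase == "KIN007"])
  expect_false(wt$viability_ok[wt$kinase == "KIN007"])
  # everything else is quiet
  expect_equal(sum(wt$mode != "none"), 1L)
})

test_that("gain calls mirror loss calls on a low baseline", {
  pl <- simulate_y2h_plate(n_kinases = 12L, baseline_interaction = FALSE,
                           true_modulators = c(KIN005 = "gain"),
                           noise = 0, seed = 2L)
  wt <- dplyr::filter(call_modulators(pl), construct_type == "kinase")
  expect_equal(wt$mode[wt$kinase == "KIN005"], "gain")
  expect_equal(sum(wt$mode != "none"), 1L)
})

test_that("an infinite shift threshold yields no calls", {
  pl <- simulate_y2h_plate(n_kinases = 20L,
                           true_modulators = c(KIN001 = "loss"), seed = 8L)
  calls <- call_modulators(pl, min_shift = Inf)
  expect_true(all(calls$mode == "none"))
})

test_that("loss and gain are mutually exclusive per kinase", {
  for (s in 1:10) {
    pl <- simulate_y2h_plate(
      n_kinases = 30L,
      true_modulators = c(KIN002 = "loss", KIN009 = "loss"),
      noise = 0.8, seed = s)
    calls <- call_modulators(pl)
    per_kin <- dplyr::count(
      dplyr::filter(calls, mode != "none"),
      kinase, construct_type)
    expect_true(all(per_kin$n == 1L))
  }
})

test_that("phospho-dependence follows the wild-type / kinase-dead truth table", {
  mk <- function(kinase, mode) tibble::tibble(kinase = kinase, mode = mode)
  expect_true(phospho_dependence(mk("NEK6", "gain"), mk("NEK6", "none")))
  expect_false(phospho_dependence(mk("PAK5", "gain"), mk("PAK5", "gain")))
  expect_false(phospho_dependence(mk("X", "none"), mk("X", "gain")))
  expect_false(phospho_dependence(mk("X", "none"), mk("X", "none")))
  expect_error(phospho_dependence(mk("A", "loss"), mk("B", "none")),
               class = "kinarray_integrity_error")
})

test_that("kinase-dead partners separate phospho-dependent from scaffold effects", {
  pl <- simulate_y2h_plate(
    n_kinases = 20L,
    true_modulators = c(KIN004 = "loss", KIN011 = "loss"),
    phospho_dependent = c(TRUE, FALSE), noise = 0, seed = 6L)
  tab <- phospho_dependence_table(call_modulators(pl))
  expect_true(tab$phospho_dependent[tab$kinase == "KIN004"])
  expect_false(tab$phospho_dependent[tab$kinase == "KIN011"])
  expect_equal(tab$kd_mode[tab$kinase == "KIN011"], "loss")
})
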