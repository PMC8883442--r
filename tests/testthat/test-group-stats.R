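ann_for <- function(kinases, controls = character(),
                    tyrosine = character(), ortholog = character()) {
  ids <- c(kinases, controls)
  tibble::tibble(
    protein_id = ids,
    family_group = "x",
    residue_class = ifelse(ids %in% controls, NA_character_,
                           ifelse(ids %in% tyrosine, "tyrosine",
                                  "serine_threonine")),
    yeast_ortholog = ids %in% ortholog,
    is_control = ids %in% controls,
    is_kinase_dead = FALSE, is_dark = FALSE, is_cancer = FALSE)
}

test_that("group fractions equal direct counts", {
  kin <- sprintf("K%d", 1:4)
  m <- make_matrix(c(kin, "C1"), "A", "c1", c(3L, 0L, 0L, 0L, 0L))
  ann <- ann_for(kin, controls = "C1")
  gf <- group_fractions(m, ann, "kinase_vs_control", severity = 1)
  expect_equal(gf$fraction[gf$group == "kinase"], 0.25)
  expect_equal(gf$fraction[gf$group == "control"], 0)
  expect_equal(gf$n_members[gf$group == "kinase"], 4L)
  # severity above every score gives zero everywhere
  gf0 <- group_fractions(m, ann, "kinase_vs_control", severity = 3)
  expect_equal(gf0$fraction[gf0$group == "kinase"], 0.25)
  m$score[m$protein_id == "K1"] <- 2L
  expect_true(all(group_fractions(m, ann, severity = 3)$fraction == 0))
})

test_that("group fractions match brute force on a random fixture", {
  set.seed(77)
  kin <- sprintf("K%02d", 1:12); ctrl <- sprintf("C%02d", 1:4)
  m <- make_matrix(c(kin, ctrl), c("A", "B"), sprintf("c%d", 1:5),
                   sample(0:3, 160, TRUE))
  ann <- ann_for(kin, controls = ctrl, tyrosine = kin[1:4],
                 ortholog = kin[5:8])
  for (sev in 1:3) {
    gf <- group_fractions(m, ann, "ortholog_classes", severity = sev)
    for (i in sample(nrow(gf), 10)) {
      members <- switch(gf$group[i],
        tyrosine = kin[1:4], st_ortholog = kin[5:8],
        st_non_ortholog = kin[9:12])
      sub <- m[m$protein_id %in% members & m$strain == gf$strain[i] &
                 m$condition_id == gf$condition_id[i], ]
      expect_equal(gf$fraction[i], mean(sub$score >= sev))
    }
  }
  # annotations with no controls make kinase_vs_control ill-posed
  expect_error(group_fractions(m, ann_for(kin), "kinase_vs_control"),
               class = "kinarray_parameter_error")
})

test_that("exact rank-sum p-values match hand enumeration", {
  ht <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ht$statistic, 0)
  expect_equal(ht$p.value, 0.1)  # 2 of C(6,3) = 20 assignments as extreme
  expect_equal(ht$method, "exact")

  # identical multisets: central U, p -> 1
  ht2 <- rank_sum_test(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(ht2$statistic, 16 / 2)
  expect_gte(ht2$p.value, 0.99)

  # one-sided relationships
  gt <- rank_sum_test(c(4, 5, 6), c(1, 2, 3), alternative = "greater")
  expect_equal(gt$p.value, 0.05)
  two <- rank_sum_test(c(4, 5, 6), c(1, 2, 3))
  expect_gte(two$p.value, gt$p.value)
})

test_that("exact p equals the independent pair-counting oracle on random samples", {
  set.seed(5)
  for (i in 1:120) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- sample(0:6, nx, TRUE); y <- sample(0:6, ny, TRUE)
    alt <- sample(c("two_sided", "greater", "less"), 1)
    ht <- rank_sum_test(x, y, alternative = alt, method = "exact")
    expect_equal(ht$statistic, oracle_u(x, y))
    expect_equal(ht$p.value, oracle_ranksum_p(x, y, alt), tolerance = 1e-12)
  }
})

test_that("exact p agrees with wilcox.test on untied samples", {
  set.seed(6)
  for (i in 1:25) {
    x <- rnorm(sample(3:7, 1)); y <- rnorm(sample(3:7, 1))
    ht <- rank_sum_test(x, y, method = "exact")
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ht$statistic, unname(wt$statistic))
    expect_equal(ht$p.value, wt$p.value, tolerance = 1e-12)
  }
})

test_that("the normal approximation tracks wilcox.test with ties and continuity", {
  set.seed(7)
  for (i in 1:10) {
    x <- sample(0:5, 30, TRUE); y <- sample(0:5, 35, TRUE)
    ht <- rank_sum_test(x, y, method = "normal_approx")
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    expect_equal(ht$p.value, wt$p.value, tolerance = 1e-10)
  }
  # requesting exact beyond the enumeration bound falls back with a warning
  expect_warning(
    ht <- rank_sum_test(rnorm(15), rnorm(15), method = "exact"),
    "normal approximation")
  expect_equal(ht$method, "normal_approx")
})

test_that("p-values are proper and sided consistently", {
  set.seed(9)
  for (i in 1:30) {
    x <- rnorm(4); y <- rnorm(5)
    two <- rank_sum_test(x, y)$p.value
    g <- rank_sum_test(x, y, "greater")$p.value
    l <- rank_sum_test(x, y, "less")$p.value
    expect_gte(min(two, g, l), 0); expect_lte(max(two, g, l), 1)
    expect_gte(two + 1e-12, min(g, l))  # two-sided >= favoured one-sided
  }
})

test_that("group comparison flags a planted class effect and not its absence", {
  sim <- simulate_screen(sim_config(
    n_tyrosine = 25L, n_st_ortholog = 10L, n_st_non_ortholog = 25L,
    n_controls = 0L, n_kinase_dead = 0L,
    strains = c(S1 = 0, S2 = 0.3), n_conditions = 20L, fraction_toxic = 0,
    clones_per_protein = 1L, replicates = 1L, prob_evaluated = 1,
    seed = 19L))
  gf <- group_fractions(sim$observations, sim$annotations,
                        "ortholog_classes", severity = 1)
  cmp <- compare_groups(gf, list(c("tyrosine", "st_non_ortholog")),
                        method = "normal_approx")
  expect_lt(cmp$p.value, 0.01)
  expect_gt(cmp$median1, cmp$median2)  # tyrosine offset is positive

  # identical groups: compare a group against itself
  self_gf <- dplyr::bind_rows(
    gf[gf$group == "tyrosine", ],
    dplyr::mutate(gf[gf$group == "tyrosine", ], group = "copy"))
  self <- compare_groups(self_gf, list(c("tyrosine", "copy")),
                         method = "normal_approx")
  expect_gt(self$p.value, 0.9)
})

test_that("a single condition-strain pair still yields an exact-method report", {
  kin <- c("K1", "K2"); ctrl <- c("C1", "C2")
  m <- make_matrix(c(kin, ctrl), "A", "c1", c(3L, 3L, 0L, 0L))
  gf <- group_fractions(m, ann_for(kin, controls = ctrl), severity = 1)
  cmp <- compare_groups(gf, list(c("kinase", "control")))
  expect_equal(cmp$method, "exact")
  expect_equal(cmp$n1, 1L)
})
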