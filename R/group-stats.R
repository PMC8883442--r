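#' Per-condition-strain phenotype fractions by protein group
#'
#' For each retained condition-strain pair, the fraction of each group's
#' members with a growth score at or above `severity`. These per-pair
#' fractions are the sampling unit of the group comparisons (kinases vs
#' controls; tyrosine vs serine/threonine ortholog classes).
#'
#' @param matrix Kinase-condition score tibble.
#' @param annotations Annotation tibble (`protein_id`, `is_control`,
#'   `residue_class`, `yeast_ortholog`).
#' @param grouping `"kinase_vs_control"` (default) or `"ortholog_classes"`
#'   (tyrosine / st_ortholog / st_non_ortholog; controls excluded).
#' @param severity Minimum score counted as a phenotype (default 3,
#'   "strong").
#' @param retained Optional flagged tibble from [filter_conditions()] or
#'   retained pairs; when given, only those condition-strain pairs are used.
#'
#' @return Tibble `condition_id`, `strain`, `group`, `fraction`, `n_members`.
#' @export
group_fractions <- function(matrix, annotations,
                            grouping = c("kinase_vs_control", "ortholog_classes"),
                            severity = 3L, retained = NULL) {
  grouping <- match.arg(grouping)
  ann <- tibble::as_tibble(annotations)
  ann$group <- switch(grouping,
    kinase_vs_control = ifelse(ann$is_control, "control", "kinase"),
    ortholog_classes = dplyr::case_when(
      ann$is_control ~ NA_character_,
      ann$residue_class == "tyrosine" ~ "tyrosine",
      ann$yeast_ortholog ~ "st_ortholog",
      TRUE ~ "st_non_ortholog"))
  ann <- filter(ann, !is.na(.data$group))
  expected <- switch(grouping,
    kinase_vs_control = c("kinase", "control"),
    ortholog_classes = c("tyrosine", "st_ortholog", "st_non_ortholog"))
  empty <- setdiff(expected, unique(ann$group))
  if (length(empty) > 0L) {
    abort(paste0("Grouping yields empty group(s): ",
                 paste(empty, collapse = ", ")),
          class = "kinarray_parameter_error")
  }
  m <- matrix
  if (!is.null(retained)) {
    if ("excluded" %in% names(retained)) retained <- filter(retained, !.data$excluded)
    m <- semi_join(m, retained, by = c("condition_id", "strain"))
  }
  m %>%
    inner_join(ann[c("protein_id", "group")], by = "protein_id") %>%
    filter(!is.na(.data$score)) %>%
    group_by(.data$condition_id, .data$strain, .data$group) %>%
    summarise(fraction = mean(.data$score >= severity),
              n_members = n(), .groups = "drop")
}

#' Mann-Whitney rank-sum test
#'
#' Two-sample rank-sum test implemented from first principles. The statistic
#' is `U = #{(i, j): x_i > y_j} + 0.5 * #{x_i = y_j}`. The exact method
#' enumerates the full permutation null (all reassignments of the pooled
#' values to the two groups) and is available for `min(n_x, n_y) <= 8` and
#' `n_x + n_y <= 20`; beyond that, or with `method = "normal_approx"`, a
#' normal approximation with continuity and tie corrections is used.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param alternative `"two_sided"` (default), `"greater"` (x tends larger),
#'   or `"less"`.
#' @param method `"auto"` (exact when within the enumeration bound),
#'   `"exact"` (falls back to the approximation with a warning beyond the
#'   bound), or `"normal_approx"`.
#'
#' @return Object of class `"rank_sum_test"`: list with `statistic` (U),
#'   `p.value`, `method`, `alternative`, `n_x`, `n_y`. [tidy()] returns a
#'   one-row tibble.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("two_sided", "greater", "less"),
                          method = c("auto", "exact", "normal_approx")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    abort("Both samples must be non-empty.", class = "kinarray_parameter_error")
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  within_bound <- min(nx, ny) <= 8L && n <= 20L
  if (method == "exact" && !within_bound) {
    warn("Exact enumeration bound exceeded; using normal approximation.")
    method <- "normal_approx"
  }
  use_exact <- (method == "exact") || (method == "auto" && within_bound)
  if (use_exact) {
    p <- exact_ranksum_p(r, nx, u_obs, alternative)
    method_used <- "exact"
  } else {
    p <- approx_ranksum_p(r, nx, ny, u_obs, alternative)
    method_used <- "normal_approx"
  }
  structure(list(statistic = u_obs, p.value = p, method = method_used,
                 alternative = alternative, n_x = nx, n_y = ny),
            class = "rank_sum_test")
}

exact_ranksum_p <- function(r, nx, u_obs, alternative) {
  n <- length(r)
  idx <- combn(n, nx)
  base <- nx * (nx + 1) / 2
  u_all <- colSums(matrix(r[idx], nrow = nx)) - base
  mu <- nx * (n - nx) / 2
  eps <- sqrt(.Machine$double.eps)
  switch(alternative,
    two_sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps),
    greater = mean(u_all >= u_obs - eps),
    less = mean(u_all <= u_obs + eps))
}

approx_ranksum_p <- function(r, nx, ny, u_obs, alternative) {
  n <- nx + ny
  mu <- nx * ny / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  sigma <- sqrt(sigma2)
  cc <- 0.5  # continuity correction
  switch(alternative,
    two_sided = {
      z <- (u_obs - mu - sign(u_obs - mu) * cc) / sigma
      min(1, 2 * pnorm(-abs(z)))
    },
    greater = pnorm((u_obs - mu - cc) / sigma, lower.tail = FALSE),
    less = pnorm((u_obs - mu + cc) / sigma))
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat("Mann-Whitney rank-sum test (", x$method, ")\n",
      "U = ", x$statistic, ", n = (", x$n_x, ", ", x$n_y, "), ",
      x$alternative, " p = ", format.pval(x$p.value, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' @rdname rank_sum_test
#' @param x A `rank_sum_test` object (for `tidy`/`glance`).
#' @param ... Unused.
#' @method tidy rank_sum_test
#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value,
         method = x$method, alternative = x$alternative,
         n_x = x$n_x, n_y = x$n_y)
}

#' @rdname rank_sum_test
#' @method glance rank_sum_test
#' @export
glance.rank_sum_test <- function(x, ...) tidy(x)

#' Compare phenotype fractions between protein groups
#'
#' Runs a rank-sum test per requested pair of groups, using each group's
#' per-condition-strain phenotype fractions as the two samples.
#'
#' @param fractions Tibble from [group_fractions()].
#' @param pairings List of length-2 character vectors naming group pairs;
#'   default: all pairs present.
#' @param alternative,method Passed to [rank_sum_test()].
#' @param adjust Multiple-testing adjustment for the p-values, as in
#'   [stats::p.adjust()] (default `"none"`, matching raw reporting; `"BH"`
#'   available for larger comparison sets).
#'
#' @return Tibble with one row per comparison: groups, sample sizes,
#'   medians, `statistic`, `p.value` (adjusted if requested), `method`.
#' @export
compare_groups <- function(fractions, pairings = NULL,
                           alternative = "two_sided", method = "auto",
                           adjust = "none") {
  groups <- sort(unique(fractions$group))
  if (is.null(pairings)) {
    pairings <- combn(groups, 2L, simplify = FALSE)
  }
  rows <- purrr::map(pairings, function(pr) {
    g1 <- fractions$fraction[fractions$group == pr[1]]
    g2 <- fractions$fraction[fractions$group == pr[2]]
    ht <- rank_sum_test(g1, g2, alternative = alternative, method = method)
    tibble(group1 = pr[1], group2 = pr[2],
           n1 = length(g1), n2 = length(g2),
           median1 = median(g1), median2 = median(g2),
           statistic = ht$statistic, p.value = ht$p.value,
           method = ht$method)
  })
  out <- bind_rows(rows)
  out$p.value <- stats::p.adjust(out$p.value, method = adjust)
  out
}
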