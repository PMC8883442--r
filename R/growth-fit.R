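#' Fit a four-parameter logistic to an OD595 growth curve
#'
#' Least-squares fit of `od = baseline + (K - baseline) / (1 + exp(-r (t -
#' t0)))` via Levenberg-Marquardt. Default initial values: `baseline` =
#' first OD, `K` = maximum OD, `t0` = time of the half-range crossing,
#' `r` = 0.5 per hour. Convergence is reported, never silently assumed;
#' near-flat curves (`K - baseline` below 1% of the OD range, or failure to
#' converge) are flagged degenerate.
#'
#' @param curve Tibble with columns `time_h` (strictly increasing) and `od`;
#'   at least 8 time points.
#' @param init Optional named list overriding any of `K`, `r`, `t0`,
#'   `baseline` starting values.
#'
#' @return Object of class `"logistic_fit"`: list with `K`, `r`, `t0`,
#'   `baseline`, `rss`, `converged`, `degenerate`, `n`, `data`. [tidy()]
#'   gives per-parameter estimates, [glance()] a one-row fit summary.
#' @examples
#' curve <- simulate_growth_curve(K = 1, r = 0.5, t0 = 8, baseline = 0.1)
#' fit_logistic(curve)
#' @export
fit_logistic <- function(curve, init = NULL) {
  if (!all(c("time_h", "od") %in% names(curve))) {
    abort("curve needs columns time_h and od.", class = "kinarray_parameter_error")
  }
  if (nrow(curve) < 8L) {
    abort("Logistic fitting needs at least 8 time points.",
          class = "kinarray_parameter_error")
  }
  t <- curve$time_h; od <- curve$od
  half <- min(od) + (max(od) - min(od)) / 2
  above <- which(od >= half)
  start <- list(
    baseline = od[1L],
    K = max(od),
    t0 = if (length(above) > 0L) t[above[1L]] else median(t),
    r = 0.5)
  for (nm in names(init)) start[[nm]] <- init[[nm]]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      od ~ baseline + (K - baseline) / (1 + exp(-r * (time_h - t0))),
      data = curve, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- c(start, list(rss = NA_real_, converged = FALSE, degenerate = TRUE,
                         n = nrow(curve), data = curve,
                         message = conditionMessage(fit)))
    return(structure(out, class = "logistic_fit"))
  }
  est <- as.list(stats::coef(fit))
  conv <- isTRUE(fit$convInfo$isConv)
  degenerate <- !conv || (est$K - est$baseline) < 0.01 * max(diff(range(od)), .Machine$double.eps)
  structure(list(K = est$K, r = est$r, t0 = est$t0, baseline = est$baseline,
                 rss = sum(stats::resid(fit)^2), converged = conv,
                 degenerate = degenerate, n = nrow(curve), data = curve,
                 message = NULL),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic growth fit (n = %d): K = %.4g, r = %.4g /h, t0 = %.4g h, baseline = %.4g\n",
    x$n, x$K, x$r, x$t0, x$baseline))
  cat(sprintf("rss = %.4g; converged: %s%s\n", x$rss, x$converged,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' @rdname fit_logistic
#' @param x A `logistic_fit` object.
#' @param ... Unused.
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(term = c("K", "r", "t0", "baseline"),
         estimate = c(x$K, x$r, x$t0, x$baseline))
}

#' @rdname fit_logistic
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(K = x$K, r = x$r, t0 = x$t0, baseline = x$baseline,
         rss = x$rss, converged = x$converged, degenerate = x$degenerate,
         n = x$n)
}

#' Area under a growth curve
#'
#' Trapezoidal integral of OD over the recorded time span (OD x hours).
#' Defined for any curve with at least two points, which makes it the
#' robust comparison metric for strongly inhibited, non-sigmoid growth.
#'
#' @param curve Tibble with `time_h`, `od`.
#' @return Numeric scalar.
#' @export
curve_auc <- function(curve) {
  if (nrow(curve) < 2L) {
    abort("AUC needs at least 2 points.", class = "kinarray_parameter_error")
  }
  pracma::trapz(curve$time_h, curve$od)
}

#' Compare wild-type vs kinase-dead growth curves
#'
#' Computes a growth metric per replicate curve in each set and reports the
#' effect as `mean(kinase-dead) - mean(wild-type)`: positive values mean the
#' active kinase inhibits growth.
#'
#' @param wt,kd Tibbles of replicate curves with columns `time_h`, `od`,
#'   `replicate`.
#' @param metric `"auc"` (default, always defined), `"K"` (fitted carrying
#'   capacity; falls back to AUC with a warning if any fit fails to
#'   converge), or `"max_od"`.
#'
#' @return One-row tibble: `metric`, `effect`, `wt_mean`, `kd_mean`,
#'   `wt_sd`, `kd_sd`, `n_wt`, `n_kd`; per-replicate values in the
#'   `"values"` attribute.
#' @export
compare_wt_kd <- function(wt, kd, metric = c("auc", "K", "max_od")) {
  metric <- match.arg(metric)
  per_rep <- function(curves, label, m) {
    curves %>%
      group_by(replicate = .data$replicate) %>%
      dplyr::group_modify(function(d, key) {
        value <- switch(m,
          auc = curve_auc(d),
          max_od = max(d$od),
          K = {
            f <- fit_logistic(d)
            if (!f$converged || f$degenerate) NA_real_ else f$K
          })
        tibble(value = value)
      }) %>%
      ungroup() %>%
      mutate(set = label)
  }
  vals <- bind_rows(per_rep(wt, "wt", metric), per_rep(kd, "kd", metric))
  used <- metric
  if (metric == "K" && anyNA(vals$value)) {
    warn("Logistic fit unavailable for some replicates; falling back to AUC.")
    used <- "auc"
    vals <- bind_rows(per_rep(wt, "wt", "auc"), per_rep(kd, "kd", "auc"))
  }
  wt_v <- vals$value[vals$set == "wt"]; kd_v <- vals$value[vals$set == "kd"]
  out <- tibble(metric = used,
                effect = mean(kd_v) - mean(wt_v),
                wt_mean = mean(wt_v), kd_mean = mean(kd_v),
                wt_sd = stats::sd(wt_v), kd_sd = stats::sd(kd_v),
                n_wt = length(wt_v), n_kd = length(kd_v))
  attr(out, "values") <- vals
  out
}
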