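#' Difference-in-differences effect of one outcome path pair
#'
#' The effect is the change in the treated series (post-period mean minus
#' pre-period mean) minus the same change in its synthetic control, in rate
#' per 100 patients per month.
#'
#' @param treated_path numeric outcome path of the treated unit.
#' @param sc_path aligned numeric path of the synthetic control.
#' @param pre_idx,post_idx index vectors into the paths for the pre- and
#'   post-intervention windows; both must be non-empty.
#' @return the scalar effect `delta`.
#' @export
did_effect <- function(treated_path, sc_path, pre_idx, post_idx) {
  if (!length(pre_idx) || !length(post_idx))
    stopf("pre and post windows must be non-empty")
  if (length(treated_path) != length(sc_path))
    stopf("paths are not aligned")
  (mean(treated_path[post_idx]) - mean(treated_path[pre_idx])) -
    (mean(sc_path[post_idx]) - mean(sc_path[pre_idx]))
}

# Fit one unit (true treated or pseudo-treated placebo) and return its
# per-outcome DiD deltas plus fit diagnostics.
fit_and_effects <- function(panel, treated_id, donor_ids, spec,
                            pre_window, post_window, ...) {
  pseudo_pool <- structure(list(treated_id = treated_id,
                                donor_ids = donor_ids,
                                constraint_log = NULL),
                           class = "donor_pool")
  fit <- fit_synthetic_control(panel, pseudo_pool, spec, pre_window, ...)
  months <- c(pre_window, post_window)
  paths <- predict_outcomes(fit, panel, months)
  pre_idx <- seq_along(pre_window)
  post_idx <- length(pre_window) + seq_along(post_window)
  deltas <- vapply(spec$outcomes, function(oc) {
    p <- paths[paths$outcome == oc, ]
    did_effect(p$treated, p$synthetic, pre_idx, post_idx)
  }, numeric(1))
  list(fit = fit, deltas = deltas)
}

#' Placebo effect distribution across the donor pool
#'
#' Re-runs the full synthetic-control fit treating each donor in turn as if
#' it were the intervention unit (its donor pool being the remaining donors,
#' with the same predictor spec and windows) and records its
#' difference-in-differences effect per outcome. Donors whose placebo fit
#' fails are dropped and logged.
#'
#' @param panel monthly panel data.frame.
#' @param pool the treated practice's [build_donor_pool()] result.
#' @param spec a [predictor_spec()].
#' @param pre_window,post_window month-index windows around the treated
#'   practice's join month.
#' @param min_placebos minimum number of successful placebo fits below which
#'   inference is refused (default 10).
#' @param ... further arguments to [fit_synthetic_control()].
#' @return matrix of placebo deltas (donors x outcomes) with attributes
#'   `failed` (ids of failed placebo fits) and `pre_mspe` (overall placebo
#'   pre-period MSPEs).
#' @export
run_placebos <- function(panel, pool, spec, pre_window, post_window,
                         min_placebos = 10, ...) {
  res <- list(); failed <- character(0); mspes <- c()
  for (j in pool$donor_ids) {
    r <- tryCatch(
      fit_and_effects(panel, j, setdiff(pool$donor_ids, j), spec,
                      pre_window, post_window, ...),
      error = function(e) e
    )
    if (inherits(r, "error")) {
      failed <- c(failed, j)
    } else {
      res[[j]] <- r$deltas
      mspes[j] <- r$fit$objective
    }
  }
  if (length(res) < min_placebos)
    stopf("only %d placebo fits succeeded (< %d); inference would be unreliable",
          length(res), min_placebos)
  out <- do.call(rbind, res)
  attr(out, "failed") <- failed
  attr(out, "pre_mspe") <- mspes
  out
}

#' Placebo-based inference for one effect estimate
#'
#' The standard error is the sample standard deviation of the placebo effect
#' distribution; the 95% CI is `delta +/- 1.96 * se` and the two-sided
#' p-value uses the standard normal reference, `2 * (1 - pnorm(|delta|/se))`.
#'
#' @param delta the treated practice's effect.
#' @param placebo_deltas numeric vector of placebo effects (>= 10, SD > 0).
#' @param treated_id,outcome identifiers carried into the result.
#' @param pre_mspe_treated optional treated pre-period MSPE diagnostic.
#' @return object of class `effect_estimate` with fields `delta`, `se`,
#'   `ci95`, `p`, `placebo_deltas`.
#' @export
infer_effect <- function(delta, placebo_deltas, treated_id = NA_character_,
                         outcome = NA_character_, pre_mspe_treated = NA_real_) {
  if (length(placebo_deltas) < 10)
    stopf("need at least 10 placebo effects, got %d", length(placebo_deltas))
  se <- stats::sd(placebo_deltas)
  if (se == 0) stopf("placebo effect distribution is degenerate (SD = 0)")
  structure(list(treated_id = treated_id, outcome = outcome,
                 delta = delta, se = se,
                 ci95 = c(delta - 1.96 * se, delta + 1.96 * se),
                 p = 2 * (1 - stats::pnorm(abs(delta) / se)),
                 placebo_deltas = as.numeric(placebo_deltas),
                 pre_mspe_treated = pre_mspe_treated),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s %s: delta %.4g per 100/month (se %.4g, 95%% CI %.4g to %.4g, p = %.3g; %d placebos)\n",
              x$treated_id, x$outcome, x$delta, x$se, x$ci95[1], x$ci95[2],
              x$p, length(x$placebo_deltas)))
  invisible(x)
}

#' Effect estimates with placebo inference for one treated practice
#'
#' Convenience wrapper: fits the treated practice's synthetic control, runs
#' the placebo distribution over its donor pool, and returns one
#' `effect_estimate` per outcome. The pre-window runs from the first panel
#' month to the month before join; the post-window from the join month to
#' the last panel month, truncated at an exit month when one is scheduled.
#' An optional cap excludes placebos whose pre-period fit is worse than
#' `mspe_ratio_cap` times the treated fit's.
#'
#' @inheritParams run_placebos
#' @param schedule intervention schedule.
#' @param mspe_ratio_cap optional placebo fit-quality exclusion multiplier.
#' @return list with `fit` (the treated `scm_fit`) and `estimates`
#'   (list of `effect_estimate`, one per outcome).
#' @export
estimate_practice_effects <- function(panel, schedule, pool, spec,
                                      mspe_ratio_cap = NULL,
                                      min_placebos = 10, ...) {
  sc <- schedule[[pool$treated_id]]
  months <- sort(unique(panel$month_index))
  pre_window <- months[months < sc$join_month]
  post_window <- months[months >= sc$join_month]
  if (!is.null(sc$exit_month) && !is.na(sc$exit_month))
    post_window <- post_window[post_window < sc$exit_month]

  tr <- fit_and_effects(panel, pool$treated_id, pool$donor_ids, spec,
                        pre_window, post_window, ...)
  pl <- run_placebos(panel, pool, spec, pre_window, post_window,
                     min_placebos = min_placebos, ...)
  keep <- rep(TRUE, nrow(pl))
  if (!is.null(mspe_ratio_cap)) {
    keep <- attr(pl, "pre_mspe") <= mspe_ratio_cap * tr$fit$objective
    if (sum(keep) < min_placebos)
      stopf("MSPE-ratio cap leaves %d placebos (< %d)", sum(keep), min_placebos)
  }
  est <- lapply(spec$outcomes, function(oc)
    infer_effect(tr$deltas[[oc]], pl[keep, oc],
                 treated_id = pool$treated_id, outcome = oc,
                 pre_mspe_treated = tr$fit$objective))
  names(est) <- spec$outcomes
  list(fit = tr$fit, estimates = est,
       failed_placebos = attr(pl, "failed"),
       n_placebos = sum(keep))
}
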