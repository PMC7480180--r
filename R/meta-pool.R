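#' Fixed-effect inverse-variance pooling
#'
#' Combines per-practice effect estimates with weights \eqn{w_i = 1/se_i^2}:
#' pooled effect \eqn{\sum w_i \delta_i / \sum w_i}, pooled SE
#' \eqn{(\sum w_i)^{-1/2}}, 95% CI at \eqn{\pm 1.96} SE and a two-sided
#' normal p-value.
#'
#' @param deltas numeric vector of per-practice effects.
#' @param ses positive standard errors, same length.
#' @param outcome outcome label carried into the result.
#' @param allow_single permit `k = 1`, in which case the single estimate is
#'   returned unchanged (no heterogeneity assessment possible).
#' @return object of class `pooled_effect`.
#' @export
pool_fixed <- function(deltas, ses, outcome = NA_character_,
                       allow_single = FALSE) {
  k <- length(deltas)
  if (length(ses) != k) stopf("deltas and ses differ in length")
  if (any(ses <= 0)) stopf("all standard errors must be > 0")
  if (k < 2 && !allow_single)
    stopf("need at least 2 estimates to pool (or set allow_single = TRUE)")
  w <- 1 / ses^2
  est <- sum(w * deltas) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- if (k >= 2) heterogeneity(deltas, ses) else
    list(Q = NA_real_, df = 0L, q_p = NA_real_, i2 = NA_real_,
         i2_ci95 = c(NA_real_, NA_real_), tau2 = NA_real_)
  new_pooled(outcome, est, se, het, model = "fixed", k = k)
}

#' Heterogeneity of a set of effect estimates
#'
#' Cochran's \eqn{Q = \sum w_i (\delta_i - \hat\delta_{FE})^2} with
#' \eqn{w_i = 1/se_i^2} and `df = k - 1`; Higgins-Thompson
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100} (0 when Q = 0) with its 95% CI
#' from the test-based method on \eqn{\ln H}; DerSimonian-Laird
#' \eqn{\tau^2 = \max(0, (Q - df)/(\sum w - \sum w^2/\sum w))}.
#'
#' @inheritParams pool_fixed
#' @return list with `Q`, `df`, `q_p`, `i2`, `i2_ci95`, `tau2`.
#' @export
heterogeneity <- function(deltas, ses) {
  k <- length(deltas)
  if (k < 2) stopf("heterogeneity requires at least 2 estimates")
  if (any(ses <= 0)) stopf("all standard errors must be > 0")
  w <- 1 / ses^2
  est <- sum(w * deltas) / sum(w)
  Q <- sum(w * (deltas - est)^2)
  df <- k - 1L
  q_p <- stats::pchisq(Q, df, lower.tail = FALSE)
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  list(Q = Q, df = df, q_p = q_p, i2 = i2,
       i2_ci95 = i2_ci_test_based(Q, k), tau2 = tau2)
}

# Test-based 95% CI for I^2 (Higgins & Thompson): CI on ln H with
# se(ln H) = 0.5 (ln Q - ln df)/(sqrt(2Q) - sqrt(2k-3))    if Q > k
#          = sqrt( 1/(2(k-2)) * (1 - 1/(3(k-2)^2)) )       otherwise (k > 2),
# then H bounds floored at 1 and mapped through I^2 = 100 (H^2-1)/H^2.
i2_ci_test_based <- function(Q, k) {
  df <- k - 1
  if (k < 3 && Q <= k) return(c(0, 100))  # se undefined for k = 2, Q <= k
  se_lnH <- if (Q > k) {
    0.5 * (log(Q) - log(df)) / (sqrt(2 * Q) - sqrt(2 * k - 3))
  } else {
    sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
  }
  lnH <- 0.5 * log(max(Q / df, 1))
  H_bounds <- exp(lnH + c(-1, 1) * 1.96 * se_lnH)
  H_bounds <- pmax(H_bounds, 1)
  100 * (H_bounds^2 - 1) / H_bounds^2
}

#' Pool with data-driven fixed/random model choice
#'
#' Uses the fixed-effect model when the heterogeneity test is not
#' significant (`q_p >= alpha`); otherwise refits with random-effects
#' (DerSimonian-Laird) weights \eqn{1/(se_i^2 + \tau^2)}.
#'
#' @inheritParams pool_fixed
#' @param alpha significance threshold of the Q test (default 0.05).
#' @return object of class `pooled_effect` whose `model` field records the
#'   choice.
#' @export
pool_auto <- function(deltas, ses, outcome = NA_character_, alpha = 0.05) {
  fe <- pool_fixed(deltas, ses, outcome = outcome)
  if (fe$q_p >= alpha) return(fe)
  het <- heterogeneity(deltas, ses)
  w <- 1 / (ses^2 + het$tau2)
  est <- sum(w * deltas) / sum(w)
  se <- 1 / sqrt(sum(w))
  new_pooled(outcome, est, se, het, model = "random", k = length(deltas))
}

new_pooled <- function(outcome, est, se, het, model, k) {
  structure(list(outcome = outcome, delta_pooled = est, se_pooled = se,
                 ci95 = c(est - 1.96 * se, est + 1.96 * se),
                 p = 2 * (1 - stats::pnorm(abs(est) / se)),
                 Q = het$Q, df = het$df, q_p = het$q_p,
                 i2 = het$i2, i2_ci95 = het$i2_ci95, tau2 = het$tau2,
                 model = model, k = k),
            class = "pooled_effect")
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf("Pooled %s effect (%s-effects, k = %d): %.4g per 100/month\n",
              x$outcome, x$model, x$k, x$delta_pooled))
  cat(sprintf("  95%% CI %.4g to %.4g, p = %.3g\n",
              x$ci95[1], x$ci95[2], x$p))
  if (!is.na(x$Q))
    cat(sprintf("  heterogeneity: Q = %.3g (df = %d, p = %.2g), I2 = %.1f%% (95%% CI %.1f%% to %.1f%%), tau2 = %.3g\n",
                x$Q, x$df, x$q_p, x$i2, x$i2_ci95[1], x$i2_ci95[2], x$tau2))
  invisible(x)
}

#' Text forest summary of per-practice and pooled effects
#'
#' @param estimates list of `effect_estimate` for one outcome.
#' @param pooled the corresponding `pooled_effect`.
#' @return character vector of formatted lines, invisibly printed.
#' @export
forest_summary <- function(estimates, pooled) {
  lines <- vapply(estimates, function(e)
    sprintf("  %-8s %8.4f  [%8.4f, %8.4f]  p=%.3g",
            e$treated_id, e$delta, e$ci95[1], e$ci95[2], e$p), character(1))
  lines <- c(sprintf("Outcome %s (per 100 patients per month):", pooled$outcome),
             lines,
             sprintf("  %-8s %8.4f  [%8.4f, %8.4f]  p=%.3g  (%s, I2=%.1f%%)",
                     "POOLED", pooled$delta_pooled, pooled$ci95[1],
                     pooled$ci95[2], pooled$p, pooled$model, pooled$i2))
  cat(lines, sep = "\n")
  invisible(lines)
}
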