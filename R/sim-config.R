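#' Simulation configuration for synthetic GP-practice panels
#'
#' Bundles and validates every knob of the synthetic monthly panel generator.
#' Defaults are calibrated to a UK urban primary-care setting: outcome levels
#' of roughly 2.7 ED attendances, 0.87 unplanned admissions and 0.12 unplanned
#' readmissions per 100 registered patients per month, a 48-month panel, and
#' staggered intervention joins between months 15 and 40.
#'
#' @param n_treated number of treated (intervention) practices.
#' @param n_donors number of candidate donor practices.
#' @param n_months panel length in months (>= 2).
#' @param outcome_means length-3 vector of mean rates per 100 patients per
#'   month for (ED attendances, unplanned admissions, unplanned readmissions).
#' @param outcome_sds length-3 between-practice SDs of the practice-level
#'   intercepts, same units as `outcome_means`.
#' @param factor_loading_sd SD of practice loadings on the shared latent
#'   time factor (loadings are centred at 1).
#' @param seasonal_amplitude amplitude of the shared annual cycle, as a
#'   fraction of each outcome mean.
#' @param treatment_effects length-3 additive post-join change in each rate
#'   (per 100 patients per month) applied to treated practices.
#' @param join_months integer month indices at which treated practices join,
#'   recycled across treated practices; each strictly inside (1, n_months).
#' @param exit_months optional integer vector (NA allowed per practice) of
#'   months at which a treated practice leaves the programme.
#' @param list_size_range length-2 positive increasing range from which
#'   registered-list sizes are drawn uniformly.
#' @param noise_sd length-3 SD of the idiosyncratic monthly noise per outcome.
#' @param count_mode if `TRUE`, monthly event counts are drawn as Poisson with
#'   mean `rate * list_size / 100` and rates recomputed from them, adding
#'   realistic small-denominator granularity.
#' @param seed integer seed governing all generator randomness.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [generate_panel()]
#' @export
sim_config <- function(n_treated = 10,
                       n_donors = 40,
                       n_months = 48,
                       outcome_means = c(2.70, 0.87, 0.12),
                       outcome_sds = c(0.55, 0.22, 0.045),
                       factor_loading_sd = 0.10,
                       seasonal_amplitude = 0.05,
                       treatment_effects = c(0, -0.11, -0.021),
                       join_months = c(15, 15, 15, 22, 25, 28, 30, 32, 35, 40),
                       exit_months = NULL,
                       list_size_range = c(5000, 7000),
                       noise_sd = c(0.18, 0.06, 0.025),
                       count_mode = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_treated = as.integer(n_treated), n_donors = as.integer(n_donors),
    n_months = as.integer(n_months),
    outcome_means = as.numeric(outcome_means),
    outcome_sds = as.numeric(outcome_sds),
    factor_loading_sd = as.numeric(factor_loading_sd),
    seasonal_amplitude = as.numeric(seasonal_amplitude),
    treatment_effects = as.numeric(treatment_effects),
    join_months = as.integer(rep_len(join_months, n_treated)),
    exit_months = if (is.null(exit_months)) rep(NA_integer_, n_treated)
                  else as.integer(rep_len(exit_months, n_treated)),
    list_size_range = as.numeric(list_size_range),
    noise_sd = as.numeric(noise_sd),
    count_mode = isTRUE(count_mode),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_treated < 1 || cfg$n_donors < 1)
    stopf("n_treated and n_donors must be at least 1")
  if (cfg$n_months < 2) stopf("n_months must be >= 2")
  for (nm in c("outcome_means", "outcome_sds", "treatment_effects", "noise_sd"))
    if (length(cfg[[nm]]) != 3)
      stopf("%s must have length 3 (ED, admissions, readmissions)", nm)
  if (any(cfg$outcome_means <= 0)) stopf("all outcome means must be > 0")
  if (any(cfg$outcome_sds < 0) || any(cfg$noise_sd < 0))
    stopf("outcome_sds and noise_sd must be non-negative")
  if (any(cfg$join_months <= 1) || any(cfg$join_months >= cfg$n_months))
    stopf("join_months must lie strictly inside (1, n_months)")
  ex <- cfg$exit_months
  bad <- !is.na(ex) & ex <= cfg$join_months
  if (any(bad)) stopf("exit month must come after the join month")
  r <- cfg$list_size_range
  if (length(r) != 2 || any(r <= 0) || r[1] >= r[2])
    stopf("list_size_range must be positive and increasing")
  # A calibration whose noise routinely drives draws below zero would be
  # silently distorted by clipping; refuse it up front.
  clip_p <- stats::pnorm(0, mean = cfg$outcome_means, sd = cfg$noise_sd)
  if (any(clip_p > 0.10))
    stopf("unusable calibration: outcome %d would clip at zero in %.0f%% of draws",
          which.max(clip_p), 100 * max(clip_p))
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic panel configuration\n")
  cat(sprintf("  practices: %d treated + %d donors, %d months\n",
              x$n_treated, x$n_donors, x$n_months))
  cat(sprintf("  outcome means (per 100/month): %.2f ED, %.2f adm, %.2f readm\n",
              x$outcome_means[1], x$outcome_means[2], x$outcome_means[3]))
  cat(sprintf("  treatment effects: %s\n",
              paste(format(x$treatment_effects), collapse = ", ")))
  cat(sprintf("  join months: %s\n", paste(x$join_months, collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
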