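#' Per-admission unit cost from episode reference costs
#'
#' National reference costs are published per finished consultant episode
#' (FCE); an admission can span several episodes. The per-admission unit
#' cost is the FCE reference cost scaled by the national ratio of finished
#' consultant episodes to finished admission episodes (FAE), rounded to the
#' nearest whole currency unit (halves up).
#'
#' @param reference_cost currency per FCE.
#' @param fce,fae national episode counts (FAE > 0).
#' @return whole-currency cost per admission.
#' @export
unit_cost <- function(reference_cost, fce, fae) {
  if (any(c(reference_cost, fce, fae) <= 0))
    stopf("reference_cost, fce and fae must all be positive")
  round_half_up(reference_cost * fce / fae)
}

#' Avoided events implied by a rate effect
#'
#' Converts an effect in events per 100 patients per month into whole
#' monthly events for a registered population (rounded, halves up), then
#' annualises the rounded monthly count. Rounding before annualising keeps
#' the published monthly and annual figures consistent (e.g. 74/month
#' -> 888/year rather than 890).
#'
#' @param effect rate change per 100 patients per month (sign is ignored).
#' @param population registered patients covered.
#' @return named numeric vector `c(monthly, annual)`.
#' @export
annualize_events <- function(effect, population) {
  if (population <= 0) stopf("population must be positive")
  monthly <- round_half_up(abs(effect) / 100 * population)
  c(monthly = monthly, annual = 12 * monthly)
}

#' Cost savings implied by a pooled effect
#'
#' Annual savings are the annualised avoided events multiplied by the
#' per-admission unit cost; the sensitivity range repeats the computation at
#' the 95% CI bounds of the effect.
#'
#' @param effect pooled rate change per 100 patients per month.
#' @param ci95 length-2 confidence bounds of the effect.
#' @param population registered patients covered.
#' @param reference_cost,fce,fae passed to [unit_cost()].
#' @return object of class `cost_result` with the population, effect, event
#'   counts, unit cost, point savings and CI-bound savings (`savings_lo` /
#'   `savings_hi` are the smaller and larger of the two bound estimates).
#' @export
cost_savings <- function(effect, ci95, population,
                         reference_cost = 1603, fce = 20e6, fae = 16.6e6) {
  uc <- unit_cost(reference_cost, fce, fae)
  ev <- annualize_events(effect, population)
  sv <- ev[["annual"]] * uc
  bounds <- vapply(ci95, function(b)
    annualize_events(b, population)[["annual"]] * uc, numeric(1))
  structure(list(population = population, effect = effect, ci95 = ci95,
                 monthly_events = ev[["monthly"]],
                 annual_events = ev[["annual"]],
                 reference_cost = reference_cost, fce = fce, fae = fae,
                 unit_cost = uc, savings = sv,
                 savings_lo = min(bounds), savings_hi = max(bounds)),
            class = "cost_result")
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf("Population %s; effect %.4g per 100/month\n",
              format(x$population, big.mark = " "), x$effect))
  cat(sprintf("  avoided events: %d per month, %d per year\n",
              x$monthly_events, x$annual_events))
  cat(sprintf("  unit cost: %s (reference %s x FCE/FAE %.3g)\n",
              format(x$unit_cost, big.mark = " "),
              format(x$reference_cost, big.mark = " "), x$fce / x$fae))
  cat(sprintf("  annual savings: %s (CI-bound range %s to %s)\n",
              format(x$savings, big.mark = " "),
              format(x$savings_lo, big.mark = " "),
              format(x$savings_hi, big.mark = " ")))
  invisible(x)
}
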