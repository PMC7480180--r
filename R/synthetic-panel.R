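#' Generate a synthetic monthly GP-practice panel
#'
#' Simulates a rectangular practice-by-month panel with the structure the
#' synthetic-control estimator assumes: practice-level intercepts, a shared
#' annual cycle, a shared smooth latent time factor with heterogeneous
#' loadings (an interactive fixed-effects model), idiosyncratic noise, and
#' covariates correlated with the outcome intercepts (deprivation-like
#' covariates rise with a practice's underlying admission propensity).
#' Treated practices receive the configured additive treatment effect on each
#' outcome from their join month onwards (until an exit month, if present).
#' Rates are clipped at zero.
#'
#' For practice i, outcome o and month t the generated rate is
#' \deqn{y_{iot} = \max(0,\; \alpha_{io} + s_o(t) + \gamma_i f(t) c_o +
#'       \delta_o [t \ge join_i] + \varepsilon_{iot})}
#' with practice intercepts \eqn{\alpha_{io}}, annual cycle \eqn{s_o},
#' smooth shared factor \eqn{f}, loadings \eqn{\gamma_i \sim N(1, \sigma_\gamma)}
#' and Gaussian noise \eqn{\varepsilon}.
#'
#' @param config a [sim_config()] object.
#' @return a list with components `panel` (data.frame, one row per
#'   practice-month, columns as written by [write_panel()]) and `schedule`
#'   (named list mapping treated practice id to
#'   `list(join_month, exit_month)`), plus attribute `truth` holding the
#'   latent intercepts, loadings and factor path for diagnostics.
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  with_seed(config$seed, generate_panel_impl(config))
}

generate_panel_impl <- function(cfg) {
  n_prac <- cfg$n_treated + cfg$n_donors
  ids <- c(sprintf("T%02d", seq_len(cfg$n_treated)),
           sprintf("D%03d", seq_len(cfg$n_donors)))
  months <- seq_len(cfg$n_months)

  # Practice-level severity score: shared across outcomes so that the three
  # rates and the deprivation-like covariates co-move across practices.
  sev <- stats::rnorm(n_prac)
  alpha <- outer(sev, cfg$outcome_sds) +
    matrix(cfg$outcome_means, n_prac, 3, byrow = TRUE)

  # Shared smooth latent factor: standardized moving average of a random walk.
  f <- cumsum(stats::rnorm(cfg$n_months))
  f <- stats::filter(f, rep(1 / 5, 5), sides = 2)
  f[is.na(f)] <- 0
  f <- as.numeric(scale(f))
  gamma <- stats::rnorm(n_prac, mean = 1, sd = cfg$factor_loading_sd)
  factor_scale <- 0.05 * cfg$outcome_means

  season <- sin(2 * pi * months / 12)
  list_size <- round(stats::runif(n_prac, cfg$list_size_range[1],
                                  cfg$list_size_range[2]))

  schedule <- list()
  join_of <- rep(NA_integer_, n_prac)
  exit_of <- rep(NA_integer_, n_prac)
  for (i in seq_len(cfg$n_treated)) {
    join_of[i] <- cfg$join_months[i]
    exit_of[i] <- cfg$exit_months[i]
    schedule[[ids[i]]] <- list(join_month = cfg$join_months[i],
                               exit_month = cfg$exit_months[i])
  }

  rows <- vector("list", n_prac)
  for (i in seq_len(n_prac)) {
    y <- matrix(0, cfg$n_months, 3)
    for (o in 1:3) {
      y[, o] <- alpha[i, o] +
        cfg$seasonal_amplitude * cfg$outcome_means[o] * season +
        gamma[i] * f * factor_scale[o] +
        stats::rnorm(cfg$n_months, 0, cfg$noise_sd[o])
      if (!is.na(join_of[i])) {
        post <- months >= join_of[i]
        if (!is.na(exit_of[i])) post <- post & months < exit_of[i]
        y[post, o] <- y[post, o] + cfg$treatment_effects[o]
      }
    }
    y <- pmax(y, 0)
    if (cfg$count_mode) {
      # Redraw as Poisson event counts at the practice's list size and
      # recompute the rate, giving integer-granular rates.
      for (o in 1:3) {
        lambda <- y[, o] * list_size[i] / 100
        y[, o] <- stats::rpois(cfg$n_months, lambda) / list_size[i] * 100
      }
    }
    em_los <- pmax(stats::rnorm(cfg$n_months,
                                mean = 5 + 0.4 * sev[i], sd = 0.5), 0)
    rows[[i]] <- data.frame(
      practice_id = ids[i], month_index = months,
      list_size = list_size[i],
      ed_rate = y[, 1], adm_rate = y[, 2], readm_rate = y[, 3],
      em_los = em_los,
      stringsAsFactors = FALSE
    )
  }
  panel <- do.call(rbind, rows)

  cov <- practice_covariates(ids, sev, list_size)
  panel <- merge(panel, cov, by = "practice_id", sort = FALSE)
  panel <- panel[order(panel$practice_id, panel$month_index), PANEL_COLS]
  rownames(panel) <- NULL

  out <- list(panel = panel, schedule = schedule)
  attr(out, "truth") <- list(alpha = alpha, gamma = gamma, factor = f,
                             severity = sev, ids = ids)
  out
}

# Time-constant covariates, drawn so deprivation-like measures correlate
# positively with the practice severity score driving outcome intercepts.
practice_covariates <- function(ids, sev, list_size) {
  n <- length(ids)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  gp_count <- pmax(1, round(list_size / 1600 + stats::rnorm(n, 0, 1)))
  nurse_count <- pmax(1, round(list_size / 3000 + stats::rnorm(n, 0, 0.8)))
  bme_pct <- clamp(25 + 10 * sev + stats::rnorm(n, 0, 8), 0, 100)
  imd <- clamp(30 + 8 * sev + stats::rnorm(n, 0, 5), 1, 80)
  urban_pct <- clamp(90 + stats::rnorm(n, 0, 8), 0, 100)
  # Age-sex bands perturbed around a typical urban profile, renormalised to
  # sum to 100%.
  base <- c(11, 29, 10, 12, 30, 8)
  bands <- t(vapply(seq_len(n), function(i) {
    b <- pmax(base + stats::rnorm(6, 0, 1.5), 1)
    b / sum(b) * 100
  }, numeric(6)))
  prev <- function(mu, slope, sd) pmax(mu + slope * sev + stats::rnorm(n, 0, sd), 0)
  data.frame(
    practice_id = ids,
    gp_count = gp_count, nurse_count = nurse_count, bme_pct = bme_pct,
    f0_19_pct = bands[, 1], f20_64_pct = bands[, 2], f65_pct = bands[, 3],
    m0_19_pct = bands[, 4], m20_64_pct = bands[, 5], m65_pct = bands[, 6],
    imd = imd, urban_pct = urban_pct,
    prev_chd_pct = prev(3.0, 0.4, 0.5),
    prev_diabetes_pct = prev(6.5, 0.8, 1.0),
    prev_copd_pct = prev(2.0, 0.4, 0.4),
    stringsAsFactors = FALSE
  )
}

#' Add a treatment effect to a panel's post-intervention rates
#'
#' Adds the given effect (per 100 patients per month) to each outcome of each
#' scheduled practice from its join month (to its exit month, when present),
#' clipping resulting rates at zero. Used for parameter-recovery experiments
#' on otherwise effect-free panels.
#'
#' @param panel a monthly panel data.frame as produced by [generate_panel()].
#' @param schedule named list: practice id -> `list(join_month, exit_month)`.
#' @param effects length-3 additive effects for
#'   (ed_rate, adm_rate, readm_rate).
#' @return the modified panel.
#' @export
inject_effect <- function(panel, schedule, effects) {
  stopifnot(length(effects) == 3)
  missing_ids <- setdiff(names(schedule), unique(panel$practice_id))
  if (length(missing_ids))
    stopf("schedule practice(s) not in panel: %s",
          paste(missing_ids, collapse = ", "))
  for (id in names(schedule)) {
    sc <- schedule[[id]]
    post <- panel$practice_id == id & panel$month_index >= sc$join_month
    if (!is.null(sc$exit_month) && !is.na(sc$exit_month))
      post <- post & panel$month_index < sc$exit_month
    for (o in seq_along(OUTCOME_COLS)) {
      col <- OUTCOME_COLS[o]
      panel[post, col] <- pmax(panel[post, col] + effects[o], 0)
    }
  }
  panel
}
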