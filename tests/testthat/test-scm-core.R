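test_that("assemble_matrices stacks covariate means over outcome paths", {
  set.seed(10)
  pre <- 1:12
  paths <- lapply(1:3, function(i) list(ed_rate = rnorm(14, 2.5, 0.2),
                                        adm_rate = rnorm(14, 1, 0.1),
                                        readm_rate = rnorm(14, 0.12, 0.02)))
  names(paths) <- c("T", "D1", "D2")
  panel <- path_panel(paths, n_months = 14)
  spec <- predictor_spec(covariates = c("imd", "bme_pct"),
                         standardize = FALSE)
  pool <- manual_pool("T", c("D1", "D2"))
  m <- assemble_matrices(panel, pool, spec, pre)
  expect_length(m$X1, 2 + 3 * 12)
  expect_equal(dim(m$X0), c(38, 2))
  expect_length(m$Z1, 36)
  expect_equal(table(m$z_outcome)[["adm_rate"]], 12L)
})

test_that("a donor identical to the treated unit has X0 column equal to X1", {
  set.seed(11)
  n <- 12
  path <- 1 + 0.1 * sin(1:n)
  panel <- path_panel(list(T = list(adm_rate = path),
                           D1 = list(adm_rate = path),
                           D2 = list(adm_rate = 1 + 0.05 * cos(1:n))),
                      n_months = n)
  spec <- predictor_spec(covariates = "imd", outcomes = "adm_rate",
                         standardize = FALSE)
  m <- assemble_matrices(panel, manual_pool("T", c("D1", "D2")), spec, 1:n)
  expect_equal(unname(m$X0[, "D1"]), unname(m$X1))
})

test_that("standardization drops zero-variance rows with a warning", {
  set.seed(12)
  n <- 10
  panel <- path_panel(list(T = list(adm_rate = rnorm(n, 1, 0.1)),
                           D1 = list(adm_rate = rnorm(n, 1, 0.1)),
                           D2 = list(adm_rate = rnorm(n, 1, 0.1))),
                      n_months = n)
  # 'imd' is constant across donors in these helper panels
  spec <- predictor_spec(covariates = "imd", outcomes = "adm_rate",
                         standardize = TRUE)
  expect_warning(
    m <- assemble_matrices(panel, manual_pool("T", c("D1", "D2")), spec, 1:n),
    "zero-variance"
  )
  expect_equal(m$dropped, "imd")
  expect_length(m$X1, n)
})

test_that("an outcome with no donor variance at all is an error", {
  n <- 10
  panel <- path_panel(list(T = list(adm_rate = rep(1.1, n)),
                           D1 = list(adm_rate = rep(1, n)),
                           D2 = list(adm_rate = rep(1, n))),
                      n_months = n)
  spec <- predictor_spec(covariates = character(0), outcomes = "adm_rate",
                         standardize = FALSE)
  expect_error(
    assemble_matrices(panel, manual_pool("T", c("D1", "D2")), spec, 1:n),
    "zero variance across all donors"
  )
})

test_that("inner QP solves forced, midpoint and random cases exactly", {
  # single donor: forced
  expect_equal(solve_inner_weights(c(1, 2), matrix(c(1, 1), 2,
                                                   dimnames = list(NULL, "D1")),
                                   c(0.5, 0.5)),
               c(D1 = 1))
  # treated exactly midway between two donors
  X0 <- cbind(D1 = c(0, 0), D2 = c(2, 2))
  w <- solve_inner_weights(c(1, 1), X0, c(0.5, 0.5))
  expect_equal(unname(w), c(0.5, 0.5), tolerance = 1e-6)
  # random 3-donor problems match a brute-force simplex grid
  for (s in 1:5) {
    set.seed(100 + s)
    X0 <- matrix(rnorm(15), 5, dimnames = list(NULL, c("a", "b", "c")))
    X1 <- rnorm(5)
    V <- runif(5); V <- V / sum(V)
    w <- solve_inner_weights(X1, X0, V)
    obj <- function(ww) sum(V * (X1 - X0 %*% ww)^2)
    expect_lte(obj(w), grid_min(obj, 3, step = 0.01) + 1e-3)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w >= -1e-9))
  }
  expect_error(solve_inner_weights(c(1, 1), X0, c(2, 2, 2, 2, 2)), "sum to 1")
})

test_that("a perfect clone in the pool is recovered with weight one", {
  set.seed(21)
  n <- 16
  path <- 1 + 0.2 * sin(1:n) + rnorm(n, 0, 0.05)
  panel <- path_panel(list(T = list(adm_rate = path),
                           CLONE = list(adm_rate = path),
                           D2 = list(adm_rate = rnorm(n, 1.3, 0.1)),
                           D3 = list(adm_rate = rnorm(n, 0.8, 0.1))),
                      n_months = n)
  spec <- predictor_spec(covariates = character(0), outcomes = "adm_rate")
  fit <- fit_synthetic_control(panel, manual_pool("T", c("CLONE", "D2", "D3")),
                               spec, 1:n)
  expect_equal(unname(fit$W["CLONE"]), 1, tolerance = 1e-4)
  expect_lte(fit$objective, 1e-10)
})

test_that("an exact average of two donors splits the weight evenly", {
  set.seed(22)
  n <- 16
  a <- 1 + 0.2 * sin(1:n) + rnorm(n, 0, 0.1)
  b <- 1 - 0.2 * cos(1:n) + rnorm(n, 0, 0.1)
  noise <- rnorm(n, 1, 0.3)
  panel <- path_panel(list(T = list(adm_rate = (a + b) / 2),
                           A = list(adm_rate = a), B = list(adm_rate = b),
                           C = list(adm_rate = noise)),
                      n_months = n)
  spec <- predictor_spec(covariates = character(0), outcomes = "adm_rate")
  fit <- fit_synthetic_control(panel, manual_pool("T", c("A", "B", "C")),
                               spec, 1:n)
  expect_equal(unname(fit$W[c("A", "B")]), c(0.5, 0.5), tolerance = 0.02)
  expect_lte(unname(fit$W["C"]), 0.02)
})

test_that("factor-structure panels admit a near-perfect pre-period fit", {
  # treated intercept an exact convex combination of two donors', shared
  # factor, no noise: the SCM identity holds and pre-MSPE vanishes
  cfg <- sim_config(n_treated = 1, n_donors = 3, n_months = 24,
                    outcome_sds = c(0.3, 0.12, 0.02), factor_loading_sd = 0,
                    noise_sd = c(0, 0, 0), join_months = 13, seed = 31)
  g <- generate_panel(cfg)
  p <- g$panel
  # rebuild the treated practice as 0.4 * D001 + 0.6 * D002
  for (col in c("ed_rate", "adm_rate", "readm_rate", "em_los",
                scmeval:::COVARIATE_COLS, "list_size")) {
    mix <- 0.4 * p[p$practice_id == "D001", col] +
           0.6 * p[p$practice_id == "D002", col]
    p[p$practice_id == "T01", col] <- mix
  }
  spec <- predictor_spec(covariates = c("imd", "bme_pct"))
  fit <- fit_synthetic_control(p, manual_pool("T01", c("D001", "D002", "D003")),
                               spec, 1:12)
  expect_lt(fit$objective, 1e-8)
  # weights are identified only up to the family of Z-perfect combinations
  # (the intercepts are driven by a single latent score), so assert the fit,
  # not the weights: the synthetic pre-period path reproduces the treated one
  pre <- predict_outcomes(fit, p, 1:12)
  expect_equal(pre$synthetic, pre$treated, tolerance = 1e-4)
})

test_that("fitted weights live on the simplex and beat the equal-V baseline", {
  for (s in 1:4) {
    set.seed(200 + s)
    n <- 12
    paths <- lapply(1:5, function(i) list(adm_rate = rnorm(n, 1, 0.2),
                                          ed_rate = rnorm(n, 2.5, 0.3)))
    names(paths) <- c("T", paste0("D", 1:4))
    panel <- path_panel(paths, n_months = n)
    spec <- predictor_spec(covariates = "list_size", standardize = FALSE,
                           outcomes = c("ed_rate", "adm_rate"))
    pool <- manual_pool("T", paste0("D", 1:4))
    fit <- fit_synthetic_control(panel, pool, spec, 1:n,
                                 multistarts = 2, maxit = 50)
    expect_equal(sum(fit$W), 1, tolerance = 1e-6)
    expect_true(all(fit$W >= -1e-9))
    expect_equal(sum(fit$V), 1, tolerance = 1e-6)
    expect_true(all(fit$V >= 0))
    eq_fit <- fit_synthetic_control(panel, pool, spec, 1:n, optimize_v = FALSE)
    expect_lte(fit$objective, eq_fit$objective + 1e-12)
  }
})

test_that("synthetic paths are convex combinations of donor paths", {
  set.seed(33)
  n <- 20
  paths <- lapply(1:6, function(i) list(adm_rate = rnorm(n, 1, 0.2)))
  names(paths) <- c("T", paste0("D", 1:5))
  panel <- path_panel(paths, n_months = n)
  spec <- predictor_spec(covariates = character(0), outcomes = "adm_rate")
  pool <- manual_pool("T", paste0("D", 1:5))
  fit <- fit_synthetic_control(panel, pool, spec, 1:10, optimize_v = FALSE)
  pred <- predict_outcomes(fit, panel, 1:n)
  donor_mat <- sapply(paste0("D", 1:5),
                      function(id) panel$adm_rate[panel$practice_id == id])
  expect_true(all(pred$synthetic >= apply(donor_mat, 1, min) - 1e-9))
  expect_true(all(pred$synthetic <= apply(donor_mat, 1, max) + 1e-9))

  # degenerate weight vectors reproduce single donors exactly
  fit$W <- setNames(c(1, 0, 0, 0, 0), paste0("D", 1:5))
  pred1 <- predict_outcomes(fit, panel, 1:n)
  expect_equal(pred1$synthetic, donor_mat[, "D1"])
  expect_error(predict_outcomes(fit, panel, 1:(n + 2)), "outside panel range")
})
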