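test_that("sim_config rejects invalid calibrations", {
  expect_error(sim_config(n_months = 1), "n_months")
  expect_error(sim_config(join_months = 1), "join_months")
  expect_error(sim_config(join_months = 48), "join_months")
  expect_error(sim_config(list_size_range = c(7000, 5000)), "list_size_range")
  expect_error(sim_config(exit_months = 10, join_months = 20), "exit month")
  # noise so large relative to the mean that >10% of draws would clip at 0
  expect_error(sim_config(outcome_means = c(2.7, 0.87, 0.05),
                          noise_sd = c(0.18, 0.06, 0.05)),
               "unusable calibration")
})

test_that("generation is seed-reproducible, rectangular and non-negative", {
  cfg <- sim_config(n_treated = 3, n_donors = 8, n_months = 30,
                    join_months = c(12, 18, 24), seed = 42)
  g1 <- generate_panel(cfg)
  g2 <- generate_panel(cfg)
  expect_identical(g1$panel, g2$panel)
  expect_identical(g1$schedule, g2$schedule)

  p <- g1$panel
  expect_equal(nrow(p), 11 * 30)
  expect_false(anyDuplicated(paste(p$practice_id, p$month_index)) > 0)
  expect_true(all(table(p$practice_id) == 30))
  expect_true(all(p[, c("ed_rate", "adm_rate", "readm_rate")] >= 0))
  expect_equal(sort(names(g1$schedule)), c("T01", "T02", "T03"))
  # a different seed gives different draws
  g3 <- generate_panel(sim_config(n_treated = 3, n_donors = 8, n_months = 30,
                                  join_months = c(12, 18, 24), seed = 43))
  expect_false(identical(g1$panel$adm_rate, g3$panel$adm_rate))
})

test_that("null-effect panels show no systematic treated/donor post gap", {
  rejections <- 0
  for (s in 1:20) {
    g <- generate_panel(sim_config(n_treated = 5, n_donors = 20,
                                   treatment_effects = c(0, 0, 0),
                                   join_months = 25, seed = 1000 + s))
    p <- g$panel[g$panel$month_index >= 25, ]
    post_mean <- tapply(p$adm_rate, p$practice_id, mean)
    treated <- grepl("^T", names(post_mean))
    pv <- stats::t.test(post_mean[treated], post_mean[!treated])$p.value
    if (pv < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)
})

test_that("default calibration matches the target admission-rate level", {
  means <- vapply(1:10, function(s) {
    g <- generate_panel(sim_config(seed = s))
    pre <- g$panel[g$panel$month_index < 15, ]
    mean(pre$adm_rate)
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.87), 0.15)
})

test_that("degenerate generator settings give exact clones and exact gaps", {
  # no noise, common loadings, no intercept spread: every series identical
  cfg <- sim_config(n_treated = 1, n_donors = 4, n_months = 24,
                    outcome_sds = c(0, 0, 0), factor_loading_sd = 0,
                    noise_sd = c(0, 0, 0), treatment_effects = c(0, 0, 0),
                    join_months = 13, seed = 5)
  g <- generate_panel(cfg)
  tr <- g$panel[g$panel$practice_id == "T01", "adm_rate"]
  for (id in c("D001", "D002", "D003", "D004"))
    expect_equal(g$panel[g$panel$practice_id == id, "adm_rate"], tr)

  # with an injected effect the treated-minus-donor post gap is exact
  cfg2 <- sim_config(n_treated = 1, n_donors = 4, n_months = 24,
                     outcome_sds = c(0.1, 0.05, 0.01), factor_loading_sd = 0,
                     noise_sd = c(0, 0, 0),
                     treatment_effects = c(0, -0.11, -0.021),
                     join_months = 13, seed = 5)
  g2 <- generate_panel(cfg2)
  gap <- function(id, col) {
    x <- g2$panel[g2$panel$practice_id == id, col]
    mean(x[13:24]) - mean(x[1:12])
  }
  donor_gap <- mean(vapply(c("D001", "D002", "D003", "D004"),
                           gap, numeric(1), col = "adm_rate"))
  expect_equal(gap("T01", "adm_rate") - donor_gap, -0.11, tolerance = 1e-12)
  donor_gap_r <- mean(vapply(c("D001", "D002", "D003", "D004"),
                             gap, numeric(1), col = "readm_rate"))
  expect_equal(gap("T01", "readm_rate") - donor_gap_r, -0.021,
               tolerance = 1e-12)
})

test_that("count mode produces integer-granular non-negative rates", {
  cfg <- sim_config(n_treated = 2, n_donors = 5, n_months = 12,
                    join_months = 6, count_mode = TRUE, seed = 9)
  g <- generate_panel(cfg)
  counts <- g$panel$adm_rate * g$panel$list_size / 100
  expect_equal(counts, round(counts), tolerance = 1e-9)
  expect_true(all(g$panel$adm_rate >= 0))
})

test_that("inject_effect adds, truncates at exit, and clips at zero", {
  ids <- c("A", "B", "C")
  panel <- constant_panel(ids, n_months = 48)
  sched <- simple_schedule("A", join = 25)

  expect_identical(inject_effect(panel, sched, c(0, 0, 0)), panel)

  out <- inject_effect(panel, sched, c(0, -0.11, 0))
  a <- out[out$practice_id == "A", ]
  expect_equal(a$adm_rate[a$month_index >= 25], rep(0.89, 24))
  expect_equal(a$adm_rate[a$month_index < 25], rep(1.0, 24))
  expect_identical(out[out$practice_id != "A", ],
                   panel[panel$practice_id != "A", ])

  clip <- inject_effect(panel, sched, c(0, -5, 0))
  expect_equal(clip[clip$practice_id == "A" & clip$month_index >= 25,
                    "adm_rate"], rep(0, 24))

  sched_exit <- simple_schedule("A", join = 25, exit = 40)
  ex <- inject_effect(panel, sched_exit, c(0, -0.11, 0))
  a <- ex[ex$practice_id == "A", ]
  expect_equal(a$adm_rate[a$month_index %in% 25:39], rep(0.89, 15))
  expect_equal(a$adm_rate[a$month_index >= 40], rep(1.0, 9))

  expect_error(inject_effect(panel, simple_schedule("Z", 10), c(0, 0, 0)),
               "not in panel")
})
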