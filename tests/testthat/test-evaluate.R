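test_that("error metrics follow their definitions", {
  expect_equal(rr_mae(c(10, 12, 14), c(10, 12, 14)), 0)
  expect_equal(rr_mae(c(10, 12, 14), c(12, 12, 11)), 5 / 3)
  expect_equal(rr_mae(14, 30), 16)

  expect_equal(rr_rmse(c(10, 12, 14), c(10, 12, 14)), 0)
  expect_equal(rr_rmse(c(10, 12, 14), c(12, 12, 11)), sqrt(13 / 3))

  expect_equal(percentage_error(14, 30), 800 / 7)   # +114.29%
  expect_equal(percentage_error(14, 14), 0)
  expect_equal(percentage_error(14, 7), -50)
  expect_error(percentage_error(0, 10), class = "respyre_data_error")

  expect_equal(cp2(c(1, 1, 1, 1), c(2, 4, 2, 6)), 50)
  expect_equal(cp2(c(10, 10), c(12, 8)), 100)        # boundary is inclusive
  expect_equal(cp2(1:5, 1:5), 100)
})

test_that("metrics match a naive loop oracle on random pairs", {
  withr::with_seed(10, {
    ref <- runif(1000, 4, 60)
    est <- ref + rnorm(1000, sd = 3)
  })
  loop_mae <- 0; loop_mse <- 0; loop_cp <- 0
  for (i in seq_along(ref)) {
    loop_mae <- loop_mae + abs(ref[i] - est[i])
    loop_mse <- loop_mse + (ref[i] - est[i])^2
    loop_cp <- loop_cp + (abs(ref[i] - est[i]) <= 2)
  }
  expect_equal(rr_mae(ref, est), loop_mae / 1000, tolerance = 1e-12)
  expect_equal(rr_rmse(ref, est), sqrt(loop_mse / 1000), tolerance = 1e-12)
  expect_equal(cp2(ref, est), 100 * loop_cp / 1000, tolerance = 1e-12)
  expect_gte(rr_rmse(ref, est), rr_mae(ref, est))
})

test_that("rmse dominates mae on random fixtures", {
  for (s in 1:10) {
    withr::with_seed(s, {
      ref <- runif(50, 4, 60)
      est <- ref + rnorm(50, sd = runif(1, 0.1, 10))
    })
    expect_gte(rr_rmse(ref, est), rr_mae(ref, est))
  }
})

test_that("abstained estimates are excluded and accounted for", {
  win <- tibble::tibble(rr_ref = c(10, 12, 14, 16),
                        rr_est = c(10, NA, 14, 17))
  rep <- evaluation_report(win)
  m <- glance(rep)
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$n_windows, 4)
  expect_equal(m$n_abstained, 1)
  expect_equal(m$n_windows, nrow(tidy(rep)))
  expect_error(evaluation_report(tibble::tibble(rr_ref = 1, rr_est = NA)),
               class = "respyre_data_error")
})

test_that("fluctuation flagging isolates corrupted windows", {
  t <- seq(0, 60 - 0.25, by = 0.25)
  clean <- lapply(1:10, function(i) sin(2 * pi * 0.25 * t + i))
  wins <- tibble::tibble(subject = "s1", window = 1:10, samples = clean)
  expect_equal(nrow(flag_fluctuation_segments(wins)), 0)

  # one window with a large step artifact
  bad <- clean
  bad[[4]] <- bad[[4]] + c(numeric(100), rep(10, 140))
  wins_bad <- tibble::tibble(subject = "s1", window = 1:10, samples = bad)
  fl <- flag_fluctuation_segments(wins_bad)
  expect_equal(fl$window, 4)
  expect_match(fl$reason, "sd_ratio")

  # rail-sitting windows are caught even with normal variance
  railed <- clean
  railed[[7]] <- pmin(pmax(3 * clean[[7]], -2), 2)
  fl2 <- flag_fluctuation_segments(tibble::tibble(subject = "s1", window = 1:10,
                                                  samples = railed))
  expect_equal(fl2$window, 7)
  expect_match(fl2$reason, "clip_rail")

  # identical windows: ratio is 1, nothing flagged
  same <- tibble::tibble(subject = "s1", window = 1:5,
                         samples = replicate(5, sin(t), simplify = FALSE))
  expect_equal(nrow(flag_fluctuation_segments(same)), 0)
})

test_that("report round-trips through JSON and writes CSV rows", {
  win <- tibble::tibble(subject = "a", window = 1:3, rr_ref = c(10, 12, 14),
                        rr_est = c(11.95, 13.95, 15.95))
  rep <- evaluation_report(win)
  expect_equal(glance(rep)$mae, 1.95)
  tmp <- withr::local_tempdir()

  json <- file.path(tmp, "report.json")
  write_report(rep, json)
  expect_match(paste(readLines(json), collapse = ""), "1.95", fixed = TRUE)
  back <- read_report(json)
  expect_equal(glance(back)$mae, glance(rep)$mae)
  expect_equal(nrow(back$windows), 3)

  csv <- file.path(tmp, "report.csv")
  write_report(rep, csv)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 3)

  # empty window list: header only
  empty_rep <- rep
  empty_rep$windows <- win[0, ]
  write_report(empty_rep, csv)
  expect_equal(length(readLines(csv)), 1)
})
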