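# Tumor volumes, deltaT/deltaC, TGI bands, mRECIST, ethical censoring.

flat_series <- function(v) data.frame(day = c(0, 3, 7, 10), tv = rep(v, 4))

test_that("tumor volume implements length x width^2 x pi/6", {
  expect_equal(tumor_volume(0, 0), 0)
  expect_equal(tumor_volume(10, 10), 523.599, tolerance = 1e-5)
  expect_equal(tumor_volume(12, 6), 226.195, tolerance = 1e-5)
  expect_warning(v <- tumor_volume(6, 12), "swapped")
  expect_equal(v, 226.195, tolerance = 1e-5)
  # strictly increasing in each argument on positives
  expect_true(tumor_volume(10, 5) < tumor_volume(11, 5))
  expect_true(tumor_volume(10, 5) < tumor_volume(10, 6))
})

make_two_arm <- function(ctrl_fun, trt_fun, days = c(0, 3, 7, 10, 14)) {
  mk <- function(arm, fun) {
    do.call(rbind, lapply(1:3, function(i) {
      tv <- fun(days)
      w <- (6 * tv / pi)^(1 / 3)
      data.frame(study = "s", arm = arm, animal = paste0(arm, i),
                 day = days, length_mm = w, width_mm = w)
    }))
  }
  rbind(mk("vehicle", ctrl_fun), mk("treated", trt_fun))
}

test_that("deltaT/deltaC matches its defining ratio", {
  grow <- function(d) 100 * exp(0.1 * d)
  st <- make_two_arm(grow, grow)
  expect_equal(delta_t_over_c(st, 14), 100, tolerance = 1e-9)

  flat <- function(d) rep(100, length(d))
  expect_equal(delta_t_over_c(make_two_arm(grow, flat), 14), 0,
               tolerance = 1e-9)

  shrink <- function(d) 100 * exp(-0.1 * d)
  expect_lt(delta_t_over_c(make_two_arm(grow, shrink), 14), 0)

  # non-growing control: undefined with a diagnostic
  expect_error(delta_t_over_c(make_two_arm(flat, grow), 14),
               "control arm did not grow")
})

test_that("TGI bands split at 0 and 50 with closed partial band", {
  expect_equal(classify_tgi(c(-10, -0.001, 0, 25, 50, 50.001, 75)),
               c("response", "response", "partial", "partial", "partial",
                 "none", "none"))
})

test_that("response statistics handle both modes", {
  # monotone shrink to -97%
  days <- c(0, 3, 7, 10, 14)
  vols <- 100 * c(1, 0.8, 0.5, 0.2, 0.03)
  st <- response_statistics(days, vols, mode = "minimum")
  expect_equal(st$best_response, -97)
  expect_lt(st$best_avg_response, -40)
  st2 <- response_statistics(days, vols, mode = "last_day")
  expect_equal(st2$best_response, -97)
  expect_equal(st2$best_avg_response, -97)

  # flat curve
  fl <- response_statistics(c(0, 3, 7), c(50, 50, 50))
  expect_equal(c(fl$best_response, fl$best_avg_response), c(0, 0))

  # monotone doubling: best response is the first post-baseline change
  dbl <- response_statistics(c(0, 3, 7, 10), c(100, 130, 170, 220))
  expect_equal(dbl$best_response, 30)
  expect_equal(dbl$best_avg_response, 30) # running mean is increasing

  expect_error(response_statistics(c(3, 7), c(1, 2)), "day-0")
})

test_that("mRECIST categories follow the printed thresholds in order", {
  expect_equal(mrecist_classify(-97, -45), "CR")
  expect_equal(mrecist_classify(0, 0), "SD")
  expect_equal(mrecist_classify(40, 50), "PD")
  # the category function is total and single-valued on a grid
  grid <- expand.grid(best = c(-100, -96, -95, -60, -51, -50, -10, 0, 34,
                               35, 100),
                      avg = c(-50, -41, -40, -25, -21, -20, 0, 29, 30, 50))
  cats <- mrecist_classify(grid$best, grid$avg)
  expect_true(all(cats %in% c("CR", "PR", "SD", "PD")))
  expect_equal(length(cats), nrow(grid))
  # monotone: improving either statistic never moves the label toward PD
  rank <- c(CR = 1, PR = 2, SD = 3, PD = 4)
  for (i in seq_len(nrow(grid))) {
    better <- mrecist_classify(grid$best[i] - 10, grid$avg[i] - 10)
    expect_lte(rank[better], rank[cats[i]])
  }
})

test_that("ethical censoring truncates the whole study at the cap", {
  grow <- function(d) 400 * exp(0.12 * d)
  slow <- function(d) 100 * exp(0.01 * d)
  st <- make_two_arm(grow, slow, days = c(0, 3, 7, 10, 14, 17, 21))
  cens <- apply_ethical_censoring(st, cap_mm3 = 1500)
  # control passes 1500 between day 10 (1328) and day 14 (2146)
  expect_equal(cens$stop_day, 14)
  expect_equal(max(cens$study$day), 14)
  expect_equal(max(cens$study$day[cens$study$arm == "treated"]), 14)

  unch <- apply_ethical_censoring(st, cap_mm3 = 1e9)
  expect_true(is.na(unch$stop_day))
  expect_equal(nrow(unch$study), nrow(st))

  zero <- apply_ethical_censoring(st, cap_mm3 = 0)
  expect_equal(zero$stop_day, 0)
  expect_true(all(zero$study$day == 0))
})

test_that("noise-free stasis gives deltaT/deltaC 0 and SD for all treated", {
  d <- growth_study_design(n_per_arm = 5, growth_rate = 0.08,
                           treatment_effect = 0, noise_cv = 0,
                           max_day = 28, seed = 13)
  res <- analyze_growth_study(gen_growth_study(d))
  expect_equal(res$per_arm$dtc, 0, tolerance = 1e-9)
  expect_equal(res$per_arm$tgi_band, "partial") # 0 sits in the 0-50 band
  treated <- res$per_animal[res$per_animal$arm == "treated", ]
  expect_true(all(treated$mrecist == "SD"))
  expect_true(all(res$per_animal$best_response[res$per_animal$arm ==
                                                 "treated"] == 0))
})

test_that("growth studies round-trip and analyze end to end", {
  d <- growth_study_design(n_per_arm = 4, growth_rate = 0.1,
                           treatment_effect = -0.4, noise_cv = 0.1,
                           seed = 21)
  st <- gen_growth_study(d)
  path <- tempfile(fileext = ".csv")
  write_growth_study(st, path)
  back <- read_growth_study(path)
  expect_equal(back$length_mm, st$length_mm, tolerance = 1e-9)

  res <- analyze_growth_study(back)
  expect_lt(res$per_arm$dtc, 0) # regressing arm
  expect_equal(res$per_arm$tgi_band, "response")
  expect_true(all(res$per_animal$mrecist[res$per_animal$arm == "treated"]
                  %in% c("CR", "PR", "SD")))
})
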