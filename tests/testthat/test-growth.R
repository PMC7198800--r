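make_run <- function(values_by_well, times = seq(0, 12, by = 0.5)) {
  do.call(rbind, lapply(names(values_by_well), function(w)
    data.frame(plate_id = "p1", well = w, replicate = 1,
               substrate_id = w, time_h = times,
               value = values_by_well[[w]])))
}

test_that("background subtraction removes the control series", {
  tt <- seq(0, 12, by = 0.5)
  ctrl <- 0.02 + 0.001 * tt
  run <- make_run(list(A1 = ctrl, B1 = ctrl, C1 = ctrl + 0.2))
  out <- subtract_background(run)
  expect_equal(out$value[out$well == "B1"], rep(0, length(tt)))
  expect_equal(out$value[out$well == "C1"], rep(0.2, length(tt)))
  expect_equal(out$value[out$well == "A1"], ctrl)   # control retained

  zero <- make_run(list(A1 = rep(0, length(tt)), B1 = ctrl))
  expect_equal(subtract_background(zero)$value[zero$well == "B1"],
               ctrl)

  bad <- rbind(make_run(list(A1 = ctrl)),
               data.frame(plate_id = "p1", well = "B1", replicate = 1,
                          substrate_id = "B1", time_h = tt + 0.1,
                          value = ctrl))
  expect_error(subtract_background(bad), "time grid")
  expect_error(subtract_background(make_run(list(B1 = ctrl))),
               "control well")
})

test_that("logistic fitting inverts noiseless curves", {
  tt <- seq(0, 72, by = 1 / 6)
  v <- 0.5 / (1 + ((0.5 - 0.05) / 0.05) * exp(-0.3 * tt))
  f <- fit_logistic(tt, v)
  expect_true(f$converged)
  expect_equal(f$K, 0.5, tolerance = 1e-3)
  expect_equal(f$r, 0.3, tolerance = 1e-3)
  expect_equal(f$N0, 0.05, tolerance = 1e-3)
  # analytic AUC of the fitted curve matches numerical integration
  num <- stats::integrate(function(x)
    f$K / (1 + ((f$K - f$N0) / f$N0) * exp(-f$r * x)), 0, 72)$value
  expect_equal(f$auc, num, tolerance = 1e-6)
})

test_that("noisy fits recover the carrying capacity", {
  tt <- seq(0, 72, by = 1 / 6)
  v <- withr::with_seed(1,
    0.5 / (1 + ((0.5 - 0.05) / 0.05) * exp(-0.3 * tt)) +
      stats::rnorm(length(tt), 0, 0.01))
  f <- fit_logistic(tt, v)
  expect_true(f$converged)
  expect_lt(abs(f$K - 0.5), 0.05)
})

test_that("degenerate series are flagged, short series rejected", {
  tt <- seq(0, 12, by = 0.5)
  f <- fit_logistic(tt, rep(0.02, length(tt)))
  expect_false(f$converged)
  expect_equal(f$K, 0.02)
  expect_equal(f$r, 0)
  expect_error(fit_logistic(1:5, rep(1, 5)), "at least 10")
  expect_error(fit_logistic(tt, rep(1, 3)), "match time")
  expect_error(fit_logistic(c(1, 1, 2:10), rnorm(11)),
               "strictly increasing")
})

test_that("growth calls follow the 2-of-3 carrying-capacity rule", {
  expect_true(call_growth(c(0.15, 0.12, 0.05)))
  expect_false(call_growth(c(0.15, 0.05, 0.05)))
  expect_false(call_growth(c(0, 0, 0)))
  # threshold is strict and order does not matter
  expect_false(call_growth(c(0.1, 0.1, 0.1)))
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1)))
    expect_true(call_growth(c(0.15, 0.12, 0.05)[perm]))
})

test_that("intensity scoring maps ranked z-scores onto quartiles 1-4", {
  subs <- paste0("s", 1:8)
  auc <- expand.grid(substrate = subs, replicate = 1:3,
                     stringsAsFactors = FALSE)
  auc$strain <- "st1"
  auc$auc <- rep(seq(1, 8), times = 3)   # strictly increasing wells
  calls <- data.frame(strain = "st1", substrate = subs, call = TRUE)
  gm <- score_intensities(auc, calls)
  expect_identical(gm$intensity[match(subs, gm$substrate)],
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  # z-scored replicate AUCs have mean 0 and unit sd per strain
  z <- (seq(1, 8) - mean(seq(1, 8))) / sd(seq(1, 8))
  expect_equal(gm$mean_z[match(subs, gm$substrate)], z,
               tolerance = 1e-9)
  expect_equal(mean(gm$mean_z), 0, tolerance = 1e-9)
  expect_equal(sd(gm$mean_z), 1, tolerance = 1e-9)
  # intensity is monotone in the averaged z-score
  ord <- order(gm$mean_z)
  expect_true(all(diff(gm$intensity[ord]) >= 0))
})

test_that("non-growth wells score zero; degenerate and small inputs guarded", {
  subs <- paste0("s", 1:5)
  auc <- expand.grid(substrate = subs, replicate = 1:3,
                     stringsAsFactors = FALSE)
  auc$strain <- "st1"
  auc$auc <- rep(c(4, 5, 6, 7, 1), times = 3)
  calls <- data.frame(strain = "st1", substrate = subs,
                      call = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  gm <- score_intensities(auc, calls)
  expect_equal(gm$intensity[gm$substrate == "s5"], 0)
  expect_true(all(gm$intensity[gm$call] >= 1))

  auc$auc <- 2
  expect_warning(gm2 <- score_intensities(auc, calls), "constant")
  expect_true(all(gm2$intensity[gm2$call] == 1))

  calls$call <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_error(score_intensities(auc, calls), "fewer than 4")
})

test_that("excluded substrates are dropped before scoring", {
  subs <- paste0("s", 1:9)
  auc <- expand.grid(substrate = subs, replicate = 1:3,
                     stringsAsFactors = FALSE)
  auc$strain <- "st1"
  auc$auc <- rep(1:9, times = 3)
  calls <- data.frame(strain = "st1", substrate = subs, call = TRUE)
  gm <- score_intensities(auc, calls, exclude = "s9")
  expect_false("s9" %in% gm$substrate)
  expect_identical(gm$intensity[match(paste0("s", 1:8),
                                      gm$substrate)],
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
})
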