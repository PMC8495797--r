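test_that("rank-based AUC equals the exhaustive pairwise oracle", {
  set.seed(11)
  for (case in 1:100) {
    n <- sample(5:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(compute_auc(scores, labels), auc_bruteforce(scores, labels))
  }
})

test_that("AUC endpoints and error cases behave as defined", {
  expect_equal(compute_auc(1:10, rep(c(FALSE, TRUE), each = 5)), 1.0)
  expect_equal(compute_auc(10:1, rep(c(FALSE, TRUE), each = 5)), 0.0)
  set.seed(4)
  s <- runif(10000); l <- runif(10000) < 0.5
  expect_lt(abs(compute_auc(s, l) - 0.5), 0.02)
  expect_error(compute_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("rank-based AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  s <- c(runif(300), runif(200, 0.3, 1.3))
  l <- rep(c(FALSE, TRUE), c(300, 200))
  expect_equal(compute_auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))))
})

test_that("Monte-Carlo CV is seeded, reproducible and well-calibrated on null data", {
  null <- sim_presence_tows(3000, params = NULL, prevalence = 0.3, seed = 5)
  cv1 <- monte_carlo_cv(null$temp, null$presence, n_iter = 20, seed = 9)
  cv2 <- monte_carlo_cv(null$temp, null$presence, n_iter = 20, seed = 9)
  expect_identical(cv1$auc, cv2$auc)
  expect_identical(length(cv1$auc), 20L)
  expect_identical(cv1$n_train, round(0.75 * 3000))
  expect_gt(mean(cv1$auc), 0.45)
  expect_lt(mean(cv1$auc), 0.55)
})

test_that("year-block CV builds the exact rolling-window structure", {
  d <- sim_presence_tows(4000, dome_params(0.5), years = 1985:2015, seed = 2)
  cv <- year_block_cv(d$temp, d$presence, d$year, block_years = 7)
  expect_identical(nrow(cv$blocks), 25L)
  expect_identical(cv$blocks$start[1], 1985L)
  expect_identical(cv$blocks$end[1], 1991L)
  expect_identical(cv$blocks$start[25], 2009L)
  expect_identical(cv$blocks$end[25], 2015L)
  expect_true(all(cv$auc > 0.5, na.rm = TRUE))
})

test_that("rolling windows cover every year with the right multiplicity", {
  # identity holds for any span >= block + 1
  for (span in c(8, 12, 31)) {
    years <- 1985:(1984 + span)
    starts <- years[1]:(years[span] - 6)
    covered <- unlist(lapply(starts, function(s) s:(s + 6)))
    expect_setequal(unique(covered), years)
    counts <- table(covered)
    interior <- years[years >= years[1] + 6 & years <= years[span] - 6]
    expect_true(all(counts[as.character(interior)] == 7))
  }
  d <- sim_presence_tows(500, dome_params(0.5), years = 1990:1996, seed = 3)
  expect_error(year_block_cv(d$temp, d$presence, d$year, block_years = 7),
               "distinct years")
})

test_that("block CV AUCs overlap the random-CV range on stationary data", {
  d <- sim_presence_tows(6000, dome_params(0.5), years = 1985:2015, seed = 17)
  mc <- monte_carlo_cv(d$temp, d$presence, n_iter = 25, seed = 17)
  yb <- year_block_cv(d$temp, d$presence, d$year)
  # with no temporal structure the two schemes estimate the same skill
  expect_lt(abs(mean(yb$auc, na.rm = TRUE) - mean(mc$auc)), 0.05)
  expect_true(all(yb$auc > 0.5, na.rm = TRUE))
})

test_that("cross-survey AUC matrix: diagonal equals within-survey AUC, rows are deterministic", {
  params <- dome_params(p_max = 0.8)
  wide <- sim_presence_tows(4000, params, seed = 41)
  narrow <- sim_presence_tows(4000, params, temp_range = c(15, 20), seed = 42)
  curves <- list(
    wide = fit_presence_curve(wide$temp, wide$presence),
    narrow = fit_presence_curve(narrow$temp, narrow$presence))
  datasets <- list(wide = wide, narrow = narrow, wide2 = wide)
  m <- cross_survey_auc(curves, datasets)
  expect_equal(m["wide", "wide"],
               compute_auc(predict(curves$wide, wide$temp, "response"),
                           wide$presence))
  # identical datasets give identical columns
  expect_identical(m[, "wide"], m[, "wide2"])
  # the narrow-window curve transfers worse to wide-range data
  expect_lt(m["narrow", "wide"], m["wide", "wide"])
})

test_that("quality ranks follow the decile binning convention", {
  expect_identical(rank_bin(0.05), 1L)
  expect_identical(rank_bin(0.95), 10L)
  expect_identical(rank_bin(1.0), 10L)
  expect_identical(rank_bin(0.1), 2L)
  expect_identical(rank_bin(0), 1L)
  expect_identical(rank_bin(c(0.25, 0.85)), c(3L, 9L))
  expect_error(rank_bin(1.2), "\\[0, 1\\]")
  expect_error(rank_bin(-0.1), "\\[0, 1\\]")
})

test_that("quality-ranking CV conserves tows and is reproducible", {
  params <- dome_params(p_max = 0.8)
  train <- sim_presence_tows(2000, params, seed = 51)
  test <- sim_presence_tows(1500, params, seed = 52)
  qr1 <- quality_ranking_cv(train, test, n_iter = 5, seed = 3)
  qr2 <- quality_ranking_cv(train, test, n_iter = 5, seed = 3)
  expect_identical(qr1$n, qr2$n)
  expect_identical(qr1$n_present, qr2$n_present)
  expect_identical(sum(qr1$n), 1500L * 5L)
  expect_true(all(qr1$proportion >= 0 & qr1$proportion <= 1, na.rm = TRUE))
  # empty ranks report NA proportion, not zero
  if (any(qr1$n == 0)) expect_true(all(is.na(qr1$proportion[qr1$n == 0])))

  # same-source: held-out 25% scored each iteration
  qr3 <- quality_ranking_cv(train, test = NULL, n_iter = 4, seed = 3)
  expect_equal(sum(qr3$n), 4 * (2000 - round(0.75 * 2000)))
})

test_that("presence rises with habitat quality rank for a well-specified model", {
  params <- dome_params(p_max = 0.8)
  train <- sim_presence_tows(3000, params, seed = 61)
  test <- sim_presence_tows(8000, params, seed = 62)
  qr <- quality_ranking_cv(train, test, n_iter = 20, seed = 7)
  ok <- !is.na(qr$proportion)
  rho <- cor(qr$rank[ok], qr$proportion[ok], method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("a lab optimum warmer than sampled water leaves top ranks sparse", {
  lab <- gen_lab_scope(t_opt_lab = 28, n_per_temp = 12, seed = 9,
                       temps = c(12, 16.5, 21, 25.5, 30))
  # test tows sample cool shelf water only (5-20 C)
  test <- sim_presence_tows(4000, dome_params(0.8), temp_range = c(5, 20),
                            seed = 71)
  qr <- quality_ranking_cv(lab, test, n_iter = 10, seed = 11)
  # tows never reach temperatures near the lab optimum, so the top decile
  # collects far fewer tows than the mid deciles
  expect_lt(qr$n[10], 0.2 * max(qr$n))
})
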