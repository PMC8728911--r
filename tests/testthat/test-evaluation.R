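test_that("absolute_error equals the brute-force shift minimum on the integer grid", {
  expect_equal(absolute_error(0, 0), 0)
  expect_equal(absolute_error(90, -90), 180)
  expect_equal(absolute_error(179, -179), 2)
  grid <- -180:180
  pm <- matrix(rep(grid, times = 361), 361, 361)
  am <- t(pm)
  got <- absolute_error(as.numeric(pm), as.numeric(am))
  want <- pmin(abs(pm - am), abs(pm - am + 360), abs(pm - am - 360))
  expect_equal(got, as.numeric(want))
  expect_true(all(got >= 0 & got <= 180))
})

test_that("improvement reproduces the published comparison arithmetic", {
  expect_equal(improvement(8.73, c(9.00, 11.99)), 3.09, tolerance = 0.002)
  expect_equal(improvement(16.48, c(15.93, 16.43, 17.22)), -3.34,
               tolerance = 0.002)
  expect_equal(improvement(5, c(5, 7)), 0)
  expect_error(improvement(5, numeric(0)), "empty")
})

test_that("delta_percent reproduces the published relative-difference arithmetic", {
  expect_equal(delta_percent(16.30, 15.59), 4.55, tolerance = 0.002)
  expect_equal(delta_percent(7, 7), 0)
  expect_equal(delta_percent(10, 5), 100)
})

test_that("spearman_rho matches the rank-then-Pearson oracle, including ties", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, rev(1:10)), -1)
  set.seed(51)
  for (k in 1:20) {
    x <- sample(1:5, 30, replace = TRUE)  # heavy ties
    y <- x + rnorm(30)
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-9)
  }
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_error(spearman_rho(1, 1), "at least 2")
})

test_that("per-stratum MAE recombines into the overall MAE by residue weights", {
  ds <- small_dataset()
  b <- small_bundle()
  p <- ds$test[[1]]
  pred <- predict_angles(b, p)
  actual <- p$angles
  ss3 <- map_ss8_to_ss3(p$ss8_true)
  overall <- mae_angle(pred, actual, "psi")
  parts <- lapply(SS3_CLASSES, function(cl)
    mae_angle(pred, actual, "psi", stratum = ss3 == cl))
  counts <- vapply(parts, `[[`, 0L, "count")
  maes <- vapply(parts, `[[`, 0, "mae")
  expect_equal(sum(counts), overall$count)
  expect_equal(sum(maes[counts > 0] * counts[counts > 0]) / sum(counts),
               overall$mae, tolerance = 1e-9)
  # pred == actual gives 0 in every stratum
  same <- mae_angle(actual, actual, "psi")
  expect_equal(same$mae, 0)
  # empty stratum is absent (NA), not zero
  empty <- mae_angle(pred, actual, "psi", stratum = rep(FALSE, nrow(pred)))
  expect_true(is.na(empty$mae))
  expect_equal(empty$count, 0L)
})

test_that("threshold-coverage curves follow the per-protein counting rule", {
  perfect <- list(a = rep(0, 10), b = rep(0, 20))
  cv <- threshold_coverage(perfect)
  expect_true(all(cv$pct_proteins == 100))
  terrible <- list(a = rep(100, 10), b = rep(100, 5))
  cv2 <- threshold_coverage(terrible)
  expect_equal(cv2$pct_proteins[cv2$pct_angles == 0], c(100, 100))
  expect_true(all(cv2$pct_proteins[cv2$pct_angles > 0] == 0))
  # seeded case equals a direct counting oracle
  set.seed(52)
  aes <- lapply(1:15, function(i) runif(sample(20:40, 1), 0, 30))
  cv3 <- threshold_coverage(aes)
  for (t in c(6, 12))
    for (x in seq(0, 100, 10)) {
      frac <- vapply(aes, function(v) 100 * mean(v <= t), 0)
      want <- 100 * mean(frac >= x)
      expect_equal(cv3$pct_proteins[cv3$threshold == t & cv3$pct_angles == x],
                   want)
    }
  # monotonicity: non-increasing in x, non-decreasing in threshold
  for (t in c(6, 12))
    expect_true(all(diff(cv3$pct_proteins[cv3$threshold == t]) <= 0))
  expect_true(all(cv3$pct_proteins[cv3$threshold == 12] >=
                    cv3$pct_proteins[cv3$threshold == 6]))
})

test_that("length-group report bins proteins and recombines to the overall MAE", {
  ds <- small_dataset()
  b <- small_bundle()
  prot <- ds$test
  preds <- predict_angles_set(b, prot)
  actual <- lapply(prot, function(p) p$angles)
  rep <- length_group_report(preds, actual)
  expect_equal(rep$group[nrow(rep)], "Overall")
  expect_equal(sum(rep$count[-nrow(rep)]), length(prot))
  # lengths 40-70 all land in the first bin
  expect_equal(rep$group[1], "001-100")
  # per-bin MAE equals filtered flat recomputation
  flat <- unlist(lapply(seq_along(preds), function(i) {
    p <- preds[[i]][["phi"]]; a <- actual[[i]][["phi"]]
    k <- !is.na(p) & !is.na(a)
    absolute_error(p[k], a[k])
  }))
  expect_equal(rep$mae_phi[nrow(rep)], mean(flat), tolerance = 1e-12)
})

test_that("evaluate_predictions assembles a coherent report", {
  ds <- small_dataset()
  b <- small_bundle()
  prot <- ds$test
  preds <- predict_angles_set(b, prot)
  actual <- lapply(prot, function(p) p$angles)
  ss3 <- lapply(prot, function(p) map_ss8_to_ss3(p$ss8_true))
  rep <- evaluate_predictions(preds, actual, ss3)
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep$overall), 4L)
  expect_true(all(rep$overall$mae >= 0 & rep$overall$mae <= 180))
  expect_true(all(abs(rep$overall$spearman) <= 1, na.rm = TRUE))
  # class counts sum to the overall defined count per angle
  for (ang in c("phi", "psi", "theta", "tau")) {
    cls <- rep$by_class[rep$by_class$angle == ang, ]
    expect_equal(sum(cls$count), rep$overall$count[rep$overall$angle == ang])
  }
  dir <- withr::local_tempdir()
  write_eval_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("overall.tsv", "by_class.tsv",
                                               "coverage.tsv",
                                               "length_groups.tsv")))))
})
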