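test_that("periodic MAE loss handles wrap-around and exclusion flags", {
  expect_equal(periodic_mae_loss(c(10, 20), c(10, 20)), 0)
  expect_equal(periodic_mae_loss(179, -179), 2)
  set.seed(41)
  p <- runif(300, -180, 180)
  a <- runif(300, -180, 180)
  brute <- mean(vapply(seq_along(p), function(i) oracle_ae(p[i], a[i]), 0))
  expect_equal(periodic_mae_loss(p, a), brute, tolerance = 1e-9)
  # flagged-out entries are excluded
  d <- c(TRUE, FALSE, TRUE)
  expect_equal(periodic_mae_loss(c(0, 90, 10), c(0, 0, 10), d), 0)
  expect_error(periodic_mae_loss(1, 2, FALSE), "no defined")
  # symmetry, boundedness, shift invariance
  expect_equal(periodic_mae_loss(p, a), periodic_mae_loss(a, p))
  expect_true(periodic_mae_loss(p, a) <= 180)
  expect_equal(periodic_mae_loss(p + 720, a), periodic_mae_loss(p, a),
               tolerance = 1e-9)
})

test_that("the network can fit a constant target", {
  set.seed(42)
  x <- matrix(runif(200 * 10), 200, 10)
  y <- rep(42, 200)
  fit <- train_model(x[1:150, ], y[1:150], x[151:200, ], y[151:200],
                     config = fcnn_config(10L, hidden = c(20L, 20L, 20L)),
                     schedule = training_schedule(max_epochs = 120, seed = 2,
                                                  batch_size = 32))
  expect_lt(fit$best_loss, 0.5)
})

test_that("training is bit-reproducible under a fixed seed", {
  set.seed(43)
  x <- matrix(runif(300 * 8), 300, 8)
  y <- wrap_angle(360 * x[, 1] - 180 + 10 * x[, 2])
  sch <- training_schedule(max_epochs = 12, seed = 9, batch_size = 64)
  f1 <- train_model(x[1:250, ], y[1:250], x[251:300, ], y[251:300],
                    config = fcnn_config(8L, c(15L, 15L, 15L)), schedule = sch)
  f2 <- train_model(x[1:250, ], y[1:250], x[251:300, ], y[251:300],
                    config = fcnn_config(8L, c(15L, 15L, 15L)), schedule = sch)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$par, f2$par)
})

test_that("the learning-rate trace halves after stagnation and never rises", {
  set.seed(44)
  x <- matrix(runif(200 * 6), 200, 6)
  y <- runif(200, -180, 180)
  fit <- train_model(x[1:150, ], y[1:150], x[151:200, ], y[151:200],
                     config = fcnn_config(6L, c(10L, 10L, 10L)),
                     schedule = training_schedule(max_epochs = 150, seed = 3,
                                                  batch_size = 50))
  lr <- fit$history$lr
  expect_true(all(diff(lr) <= 0))
  # each decrease is exactly x0.5
  changed <- which(diff(lr) < 0)
  expect_gt(length(changed), 0L)
  expect_equal(lr[changed + 1] / lr[changed], rep(0.5, length(changed)))
  expect_true(all(lr >= 1e-15))
  # halving happens only after >= patience consecutive non-improving epochs
  mon <- fit$history$val_loss
  for (j in changed) {
    if (j < 4) next
    window <- mon[(j - 2):j]
    best_before <- min(mon[1:(j - 3)])
    expect_true(all(window >= best_before))
  }
})

test_that("a trained bundle has one model per (class, angle) slot", {
  b <- small_bundle()
  expect_s3_class(b, "model_bundle")
  expect_equal(length(b$models), 12L)
  expect_setequal(names(b$models),
                  as.vector(outer(SS3_CLASSES, c("phi", "psi", "theta", "tau"),
                                  paste, sep = ".")))
  # settings follow the shipped defaults
  ds <- default_settings()
  for (i in seq_len(nrow(ds))) {
    key <- paste(ds$class[i], ds$angle[i], sep = ".")
    expect_equal(b$models[[key]]$setting$name, ds$setting[i])
  }
  # input widths match each slot's setting
  for (m in b$models)
    expect_equal(m$fit$config$input_width,
                 ssbap:::ahiw_width(m$setting) * m$setting$window)
})

test_that("shipped default settings match the published best-setting table", {
  ds <- default_settings()
  get <- function(cl, ang) ds$setting[ds$class == cl & ds$angle == ang]
  for (ang in c("phi", "psi", "theta", "tau"))
    expect_equal(get("helix", ang), "YYR9")
  expect_equal(get("sheet", "psi"), "YYZ9")
  for (ang in c("phi", "theta", "tau"))
    expect_equal(get("sheet", ang), "YYR9")
  expect_equal(get("coil", "phi"), "YYR5")
  expect_equal(get("coil", "theta"), "YYR5")
  expect_equal(get("coil", "psi"), "YYR9")
  expect_equal(get("coil", "tau"), "YYR9")
})

test_that("inference routes each residue to its predicted class's models only", {
  ds <- small_dataset()
  b <- small_bundle()
  p <- ds$test[[1]]
  pred <- predict_angles(b, p)
  used <- attr(pred, "models_used")
  ss3 <- map_ss8_to_ss3(p$ss8_pred)
  present <- unique(ss3)
  for (cl in SS3_CLASSES) {
    keys <- paste(cl, c("phi", "psi", "theta", "tau"), sep = ".")
    if (cl %in% present) {
      expect_equal(unname(used[keys]), rep(sum(ss3 == cl), 4L))
    } else {
      expect_false(any(keys %in% names(used)))
    }
  }
  # an all-helix protein consults helix models only
  ph <- p
  ph$ss8_pred <- rep("H", nchar(p$sequence))
  uh <- attr(predict_angles(b, ph), "models_used")
  expect_true(all(grepl("^helix\\.", names(uh))))
})

test_that("per-residue predictions equal direct invocation of the routed model", {
  ds <- small_dataset()
  b <- small_bundle()
  p <- ds$test[[2]]
  pred <- predict_angles(b, p)
  ss3 <- map_ss8_to_ss3(p$ss8_pred)
  i <- 5L
  m <- b$models[[paste(ss3[i], "phi", sep = ".")]]
  enc <- encode_proteins(p, m$setting)
  x <- apply_normalization(enc$x[i, , drop = FALSE], m$stats)
  expect_equal(pred$phi[i], wrap_angle(predict(m$fit, x)))
})

test_that("predictions obey the wrap and clamp output contracts", {
  ds <- small_dataset()
  b <- small_bundle()
  pred <- predict_angles(b, ds$test[[1]])
  n <- nrow(pred)
  for (col in c("phi", "psi", "tau")) {
    v <- pred[[col]][!is.na(pred[[col]])]
    expect_true(all(v > -180 & v <= 180))
  }
  th <- pred$theta[!is.na(pred$theta)]
  expect_true(all(th >= 0 & th <= 180))
  expect_true(is.na(pred$phi[1]))
  expect_true(is.na(pred$psi[n]))
  expect_true(all(is.na(pred$tau[c(1, n - 1, n)])))
})

test_that("an absent class yields an explicit empty-class error", {
  ds <- small_dataset()
  all_helix <- lapply(ds$train[1:2], function(p) {
    p$ss8_true <- rep("H", nchar(p$sequence))
    p$ss8_pred <- p$ss8_true
    p
  })
  expect_error(
    train_bundle(all_helix, all_helix,
                 schedule = training_schedule(max_epochs = 1)),
    "empty training class 'sheet'")
})

test_that("bundles reload from JSON with identical predictions", {
  ds <- small_dataset()
  b <- small_bundle()
  path <- withr::local_tempfile(fileext = ".json")
  save_bundle(b, path)
  b2 <- load_bundle(path)
  p <- ds$test[[1]]
  pr1 <- predict_angles(b, p)
  pr2 <- predict_angles(b2, p)
  expect_identical(pr1$phi, pr2$phi)
  expect_identical(pr1$tau, pr2$tau)
})
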