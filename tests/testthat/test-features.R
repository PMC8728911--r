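test_that("one-hot encoding follows the declared 8-state order", {
  expect_equal(unname(one_hot_ss8("H")), c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(one_hot_ss8("C")), c(0, 0, 0, 0, 0, 0, 0, 1))
  m <- one_hot_ss8(SS8_ALPHABET)
  expect_equal(rowSums(m), rep(1, 8))
  expect_equal(unname(m), diag(8))  # mutually orthogonal, position = index
  for (s in SS8_ALPHABET)
    expect_equal(which(one_hot_ss8(s) == 1), match(s, SS8_ALPHABET),
                 ignore_attr = TRUE)
  expect_error(one_hot_ss8("X"), "HGIEBTSC")
})

test_that("the physicochemical constants table is 20 x 7 and deterministic", {
  tab <- pcp7_table()
  expect_equal(dim(tab), c(20L, 7L))
  expect_setequal(rownames(tab), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_identical(tab, pcp7_table())
})

test_that("setting names parse to their four configuration axes", {
  s <- parse_ahiw("YNR5")
  expect_true(s$use_asa)
  expect_false(s$use_hmm)
  expect_equal(s$encoding, "range")
  expect_equal(s$window, 5L)
  expect_equal(parse_ahiw("YYZ9")$encoding, "zscore")
  expect_error(parse_ahiw("YYX9"), "invalid setting")
  expect_error(parse_ahiw("YY9"), "4 characters")
})

test_that("feature assembly yields the block widths of each setting", {
  n <- 5L
  set.seed(31)
  ss8 <- sample(SS8_ALPHABET, n, replace = TRUE)
  pssm <- matrix(rnorm(n * 20), n, 20)
  hmm <- matrix(runif(n * 20), n, 20)
  asa <- runif(n, 0, 100)
  seqv <- "ACDEF"
  full <- assemble_residue_features(ss8, pssm, hmm = hmm, asa = asa,
                                    setting = "YYR9", sequence = seqv)
  expect_equal(ncol(full), 56L)
  expect_equal(ncol(assemble_residue_features(ss8, pssm, setting = "NNR5",
                                              sequence = seqv)), 35L)
  expect_equal(ncol(assemble_residue_features(ss8, pssm, asa = asa,
                                              setting = "YNR5",
                                              sequence = seqv)), 36L)
  # fixed block order: ss8, pssm, pcp7, hmm, asa
  expect_equal(full[, 1:8], one_hot_ss8(ss8), ignore_attr = TRUE)
  expect_equal(full[, 9:28], pssm, ignore_attr = TRUE)
  expect_equal(full[, 29:35], pcp7_table()[strsplit(seqv, "")[[1]], ],
               ignore_attr = TRUE)
  expect_equal(full[, 36:55], hmm, ignore_attr = TRUE)
  expect_equal(full[, 56], asa, ignore_attr = TRUE)
  expect_error(assemble_residue_features(ss8, pssm, setting = "YYR9",
                                         sequence = seqv), "hmm")
  expect_error(assemble_residue_features(ss8, pssm, hmm = hmm,
                                         setting = "YYR9", sequence = seqv),
               "asa")
})

test_that("window encoding concatenates neighbours and zero-pads overhangs", {
  set.seed(32)
  n <- 7L
  p <- 56L
  f <- matrix(rnorm(n * p), n, p)
  w9 <- window_encode(f, 9L)
  expect_equal(dim(w9), c(n, 504L))
  w5 <- window_encode(f, 5L)
  # interior row = manual concatenation of the 5 neighbour vectors
  expect_equal(w5[4, ], as.numeric(t(f[2:6, ])), ignore_attr = TRUE)
  # terminal overhangs are zero blocks exactly
  expect_equal(w5[1, 1:(2 * p)], rep(0, 2 * p), ignore_attr = TRUE)
  expect_equal(w5[1, (2 * p + 1):(3 * p)], f[1, ], ignore_attr = TRUE)
  one <- window_encode(f[1, , drop = FALSE], 5L)
  expect_equal(one[1, ], c(rep(0, 2 * p), f[1, ], rep(0, 2 * p)),
               ignore_attr = TRUE)
  # row count preserved for all lengths
  for (L in c(1L, 2L, 5L))
    expect_equal(nrow(window_encode(f[seq_len(L), , drop = FALSE], 9L)), L)
  expect_error(window_encode(f, 4L), "odd")
})

test_that("range normalization maps training extremes to 0/1 without clipping", {
  x <- cbind(a = c(2, 4, 3), b = c(5, 5, 5))
  st <- fit_normalization(x, "range")
  expect_equal(unname(st$min), c(2, 5))
  expect_equal(unname(st$max), c(4, 5))
  tx <- apply_normalization(x, st)
  expect_equal(tx[, 1], c(0, 1, 0.5), ignore_attr = TRUE)
  expect_equal(tx[, 2], c(0, 0, 0), ignore_attr = TRUE)  # constant -> 0
  # test-set values outside the training range are not clipped
  out <- apply_normalization(cbind(a = c(0, 6), b = c(1, 2)), st)
  expect_equal(out[, 1], c(-1, 2), ignore_attr = TRUE)
})

test_that("zscore normalization standardises training columns (population sd)", {
  x <- cbind(a = c(2, 4), b = c(1, 1))
  st <- fit_normalization(x, "zscore")
  expect_equal(unname(st$mu), c(3, 1))
  expect_equal(unname(st$sigma), c(1, 0))  # population convention
  set.seed(33)
  big <- matrix(rnorm(600, mean = 5, sd = 3), 100, 6)
  st2 <- fit_normalization(big, "zscore")
  tb <- apply_normalization(big, st2)
  expect_equal(colMeans(tb), rep(0, 6), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(apply(tb, 2, function(v) sqrt(mean((v - mean(v))^2))),
               rep(1, 6), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(apply_normalization(big[, 1:3], st2), "layout mismatch")
})

test_that("feature encoding is deterministic for identical inputs", {
  ds <- small_dataset()
  f1 <- encode_proteins(ds$train[1:3], "YYR5")
  f2 <- encode_proteins(ds$train[1:3], "YYR5")
  expect_identical(f1$x, f2$x)
  expect_identical(f1$meta, f2$meta)
  expect_equal(ncol(f1$x), 56L * 5L)
  expect_equal(nrow(f1$x), sum(vapply(ds$train[1:3],
                                      function(p) nchar(p$sequence), 0L)))
})

test_that("profile files round-trip through their readers", {
  ds <- small_dataset()
  p <- ds$train[[1]]
  dir <- withr::local_tempdir()
  write_protein(p, dir)
  back <- read_protein(dir, p$id)
  expect_equal(back$sequence, p$sequence)
  expect_equal(back$ss8_true, p$ss8_true)
  expect_equal(back$ss8_pred, p$ss8_pred)
  expect_equal(back$pssm, p$pssm, tolerance = 1e-3)
  expect_equal(back$hmm, p$hmm, tolerance = 2e-3)
  expect_equal(back$asa, p$asa, tolerance = 1e-3)
  expect_equal(back$angles$phi, p$angles$phi, tolerance = 1e-5)
  # readers emit no warnings on generator output
  expect_no_warning(read_pssm(file.path(dir, paste0(p$id, ".pssm"))))
  expect_no_warning(read_hhm(file.path(dir, paste0(p$id, ".hhm"))))
  expect_no_warning(read_asa(file.path(dir, paste0(p$id, ".asa.tsv"))))
})
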