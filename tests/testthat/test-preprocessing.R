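test_that("common median re-reference zeroes the per-step median", {
  v <- rbind(c(1, 4), c(2, 5), c(10, 6))
  out <- rereference_common_median(v)
  expect_equal(out[, 1], c(-1, 0, 8))
  expect_equal(apply(out, 2, median), c(0, 0))
  # identical channels collapse to zero
  same <- matrix(3, 4, 5)
  expect_true(all(rereference_common_median(same) == 0))
  expect_warning(rereference_common_median(matrix(1, 1, 5)), "2 channels")
})

test_that("outlier-bin exclusion drops flagged bins and their neighbors", {
  set.seed(1)
  v <- matrix(rnorm(2 * 1000), 2, 1000)  # 10 bins of 100
  clean <- exclude_outlier_bins(v, bin = 100, thresh = 8)
  expect_true(all(clean$keep))
  expect_equal(ncol(clean$values), 1000)
  # one large spike in bin 5 removes bins 4-6
  v2 <- v
  v2[1, 450] <- 100
  ex <- exclude_outlier_bins(v2, bin = 100, thresh = 8)
  expect_equal(which(!ex$keep), 4:6)
  expect_equal(ncol(ex$values), 700)
  # spike in the first bin: no left neighbor to drop
  v3 <- v
  v3[2, 10] <- 100
  ex3 <- exclude_outlier_bins(v3, bin = 100, thresh = 8)
  expect_equal(which(!ex3$keep), 1:2)
  # everything flagged is an error
  v4 <- matrix(0, 1, 200)
  v4[1, c(50, 150)] <- 1e6
  expect_error(exclude_outlier_bins(v4, bin = 100, thresh = 8), "excluded")
})

test_that("linear normalization maps the reference range exactly", {
  expect_equal(normalize_linear(1000), 0.8)
  expect_equal(normalize_linear(-1000), -0.8)
  expect_equal(normalize_linear(0), 0)
  expect_equal(normalize_linear(-500), -0.4)
  # out-of-range values pass through the same affine map
  expect_equal(normalize_linear(2000), 1.6)
  # exact invertibility over the range
  x <- seq(-1000, 1000, by = 37)
  y <- normalize_linear(x)
  expect_equal(normalize_linear(y, in_range = c(-0.8, 0.8),
                                out_range = c(-1000, 1000)), x)
  expect_error(normalize_linear(1, in_range = c(1, 1)), "degenerate")
})

test_that("crossfade concatenation ramps linearly across the taper", {
  mk <- function(val, len) signal_sequence(matrix(val, 2, len), 1000,
                                           "awake", "I1", c("R1", "R1"))
  # complementary ramps: constant 1 + constant 1 stays 1
  cc <- crossfade_concat(mk(1, 100), mk(1, 100), taper_ms = 30)
  expect_equal(ncol(cc), 170)
  expect_true(all(abs(sequence_values(cc) - 1) < 1e-12))
  # 1 then 0: taper descends linearly from 1 to 0
  cc2 <- crossfade_concat(mk(1, 100), mk(0, 100), taper_ms = 30)
  seg <- sequence_values(cc2)[1, 71:100]
  expect_equal(seg, seq(1, 0, length.out = 30))
  # taper 0 is plain concatenation
  cc3 <- crossfade_concat(mk(1, 50), mk(0, 50), taper_ms = 0)
  expect_equal(ncol(cc3), 100)
  # self-crossfade reproduces the original values in the taper region
  set.seed(2)
  s <- signal_sequence(matrix(rnorm(2 * 60), 2, 60), 1000, "awake", "I1",
                       c("R1", "R1"))
  sc <- crossfade_concat(s, s, taper_ms = 10)
  expect_equal(sequence_values(sc)[, 51:60],
               sequence_values(s)[, 51:60] * seq(1, 0, length.out = 10)[
                 col(matrix(0, 2, 10))] +
                 sequence_values(s)[, 1:10] * seq(0, 1, length.out = 10)[
                   col(matrix(0, 2, 10))])
  expect_error(crossfade_concat(mk(1, 10), mk(1, 100), taper_ms = 30),
               "taper longer")
})

test_that("training-set assembly follows the sampling recipe", {
  mk_pool <- function(n, len, cond, ind)
    lapply(seq_len(n), function(i)
      signal_sequence(matrix(rnorm(2 * len), 2, len), 1000, cond, ind,
                      c("R1", "R1")))
  pools <- list()
  for (ind in c("I1", "I2", "I3"))
    pools[[ind]] <- list(awake = mk_pool(15, 20, "awake", ind),
                         anesthetized = mk_pool(15, 20, "anesthetized",
                                                ind))
  ds <- assemble_training_set(pools, n_per_condition = 12, seed = 4)
  expect_length(ds, 72)
  expect_equal(sum(vapply(ds, ncol, integer(1))), 72 * 20)
  # one individual, one per condition
  ds2 <- assemble_training_set(pools["I1"], n_per_condition = 1, seed = 1)
  expect_length(ds2, 2)
  # determinism
  ds3 <- assemble_training_set(pools, n_per_condition = 12, seed = 4)
  expect_identical(lapply(ds, c), lapply(ds3, c))
  expect_error(assemble_training_set(pools, n_per_condition = 99),
               "exhausted")
})

test_that("transition-set assembly crossfades the two conditions", {
  mk_pool <- function(n, len, cond, ind)
    lapply(seq_len(n), function(i)
      signal_sequence(matrix(rnorm(2 * len), 2, len), 1000, cond, ind,
                      c("R1", "R1")))
  pools <- list(I4 = list(awake = mk_pool(5, 400, "awake", "I4"),
                          anesthetized = mk_pool(5, 400, "anesthetized",
                                                 "I4")))
  ts <- assemble_transition_set(pools, n = 25, first = 250, second = 150,
                                taper_ms = 30, seed = 9)
  expect_length(ts, 50)
  expect_true(all(vapply(ts, ncol, integer(1)) == 250 + 150 - 30))
  expect_true(all(vapply(ts, attr, numeric(1), "switch_time") == 250))
  dirs <- vapply(ts, attr, character(1), "direction")
  expect_equal(as.integer(table(dirs)), c(25L, 25L))
  ts2 <- assemble_transition_set(pools, n = 25, first = 250, second = 150,
                                 taper_ms = 30, seed = 9)
  expect_identical(lapply(ts, c), lapply(ts2, c))
})

test_that("signal files round-trip with their metadata", {
  set.seed(6)
  s <- signal_sequence(matrix(rnorm(4 * 30), 4, 30), 1000, "anesthetized",
                       "I2", c("FP", "FP", "V1", "V1"))
  path <- file.path(tempdir(), "sig_test.tsv")
  write_signals(s, path)
  r <- read_signals(path)
  expect_equal(sequence_values(r), sequence_values(s), tolerance = 1e-8)
  expect_equal(attr(r, "sampling_rate"), 1000)
  expect_equal(attr(r, "condition"), "anesthetized")
  expect_equal(attr(r, "individual"), "I2")
  expect_equal(attr(r, "region_map"), c("FP", "FP", "V1", "V1"))
  # missing metadata is a named error
  file.remove(paste0(path, ".meta.yaml"))
  expect_error(read_signals(path), "sidecar")
  unlink(path)
})

test_that("the full preprocessing chain orders its steps", {
  set.seed(7)
  raw <- generate_sequence(regime_params("awake", n_regions = 2),
                           individual_params("I1", 4, seed = 3),
                           length_steps = 500, seed = 11)
  pp <- preprocess_sequence(raw, bin = 250)
  expect_equal(attr(pp, "preprocessing"),
               c("rereference", "outlier_exclusion", "normalize"))
  expect_true(all(abs(sequence_values(pp)) < 1))
})
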