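zero_stream <- function(spec, T, rate = 1000) {
  signal_sequence(matrix(0, n_channels(spec), T), rate, "awake", "I1",
                  rep(spec$region_names, each = spec$channels_per_region))
}

test_that("window bookkeeping accumulates H x K updates per step", {
  spec <- network_spec(n_regions = 1, channels_per_region = 1, q1 = 1,
                       q2 = 1, q3 = 1, p1 = 2, p2 = 2)
  model <- vrnn_model(spec, seed = 5)
  tr <- assimilate(model, zero_stream(spec, 25),
                   assimilation_config(H = 10, K = 5, seed = 1))
  # a step inside a full window accumulates exactly H * K iterations
  expect_equal(tr$update_counts[1], 50)
  expect_equal(max(tr$update_counts), 50)
  # the newest steps are still inside the window: partial counts
  expect_equal(tr$update_counts[25], 5)
  expect_equal(tr$update_counts[24], 10)
  expect_equal(nrow(tr$steps), 25)
})

test_that("K = 0 reduces to a pure prior rollout", {
  spec <- network_spec(n_regions = 1, channels_per_region = 1, q1 = 1,
                       q2 = 1, q3 = 1, p1 = 2, p2 = 2)
  model <- vrnn_model(spec, seed = 5)
  tr <- assimilate(model, zero_stream(spec, 30),
                   assimilation_config(H = 8, K = 0, seed = 2))
  expect_equal(tr$xhat_post[, 30], tr$xhat_prior[, 30])
  # posterior means equal prior-handoff values: z3 stays at N(0,1) mean
  expect_equal(as.numeric(tr$z3_mu), rep(0, 30))
})

test_that("assimilation never modifies the weights", {
  spec <- tiny_spec()
  model <- vrnn_model(spec, seed = 6)
  theta_before <- model$theta
  tr <- assimilate(model, zero_stream(spec, 12),
                   assimilation_config(H = 5, K = 3, seed = 3))
  expect_identical(model$theta, theta_before)
  expect_true(tr$theta_unchanged)
})

test_that("assimilation reduces window free energy on a real signal", {
  spec <- network_spec(n_regions = 1, channels_per_region = 2, q1 = 1,
                       q2 = 2, q3 = 1, p1 = 8, p2 = 8,
                       meta_prior = 0.001)
  model <- vrnn_model(spec, seed = 3)
  sq <- sinusoid_sequence(100)
  model <- train_vrnn(model, list(sq), n_updates = 1200, seed = 11)
  tt <- 101:160
  x2 <- rbind(0.5 * sin(2 * pi * tt / 25), 0.4 * sin(2 * pi * tt / 50 + 1))
  stream <- signal_sequence(x2, 100, "awake", "I1", rep("R1", 2))
  tr <- assimilate(model, stream,
                   assimilation_config(H = 20, K = 15, seed = 4))
  expect_gte(mean(tr$steps$F_after <= tr$steps$F_before), 0.95)
  # and the assimilated prediction beats the prior rollout on average
  err_post <- mean((tr$xhat_post - sequence_values(stream))^2)
  err_prior <- mean((tr$xhat_prior - sequence_values(stream))^2)
  expect_lt(err_post, err_prior)
})

test_that("self-generated signals are recovered by assimilation", {
  # generate from the model itself with a known constant global latent and
  # near-deterministic lower levels, then assimilate the result
  spec <- network_spec(n_regions = 1, channels_per_region = 2, q1 = 1,
                       q2 = 2, q3 = 1, p1 = 6, p2 = 6,
                       meta_prior = 0.001)
  model <- vrnn_model(spec, seed = 9)
  T <- 60
  z3_true <- 0.7
  gen <- cortwin:::pv_generate(unclass(spec), model$theta, T,
                               cortwin:::zero_eps(spec, T), TRUE,
                               cortwin:::empty_init(spec),
                               m3 = 1, z3c = z3_true,
                               m2 = matrix(0, 2, T),
                               z2c = matrix(0, 2, T),
                               m1 = matrix(0, 1, T),
                               z1c = matrix(0, 1, T))
  stream <- signal_sequence(gen$xhat, 100, "awake", "I1", rep("R1", 2))
  tr <- assimilate(model, stream,
                   assimilation_config(H = T, K = 150, seed = 5))
  final_err <- mean(tail(tr$steps$recon_error, 10))
  expect_lt(final_err, 0.05)
})

test_that("multi-step prediction is deterministic and consistent at n = 1", {
  spec <- tiny_spec()
  model <- vrnn_model(spec, seed = 2)
  set.seed(30)
  x <- matrix(0.3 * sin(outer(1:4, 1:40, function(i, t) t / (3 + i))),
              4, 40)
  stream <- signal_sequence(x, 100, "awake", "I1",
                            rep(spec$region_names, each = 2))
  tr <- assimilate(model, stream,
                   assimilation_config(H = 10, K = 4, seed = 6))
  p1 <- predict_ahead(model, tr, n_steps = 5, from = 20)
  p2 <- predict_ahead(model, tr, n_steps = 5, from = 20)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(4L, 5L))
  expect_error(predict_ahead(model, tr, n_steps = 0), "n_steps")
  # sampled rollouts are reproducible under a seed
  s1 <- predict_ahead(model, tr, n_steps = 5, from = 20, sample = TRUE,
                      seed = 3)
  s2 <- predict_ahead(model, tr, n_steps = 5, from = 20, sample = TRUE,
                      seed = 3)
  expect_identical(s1, s2)
})

test_that("classify_trace_state scores sides of a known switch", {
  # synthetic trace: global latent jumps from cluster A to cluster B
  fake <- structure(list(
    z3_mu = cbind(matrix(rep(c(-0.5, 0), 10), 2),
                  matrix(rep(c(0.5, 0), 10), 2)),
    steps = data.frame(t = 1:20), switch_time = 10),
    class = "assimilation_trace")
  ref <- list(points = rbind(c(-0.5, 0), c(-0.45, 0.05),
                             c(0.5, 0), c(0.55, -0.05)),
              labels = c("awake", "awake", "anesthetized", "anesthetized"))
  res <- classify_trace_state(fake, ref, before_label = "awake",
                              after_label = "anesthetized", k = 1)
  expect_equal(res$prop_before, 1)
  expect_equal(res$prop_after, 1)
  # swapped reference labels flip the proportions
  ref2 <- ref; ref2$labels <- rev(ref$labels)
  res2 <- classify_trace_state(fake, ref2, before_label = "awake",
                               after_label = "anesthetized", k = 1)
  expect_equal(res2$prop_before, 0)
  expect_equal(res2$prop_after, 0)
  # a trace sitting exactly on one centroid goes to that cluster
  fake3 <- fake; fake3$z3_mu <- matrix(rep(c(-0.5, 0), 20), 2)
  res3 <- classify_trace_state(fake3, ref, before_label = "awake",
                               after_label = "awake", k = 1)
  expect_equal(res3$prop_before, 1)
  expect_equal(res3$prop_after, 1)
  expect_error(classify_trace_state(fake, list(points = NULL,
                                               labels = character(0)),
                                    before_label = "a", after_label = "b"),
               "empty reference")
})
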