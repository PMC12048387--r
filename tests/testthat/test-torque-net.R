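test_that("parameter accounting matches hand counts and weight enumeration", {
  x <- matrix(rnorm(40), 10, 4)
  y <- rep(c(1, 2), 5)
  net <- torque_net(x, y, hidden = c(3, 2), epochs = 0, seed = 1)
  fp <- model_footprint(net)
  expect_equal(fp$parameters, 29)           # 15 + 8 + 6
  manual <- sum(vapply(net$weights, length, numeric(1)))
  expect_equal(fp$parameters, manual)
  # FLOPs roughly twice the parameter count for the dense stack
  expect_gt(fp$flops, 1.4 * fp$parameters)
  expect_lt(fp$flops, 2.6 * fp$parameters)
  expect_error(torque_net(x, y, hidden = c(0, 2), epochs = 0))
})

test_that("classifier outputs live on the probability simplex", {
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(c(0, 5, 9, 30), 5)
  net <- torque_net(x, y, hidden = c(8, 4), epochs = 3, batch_size = 8,
                    seed = 2)
  set.seed(33)
  fuzz <- matrix(rnorm(300, sd = 50), 100, 3)
  p <- predict(net, fuzz, type = "prob")
  expect_true(all(p >= 0))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  # decoded values are bounded by the class-value map
  v <- predict(net, fuzz, type = "value")
  expect_true(all(v >= 0 & v <= 30))
})

test_that("probability-weighted decoding is the expected weighted sum", {
  expect_equal(decode_weighted(c(0, 1, 0), c(10, 32.8, 50)), 32.8)
  expect_equal(decode_weighted(c(0.5, 0.5), c(10, 20)), 15)
  vals <- c(2, 4, 8, 16)
  expect_equal(decode_weighted(rep(0.25, 4), vals), mean(vals))
  expect_error(decode_weighted(c(0.5, 0.5), c(1, 2, 3)), "map")
  expect_error(decode_weighted(c(0.9, 0.3), c(1, 2)), "sum to 1")
})

test_that("data splitting follows the 7:1:2 ratios with a seeded shuffle", {
  x <- matrix(rnorm(4000), 1000, 4)
  y <- rep(c(1, 2, 3, 4), 250)
  net <- torque_net(x, y, hidden = c(4, 3), epochs = 0, seed = 9)
  expect_equal(length(net$split_idx$train), 700)
  expect_equal(length(net$split_idx$val), 100)
  expect_equal(length(net$split_idx$test), 200)
  expect_equal(sort(unlist(net$split_idx)), 1:1000,
               ignore_attr = TRUE)
  # a class missing from the training split is an error
  x20 <- matrix(rnorm(80), 20, 4)
  y20 <- rep(1:10, 2)
  expect_error(torque_net(x20, y20, hidden = c(4, 3), epochs = 0, seed = 9,
                          split = c(0.1, 0.1, 0.8)),
               "absent")
})

test_that("training is deterministic per seed and learns separable toy data", {
  set.seed(77)
  n <- 60
  y <- rep(c(1, 2, 3), each = n / 3)
  x <- cbind(y + rnorm(n, sd = 0.05), -y + rnorm(n, sd = 0.05))
  a <- torque_net(x, y, hidden = c(16, 8), epochs = 40, batch_size = 8, seed = 4)
  b <- torque_net(x, y, hidden = c(16, 8), epochs = 40, batch_size = 8, seed = 4)
  expect_identical(a$history, b$history)
  expect_identical(a$weights, b$weights)
  expect_gte(a$history$train_acc[nrow(a$history)], 0.99)
  c2 <- torque_net(x, y, hidden = c(16, 8), epochs = 40, batch_size = 8, seed = 5)
  expect_false(identical(a$weights, c2$weights))
})

test_that("evaluation reports accuracy, RMSE and Pearson r", {
  net <- small_model()
  fz <- small_features()
  ev <- evaluate(net)
  expect_s3_class(ev, "torque_eval")
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  expect_equal(sum(ev$confusion), ev$n)
  # row sums are the per-class test counts
  ytest <- fz$labels$torque[net$split_idx$test]
  expect_equal(as.numeric(rowSums(ev$confusion)),
               as.numeric(table(factor(format(ytest),
                                       levels = format(net$class_values)))))
  # perfect predictions give accuracy 1, RMSE 0, r 1
  idx <- net$split_idx$train
  evp <- evaluate(net, fz$features[idx, ], fz$labels$torque[idx])
  expect_equal(evp$accuracy, 1)
  expect_lt(evp$rmse, 0.2)
  expect_gt(evp$pearson, 0.999)
  # degenerate truth: r undefined, flagged
  one <- matrix(fz$features[1, ], 1)
  expect_warning(ev1 <- evaluate(net, one[c(1, 1), ],
                                 rep(fz$labels$torque[1], 2)), "undefined")
  expect_true(is.na(ev1$pearson))
})

test_that("Pearson correlation matches hand-evaluated cases", {
  expect_equal(stats::cor(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(stats::cor(c(1, 2, 3), c(1, 3, 2)), 0.5)
})

test_that("fine-tuning preserves architecture and respects zero epochs", {
  net <- small_model()
  fz <- small_features()
  same <- fine_tune(net, fz$features[1:20, ], fz$labels$torque[1:20], epochs = 0)
  expect_identical(same$weights, net$weights)
  tuned <- fine_tune(net, fz$features[1:40, ], fz$labels$torque[1:40],
                     epochs = 2, seed = 3)
  expect_equal(length(tuned$class_values), length(net$class_values))
  expect_equal(dim(tuned$weights$W1), dim(net$weights$W1))
  expect_error(fine_tune(net, fz$features[1:5, 1:10], fz$labels$torque[1:5]),
               "dimension mismatch")
  expect_error(fine_tune(net, fz$features[1:5, ], rep(99.9, 5)),
               "class-value map")
})

test_that("regression head fits continuous targets", {
  set.seed(12)
  x <- matrix(runif(400), 100, 4)
  y <- 2 * x[, 1] - x[, 2] + 0.1 * rnorm(100)
  net <- torque_net(x, y, task = "regression", hidden = c(16, 8),
                    epochs = 150, batch_size = 16, seed = 6)
  ev <- evaluate(net)
  expect_gt(ev$pearson, 0.8)
  expect_error(predict(net, x, type = "prob"), "classifier")
})
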