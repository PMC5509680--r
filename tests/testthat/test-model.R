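test_that("the default specification carries 360 filters", {
  spec <- network_spec()
  expect_equal(spec$conv_filters, c(24L, 48L, 96L, 192L))
  expect_equal(total_filters(spec), 360L)
  expect_error(network_spec(conv_filters = c(24, 48, 96)), "four")
})

test_that("the spatial trace for a 21-voxel patch is 25/29/14/16/8/10/5", {
  tr <- layer_trace(21)
  expect_equal(unname(tr),
               c(21L, 25L, 29L, 14L, 16L, 8L, 10L, 5L))
  net <- build_network(network_spec(), 21, seed = 1)
  expect_equal(net$flat_dim, 192L * 5L * 5L)
  expect_equal(dim(net$params$Wf1), c(256L, 4800L))
})

test_that("an incompatible patch edge fails naming the layer", {
  expect_error(layer_trace(1, network_spec(padding = "same")), "pool1")
})

test_that("network output is a two-way probability vector", {
  net <- build_network(network_spec(conv_filters = c(4, 8, 16, 32),
                                    fc_width = 16), 11, seed = 2)
  x <- withr::with_seed(1, array(rnorm(11 * 11 * 3 * 7), c(11, 11, 3, 7)))
  pr <- predict_patches(net, x)
  expect_equal(dim(pr), c(7L, 2L))
  expect_true(all(pr >= 0))
  expect_equal(unname(rowSums(pr)), rep(1, 7), tolerance = 1e-12)
  # deterministic with dropout disabled
  expect_identical(pr, predict_patches(net, x))
  # batching must not change results
  expect_equal(pr, predict_patches(net, x, batch = 2L), tolerance = 1e-12)
})

test_that("split_discovery reproduces the 560K/140K patch accounting", {
  # 70 subjects x 5000 patches per class = 700,000 discovery patches
  ps <- dummy_patch_set(rep(c(0L, 1L), each = 350000))
  sp <- split_discovery(ps, 0.8, seed = 1)
  expect_equal(length(sp$train$labels), 560000L)
  expect_equal(length(sp$test$labels), 140000L)
  expect_equal(mean(sp$train$labels), 0.5, tolerance = 0.01)
  expect_equal(mean(sp$test$labels), 0.5, tolerance = 0.01)
})

test_that("split_discovery is disjoint, exhaustive and reproducible", {
  ps <- dummy_patch_set(rep(c(0L, 1L), 5))
  sp <- split_discovery(ps, 0.8, seed = 4)
  expect_equal(length(sp$train$labels), 8L)
  expect_equal(length(sp$test$labels), 2L)
  ps2 <- toy_patch_set(20, M = 3, seed = 2)
  a <- split_discovery(ps2, 0.8, seed = 7)
  b <- split_discovery(ps2, 0.8, seed = 7)
  expect_identical(a$train$patches, b$train$patches)
  got <- rbind(a$train$coords, a$test$coords)
  expect_equal(length(a$train$labels) + length(a$test$labels), 40L)
})

test_that("the early-stopping rule matches the hand-applied examples", {
  costs <- c(1.0, 0.9, 0.8999, 0.8995, 0.8991, 0.8988, 0.8985)
  # improvements: Inf, 0.1, 1e-4, 4e-4, 4e-4, 3e-4, 3e-4 -> epochs 3..7 are
  # five consecutive epochs with improvement <= 1e-3
  expect_equal(early_stop_epoch(costs, patience = 5, tol = 1e-3), 7L)
  expect_true(is.na(early_stop_epoch(costs[1:6], patience = 5, tol = 1e-3)))
  # tol = Inf: stops after exactly `patience` epochs
  expect_equal(early_stop_epoch(rep(1, 20), patience = 5, tol = Inf), 5L)
  expect_equal(early_stop_epoch(seq(10, 1), patience = 3, tol = Inf), 3L)
  # steadily improving sequence never stops
  expect_true(is.na(early_stop_epoch(seq(2, 0.1, by = -0.1), 5, 1e-3)))
})

test_that("the classifier solves a linearly separable toy problem", {
  ps <- toy_patch_set(150, M = 5, sep = 2.5, seed = 11)
  sp <- split_discovery(ps, 0.8, seed = 1)
  # independent oracle: logistic regression on the flattened tiles
  xf <- t(matrix(sp$train$patches, ncol = length(sp$train$labels)))
  fit <- suppressWarnings(
    glm.fit(cbind(1, xf), sp$train$labels, family = binomial())
  )
  oracle_acc <- mean((fit$fitted.values > 0.5) == (sp$train$labels == 1))
  expect_gte(oracle_acc, 0.99)
  net <- build_network(network_spec(conv_filters = c(4, 8, 16, 32),
                                    fc_width = 24), 5, seed = 3)
  net <- train_network(net, sp$train, sp$test,
                       train_config(lr = 1, max_epochs = 15,
                                    batch_size = 60, seed = 5))
  fin <- predict_patches(net, sp$train$patches)
  acc <- mean((fin[, "tumour"] > 0.5) == (sp$train$labels == 1))
  expect_gte(acc, 0.95)
  # training loss decreased over the run (sanity, not monotonicity)
  h <- net$history
  expect_lt(h$train_cost[nrow(h)], h$train_cost[1])
})

test_that("training is deterministic for a fixed seed", {
  ps <- toy_patch_set(40, M = 5, seed = 21)
  sp <- split_discovery(ps, 0.8, seed = 2)
  cfg <- train_config(lr = 1, max_epochs = 3, batch_size = 32, seed = 9)
  n1 <- train_network(build_network(network_spec(conv_filters = c(2, 4, 8, 16),
                                                 fc_width = 8), 5, seed = 4),
                      sp$train, sp$test, cfg)
  n2 <- train_network(build_network(network_spec(conv_filters = c(2, 4, 8, 16),
                                                 fc_width = 8), 5, seed = 4),
                      sp$train, sp$test, cfg)
  expect_identical(n1$params, n2$params)
  expect_identical(n1$history, n2$history)
})

test_that("tol = Inf makes training stop after exactly patience epochs", {
  ps <- toy_patch_set(40, M = 5, seed = 31)
  sp <- split_discovery(ps, 0.8, seed = 2)
  net <- train_network(
    build_network(network_spec(conv_filters = c(2, 4, 8, 16), fc_width = 8),
                  5, seed = 1),
    sp$train, sp$test,
    train_config(lr = 1, max_epochs = 20, batch_size = 32,
                 improvement_tol = Inf, patience = 3, seed = 2)
  )
  expect_equal(attr(net$history, "stopped_epoch"), 3L)
  expect_equal(attr(net$history, "stop_reason"), "patience")
  expect_equal(nrow(net$history), 3L)
})

test_that("degenerate training inputs are rejected", {
  ps <- toy_patch_set(10, M = 5)
  sp <- split_discovery(ps, 0.8, seed = 1)
  one_class <- mparseg:::subset_patch_set(ps, which(ps$labels == 1L))
  net <- build_network(network_spec(conv_filters = c(2, 4, 8, 16),
                                    fc_width = 8), 5)
  expect_error(train_network(net, one_class, sp$test, train_config()),
               "both classes")
  expect_error(train_config(train_fraction = 1.2), "train_fraction")
  expect_error(train_config(patience = 0), "patience")
})

test_that("model checkpoints round-trip through JSON", {
  ps <- toy_patch_set(30, M = 5, seed = 41)
  sp <- split_discovery(ps, 0.8, seed = 1)
  net <- train_network(
    build_network(network_spec(conv_filters = c(2, 4, 8, 16), fc_width = 8),
                  5, seed = 6),
    sp$train, sp$test,
    train_config(lr = 1, max_epochs = 2, batch_size = 24, seed = 3)
  )
  tf <- withr::local_tempfile(fileext = ".json")
  save_model(net, tf)
  back <- load_model(tf)
  x <- ps$patches[, , , 1:5, drop = FALSE]
  expect_equal(predict_patches(back, x), predict_patches(net, x),
               tolerance = 1e-12)
  expect_equal(nrow(back$history), nrow(net$history))
  th <- withr::local_tempfile(fileext = ".tsv")
  write_history(net, th)
  expect_equal(nrow(read.table(th, header = TRUE)), nrow(net$history))
})
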