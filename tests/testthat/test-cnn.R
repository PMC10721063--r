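test_that("the backbone registry exposes one desk-scale backbone", {
  reg <- backbone_registry()
  expect_true("reference-small" %in% reg$name)
  expect_true(all(c("squeezenet", "shufflenet", "resnet101", "darknet19",
                    "nasnet-mobile") %in% reg$name))
  expect_error(build_backbone("resnet101", n_classes = 4), "plug-in")
  expect_error(build_backbone("nope", n_classes = 4), "unknown")
})

test_that("head replacement resizes only the final layer", {
  m <- build_backbone("reference-small", n_classes = 16, input_size = 16,
                      seed = 2)
  expect_equal(nrow(m$params$fc$W), 16)
  m4 <- replace_head(m, 4)
  expect_equal(nrow(m4$params$fc$W), 4)
  expect_identical(m4$params$conv1, m$params$conv1)
  expect_identical(m4$params$conv2, m$params$conv2)
  expect_identical(m4$params$conv3, m$params$conv3)
  m4b <- replace_head(replace_head(m, 7), 4)
  expect_identical(m4b$params$conv3, m$params$conv3)
  expect_error(replace_head(m, 1), "at least 2")
  expect_error(build_backbone("reference-small", n_classes = 1), "at least 2")
})

test_that("training is deterministic, seeded, and a no-op at zero epochs", {
  toy <- toy_images(n_per_class = 10, size = 16)
  m <- build_backbone("reference-small", n_classes = 2, input_size = 16,
                      seed = 3)
  cfg <- train_config(epochs = 3, batch_size = 8, learning_rate = 0.003,
                      seed = 7)
  t1 <- train_head(m, toy$images, toy$labels, cfg)
  t2 <- train_head(m, toy$images, toy$labels, cfg)
  expect_equal(attr(t1, "loss_trace"), attr(t2, "loss_trace"),
               tolerance = 1e-6)
  expect_identical(t1$params, t2$params)
  expect_length(attr(t1, "loss_trace"), 3)

  t0 <- train_head(m, toy$images, toy$labels,
                   train_config(epochs = 0, seed = 7))
  expect_identical(t0$params, m$params)
  expect_length(attr(t0, "loss_trace"), 0)

  expect_error(train_head(m, toy$images, rep("top", 20), cfg), "classes")
})

test_that("a separable toy fixture is fit to training accuracy 1", {
  toy <- toy_images(n_per_class = 16, size = 16)
  m <- build_backbone("reference-small", n_classes = 2, input_size = 16,
                      seed = 5)
  tm <- train_head(m, toy$images, toy$labels,
                   train_config(epochs = 10, batch_size = 8,
                                learning_rate = 0.003, seed = 11))
  f <- extract_features(tm, toy$images)
  pred <- tm$class_order[max.col(f)]
  expect_equal(mean(pred == toy$labels), 1)
  trace <- attr(tm, "loss_trace")
  expect_lt(trace[length(trace)], trace[1])
})

test_that("extraction is a pure function with head-width features", {
  toy <- toy_images(n_per_class = 4, size = 16)
  m <- build_backbone("reference-small", n_classes = 3, input_size = 16,
                      seed = 6)
  f1 <- extract_features(m, toy$images)
  expect_equal(dim(f1), c(8L, 3L))
  f2 <- extract_features(m, toy$images)
  expect_identical(f1, f2)
  expect_identical(f1[1, ], f1[1, ])
  expect_error(extract_features(m, array(0, c(8, 8, 3, 2))), "input")

  # concatenating k backbones of width c gives k * c columns
  blocks <- lapply(1:5, function(b) {
    extract_features(build_backbone("reference-small", n_classes = 16,
                                    input_size = 16, seed = b),
                     toy$images)
  })
  names(blocks) <- paste0("bb", 1:5)
  fm <- feature_matrix(blocks, rep(c("a", "b"), 4))
  expect_equal(ncol(fm) - 1, 80)
  expect_equal(unname(lengths(attr(fm, "block_spans"))), rep(16L, 5))
})

test_that("mixup and jitter augmentation keep training deterministic", {
  toy <- toy_images(n_per_class = 8, size = 16)
  m <- build_backbone("reference-small", n_classes = 2, input_size = 16,
                      seed = 8)
  cfg <- train_config(epochs = 2, batch_size = 8, learning_rate = 0.003,
                      seed = 9, mixup_alpha = 0.2, augment_noise = 0.05)
  a <- train_head(m, toy$images, toy$labels, cfg)
  b <- train_head(m, toy$images, toy$labels, cfg)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, train_head(m, toy$images, toy$labels,
                                              train_config(epochs = 2,
                                                           batch_size = 8,
                                                           learning_rate = 0.003,
                                                           seed = 10))$params))
})
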