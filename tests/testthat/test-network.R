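test_that("cuboid convolution computes the literal triple sum", {
  # all-ones 4x4x2 input, all-ones 3x3x2 filter: every valid position sums
  # 3*3*2 = 18 products
  out <- cuboid_convolve(array(1, c(4, 4, 2)), array(1, c(3, 3, 2)), "valid")
  expect_identical(dim(out), c(2L, 2L))
  expect_true(all(out == 18))
  # independent brute-force enumeration on a random case
  set.seed(5)
  X <- array(rnorm(5 * 6 * 3), c(5, 6, 3))
  f <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
  ref <- matrix(0, 3, 4)
  for (h in 1:3) for (w in 1:4) {
    ref[h, w] <- sum(f * X[h:(h + 2), w:(w + 2), ])
  }
  expect_equal(cuboid_convolve(X, f, "valid"), ref)
})

test_that("a delta filter on one slice returns that slice under same-mode", {
  set.seed(1)
  X <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  f <- array(0, c(3, 3, 3))
  f[2, 2, 2] <- 1 # centred delta selecting slice 2
  expect_equal(cuboid_convolve(X, f, "same"), X[, , 2])
})

test_that("valid-mode shrinks dimensions by the filter extent", {
  X <- array(0, c(32, 32, 5))
  f <- array(0, c(3, 3, 5))
  expect_identical(dim(cuboid_convolve(X, f, "valid")), c(30L, 30L))
  expect_identical(dim(cuboid_convolve(X, f, "same")), c(32L, 32L))
  expect_error(cuboid_convolve(array(0, c(4, 4, 2)), array(0, c(3, 3, 3))),
               "z-depth")
})

test_that("conv_layer applies bias and ReLU per filter", {
  X <- array(0, c(4, 4, 1))
  fs <- list(array(1, c(3, 3, 1)), array(-1, c(3, 3, 1)))
  out <- conv_layer(X, fs, biases = c(0, 0), mode = "valid")
  expect_true(all(out == 0)) # ReLU(0) = 0
  X1 <- array(1, c(4, 4, 1))
  out1 <- conv_layer(X1, fs, biases = c(0.5, 0), mode = "valid")
  expect_true(all(out1[, , 1] == 9.5))
  expect_true(all(out1[, , 2] == 0)) # negative pre-activation clamps to 0
  expect_error(conv_layer(X, fs, biases = 1), "one bias per filter")
})

test_that("max pooling selects window maxima at the given stride", {
  # a lone 1 in a 4x4 grid survives in exactly one pooled cell
  X <- matrix(0, 4, 4)
  X[2, 3] <- 1
  out <- max_pool(X, 2, 2)
  expect_identical(dim(out), c(2L, 2L))
  expect_identical(sum(out == 1), 1L)
  expect_identical(out[1, 2], 1)
  # constant input stays constant
  expect_true(all(max_pool(array(3.5, c(6, 6, 2)), 2, 2) == 3.5))
  # non-integral output dims are rejected
  expect_error(max_pool(matrix(0, 5, 5), 2, 2), "not integral")
})

test_that("posteriors form a probability simplex and zero weights give uniform output", {
  spec <- network_spec(c(8, 8, 2),
                       list(list(filters = 2, kh = 3, kw = 3, mode = "valid")),
                       pool = list(size = 2, stride = 2), hidden = 5,
                       n_classes = 4)
  w <- init_weights(spec, seed = 2)
  x <- array(rnorm(prod(spec$input_shape)), dim = spec$input_shape)
  p <- classify(spec, w, x)$posteriors
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  w0 <- rapply(unclass(w), function(m) m * 0, how = "replace")
  p0 <- classify(spec, structure(w0, class = "network_weights"), x)$posteriors
  expect_equal(p0, rep(0.25, 4))
})

test_that("inputs that do not match the spec shape are rejected", {
  spec <- network_spec(c(8, 8, 2),
                       list(list(filters = 2, kh = 3, kw = 3, mode = "valid")),
                       pool = NULL, hidden = 4, n_classes = 3)
  w <- init_weights(spec, seed = 1)
  expect_error(classify(spec, w, array(0, c(8, 8, 3))), "does not match")
  expect_error(classify(spec, w, array(0, c(4, 4, 2))), "does not match")
})

test_that("decision rule is argmax with lowest-index tie-breaking", {
  expect_identical(decide(c(0.1, 0.7, 0.2, 0, 0, 0)), 2L)
  expect_identical(decide(rep(1 / 6, 6)), 1L)
  expect_identical(decide(c(0, 0, 1, 0)), 3L)
  expect_identical(decide(c(0.2, 0.4, 0.4)), 2L)
  expect_error(decide(c(0.5, NA)), "finite")
})

test_that("fast forward pass matches the literal-equation reference", {
  set.seed(99)
  for (i in 1:10) {
    tr <- random_triple()
    pr <- forward_reference(tr$spec, tr$weights, tr$input)
    pf <- classify(tr$spec, tr$weights, tr$input)
    expect_lt(max(abs(pr$posteriors - pf$posteriors)), 1e-10)
    expect_identical(pr$decided_class, pf$decided_class)
  }
})

test_that("analytic gradients match finite differences on a tiny network", {
  spec <- network_spec(c(6, 6, 2),
                       list(list(filters = 2, kh = 3, kw = 3, mode = "valid")),
                       pool = list(size = 2, stride = 2), hidden = 5,
                       n_classes = 3)
  set.seed(4)
  w <- init_weights(spec, seed = 3)
  x <- array(rnorm(72), dim = c(6, 6, 2))
  cspec <- ctxnet:::spec_for_cpp(spec)
  lg <- ctxnet:::cnn_loss_grad_cpp(list(x), 2L, cspec, unclass(w))
  eps <- 1e-6
  for (fld in c("conv_w", "conv_b", "fc_w", "fc_b")) {
    for (l in seq_along(w[[fld]])) {
      for (j in sample(length(w[[fld]][[l]]), min(3, length(w[[fld]][[l]])))) {
        wp <- w; wp[[fld]][[l]][j] <- wp[[fld]][[l]][j] + eps
        wm <- w; wm[[fld]][[l]][j] <- wm[[fld]][[l]][j] - eps
        num <- (ctxnet:::cnn_loss_grad_cpp(list(x), 2L, cspec, unclass(wp))$loss -
                ctxnet:::cnn_loss_grad_cpp(list(x), 2L, cspec, unclass(wm))$loss) /
               (2 * eps)
        expect_equal(lg$grads[[fld]][[l]][j], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training is deterministic given the seed and reaches the loss threshold", {
  spec <- network_spec(c(8, 8, 1),
                       list(list(filters = 3, kh = 3, kw = 3, mode = "valid")),
                       pool = list(size = 2, stride = 2), hidden = 8,
                       n_classes = 2)
  set.seed(10)
  protos <- list(matrix(as.numeric(outer(1:8, 1:8, "+") %% 2), 8, 8),
                 matrix(as.numeric(outer(1:8, 1:8, "*") %% 2), 8, 8))
  inputs <- list(); labels <- integer(0)
  for (ci in 1:2) for (r in 1:8) {
    inputs <- c(inputs, list(array(protos[[ci]] + rnorm(64, sd = 0.03), c(8, 8, 1))))
    labels <- c(labels, ci)
  }
  cfg <- train_config(max_epochs = 800, seed = 77, samples_per_class = 8)
  f1 <- train_network(spec, inputs, labels, cfg)
  f2 <- train_network(spec, inputs, labels, cfg)
  expect_true(f1$converged)
  expect_lt(f1$final_loss, cfg$loss_threshold)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$loss_history, f2$loss_history)
  # converged training implies perfect separation of the training set
  ev <- evaluate_network(spec, f1$weights, inputs, labels)
  expect_identical(ev$accuracy, 1)
})

test_that("training input validation catches bad labels and empty sets", {
  spec <- network_spec(c(6, 6, 1),
                       list(list(filters = 2, kh = 3, kw = 3, mode = "valid")),
                       pool = NULL, hidden = 4, n_classes = 2)
  expect_error(train_network(spec, list(), integer(0)), "empty")
  x <- array(0, c(6, 6, 1))
  expect_error(train_network(spec, list(x), 3L), "1..n_classes")
  expect_error(train_network(spec, list(x, x), 1L), "one label per input")
})

test_that("network specs validate their dimension chain", {
  expect_error(network_spec(c(9, 9, 1),
                            list(list(filters = 2, kh = 3, kw = 3, mode = "valid")),
                            pool = list(size = 2, stride = 2)),
               "not integral")
  expect_error(network_spec(c(8, 8, 1),
                            list(list(filters = 2, kh = 2, kw = 3, mode = "valid")),
                            pool = NULL),
               "odd")
})
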