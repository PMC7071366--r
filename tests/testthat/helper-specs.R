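# Random small architectures + conforming random weights and inputs, for
# oracle-equivalence and invariant checks.

random_triple <- function() {
  H <- sample(6:12, 1)
  W <- sample(6:12, 1)
  Z <- sample(1:4, 1)
  n_conv <- sample(1:2, 1)
  conv <- lapply(seq_len(n_conv), function(i) {
    list(filters = sample(1:4, 1), kh = sample(c(1, 3), 1),
         kw = sample(c(1, 3), 1), mode = sample(c("valid", "same"), 1))
  })
  # choose a pooling window/stride that divides the conv output evenly,
  # or no pooling at all
  shp <- c(H, W)
  for (cl in conv) {
    if (cl$mode == "valid") shp <- shp - c(cl$kh, cl$kw) + 1
  }
  pool <- NULL
  for (g in sample(2:3)) {
    if (all((shp - g) >= 0) && all((shp - g) %% g == 0)) {
      pool <- list(size = g, stride = g)
      break
    }
  }
  spec <- network_spec(c(H, W, Z), conv, pool = pool,
                       hidden = sample(3:8, 1), n_classes = sample(2:6, 1),
                       hidden_activation = sample(c("sigmoid", "tanh", "relu"), 1))
  w <- init_weights(spec, seed = sample.int(1e6, 1))
  # non-zero biases so bias handling is exercised
  w$conv_b <- lapply(w$conv_b, function(b) b + stats::rnorm(length(b), sd = 0.1))
  w$fc_b <- lapply(w$fc_b, function(b) b + stats::rnorm(length(b), sd = 0.1))
  x <- array(stats::rnorm(prod(spec$input_shape)), dim = spec$input_shape)
  list(spec = spec, weights = w, input = x)
}
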