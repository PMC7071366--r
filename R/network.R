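# Network specification, initialisation, training and prediction.
#
# Two forward passes coexist: a fast trainable implementation (C++, im2col)
# and `forward_reference()`, a deliberately slow pure-R transcription of the
# defining layer equations (triple-sum cuboid convolution, bias + ReLU,
# windowed max-pooling, dense layers, softmax). The two must agree to
# floating-point tolerance on any (spec, weights, input) triple; the test
# suite enforces this on randomly generated triples.

#' Specify a convolutional classifier architecture
#'
#' The architecture family is: a sequence of cuboid convolution layers
#' (each filter spans the full z-depth of its input, bias + ReLU), an
#' optional max-pooling layer, flattening, hidden dense layers, and a
#' softmax output layer with one unit per class.
#'
#' @param input_shape Integer vector `c(H, W, depth)`.
#' @param conv_layers List of convolution layers, each a list with
#'   `filters` (number of filters K), `kh`, `kw` (odd filter height/width)
#'   and `mode` (`"valid"` or `"same"`).
#' @param pool `list(size = gamma, stride = s)` for gamma x gamma max
#'   pooling at stride s, or `NULL` for no pooling. Pooled dimensions
#'   `(H - gamma)/s + 1` must be integral.
#' @param hidden Integer vector of hidden dense-layer widths.
#' @param n_classes Number of classes L (softmax outputs).
#' @param hidden_activation One of `"sigmoid"`, `"tanh"`, `"relu"`.
#' @return A `network_spec` object.
#' @seealso [context_net_spec()] for the standard experiment architecture.
#' @export
network_spec <- function(input_shape, conv_layers, pool = list(size = 2, stride = 2),
                         hidden = 100, n_classes = 6,
                         hidden_activation = c("sigmoid", "tanh", "relu")) {
  hidden_activation <- match.arg(hidden_activation)
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1))
  shape <- as.integer(input_shape)
  depth <- shape[3L]
  conv_layers <- lapply(conv_layers, function(cl) {
    stopifnot(all(c("filters", "kh", "kw") %in% names(cl)))
    if (is.null(cl$mode)) cl$mode <- "valid"
    if (!cl$mode %in% c("valid", "same")) stop("conv mode must be 'valid' or 'same'")
    if (cl$kh %% 2L == 0L || cl$kw %% 2L == 0L) {
      stop("filter height and width must be odd (2a+1, 2b+1)")
    }
    cl
  })
  spec <- structure(
    list(input_shape = shape, conv_layers = conv_layers, pool = pool,
         hidden = as.integer(hidden), n_classes = as.integer(n_classes),
         hidden_activation = hidden_activation),
    class = "network_spec"
  )
  layer_shapes(spec) # validates the dimension chain (pooling divisibility)
  spec
}

#' The standard context-integrating architecture for a given span
#'
#' Builds the experiment architecture for 32 x 32 letter stimuli with
#' context span `S`: two valid-mode convolution layers of 32 filters each
#' (3 x 3 x depth, then 3 x 3 x 32), 2 x 2 max pooling at stride 2, a
#' 100-unit sigmoid hidden layer, and a 6-way softmax output. With
#' `span = 4` the layer chain is 32x32x5 -> 30x30x32 -> 28x28x32 ->
#' 14x14x32 -> 6272 -> 100 -> 6; `span = 0` is the context-free special
#' case with a 32x32x1 input.
#'
#' @param span Context span S (depth of the input cuboid is `1 + S`).
#' @param n_classes Number of classes (default 6 target letters).
#' @return A `network_spec`.
#' @export
context_net_spec <- function(span, n_classes = 6) {
  network_spec(
    input_shape = c(32, 32, 1 + span),
    conv_layers = list(
      list(filters = 32, kh = 3, kw = 3, mode = "valid"),
      list(filters = 32, kh = 3, kw = 3, mode = "valid")
    ),
    pool = list(size = 2, stride = 2),
    hidden = 100,
    n_classes = n_classes,
    hidden_activation = "sigmoid"
  )
}

#' Layer-by-layer output shapes of a network
#'
#' @param spec A [network_spec()].
#' @return Named list of dimension vectors: input, one entry per
#'   convolution layer, the pooled shape (if pooling), the flattened
#'   length, hidden widths and output width.
#' @export
layer_shapes <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  shapes <- list(input = spec$input_shape)
  H <- spec$input_shape[1L]; W <- spec$input_shape[2L]; Z <- spec$input_shape[3L]
  for (i in seq_along(spec$conv_layers)) {
    cl <- spec$conv_layers[[i]]
    if (cl$mode == "valid") {
      H <- as.integer(H - cl$kh + 1)
      W <- as.integer(W - cl$kw + 1)
    }
    if (H < 1 || W < 1) stop("convolution output has non-positive size")
    Z <- as.integer(cl$filters)
    shapes[[paste0("conv", i)]] <- c(H, W, Z)
  }
  if (!is.null(spec$pool)) {
    g <- as.integer(spec$pool$size); st <- as.integer(spec$pool$stride)
    if ((H - g) %% st != 0L || (W - g) %% st != 0L) {
      stop(sprintf("pooled dimensions (%d - %d)/%d + 1 are not integral", H, g, st))
    }
    H <- (H - g) %/% st + 1L
    W <- (W - g) %/% st + 1L
    shapes$pooled <- c(H, W, Z)
  }
  shapes$flatten <- H * W * Z
  for (i in seq_along(spec$hidden)) {
    shapes[[paste0("dense", i)]] <- spec$hidden[i]
  }
  shapes$output <- spec$n_classes
  shapes
}

# Filter z-depth entering each conv layer.
conv_in_depths <- function(spec) {
  c(spec$input_shape[3L],
    utils::head(vapply(spec$conv_layers, function(cl) cl$filters, numeric(1)), -1L))
}

#' Initialise network weights
#'
#' Fan-based (Glorot-style) uniform initialisation of all filters and
#' dense weights; biases start at zero. Deterministic given `seed`.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return A `network_weights` list with `conv_w` (one `(kh*kw*depth) x K`
#'   matrix per convolution layer, rows ordered filter-row fastest, then
#'   filter-column, then input channel), `conv_b`, `fc_w`, `fc_b`.
#' @export
init_weights <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  depths <- conv_in_depths(spec)
  conv_w <- list(); conv_b <- list()
  for (i in seq_along(spec$conv_layers)) {
    cl <- spec$conv_layers[[i]]
    fan_in <- cl$kh * cl$kw * depths[i]
    fan_out <- cl$kh * cl$kw * cl$filters
    lim <- sqrt(6 / (fan_in + fan_out))
    conv_w[[i]] <- matrix(stats::runif(fan_in * cl$filters, -lim, lim),
                          nrow = fan_in, ncol = cl$filters)
    conv_b[[i]] <- rep(0, cl$filters)
  }
  shapes <- layer_shapes(spec)
  sizes <- c(shapes$flatten, spec$hidden, spec$n_classes)
  fc_w <- list(); fc_b <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    lim <- sqrt(6 / (sizes[i] + sizes[i + 1L]))
    fc_w[[i]] <- matrix(stats::runif(sizes[i] * sizes[i + 1L], -lim, lim),
                        nrow = sizes[i + 1L], ncol = sizes[i])
    fc_b[[i]] <- rep(0, sizes[i + 1L])
  }
  structure(list(conv_w = conv_w, conv_b = conv_b, fc_w = fc_w, fc_b = fc_b),
            class = "network_weights")
}

as_input_cuboid <- function(x, spec) {
  if (inherits(x, "integrated_input")) x <- x$cuboid
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) stop("input must be an H x W x Z array")
  if (!identical(as.integer(dim(x)), spec$input_shape)) {
    stop(sprintf("input shape (%s) does not match spec input shape (%s)",
                 paste(dim(x), collapse = "x"),
                 paste(spec$input_shape, collapse = "x")))
  }
  x
}

spec_for_cpp <- function(spec) {
  list(input_shape = spec$input_shape,
       conv_layers = lapply(spec$conv_layers, function(cl) {
         list(filters = as.integer(cl$filters), kh = as.integer(cl$kh),
              kw = as.integer(cl$kw), mode = cl$mode)
       }),
       pool = if (is.null(spec$pool)) NULL else
         list(size = as.integer(spec$pool$size), stride = as.integer(spec$pool$stride)),
       hidden = as.integer(spec$hidden),
       n_classes = as.integer(spec$n_classes),
       hidden_activation = spec$hidden_activation)
}

#' Class posterior probabilities for one or more inputs
#'
#' Runs the fast forward pass and returns softmax outputs, which are
#' interpreted as class posterior probability estimates.
#'
#' @param spec A [network_spec()].
#' @param weights Conforming `network_weights`.
#' @param inputs A single input (integrated input, matrix or array) or a
#'   list of inputs.
#' @return Numeric matrix, one row per input, `n_classes` columns; each
#'   row is non-negative and sums to 1.
#' @export
forward_posteriors <- function(spec, weights, inputs) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.list(inputs) || inherits(inputs, "integrated_input")) inputs <- list(inputs)
  cubes <- lapply(inputs, as_input_cuboid, spec = spec)
  cnn_forward_cpp(cubes, spec_for_cpp(spec), unclass(weights))
}

#' Classify a single input
#'
#' @inheritParams forward_posteriors
#' @param input A single classifier input.
#' @return A `prediction`: list with `posteriors` (length-L vector) and
#'   `decided_class` (argmax index, ties broken by lowest index).
#' @export
classify <- function(spec, weights, input) {
  p <- drop(forward_posteriors(spec, weights, list(input)))
  structure(list(posteriors = p, decided_class = decide(p)), class = "prediction")
}

#' Decision rule: maximum a-posteriori class
#'
#' @param posteriors Vector of class posterior probabilities.
#' @return Index of the largest posterior; ties go to the lowest index.
#' @export
decide <- function(posteriors) {
  if (any(!is.finite(posteriors))) stop("posteriors must be finite")
  which.max(posteriors)
}

#' Reference forward pass (literal layer equations)
#'
#' Pure-R transcription of the defining equations: the cuboid convolution
#' as an explicit triple sum over the receptive field, bias + ReLU, the
#' max within each pooling window, dense affine maps, and the softmax.
#' Slow by construction; used as the independent oracle for the fast
#' implementation.
#'
#' @inheritParams classify
#' @return A `prediction` (see [classify()]).
#' @export
forward_reference <- function(spec, weights, input) {
  stopifnot(inherits(spec, "network_spec"))
  X <- as_input_cuboid(input, spec)
  depths <- conv_in_depths(spec)
  for (l in seq_along(spec$conv_layers)) {
    cl <- spec$conv_layers[[l]]
    maps <- lapply(seq_len(cl$filters), function(k) {
      f <- array(weights$conv_w[[l]][, k], dim = c(cl$kh, cl$kw, depths[l]))
      cuboid_convolve(X, f, mode = cl$mode) + weights$conv_b[[l]][k]
    })
    X <- array(0, dim = c(dim(maps[[1L]]), cl$filters))
    for (k in seq_len(cl$filters)) X[, , k] <- pmax(maps[[k]], 0)
  }
  if (!is.null(spec$pool)) X <- max_pool(X, spec$pool$size, spec$pool$stride)
  a <- as.vector(X)
  nfc <- length(weights$fc_w)
  for (l in seq_len(nfc)) {
    z <- drop(weights$fc_w[[l]] %*% a) + weights$fc_b[[l]]
    a <- if (l < nfc) {
      switch(spec$hidden_activation,
             sigmoid = 1 / (1 + exp(-z)),
             tanh = tanh(z),
             relu = pmax(z, 0))
    } else {
      e <- exp(z - max(z))
      e / sum(e)
    }
  }
  structure(list(posteriors = a, decided_class = decide(a)), class = "prediction")
}

#' Cuboid convolution of an input with a single filter
#'
#' Correlates an `H x W x Z` input with a `(2a+1) x (2b+1) x Z` filter:
#' each output entry is the triple sum, over the two spatial offsets and
#' the full z-depth, of elementwise products over the receptive field.
#' `mode = "same"` zero-pads to preserve `H x W`; `mode = "valid"` yields
#' `(H - 2a) x (W - 2b)`.
#'
#' @param input Numeric `H x W x Z` array (a matrix is taken as `Z = 1`).
#' @param filter Numeric `(2a+1) x (2b+1) x Z` array with matching depth.
#' @param mode `"valid"` or `"same"`.
#' @return Numeric matrix of filter outputs.
#' @examples
#' cuboid_convolve(array(1, c(4, 4, 2)), array(1, c(3, 3, 2)), "valid")
#' @export
cuboid_convolve <- function(input, filter, mode = c("valid", "same")) {
  mode <- match.arg(mode)
  if (is.matrix(input)) input <- array(input, dim = c(dim(input), 1L))
  if (is.matrix(filter)) filter <- array(filter, dim = c(dim(filter), 1L))
  di <- dim(input); df <- dim(filter)
  if (df[3L] != di[3L]) stop("filter z-depth must equal input z-depth")
  if (any(df[1:2] %% 2 == 0)) stop("filter height and width must be odd")
  a <- (df[1L] - 1L) / 2L; b <- (df[2L] - 1L) / 2L
  if (mode == "same") {
    padded <- array(0, dim = c(di[1L] + 2 * a, di[2L] + 2 * b, di[3L]))
    padded[a + seq_len(di[1L]), b + seq_len(di[2L]), ] <- input
    input <- padded
    di <- dim(input)
  }
  Ho <- di[1L] - df[1L] + 1L; Wo <- di[2L] - df[2L] + 1L
  out <- matrix(0, Ho, Wo)
  for (h in seq_len(Ho)) {
    for (w in seq_len(Wo)) {
      acc <- 0
      for (z in seq_len(di[3L])) {
        for (u in seq_len(df[1L])) {
          for (v in seq_len(df[2L])) {
            acc <- acc + filter[u, v, z] * input[h + u - 1L, w + v - 1L, z]
          }
        }
      }
      out[h, w] <- acc
    }
  }
  out
}

#' Convolution layer: filter bank, bias and ReLU
#'
#' Applies a bank of cuboid filters to an input cuboid, adds one bias per
#' filter and passes the result through the ReLU nonlinearity, stacking
#' the K activation maps into an output cuboid.
#'
#' @param input Numeric `H x W x Z` array (matrix taken as `Z = 1`).
#' @param filters List of K filter arrays, each `(2a+1) x (2b+1) x Z`.
#' @param biases Numeric vector of K biases, one per filter.
#' @param mode `"valid"` or `"same"`.
#' @return `H' x W' x K` array of ReLU activations.
#' @export
conv_layer <- function(input, filters, biases, mode = c("valid", "same")) {
  mode <- match.arg(mode)
  if (length(filters) != length(biases)) {
    stop("one bias per filter required")
  }
  maps <- lapply(seq_along(filters), function(k) {
    pmax(cuboid_convolve(input, filters[[k]], mode) + biases[k], 0)
  })
  out <- array(0, dim = c(dim(maps[[1L]]), length(filters)))
  for (k in seq_along(maps)) out[, , k] <- maps[[k]]
  out
}

#' Channel-wise max pooling
#'
#' Replaces each `size x size` window (at the given stride) of every
#' channel with its maximum. Output height is `(H - size)/stride + 1`,
#' which must be integral.
#'
#' @param input Numeric `H x W x K` array (or matrix, taken as `K = 1`).
#' @param size Pooling window edge length.
#' @param stride Pooling stride.
#' @return Pooled array of the same depth.
#' @export
max_pool <- function(input, size, stride) {
  was_matrix <- is.matrix(input)
  if (was_matrix) input <- array(input, dim = c(dim(input), 1L))
  d <- dim(input)
  if ((d[1L] - size) %% stride != 0L || (d[2L] - size) %% stride != 0L) {
    stop("pooled dimensions (H - size)/stride + 1 are not integral")
  }
  Ho <- (d[1L] - size) %/% stride + 1L
  Wo <- (d[2L] - size) %/% stride + 1L
  out <- array(0, dim = c(Ho, Wo, d[3L]))
  for (k in seq_len(d[3L])) {
    for (h in seq_len(Ho)) {
      for (w in seq_len(Wo)) {
        rows <- (h - 1L) * stride + seq_len(size)
        cols <- (w - 1L) * stride + seq_len(size)
        out[h, w, k] <- max(input[rows, cols, k])
      }
    }
  }
  if (was_matrix && d[3L] == 1L) out[, , 1L] else out
}

#' Training hyperparameters
#'
#' @param learning_rate Step size of the gradient-descent update.
#' @param batch_size Mini-batch size.
#' @param max_epochs Upper bound on training epochs.
#' @param loss_threshold Stop when the epoch-end mean cross-entropy over
#'   the full training set falls below this value (default 0.001).
#' @param optimizer `"adam"` or `"sgd"` (gradient descent with momentum).
#' @param momentum Momentum coefficient for `optimizer = "sgd"`.
#' @param train_noise_variance Gaussian variance of the small perturbation
#'   applied to training exemplars (default 0.001, a "noise-free" training
#'   set with minor variation).
#' @param samples_per_class Number of training exemplars drawn per class.
#' @param seed Integer seed controlling initialisation, exemplar noise and
#'   batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 16, max_epochs = 500,
                         loss_threshold = 0.001, optimizer = c("adam", "sgd"),
                         momentum = 0.9, train_noise_variance = 0.001,
                         samples_per_class = 10, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(loss_threshold > 0, samples_per_class >= 1, max_epochs >= 1,
            learning_rate > 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), loss_threshold = loss_threshold,
                 optimizer = optimizer, momentum = momentum,
                 train_noise_variance = train_noise_variance,
                 samples_per_class = as.integer(samples_per_class),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a network by gradient-descent backpropagation
#'
#' Minimises the softmax cross-entropy by mini-batch backpropagation,
#' stopping when the epoch-end mean cross-entropy over the training set
#' falls below `config$loss_threshold` (or `max_epochs` is reached, in
#' which case the result is flagged as non-converged). Deterministic
#' given `config$seed`.
#'
#' @param spec A [network_spec()].
#' @param inputs List of training inputs conforming to the spec.
#' @param labels Integer class labels in `1..n_classes`.
#' @param config A [train_config()].
#' @param weights Optional initial `network_weights`; by default drawn
#'   with [init_weights()] from `config$seed`.
#' @return A `trained_network`: list with `spec`, `weights`,
#'   `loss_history`, `epochs`, `converged`, `final_loss`,
#'   `train_accuracy`.
#' @export
train_network <- function(spec, inputs, labels, config = train_config(),
                          weights = NULL) {
  stopifnot(inherits(spec, "network_spec"), inherits(config, "train_config"))
  if (length(inputs) == 0L) stop("training set is empty")
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > spec$n_classes)) {
    stop("labels must lie in 1..n_classes")
  }
  if (length(labels) != length(inputs)) stop("one label per input required")
  if (is.null(weights)) weights <- init_weights(spec, seed = config$seed)
  cubes <- lapply(inputs, as_input_cuboid, spec = spec)
  fit <- cnn_train_cpp(cubes, labels, spec_for_cpp(spec), unclass(weights),
                       config$learning_rate, config$batch_size, config$max_epochs,
                       config$loss_threshold, config$optimizer, config$momentum,
                       config$seed)
  structure(list(spec = spec, weights = structure(fit$weights, class = "network_weights"),
                 loss_history = fit$loss_history, epochs = fit$epochs,
                 converged = fit$converged, final_loss = fit$final_loss,
                 train_accuracy = fit$train_accuracy, config = config),
            class = "trained_network")
}

#' Mean cross-entropy and accuracy of a network on a labelled set
#'
#' @param spec,weights Network and conforming weights.
#' @param inputs List of inputs.
#' @param labels Integer labels in `1..n_classes`.
#' @return List with `cross_entropy` (mean over inputs) and `accuracy`.
#' @export
evaluate_network <- function(spec, weights, inputs, labels) {
  p <- forward_posteriors(spec, weights, inputs)
  idx <- cbind(seq_along(labels), as.integer(labels))
  list(cross_entropy = mean(-log(pmax(p[idx], 1e-300))),
       accuracy = mean(max.col(p, ties.method = "first") == labels))
}

#' @export
print.network_spec <- function(x, ...) {
  sh <- layer_shapes(x)
  chain <- vapply(sh, function(d) paste(d, collapse = "x"), character(1))
  cat("<network_spec>\n  ", paste(chain, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' @export
print.trained_network <- function(x, ...) {
  cat(sprintf("<trained_network: %d epochs, final loss %.3g, train accuracy %.3f%s>\n",
              x$epochs, x$final_loss, x$train_accuracy,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
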