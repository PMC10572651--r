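# Per-client multilayer perceptron with a flat parameter vector, trained by
# plain mini-batch gradient descent for exact reproducibility.

#' Describe a multilayer perceptron architecture
#'
#' The local classifier is an MLP over the 8-dimensional Pa/Pd feature
#' vector with a softmax head over the three classes.
#'
#' @param input_dim Input dimension (8 for the feature-vector mode).
#' @param hidden Integer vector of hidden-layer widths; default one layer
#'   of 16 rectifier units.
#' @param n_classes Number of output classes; fixed at 3.
#' @param activation Hidden nonlinearity; only \code{"relu"} is provided.
#' @return Object of class \code{"mlp_architecture"}.
#' @export
mlp_architecture <- function(input_dim = 8L, hidden = 16L, n_classes = 3L,
                             activation = "relu") {
  if (input_dim < 1L) stop("input_dim must be at least 1")
  if (n_classes != 3L) stop("the classifier is three-way; n_classes must be 3")
  if (!identical(activation, "relu")) stop("unsupported activation: ", activation)
  if (any(hidden < 1L)) stop("hidden widths must be positive")
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 n_classes = 3L, activation = "relu"),
            class = "mlp_architecture")
}

layer_dims <- function(arch) {
  c(arch$input_dim, arch$hidden, arch$n_classes)
}

#' Number of trainable parameters implied by an architecture
#'
#' @param arch An \code{mlp_architecture}.
#' @return Integer: sum over layers of fan_in * fan_out + fan_out.
#' @export
n_params <- function(arch) {
  d <- layer_dims(arch)
  sum(d[-length(d)] * d[-1] + d[-1])
}

#' Initialize model parameters
#'
#' Weights are drawn uniformly on \code{[-1/sqrt(fan_in), 1/sqrt(fan_in)]};
#' biases start at zero. Deterministic given the seed.
#'
#' @param arch An \code{mlp_architecture}.
#' @param seed Integer seed.
#' @return Object of class \code{"mlp_params"}: list with \code{flat}
#'   (numeric parameter vector) and \code{arch}.
#' @export
init_params <- function(arch, seed = 1L) {
  d <- layer_dims(arch)
  flat <- with_seed(seed, {
    unlist(lapply(seq_len(length(d) - 1L), function(l) {
      lim <- 1 / sqrt(d[l])
      c(stats::runif(d[l] * d[l + 1], -lim, lim), rep(0, d[l + 1]))
    }))
  })
  mlp_params(flat, arch)
}

#' @rdname init_params
#' @param flat Numeric parameter vector of length \code{n_params(arch)}.
#' @export
mlp_params <- function(flat, arch) {
  if (length(flat) != n_params(arch))
    stop("flat parameter vector has length ", length(flat),
         " but the architecture implies ", n_params(arch))
  if (any(!is.finite(flat))) stop("parameters must be finite")
  structure(list(flat = as.numeric(flat), arch = arch), class = "mlp_params")
}

# Split the flat vector into per-layer weight matrices and bias vectors.
unflatten <- function(params) {
  d <- layer_dims(params$arch)
  out <- vector("list", length(d) - 1L)
  at <- 0L
  for (l in seq_len(length(d) - 1L)) {
    nw <- d[l] * d[l + 1L]
    W <- matrix(params$flat[at + seq_len(nw)], d[l], d[l + 1L])
    b <- params$flat[at + nw + seq_len(d[l + 1L])]
    out[[l]] <- list(W = W, b = b)
    at <- at + nw + d[l + 1L]
  }
  out
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass; returns activations of every layer plus class probabilities.
mlp_forward <- function(layers, x) {
  a <- list(x)
  nl <- length(layers)
  for (l in seq_len(nl)) {
    z <- a[[l]] %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(a[[l]]), length(layers[[l]]$b), byrow = TRUE)
    a[[l + 1L]] <- if (l < nl) pmax(z, 0) else z
  }
  list(a = a, probs = softmax_rows(a[[nl + 1L]]))
}

encode_labels <- function(y) {
  if (is.character(y) || is.factor(y)) {
    yi <- match(as.character(y), class_labels())
    if (any(is.na(yi))) stop("unknown class label in y")
    yi
  } else as.integer(y)
}

#' Softmax cross-entropy loss with L2 penalty
#'
#' @param params An \code{mlp_params}.
#' @param x Feature matrix (rows = cases).
#' @param y Labels (character or integer 1..3).
#' @param l2 Ridge penalty on the weights (biases unpenalized).
#' @return Mean cross-entropy plus \code{l2/2 * sum(W^2)}.
#' @export
mlp_loss <- function(params, x, y, l2 = 0) {
  yi <- encode_labels(y)
  layers <- unflatten(params)
  p <- mlp_forward(layers, x)$probs
  ce <- -mean(log(pmax(p[cbind(seq_len(nrow(x)), yi)], 1e-300)))
  ce + l2 / 2 * sum(vapply(layers, function(L) sum(L$W^2), numeric(1)))
}

mlp_gradient <- function(layers, x, yi, l2) {
  fw <- mlp_forward(layers, x)
  n <- nrow(x)
  nl <- length(layers)
  Y <- matrix(0, n, ncol(fw$probs))
  Y[cbind(seq_len(n), yi)] <- 1
  delta <- (fw$probs - Y) / n
  grads <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    grads[[l]] <- list(W = crossprod(fw$a[[l]], delta) + l2 * layers[[l]]$W,
                       b = colSums(delta))
    if (l > 1L)
      delta <- (delta %*% t(layers[[l]]$W)) * (fw$a[[l]] > 0)
  }
  grads
}

#' Training configuration for local gradient descent
#'
#' @param epochs Passes over the shard (>= 1).
#' @param learning_rate Step size (> 0; 0 is admitted and leaves parameters
#'   untouched, useful for ablations).
#' @param batch_size Mini-batch size; shards smaller than one batch train
#'   full-batch.
#' @param seed Seed for the per-epoch shuffle.
#' @param l2 Ridge penalty on weights.
#' @return List of class \code{"training_config"}.
#' @export
training_config <- function(epochs = 60L, learning_rate = 0.1,
                            batch_size = 16L, seed = 1L, l2 = 1e-4) {
  if (epochs < 1L) stop("epochs must be at least 1")
  if (learning_rate < 0) stop("learning_rate must be nonnegative")
  if (batch_size < 1L) stop("batch_size must be at least 1")
  if (l2 < 0) stop("l2 must be nonnegative")
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), l2 = l2),
            class = "training_config")
}

#' Train the local model on a shard
#'
#' Mini-batch gradient descent on softmax cross-entropy with an L2 weight
#' penalty. The shard order is reshuffled every epoch from
#' \code{cfg$seed}; the trajectory is fully deterministic given the seed
#' and shard order. Features are expected to be standardized with the
#' globally broadcast training statistics (see \code{\link{feature_stats}}).
#'
#' @param params Starting \code{mlp_params}.
#' @param x Feature matrix (rows = cases), standardized.
#' @param y Labels (character or integer 1..3).
#' @param cfg A \code{\link{training_config}}.
#' @return Trained \code{mlp_params}.
#' @export
train_local <- function(params, x, y, cfg) {
  if (!is.matrix(x)) x <- matrix(x, ncol = params$arch$input_dim)
  if (nrow(x) < 1L) stop("shard must be non-empty")
  if (ncol(x) != params$arch$input_dim)
    stop("feature dimension ", ncol(x), " does not match architecture input ",
         params$arch$input_dim)
  yi <- encode_labels(y)
  layers <- unflatten(params)
  n <- nrow(x)
  bs <- min(cfg$batch_size, n)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        g <- mlp_gradient(layers, x[idx, , drop = FALSE], yi[idx], cfg$l2)
        for (l in seq_along(layers)) {
          layers[[l]]$W <- layers[[l]]$W - cfg$learning_rate * g[[l]]$W
          layers[[l]]$b <- layers[[l]]$b - cfg$learning_rate * g[[l]]$b
        }
      }
      if (any(!vapply(layers, function(L) all(is.finite(L$W)) && all(is.finite(L$b)),
                      logical(1))))
        stop("training diverged (non-finite parameters); lower the learning rate")
    }
  })
  flat <- unlist(lapply(layers, function(L) c(as.numeric(L$W), L$b)))
  mlp_params(flat, params$arch)
}

#' Predict class labels and probabilities
#'
#' Softmax probabilities sum to one; the label is the argmax, ties broken
#' toward the earlier label in declared order.
#'
#' @param object An \code{mlp_params}.
#' @param x Feature matrix or single feature vector (standardized).
#' @param ... Unused.
#' @return List with \code{label} (character) and \code{probs}
#'   (n x 3 matrix, columns in \code{class_labels()} order).
#' @export
predict.mlp_params <- function(object, x, ...) {
  if (!is.matrix(x)) x <- matrix(x, ncol = object$arch$input_dim)
  if (ncol(x) != object$arch$input_dim)
    stop("feature dimension ", ncol(x), " does not match architecture input ",
         object$arch$input_dim)
  p <- mlp_forward(unflatten(object), x)$probs
  colnames(p) <- class_labels()
  list(label = class_labels()[apply(p, 1, which.max)], probs = p)
}

#' @export
print.mlp_params <- function(x, ...) {
  cat("MLP parameters:", length(x$flat), "values; layers",
      paste(layer_dims(x$arch), collapse = "-"), "\n")
  invisible(x)
}

#' Standardization statistics broadcast to clients
#'
#' Per-feature mean and standard deviation computed once on the pooled
#' training features; constant features get sd 1 so standardization is a
#' no-op for them.
#'
#' @param x Training feature matrix.
#' @return List with \code{mean} and \code{sd} vectors.
#' @export
feature_stats <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mean = m, sd = s)
}

#' @rdname feature_stats
#' @param stats_ Statistics from \code{feature_stats}.
#' @export
standardize_features <- function(x, stats_) {
  if (!is.matrix(x)) x <- matrix(x, ncol = length(stats_$mean))
  sweep(sweep(x, 2, stats_$mean, "-"), 2, stats_$sd, "/")
}

#' Write / read model parameters
#'
#' The flat vector is stored as plain text alongside a JSON sidecar
#' describing the architecture (format version 1).
#'
#' @param params An \code{mlp_params}.
#' @param path Base path; \code{<path>.txt} and \code{<path>.json} are
#'   written.
#' @export
write_params <- function(params, path) {
  writeLines(format(params$flat, digits = 17), paste0(path, ".txt"))
  jsonlite::write_json(
    list(format_version = 1L,
         input_dim = params$arch$input_dim,
         hidden = I(params$arch$hidden),
         n_classes = params$arch$n_classes,
         activation = params$arch$activation),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(as.integer(meta$format_version), 1L))
    stop("unsupported parameter format version")
  arch <- mlp_architecture(meta$input_dim, as.integer(meta$hidden),
                           meta$n_classes, meta$activation)
  mlp_params(as.numeric(readLines(paste0(path, ".txt"))), arch)
}
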