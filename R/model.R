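#' Configuration of the 1-D convolutional hot-spot classifier
#'
#' The reference architecture has three convolution blocks (64, 16 and 4
#' kernels of sizes 7, 5 and 3; 'same' padding; ReLU; max-pooling of size 2),
#' one dropout of rate 0.5, an 8-unit fully connected ReLU layer and a single
#' sigmoid output, trained with RMSprop on binary cross-entropy with early
#' stopping on validation F1. `n_conv_layers` other than 3 follow the
#' copy-layer-2 rule (see [resolve_depth()]). Training-loop settings the
#' architecture leaves open (epochs, patience, batch size, learning rate)
#' default to the values below and are recorded on the object.
#'
#' @param n_conv_layers Number of convolution blocks, 2-5 (default 3).
#' @param filters,kernel_sizes Optional explicit per-layer settings; both
#'   must have length `n_conv_layers`. When `NULL`, [resolve_depth()]
#'   derives them from the three-layer reference.
#' @param pool_size Max-pooling width (default 2).
#' @param activation Only `"relu"` is implemented.
#' @param dropout_rate Dropout after the last pooling block, in \[0, 1)
#'   (default 0.5).
#' @param dense_units Width of the fully connected layer (default 8).
#' @param learning_rate RMSprop learning rate (default 0.001).
#' @param max_epochs Training epoch cap (default 200).
#' @param patience Early-stopping patience in epochs without validation-F1
#'   improvement (default 20).
#' @param batch_size Minibatch size (default 32).
#' @param seed Integer seed for weight initialization, shuffling and
#'   dropout.
#' @return An object of class `cnn1d_config`.
#' @export
cnn_config <- function(n_conv_layers = 3L, filters = NULL, kernel_sizes = NULL,
                       pool_size = 2L, activation = "relu",
                       dropout_rate = 0.5, dense_units = 8L,
                       learning_rate = 0.001, max_epochs = 200L,
                       patience = 20L, batch_size = 32L, seed = 1L) {
  n_conv_layers <- as.integer(n_conv_layers)
  if (!identical(activation, "relu")) {
    abort("Only the 'relu' activation is implemented.")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1).")
  }
  if (pool_size < 1L) abort("`pool_size` must be >= 1.")
  cfg <- structure(
    list(
      n_conv_layers = n_conv_layers, filters = filters,
      kernel_sizes = kernel_sizes, pool_size = as.integer(pool_size),
      activation = activation, dropout_rate = dropout_rate,
      dense_units = as.integer(dense_units),
      learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
      patience = as.integer(patience), batch_size = as.integer(batch_size),
      seed = as.integer(seed)
    ),
    class = "cnn1d_config"
  )
  resolve_depth(cfg)
}

#' Resolve per-layer filters and kernel sizes for a requested depth
#'
#' Depth 3 is the reference: filters (64, 16, 4), kernels (7, 5, 3). Deeper
#' variants insert copies of the second layer (16 filters, kernel 5) before
#' the last block; the two-layer variant drops the second layer so the entry
#' and exit blocks keep their shapes.
#'
#' @param cfg A `cnn1d_config`.
#' @return The config with `filters` and `kernel_sizes` filled in and
#'   validated.
#' @export
resolve_depth <- function(cfg) {
  stopifnot(inherits(cfg, "cnn1d_config"))
  d <- cfg$n_conv_layers
  if (!d %in% 2:5) abort("`n_conv_layers` must be one of 2, 3, 4, 5.")
  if (is.null(cfg$filters) != is.null(cfg$kernel_sizes)) {
    abort("Provide both `filters` and `kernel_sizes`, or neither.")
  }
  if (is.null(cfg$filters)) {
    mid <- d - 2L
    cfg$filters <- as.integer(c(64L, rep(16L, mid), 4L))
    cfg$kernel_sizes <- as.integer(c(7L, rep(5L, mid), 3L))
  } else {
    if (length(cfg$filters) != d || length(cfg$kernel_sizes) != d) {
      abort(sprintf(
        "`filters` and `kernel_sizes` must each have length %d", d
      ))
    }
    cfg$filters <- as.integer(cfg$filters)
    cfg$kernel_sizes <- as.integer(cfg$kernel_sizes)
  }
  if (any(cfg$kernel_sizes %% 2L == 0L)) {
    abort("Kernel sizes must be odd for length-preserving 'same' padding.")
  }
  cfg
}

#' @export
print.cnn1d_config <- function(x, ...) {
  cat(sprintf(
    "<cnn1d_config> %d conv blocks: filters (%s), kernels (%s), pool %d, dropout %.2f, dense %d\n",
    x$n_conv_layers, paste(x$filters, collapse = ", "),
    paste(x$kernel_sizes, collapse = ", "), x$pool_size, x$dropout_rate,
    x$dense_units
  ))
  invisible(x)
}

#' Build (and initialize) the 1-D CNN for a given input shape
#'
#' Verifies the window survives the pooling cascade, derives all layer
#' shapes and the trainable-parameter count, and initializes weights
#' (Glorot-uniform, zero biases) deterministically under `cfg$seed`.
#'
#' @param cfg A [cnn_config()].
#' @param width Window width (positions per example).
#' @param dim Per-residue feature dimension D.
#' @return An object of class `cnn1d` with elements `config`, `width`,
#'   `dim`, `pooled_lengths`, `n_params` and `weights`.
#' @export
build_cnn <- function(cfg, width, dim) {
  stopifnot(inherits(cfg, "cnn1d_config"))
  width <- as.integer(width); dim <- as.integer(dim)
  L <- width
  pooled <- integer(cfg$n_conv_layers)
  for (l in seq_len(cfg$n_conv_layers)) {
    L <- L %/% cfg$pool_size
    pooled[l] <- L
    if (L < 1L) {
      abort(sprintf(
        "Window width %d is pooled away after %d blocks; need width >= %d",
        width, l, cfg$pool_size^cfg$n_conv_layers
      ))
    }
  }
  flat <- pooled[cfg$n_conv_layers] * cfg$filters[cfg$n_conv_layers]

  weights <- with_seed(cfg$seed, {
    cin <- dim
    conv <- vector("list", cfg$n_conv_layers)
    for (l in seq_len(cfg$n_conv_layers)) {
      k <- cfg$kernel_sizes[l]; f <- cfg$filters[l]
      conv[[l]] <- list(
        W = glorot_uniform(k * cin, f, fan_in = k * cin, fan_out = k * f),
        b = numeric(f), k = k
      )
      cin <- f
    }
    list(
      conv = conv,
      dense1 = list(
        W = glorot_uniform(flat, cfg$dense_units, flat, cfg$dense_units),
        b = numeric(cfg$dense_units)
      ),
      dense2 = list(
        W = glorot_uniform(cfg$dense_units, 1L, cfg$dense_units, 1L),
        b = numeric(1L)
      )
    )
  })

  model <- structure(
    list(config = cfg, width = width, dim = dim, pooled_lengths = pooled,
         weights = weights),
    class = "cnn1d"
  )
  model$n_params <- count_params(model)
  model
}

#' Trainable-parameter count of a model
#'
#' @param model A `cnn1d`.
#' @return Integer number of trainable parameters.
#' @export
count_params <- function(model) {
  sum(vapply(
    param_paths(model$weights),
    function(p) length(get_param(model$weights, p)),
    numeric(1)
  ))
}

#' @export
print.cnn1d <- function(x, ...) {
  cat(sprintf(
    "<cnn1d> input %d x %d, %d conv blocks (pooled lengths %s), %d parameters\n",
    x$width, x$dim, x$config$n_conv_layers,
    paste(x$pooled_lengths, collapse = " -> "), x$n_params
  ))
  invisible(x)
}
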