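# CNN feature encoder. Trained with a softmax head by mini-batch
# backpropagation (Adam); at prediction time the 256-d output of the first
# linear FC layer -- the "code" -- is handed to the Gaussian naive Bayes
# classifier. Ablation variants remove exactly one named layer.

#' Encoder configuration
#'
#' Architecture (full variant): convolution with `channels` 1-d kernels of
#' size `1 x kernel` ('same' zero padding, so a width-1024 input yields a
#' 16 x 1024 map) -> ReLU FC hidden layer of the same size -> max-pool
#' `1 x 2` stride 2 -> linear FC to the `code_dim`-d code -> dropout ->
#' linear FC to 2 -> softmax.
#'
#' @param channels Convolution kernels (default 16).
#' @param kernel Kernel width (odd; default 3).
#' @param code_dim Width of the intermediate code (default 256).
#' @param dropout Dropout probability on the code during training
#'   (inverted dropout; default 0.5).
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param patience Early stop after this many epochs without a relative
#'   training-loss improvement of at least `min_improve`.
#' @param min_improve Relative loss-improvement threshold for the plateau
#'   rule.
#' @param fc_hidden `"per_position"` (default): the 16 x 1024 ReLU hidden
#'   layer is a channel-mixing map shared across positions (1x1-conv-like);
#'   `"dense"`: a fully dense map over the flattened 16 x 1024 input.
#' @param standardize Z-score features column-wise before training.
#' @param variant One of [encoder_variants()].
#' @param seed Integer seed (initialization, shuffling, dropout).
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(channels = 16L, kernel = 3L, code_dim = 256L,
                           dropout = 0.5, epochs = 100L, batch_size = 32L,
                           learning_rate = 1e-3, patience = 5L,
                           min_improve = 1e-3,
                           fc_hidden = c("per_position", "dense"),
                           standardize = FALSE,
                           variant = "full", seed = 1L) {
  fc_hidden <- match.arg(fc_hidden)
  check_scalar_number(dropout, "dropout", lower = 0)
  if (dropout >= 1) abort_config("`dropout` must be in [0, 1)")
  kernel <- check_count(kernel, "kernel", 1L)
  if (kernel %% 2L == 0L) abort_config("`kernel` must be odd")
  cfg <- structure(
    list(
      channels = check_count(channels, "channels", 1L),
      kernel = kernel,
      code_dim = check_count(code_dim, "code_dim", 2L),
      dropout = dropout,
      epochs = check_count(epochs, "epochs", 1L),
      batch_size = check_count(batch_size, "batch_size", 1L),
      learning_rate = learning_rate,
      patience = check_count(patience, "patience", 1L),
      min_improve = check_scalar_number(min_improve, "min_improve", lower = 0),
      fc_hidden = fc_hidden,
      standardize = isTRUE(standardize),
      variant = variant,
      seed = check_count(seed, "seed", 0L)
    ),
    class = "encoder_config"
  )
  build_variant(cfg, variant)
}

#' Ablation variants
#'
#' `"relu_fc_ablation"` removes the ReLU FC hidden layer (conv feeds the
#' pool directly), `"pool_ablation"` removes the max-pool (the code FC
#' consumes the full 16 x 1024 map), `"conv_ablation"` removes the
#' convolution (the raw input feeds a width-matched dense ReLU FC). The
#' 256-d code and the softmax head are kept in every variant.
#'
#' @return Character vector of valid variant names.
#' @export
encoder_variants <- function() {
  c("full", "relu_fc_ablation", "pool_ablation", "conv_ablation")
}

#' Set the architecture variant of an encoder configuration
#'
#' @param cfg An [encoder_config()].
#' @param variant One of [encoder_variants()].
#' @return The configuration with the variant applied.
#' @export
build_variant <- function(cfg, variant) {
  if (!variant %in% encoder_variants()) {
    abort_config(sprintf(
      "unknown variant `%s` (expected one of: %s)",
      variant, paste(encoder_variants(), collapse = ", ")
    ))
  }
  cfg$variant <- variant
  cfg
}

# config + input width -> the list consumed by the C++ core
cfg_to_cpp <- function(cfg, W) {
  list(
    W = as.integer(W),
    channels = cfg$channels,
    kernel = cfg$kernel,
    code_dim = cfg$code_dim,
    dropout = cfg$dropout,
    has_conv = cfg$variant != "conv_ablation",
    has_fc = cfg$variant != "relu_fc_ablation",
    has_pool = cfg$variant != "pool_ablation",
    fc_dense = cfg$fc_hidden == "dense"
  )
}

as_feature_matrix <- function(x) {
  if (inherits(x, "feature_table")) x$features else as.matrix(x)
}

#' Number of learnable parameters of an encoder architecture
#'
#' @param cfg An [encoder_config()].
#' @param width Input feature width.
#' @return Integer parameter count.
#' @export
encoder_n_params <- function(cfg, width) {
  cpp_enc_nparams(cfg_to_cpp(cfg, width))
}

#' Initial (untrained) parameter vector
#'
#' Glorot-uniform weights, zero biases, seeded from `cfg$seed`.
#'
#' @inheritParams encoder_n_params
#' @return Numeric parameter vector.
#' @export
encoder_init <- function(cfg, width) {
  cpp_enc_init(cfg_to_cpp(cfg, width), cfg$seed)
}

#' Loss and analytic gradient of the encoder's softmax head
#'
#' Mean cross-entropy over the batch and its gradient with respect to the
#' flat parameter vector, with dropout disabled (the deterministic path the
#' finite-difference checks exercise).
#'
#' @param theta Flat parameter vector (see [encoder_init()]).
#' @param x Feature matrix (rows = examples).
#' @param labels Binary labels (1 = disease-associated).
#' @param cfg An [encoder_config()].
#' @return List with `loss` (scalar) and `grad` (vector like `theta`).
#' @export
encoder_loss_gradient <- function(theta, x, labels, cfg = encoder_config()) {
  x <- as_feature_matrix(x)
  y <- as_binary_labels(labels)
  cpp_enc_loss_grad(theta, cfg_to_cpp(cfg, ncol(x)), x, y)
}

#' Train the CNN feature encoder
#'
#' Minimizes the cross-entropy of the softmax head by mini-batch
#' backpropagation (Adam), with inverted dropout on the code and early
#' stopping when the training loss plateaus. Deterministic given
#' `cfg$seed`.
#'
#' @param x Feature matrix or `feature_table` (rows = miRNAs).
#' @param labels Binary labels, 1 = disease-associated.
#' @param cfg An [encoder_config()].
#' @return A `trained_encoder` holding the parameters, the per-epoch
#'   training-loss trace, and the input width.
#' @export
train_encoder <- function(x, labels, cfg = encoder_config()) {
  x <- as_feature_matrix(x)
  y <- as_binary_labels(labels)
  if (length(y) != nrow(x)) abort_shape("one label per feature row is required")
  if (min(table(factor(y, levels = c(0, 1)))) < 2) {
    abort_config("need at least 2 examples of each class to train")
  }
  center <- NULL
  scale <- NULL
  if (cfg$standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale, "/")
  }
  res <- cpp_enc_train(
    cfg_to_cpp(cfg, ncol(x)), x, y, cfg$epochs, cfg$batch_size,
    cfg$learning_rate, cfg$patience, cfg$min_improve, cfg$seed
  )
  structure(
    list(
      theta = res$theta, cfg = cfg, width = ncol(x),
      loss_trace = res$loss_trace, epochs_run = res$epochs_run,
      center = center, scale = scale
    ),
    class = "trained_encoder"
  )
}

prep_input <- function(encoder, x) {
  x <- as_feature_matrix(x)
  if (ncol(x) != encoder$width) {
    abort_shape(sprintf(
      "input width %d does not match the encoder's %d",
      ncol(x), encoder$width
    ))
  }
  if (!is.null(encoder$center)) {
    x <- sweep(sweep(x, 2, encoder$center), 2, encoder$scale, "/")
  }
  x
}

#' Encoder forward pass
#'
#' @param encoder A `trained_encoder`.
#' @param x Feature matrix or `feature_table`.
#' @param train_mode Apply dropout (as during training). Off by default:
#'   evaluation is a pure function of the input.
#' @param seed Dropout seed when `train_mode = TRUE`.
#' @return List with `probabilities` (n x 2, columns `negative`,
#'   `positive`; rows sum to 1) and `code` (n x code_dim, pre-dropout).
#' @export
encoder_forward <- function(encoder, x, train_mode = FALSE, seed = 1L) {
  stopifnot(inherits(encoder, "trained_encoder"))
  x <- prep_input(encoder, x)
  res <- cpp_enc_forward(
    encoder$theta, cfg_to_cpp(encoder$cfg, encoder$width),
    x, train_mode, as.integer(seed)
  )
  # exact double-precision normalization on top of the float softmax
  res$probs <- res$probs / rowSums(res$probs)
  colnames(res$probs) <- c("negative", "positive")
  list(probabilities = res$probs, code = res$code)
}

#' Extract the 256-d intermediate code
#'
#' Output of the first linear FC layer with dropout inactive; deterministic
#' per input.
#'
#' @inheritParams encoder_forward
#' @return `n x code_dim` numeric matrix.
#' @export
encode <- function(encoder, x) {
  encoder_forward(encoder, x, train_mode = FALSE)$code
}

#' @export
print.trained_encoder <- function(x, ...) {
  cat(sprintf(
    "<trained_encoder> variant=%s width=%d params=%d epochs=%d final_loss=%.4f\n",
    x$cfg$variant, x$width, length(x$theta), x$epochs_run,
    x$loss_trace[length(x$loss_trace)]
  ))
  invisible(x)
}

#' @describeIn train_encoder Per-epoch training loss as a tibble.
#' @param x A `trained_encoder`.
#' @param ... Unused.
#' @export
tidy.trained_encoder <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' @describeIn train_encoder One-row training summary.
#' @export
glance.trained_encoder <- function(x, ...) {
  tibble::tibble(
    variant = x$cfg$variant, width = x$width,
    n_parameters = length(x$theta), epochs_run = x$epochs_run,
    final_loss = x$loss_trace[length(x$loss_trace)]
  )
}

#' @describeIn train_encoder Training-loss curve.
#' @param object A `trained_encoder`.
#' @export
autoplot.trained_encoder <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training cross-entropy") +
    ggplot2::theme_minimal()
}

#' Save / load a trained encoder as portable JSON
#'
#' @param encoder A `trained_encoder`.
#' @param path Output path.
#' @return `path` invisibly; `read_encoder()` returns the object.
#' @export
write_encoder <- function(encoder, path) {
  stopifnot(inherits(encoder, "trained_encoder"))
  payload <- list(
    cfg = unclass(encoder$cfg), width = encoder$width,
    theta = encoder$theta, loss_trace = encoder$loss_trace,
    epochs_run = encoder$epochs_run,
    center = encoder$center, scale = encoder$scale
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_encoder
#' @export
read_encoder <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(encoder_config, p$cfg[setdiff(names(p$cfg), "variant")])
  cfg <- build_variant(cfg, p$cfg$variant)
  structure(
    list(
      theta = as.numeric(p$theta), cfg = cfg, width = as.integer(p$width),
      loss_trace = as.numeric(p$loss_trace),
      epochs_run = as.integer(p$epochs_run),
      center = if (length(p$center)) as.numeric(p$center) else NULL,
      scale = if (length(p$scale)) as.numeric(p$scale) else NULL
    ),
    class = "trained_encoder"
  )
}
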