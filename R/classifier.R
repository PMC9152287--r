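# Gaussian naive Bayes over the encoder codes -- the final prediction
# stage. Per-class feature independence with Gaussian likelihoods; variance
# smoothing follows the common default: eps = 1e-9 * max over features of
# the pooled per-feature variance.

#' Fit Gaussian naive Bayes
#'
#' Priors are class frequencies; per-class means and (maximum-likelihood)
#' variances are sample moments; `eps = var_smoothing * max_j Var(x_j)` is
#' added to every variance so constant features stay well-defined.
#'
#' @param codes Numeric matrix, rows = examples (typically the 256-d codes).
#' @param labels Binary labels, 1 = disease-associated.
#' @param var_smoothing Smoothing factor (default 1e-9).
#' @return A `gaussian_nb` model with `priors`, `means`, `variances`,
#'   `eps`.
#' @export
fit_gaussian_nb <- function(codes, labels, var_smoothing = 1e-9) {
  codes <- as.matrix(codes)
  y <- as_binary_labels(labels)
  if (length(y) != nrow(codes)) abort_shape("one label per code row is required")
  if (length(unique(y)) < 2) {
    abort_config("both classes must be present to fit the classifier")
  }
  classes <- c(0L, 1L)
  ml_var <- function(m) colMeans(m^2) - colMeans(m)^2
  means <- do.call(rbind, lapply(classes, function(k) {
    colMeans(codes[y == k, , drop = FALSE])
  }))
  vars <- do.call(rbind, lapply(classes, function(k) {
    ml_var(codes[y == k, , drop = FALSE])
  }))
  eps <- var_smoothing * max(ml_var(codes))
  structure(
    list(
      priors = setNames(as.numeric(table(factor(y, classes))) / length(y), classes),
      means = means, variances = vars + eps, eps = eps,
      classes = classes
    ),
    class = "gaussian_nb"
  )
}

#' Posterior probabilities from a Gaussian naive Bayes model
#'
#' Computed in log space with a log-sum-exp normalization, so posteriors
#' are finite and rows sum to 1 for any finite input.
#'
#' @param object A `gaussian_nb` model.
#' @param newdata Numeric matrix with the model's feature width.
#' @param type `"prob"` for the n x 2 posterior matrix (columns `"0"`,
#'   `"1"`), `"class"` for 0/1 labels at the 0.5 threshold.
#' @param ... Unused.
#' @return Matrix of posteriors or integer class vector.
#' @export
predict.gaussian_nb <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$means)) {
    abort_shape(sprintf(
      "feature width %d does not match the model's %d",
      ncol(newdata), ncol(object$means)
    ))
  }
  loglik <- vapply(seq_along(object$classes), function(k) {
    mu <- object$means[k, ]
    v <- object$variances[k, ]
    # sum_j log N(x_j | mu_j, v_j)
    -0.5 * colSums((t(newdata) - mu)^2 / v) -
      0.5 * sum(log(2 * pi * v)) + log(object$priors[k])
  }, numeric(nrow(newdata)))
  loglik <- matrix(loglik, nrow = nrow(newdata))
  mx <- apply(loglik, 1, max)
  post <- exp(loglik - mx)
  post <- post / rowSums(post)
  colnames(post) <- as.character(object$classes)
  if (type == "class") {
    return(as.integer(post[, "1"] >= 0.5))
  }
  post
}

#' @export
print.gaussian_nb <- function(x, ...) {
  cat(sprintf(
    "<gaussian_nb> %d features, priors = (%.3f, %.3f), eps = %.3g\n",
    ncol(x$means), x$priors[1], x$priors[2], x$eps
  ))
  invisible(x)
}

#' @describeIn fit_gaussian_nb Per-class, per-feature moments.
#' @param x A `gaussian_nb`.
#' @param ... Unused.
#' @export
tidy.gaussian_nb <- function(x, ...) {
  d <- ncol(x$means)
  tibble::tibble(
    class = rep(x$classes, each = d),
    feature = rep(seq_len(d), 2),
    mean = c(t(x$means)[, 1], t(x$means)[, 2]),
    variance = c(t(x$variances)[, 1], t(x$variances)[, 2])
  )
}

#' @describeIn fit_gaussian_nb One-row model summary.
#' @export
glance.gaussian_nb <- function(x, ...) {
  tibble::tibble(
    n_features = ncol(x$means),
    prior_negative = x$priors[["0"]],
    prior_positive = x$priors[["1"]],
    eps = x$eps
  )
}

#' Save / load a Gaussian naive Bayes model as portable JSON
#'
#' @param model A `gaussian_nb`.
#' @param path Output path.
#' @return `path` invisibly; `read_gaussian_nb()` returns the model.
#' @export
write_gaussian_nb <- function(model, path) {
  stopifnot(inherits(model, "gaussian_nb"))
  jsonlite::write_json(
    list(
      priors = as.numeric(model$priors), means = model$means,
      variances = model$variances, eps = model$eps
    ),
    path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_gaussian_nb
#' @export
read_gaussian_nb <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      priors = setNames(as.numeric(p$priors), c(0L, 1L)),
      means = as.matrix(p$means), variances = as.matrix(p$variances),
      eps = as.numeric(p$eps), classes = c(0L, 1L)
    ),
    class = "gaussian_nb"
  )
}
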