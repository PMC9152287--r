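# The experimental protocol: negative sampling at a configurable ratio,
# stratified five-fold cross-validation of the encoder + GaussianNB stack,
# per-fold ROC-AUC / PR-AUC / F1, and candidate ranking. Embeddings are
# computed once per dataset, not per fold: labels play no role in the
# unsupervised embedding stage, so folds stay leakage-free.

#' Experiment configuration
#'
#' @param negative_ratio Positive multiple for negative sampling
#'   (2, 10, 20, 30, 40, 50, ...) or `"all"` for the whole unlabeled pool.
#' @param folds Cross-validation folds (default 5).
#' @param feature_source `"both"`, `"similarity_only"` or
#'   `"interaction_only"` (the single-network comparison design).
#' @param variant Encoder ablation variant, see [encoder_variants()].
#' @param seed Integer seed driving negative sampling, fold assignment and
#'   the per-fold encoder seeds.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(negative_ratio = "all", folds = 5L,
                              feature_source = c("both", "similarity_only", "interaction_only"),
                              variant = "full", seed = 1L) {
  feature_source <- match.arg(feature_source)
  if (!identical(negative_ratio, "all")) {
    check_scalar_number(negative_ratio, "negative_ratio",
      lower = 0,
      strict_lower = TRUE
    )
  }
  if (!variant %in% encoder_variants()) {
    abort_config(sprintf("unknown variant `%s`", variant))
  }
  structure(
    list(
      negative_ratio = negative_ratio,
      folds = check_count(folds, "folds", 2L),
      feature_source = feature_source,
      variant = variant,
      seed = check_count(seed, "seed", 0L)
    ),
    class = "experiment_config"
  )
}

# positives/negatives resolved against the feature table -> design list
build_design <- function(features, labels, cfg) {
  stopifnot(inherits(features, "feature_table"), inherits(labels, "label_set"))
  pos <- features$ids[id_key(features$ids) %in% id_key(labels$positives)]
  if (length(pos) == 0) abort_config("no positive miRNA has features")
  unlab <- setdiff(features$ids, pos)
  neg <- sample_negatives(unlab, length(pos), cfg$negative_ratio, cfg$seed)
  ids <- c(pos, neg)
  list(
    ids = ids,
    y = c(rep(1L, length(pos)), rep(0L, length(neg))),
    x = apply_feature_source(features, cfg$feature_source)$features[ids, , drop = FALSE]
  )
}

#' Run one cross-validated experiment
#'
#' Samples negatives, splits positives + negatives into stratified folds,
#' and for each fold trains the encoder on the training split, encodes
#' train and test, fits Gaussian naive Bayes on the training codes and
#' scores the held-out miRNAs. Hard labels for F1 use the 0.5 posterior
#' threshold.
#'
#' @param features A `feature_table` from [mirdap_features()].
#' @param labels A [label_set].
#' @param cfg An [experiment_config()].
#' @param encoder An [encoder_config()]; its `variant` is overridden by
#'   `cfg$variant` and its seed is re-derived per fold from `cfg$seed`.
#' @return A `metrics_report` with per-fold metrics, fold score tables and
#'   the configuration echo.
#' @export
run_experiment <- function(features, labels, cfg = experiment_config(),
                           encoder = encoder_config()) {
  design <- build_design(features, labels, cfg)
  encoder <- build_variant(encoder, cfg$variant)
  folds <- kfold_split(design$y, k = cfg$folds, seed = cfg$seed)
  per_fold <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    tr <- folds[[i]]$train
    te <- folds[[i]]$test
    enc_cfg <- encoder
    enc_cfg$seed <- (cfg$seed %% 10000019L) * 131L + i # keep within int range
    enc <- train_encoder(design$x[tr, , drop = FALSE], design$y[tr], enc_cfg)
    nb <- fit_gaussian_nb(encode(enc, design$x[tr, , drop = FALSE]), design$y[tr])
    post <- predict(nb, encode(enc, design$x[te, , drop = FALSE]))[, "1"]
    per_fold[[i]] <- tibble::tibble(
      fold = i, id = design$ids[te],
      score = as.numeric(post), label = design$y[te]
    )
  }
  scores <- dplyr::bind_rows(per_fold)
  metrics <- dplyr::summarise(
    dplyr::group_by(scores, .data$fold),
    roc_auc = roc_auc(.data$score, .data$label),
    pr_auc = pr_auc(.data$score, .data$label),
    f1 = f1_score(as.integer(.data$score >= 0.5), .data$label),
    .groups = "drop"
  )
  structure(
    list(metrics = metrics, scores = scores, config = cfg, encoder = encoder),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<metrics_report> ratio=%s source=%s variant=%s folds=%d\n",
    as.character(x$config$negative_ratio), x$config$feature_source,
    x$config$variant, nrow(x$metrics)
  ))
  cat(sprintf(
    "  mean ROC-AUC %.4f | PR-AUC %.4f | F1 %.4f\n",
    g$mean_roc_auc, g$mean_pr_auc, g$mean_f1
  ))
  invisible(x)
}

#' @describeIn run_experiment Per-fold metrics.
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
tidy.metrics_report <- function(x, ...) x$metrics

#' @describeIn run_experiment One-row summary: arithmetic means of the
#'   fold metrics plus the configuration echo.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    negative_ratio = as.character(x$config$negative_ratio),
    feature_source = x$config$feature_source,
    variant = x$config$variant,
    seed = x$config$seed,
    folds = nrow(x$metrics),
    mean_roc_auc = mean(x$metrics$roc_auc),
    mean_pr_auc = mean(x$metrics$pr_auc),
    mean_f1 = mean(x$metrics$f1)
  )
}

# per-fold curves interpolated on a fixed 101-point grid
report_curves <- function(x, type = c("roc", "pr")) {
  type <- match.arg(type)
  grid <- seq(0, 1, length.out = 101)
  folds <- split(x$scores, x$scores$fold)
  rows <- lapply(folds, function(f) {
    o <- order(f$score, decreasing = TRUE)
    y <- f$label[o]
    tp <- cumsum(y)
    fp <- cumsum(1 - y)
    if (type == "roc") {
      xs <- c(0, fp / max(1, sum(1 - y)))
      ys <- c(0, tp / max(1, sum(y)))
      tibble::tibble(
        fold = f$fold[1], x = grid,
        y = stats::approx(xs, ys, xout = grid, ties = max, rule = 2)$y
      )
    } else {
      rec <- tp / max(1, sum(y))
      prec <- tp / seq_along(y)
      tibble::tibble(
        fold = f$fold[1], x = grid,
        y = stats::approx(c(0, rec), c(1, prec),
          xout = grid,
          ties = max, rule = 2
        )$y
      )
    }
  })
  dplyr::bind_rows(rows)
}

#' @describeIn run_experiment Mean ROC or PR curve across folds with a
#'   +/- one standard deviation band.
#' @param object A `metrics_report`.
#' @param type `"roc"` or `"pr"`.
#' @export
autoplot.metrics_report <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  cur <- report_curves(object, type)
  agg <- dplyr::summarise(
    dplyr::group_by(cur, .data$x),
    mean = mean(.data$y), sd = stats::sd(.data$y), .groups = "drop"
  )
  labs <- if (type == "roc") {
    c("false positive rate", "true positive rate")
  } else {
    c("recall", "precision")
  }
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$x, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = pmax(0, .data$mean - .data$sd),
        ymax = pmin(1, .data$mean + .data$sd)
      ),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::theme_minimal()
}

#' Run a grid of experiments
#'
#' Cross product of ratios, feature sources, variants and seeds; one
#' glance row per combination (the shape of the published summary tables).
#'
#' @inheritParams run_experiment
#' @param ratios List/vector of negative ratios (numbers or `"all"`).
#' @param feature_sources Character vector of feature sources.
#' @param variants Character vector of encoder variants.
#' @param seeds Integer vector of experiment seeds.
#' @return Tibble with one row per (ratio, source, variant, seed).
#' @export
run_experiments <- function(features, labels, ratios = list("all"),
                            feature_sources = "both", variants = "full",
                            seeds = 1L, encoder = encoder_config()) {
  combos <- expand.grid(
    ratio = seq_along(ratios), source = feature_sources,
    variant = variants, seed = seeds, stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cfg <- experiment_config(
      negative_ratio = ratios[[combos$ratio[i]]],
      feature_source = combos$source[i],
      variant = combos$variant[i],
      seed = combos$seed[i]
    )
    glance(run_experiment(features, labels, cfg, encoder))
  })
  dplyr::bind_rows(rows)
}

#' Rank unlabeled miRNAs by predicted disease association
#'
#' Trains the encoder + GaussianNB stack on all positives plus sampled
#' negatives, then scores every unlabeled miRNA with its positive-class
#' posterior. Training positives are excluded from the ranking; ties are
#' broken by id so runs are reproducible.
#'
#' @inheritParams run_experiment
#' @param ratio Negative-sampling ratio for the training negatives
#'   (default `"all"`).
#' @param top_k Keep the `top_k` highest-probability candidates (`NULL` =
#'   all).
#' @param seed Integer seed.
#' @return Tibble `(rank, mirna, probability)` in descending probability.
#' @export
rank_candidates <- function(features, labels, encoder = encoder_config(),
                            ratio = "all", top_k = NULL, seed = 1L) {
  cfg <- experiment_config(negative_ratio = ratio, seed = seed)
  design <- build_design(features, labels, cfg)
  enc_cfg <- encoder
  enc_cfg$seed <- (seed %% 10000019L) * 131L
  enc <- train_encoder(design$x, design$y, enc_cfg)
  nb <- fit_gaussian_nb(encode(enc, design$x), design$y)
  pos <- design$ids[design$y == 1L]
  cand <- setdiff(features$ids, pos)
  xc <- features$features[cand, , drop = FALSE]
  post <- predict(nb, encode(enc, xc))[, "1"]
  out <- tibble::tibble(mirna = cand, probability = as.numeric(post))
  out <- out[order(-out$probability, out$mirna), ]
  if (!is.null(top_k)) out <- head(out, top_k)
  tibble::tibble(rank = seq_len(nrow(out)), out)
}
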