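# Downstream evaluation protocol: protein-level pooling, embedding
# variants (partitioned / original / crafted-only / informed), the pooled
# gradient-boosting classifier, bootstrap confidence intervals, and the
# residual-subspace probes.

#' Mean-pool a per-residue matrix to a protein-level vector
#'
#' @param m An L x D matrix (L >= 1).
#' @return Column-wise arithmetic mean (length-D vector).
#' @export
mean_pool <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) == 0L) stop("cannot pool an empty matrix (L = 0)")
  colMeans(m)
}

#' Collapse the informed subspace to discrete crafted features
#'
#' Emulates a classical feature pipeline: the SS3, SS8 and amino-acid
#' blocks are replaced by the one-hot of their argmax (ties broken to the
#' lowest class index), aromaticity is thresholded at probability 0.5
#' (i.e. logit > 0), and the continuous channels (ASA, GRAVY) pass
#' through unchanged. Idempotent.
#'
#' @param informed An L x 34 informed-subspace matrix.
#' @return An L x 34 matrix in the same layout.
#' @export
crafted_only_reduce <- function(informed) {
  informed <- as.matrix(informed)
  if (ncol(informed) != 34L) stop("expected 34 informed columns")
  out <- informed
  lay <- feature_layout()
  for (tk in lay$tasks) {
    if (tk$kind == "ce") {
      block <- informed[, tk$idx, drop = FALSE]
      oh <- matrix(0, nrow(block), ncol(block))
      oh[cbind(seq_len(nrow(block)), max.col(block, "first"))] <- 1
      out[, tk$idx] <- oh
    } else if (tk$kind == "bce") {
      out[, tk$idx] <- as.numeric(informed[, tk$idx] > 0)
    }
  }
  colnames(out) <- lay$names
  out
}

#' Build a pooled protein-level design matrix for an embedding variant
#'
#' The four variants compared in downstream evaluation: `"partitioned"`
#' (informed + residual, width D), `"original"` (the raw PLM embedding,
#' width D), `"informed"` (width 34) and `"crafted_only"` (the informed
#' subspace discretized by [crafted_only_reduce()], width 34). Each
#' protein is mean-pooled over residues.
#'
#' @param embeddings Named list of L x D embedding matrices.
#' @param adapter A fitted [plmx_adapter()] (not needed for
#'   `"original"`).
#' @param variant Which embedding variant to build.
#' @param ids Protein ids (default all).
#' @return A matrix with one named row per protein.
#' @export
pooled_variant <- function(embeddings, adapter = NULL,
                           variant = c("partitioned", "original",
                                       "crafted_only", "informed"),
                           ids = names(embeddings)) {
  variant <- match.arg(variant)
  if (variant != "original" && is.null(adapter))
    stop("variant '", variant, "' needs a fitted adapter")
  rows <- lapply(ids, function(id) {
    m <- embeddings[[id]]
    switch(variant,
           original = mean_pool(m),
           partitioned = mean_pool(predict(adapter, m, type = "partitioned")),
           informed = mean_pool(predict(adapter, m, type = "informed")),
           crafted_only = mean_pool(crafted_only_reduce(
             predict(adapter, m, type = "informed"))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  colnames(out) <- switch(variant,
                          original = paste0("feature_",
                                            seq_len(ncol(out))),
                          partitioned = partitioned_feature_names(ncol(out)),
                          feature_layout()$names)
  out
}

# ---- metrics ---------------------------------------------------------------

#' Binary classification metrics
#'
#' `roc_auc()` is the rank (Mann-Whitney) statistic with ties handled by
#' midranks; `accuracy()` thresholds probabilities at 0.5; `f1_score()`
#' is the harmonic mean of precision and recall for class 1.
#'
#' @param scores Predicted probabilities (or any monotone scores for
#'   `roc_auc`).
#' @param y True 0/1 labels.
#' @return Scalar metric in `[0, 1]`.
#' @export
roc_auc <- function(scores, y) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("roc_auc needs both classes")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname roc_auc
#' @export
accuracy <- function(scores, y) mean((scores > 0.5) == (y == 1))

#' @rdname roc_auc
#' @export
f1_score <- function(scores, y) {
  pred <- scores > 0.5
  tp <- sum(pred & y == 1)
  if (tp == 0L) return(0)
  prec <- tp / sum(pred)
  rec <- tp / sum(y == 1)
  2 * prec * rec / (prec + rec)
}

#' Train the pooled gradient-boosting classifier
#'
#' Thin wrapper around [gbc_fit()] pinned to the downstream-evaluation
#' configuration: 100 iterations, depth 4, learning rate 0.05.
#'
#' @param X Pooled protein-level design matrix.
#' @param y 0/1 labels.
#' @return A `plmx_gbc` model.
#' @export
train_pooled_classifier <- function(X, y) {
  gbc_fit(X, y, n_trees = 100, max_depth = 4, learning_rate = 0.05)
}

#' Bootstrap evaluation with t confidence intervals
#'
#' Resamples the *training* data with replacement `n_rounds` times,
#' retrains, and evaluates every round on the fixed test set. Reports the
#' mean and the 95% t-interval half-width `t_{0.975, n-1} * s / sqrt(n)`
#' of each metric (half-width 0 when the metric is constant).
#'
#' @param X_train,y_train Training design and labels (resampled).
#' @param X_test,y_test Fixed test design and labels.
#' @param train_fn Function `(X, y) -> model`; the model must have a
#'   `predict(model, X)` method returning class-1 probabilities
#'   (default [train_pooled_classifier()]).
#' @param n_rounds Bootstrap rounds (default 10).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed for the resampling.
#' @return An `eval_record` data frame (one row per metric: `mean`,
#'   `ci_halfwidth`, `n_bootstrap`) with the per-round metric matrix
#'   attached as attribute `"rounds"`.
#' @export
bootstrap_evaluate <- function(X_train, y_train, X_test, y_test,
                               train_fn = train_pooled_classifier,
                               n_rounds = 10, level = 0.95, seed = 1) {
  stopifnot(n_rounds >= 2)
  per_round <- .with_seed(seed, {
    t(vapply(seq_len(n_rounds), function(r) {
      repeat {
        idx <- sample.int(length(y_train), replace = TRUE)
        if (length(unique(y_train[idx])) == 2L) break
      }
      model <- train_fn(X_train[idx, , drop = FALSE], y_train[idx])
      p <- predict(model, X_test)
      c(roc_auc = roc_auc(p, y_test), accuracy = accuracy(p, y_test),
        f1 = f1_score(p, y_test))
    }, numeric(3)))
  })
  alpha <- 1 - level
  hw <- apply(per_round, 2L, function(v) {
    s <- stats::sd(v)
    if (s == 0) 0 else stats::qt(1 - alpha / 2, n_rounds - 1) *
      s / sqrt(n_rounds)
  })
  out <- data.frame(metric = colnames(per_round),
                    mean = colMeans(per_round),
                    ci_halfwidth = hw,
                    n_bootstrap = n_rounds, row.names = NULL)
  attr(out, "rounds") <- per_round
  class(out) <- c("eval_record", "data.frame")
  out
}

# ---- residual probes -------------------------------------------------------

#' Probe the residual subspace for leftover handcrafted-feature signal
#'
#' Trains, per feature task, a two-layer neural network (hidden width
#' `floor(D/2)`, ReLU) on residual vectors of the adversarial-eval split
#' and evaluates it on the test split: classification accuracy for
#' SS3/SS8/amino acid/aromaticity, L1 for ASA/GRAVY. High probe accuracy
#' means the feature survives in the residual subspace; chance-level
#' accuracy means it was suppressed.
#'
#' @param adapter A fitted `plmx_adapter`.
#' @param embeddings,annotations The dataset (named lists).
#' @param tasks Task names to probe (default `"ss8"`; any of
#'   `ss3, ss8, asa, gravy, aromatic, aa`).
#' @param splits `dataset_split` providing `adversarial_eval` (probe
#'   training) and `test` (probe evaluation); default the adapter's own.
#' @param epochs,learning_rate Probe training settings.
#' @param seed RNG seed.
#' @return Data frame `task`, `metric` (`accuracy` or `l1`), `value`,
#'   `chance` (chance-level accuracy for classification tasks, NA
#'   otherwise).
#' @export
probe_residual <- function(adapter, embeddings, annotations,
                           tasks = "ss8", splits = adapter$splits,
                           epochs = 150, learning_rate = 1e-3, seed = 1) {
  if (length(splits$adversarial_eval) == 0L || length(splits$test) == 0L)
    stop("probe needs non-empty adversarial_eval and test splits")
  dtr <- .stack_dataset(embeddings, annotations, splits$adversarial_eval)
  dte <- .stack_dataset(embeddings, annotations, splits$test)
  rtr <- predict(adapter, dtr$X, type = "residual")
  rte <- predict(adapter, dte$X, type = "residual")
  mtr <- which(dtr$mask); mte <- which(dte$mask)
  hidden <- max(2L, floor(adapter$config$D / 2))

  all_tasks <- feature_layout()$tasks
  out <- lapply(tasks, function(tn) {
    tk <- all_tasks[[match(tn, vapply(all_tasks, `[[`, "", "name"))]]
    ytr <- dtr$targets[[tn]][mtr]
    yte <- dte$targets[[tn]][mte]
    if (tk$kind == "ce") {
      fit <- mlp_fit(rtr[mtr, , drop = FALSE], ytr, kind = "ce",
                     n_classes = length(tk$idx), hidden = hidden,
                     epochs = epochs, learning_rate = learning_rate,
                     seed = seed)
      pred <- predict(fit, rte[mte, , drop = FALSE], type = "class")
      data.frame(task = tn, metric = "accuracy",
                 value = mean(pred == yte),
                 chance = max(tabulate(yte, length(tk$idx))) / length(yte))
    } else if (tk$kind == "bce") {
      fit <- mlp_fit(rtr[mtr, , drop = FALSE], ytr, kind = "bce",
                     hidden = hidden, epochs = epochs,
                     learning_rate = learning_rate, seed = seed)
      pred <- predict(fit, rte[mte, , drop = FALSE])
      data.frame(task = tn, metric = "accuracy",
                 value = mean((pred > 0.5) == (yte > 0.5)),
                 chance = max(mean(yte), 1 - mean(yte)))
    } else {
      fit <- mlp_fit(rtr[mtr, , drop = FALSE], ytr, kind = "l1",
                     hidden = hidden, epochs = epochs,
                     learning_rate = learning_rate, seed = seed)
      pred <- predict(fit, rte[mte, , drop = FALSE])
      data.frame(task = tn, metric = "l1",
                 value = mean(abs(pred - yte)), chance = NA_real_)
    }
  })
  do.call(rbind, out)
}
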