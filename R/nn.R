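# Minimal dense-network machinery: seeded initialization, activations,
# numerically stable losses, Adam, and a generic two-layer net used for
# residual probes. Everything is plain matrix algebra so training is exactly
# reproducible from a seed.

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.relu <- function(x) (x > 0) * x

.sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise softmax, stable
.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy of logit matrix vs integer class labels (1-based)
.ce_loss <- function(logits, classes) {
  z <- logits - apply(logits, 1L, max)
  lse <- log(rowSums(exp(z)))
  mean(lse - z[cbind(seq_along(classes), classes)])
}

# gradient of .ce_loss wrt logits (already divided by n)
.ce_grad <- function(logits, classes) {
  p <- .softmax(logits)
  p[cbind(seq_along(classes), classes)] <-
    p[cbind(seq_along(classes), classes)] - 1
  p / length(classes)
}

# mean binary cross-entropy of a logit vector vs 0/1 labels, stable
.bce_loss <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

.bce_grad <- function(logits, y) (.sigmoid(logits) - y) / length(y)

.l1_loss <- function(pred, y) mean(abs(pred - y))

.l1_grad <- function(pred, y) sign(pred - y) / length(y)

# Gaussian init scaled by fan-in
.init_mat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = 1 / sqrt(nin)), nin, nout)
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# clip the global gradient norm in place
.clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm) || max_norm <= 0) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (total > max_norm) grads <- lapply(grads, function(g) g * max_norm / total)
  grads
}

#' Fit a two-layer neural network (single hidden ReLU layer)
#'
#' The generic probe architecture: `input -> hidden (ReLU) -> output`,
#' trained with Adam on cross-entropy (multi-class), binary cross-entropy
#' or L1 loss. Used for the residual-subspace probes that quantify how
#' much handcrafted-feature signal survives adversarial training, and as
#' an all-purpose small net in tests.
#'
#' @param X Numeric matrix, one row per example.
#' @param y Targets: integer class labels in `1..n_classes` for
#'   `kind = "ce"`, 0/1 for `"bce"`, numeric for `"l1"`.
#' @param kind Loss/output type.
#' @param n_classes Number of classes for `"ce"`.
#' @param hidden Hidden width (default `floor(ncol(X) / 2)`).
#' @param epochs,batch_size,learning_rate Adam training settings.
#' @param seed RNG seed controlling initialization and batch order.
#' @return An object of class `plmx_mlp` with a `predict` method: for
#'   `"ce"` predicted class probabilities (`type = "prob"`) or labels
#'   (`type = "class"`); for `"bce"` probabilities; for `"l1"` values.
#' @export
mlp_fit <- function(X, y, kind = c("ce", "bce", "l1"), n_classes = NULL,
                    hidden = max(2L, floor(ncol(X) / 2)), epochs = 100,
                    batch_size = 128, learning_rate = 1e-3, seed = 1) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n == length(y), n >= 1L)
  if (kind == "ce") {
    if (is.null(n_classes)) n_classes <- max(y)
    out_dim <- n_classes
    y <- as.integer(y)
  } else out_dim <- 1L

  .with_seed(seed, {
    params <- list(W1 = .init_mat(ncol(X), hidden), b1 = numeric(hidden),
                   W2 = .init_mat(hidden, out_dim), b2 = numeric(out_dim))
    state <- .adam_init(params)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1L, n)]
        xb <- X[rows, , drop = FALSE]
        yb <- y[rows]
        h_pre <- sweep(xb %*% params$W1, 2L, params$b1, "+")
        h <- .relu(h_pre)
        o <- sweep(h %*% params$W2, 2L, params$b2, "+")
        d_o <- switch(kind,
          ce  = .ce_grad(o, yb),
          bce = matrix(.bce_grad(drop(o), yb)),
          l1  = matrix(.l1_grad(drop(o), yb)))
        d_h <- (d_o %*% t(params$W2)) * (h_pre > 0)
        grads <- list(W1 = crossprod(xb, d_h), b1 = colSums(d_h),
                      W2 = crossprod(h, d_o),  b2 = colSums(d_o))
        upd <- .adam_step(params, grads, state, learning_rate)
        params <- upd$params
        state <- upd$state
      }
    }
    structure(list(params = params, kind = kind, n_classes = n_classes,
                   hidden = hidden, dim = ncol(X)),
              class = "plmx_mlp")
  })
}

#' @rdname mlp_fit
#' @param object A fitted `plmx_mlp`.
#' @param newdata Matrix of examples to score.
#' @param type `"response"` (probabilities / values) or `"class"`
#'   (CE only; ties broken to the lowest class index).
#' @param ... Unused.
#' @export
predict.plmx_mlp <- function(object, newdata, type = c("response", "class"),
                             ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != object$dim)
    stop("input width ", ncol(x), " does not match model width ", object$dim)
  p <- object$params
  h <- .relu(sweep(x %*% p$W1, 2L, p$b1, "+"))
  o <- sweep(h %*% p$W2, 2L, p$b2, "+")
  if (object$kind == "ce") {
    if (type == "class") return(apply(o, 1L, which.max))  # lowest index wins ties
    return(.softmax(o))
  }
  if (type == "class") stop("type = 'class' is only defined for kind = 'ce'")
  if (object$kind == "bce") .sigmoid(drop(o)) else drop(o)
}
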