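# Local-context downstream classifier: a single 1D convolutional layer
# (50 filters) over per-residue embeddings, ReLU, max-pool over sequence
# positions, dropout, and one feed-forward output unit. Trained with Adam
# at the published settings (learning rate 1e-4, batch size 16, at most
# 20 epochs, best epoch by validation loss); backpropagation is written
# out explicitly so runs are exactly reproducible from a seed.

# stack sliding windows of an L x D matrix into an (L-k+1) x (k*D) matrix;
# sequences shorter than the kernel are zero-padded up to k rows
.conv_windows <- function(X, k) {
  if (nrow(X) < k)
    X <- rbind(X, matrix(0, k - nrow(X), ncol(X)))
  L <- nrow(X); D <- ncol(X)
  nw <- L - k + 1L
  out <- matrix(0, nw, k * D)
  for (j in seq_len(k))
    out[, ((j - 1L) * D + 1L):(j * D)] <- X[j:(j + nw - 1L), , drop = FALSE]
  out
}

#' Kernel size used for a downstream task
#'
#' Aggregation-propensity models use a kernel of 6 residues; extracellular
#' vesicle (EV) association and transmembrane-helix models use 8.
#'
#' @param task One of `"aggregation"`, `"ev"`, `"transmembrane"`.
#' @return Integer kernel size.
#' @export
kernel_for_task <- function(task = c("aggregation", "ev", "transmembrane")) {
  task <- match.arg(task)
  if (task == "aggregation") 6L else 8L
}

#' Fit the 1D convolutional downstream classifier
#'
#' @param X List of per-residue matrices (L x D, variable L).
#' @param y 0/1 protein labels.
#' @param kernel Convolution kernel size (residues); see
#'   [kernel_for_task()]. Default 6.
#' @param n_filters Number of convolution filters (default 50).
#' @param dropout Dropout rate on the pooled features during training
#'   (default 0.2).
#' @param learning_rate,epochs,batch_size Adam settings (defaults 1e-4,
#'   20, 16).
#' @param val_frac Fraction of proteins held out (seeded) for best-epoch
#'   selection by validation loss, ignored if `validation` is given.
#' @param validation Optional integer indices of validation proteins.
#' @param seed RNG seed (initialization, batch order, dropout).
#' @return An object of class `plmx_cnn` with the best-validation
#'   parameters, the configuration and the per-epoch validation-loss
#'   curve (`val_curve`).
#' @export
cnn_fit <- function(X, y, kernel = 6L, n_filters = 50L, dropout = 0.2,
                    learning_rate = 1e-4, epochs = 20L, batch_size = 16L,
                    val_frac = 0.2, validation = NULL, seed = 1) {
  stopifnot(length(X) == length(y))
  y <- as.numeric(y)
  D <- ncol(X[[1]])
  n <- length(X)

  .with_seed(seed, {
    if (is.null(validation))
      validation <- sample.int(n, max(1L, round(val_frac * n)))
    tr <- setdiff(seq_len(n), validation)
    Wtr <- lapply(X, .conv_windows, k = kernel)

    params <- list(W = .init_mat(kernel * D, n_filters),
                   b = numeric(n_filters),
                   w = .init_mat(n_filters, 1L), c = 0)
    state <- .adam_init(params)
    keep <- 1 - dropout

    val_loss <- function(p) {
      logits <- vapply(validation, function(i) {
        a <- sweep(Wtr[[i]] %*% p$W, 2L, p$b, "+")
        h <- apply(a, 2L, max)
        h <- .relu(h)
        sum(p$w * h) + p$c
      }, numeric(1))
      .bce_loss(logits, y[validation])
    }

    best <- list(loss = Inf, params = params, epoch = 0L)
    curve <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample(tr)
      for (start in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, length(ord))]
        g <- lapply(params, function(x) x * 0)
        for (i in idx) {
          Xk <- Wtr[[i]]
          a <- sweep(Xk %*% params$W, 2L, params$b, "+")
          amax_pos <- max.col(t(a), "first")      # argmax position per filter
          amax <- a[cbind(amax_pos, seq_len(n_filters))]
          h <- .relu(amax)
          mask <- (stats::runif(n_filters) < keep) / keep
          hd <- h * mask
          logit <- sum(params$w * hd) + params$c
          d_logit <- (.sigmoid(logit) - y[i]) / length(idx)
          g$w <- g$w + d_logit * hd
          g$c <- g$c + d_logit
          d_h <- d_logit * drop(params$w) * mask * (amax > 0)
          d_a <- matrix(0, nrow(a), n_filters)
          d_a[cbind(amax_pos, seq_len(n_filters))] <- d_h
          g$W <- g$W + crossprod(Xk, d_a)
          g$b <- g$b + colSums(d_a)
        }
        upd <- .adam_step(params, g, state, learning_rate)
        params <- upd$params
        state <- upd$state
      }
      curve[ep] <- val_loss(params)
      if (curve[ep] < best$loss)
        best <- list(loss = curve[ep], params = params, epoch = ep)
    }
    structure(list(params = best$params, kernel = kernel,
                   n_filters = n_filters, dropout = dropout,
                   dim = D, best_epoch = best$epoch, val_curve = curve,
                   validation = validation, seed = seed),
              class = "plmx_cnn")
  })
}

#' @rdname cnn_fit
#' @param object A fitted `plmx_cnn`.
#' @param newdata List of per-residue matrices.
#' @param type `"response"` (probability) or `"class"`.
#' @param ... Unused.
#' @export
predict.plmx_cnn <- function(object, newdata,
                             type = c("response", "class"), ...) {
  type <- match.arg(type)
  p <- object$params
  logits <- vapply(newdata, function(m) {
    if (ncol(m) != object$dim)
      stop("input width ", ncol(m), " does not match model width ",
           object$dim)
    a <- sweep(.conv_windows(m, object$kernel) %*% p$W, 2L, p$b, "+")
    h <- .relu(apply(a, 2L, max))
    sum(p$w * h) + p$c
  }, numeric(1))
  if (type == "class") as.integer(logits > 0) else .sigmoid(logits)
}

#' Post-ReLU convolution activations of a fitted CNN
#'
#' @param object A fitted `plmx_cnn`.
#' @param X One per-residue matrix (L x D).
#' @return An (L - kernel + 1) x n_filters matrix of post-ReLU filter
#'   activations (rows = window start positions).
#' @export
conv_activations <- function(object, X) {
  a <- sweep(.conv_windows(as.matrix(X), object$kernel) %*% object$params$W,
             2L, object$params$b, "+")
  .relu(a)
}

#' @export
print.plmx_cnn <- function(x, ...) {
  cat("1D CNN classifier:", x$n_filters, "filters, kernel", x$kernel,
      ", dropout", x$dropout, "; best epoch", x$best_epoch, "\n")
  invisible(x)
}
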