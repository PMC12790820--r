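# The partitioning adapter: an encoder-decoder that factors a D-dim
# per-residue PLM embedding into a 34-dim informed subspace (trained to
# equal handcrafted biochemical features) and a (D-34)-dim residual
# subspace (trained adversarially, through a gradient reversal layer, to
# exclude them), while a decoder keeps the original embedding
# reconstructable. Networks and backpropagation are implemented directly
# in matrix algebra; a single Adam optimizer updates encoder, decoder and
# adversaries jointly -- the gradient reversal makes the minimax work
# without alternating updates.

#' Gradient reversal layer
#'
#' `grl_forward()` is the identity; `grl_backward()` multiplies an
#' incoming gradient by `-scale`. Inserted between the residual subspace
#' and the adversarial heads, it lets the adversary minimize its feature
#' prediction loss while the encoder receives the reversed gradient and
#' so learns to *remove* feature information from the residual.
#'
#' @param x Any numeric array (forward input).
#' @param grad Gradient flowing back from the adversary.
#' @param scale Positive reversal scale (default 1).
#' @return `x` unchanged, resp. `-scale * grad`.
#' @export
grl_forward <- function(x) x

#' @rdname grl_forward
#' @export
grl_backward <- function(grad, scale = 1) -scale * grad

#' Reconstruction loss (mean absolute error)
#'
#' @param z_orig,z_recon Matching numeric matrices (original and
#'   reconstructed embeddings).
#' @return Mean of `|z_orig - z_recon|` over all entries.
#' @export
loss_rec <- function(z_orig, z_recon) {
  if (!identical(dim(z_orig), dim(z_recon)))
    stop("shape mismatch: ", paste(dim(z_orig), collapse = "x"), " vs ",
         paste(dim(z_recon), collapse = "x"))
  mean(abs(z_orig - z_recon))
}

#' Per-task handcrafted-feature loss
#'
#' Cross-entropy for the multi-class tasks (SS3, SS8, amino acid), binary
#' cross-entropy for aromaticity, and L1 (mean absolute error) for the
#' continuous tasks (ASA, GRAVY). Used both for the informed-subspace
#' loss and for the adversarial heads.
#'
#' @param pred For `"ce"` a logit matrix (one column per class), for
#'   `"bce"` a logit vector, for `"l1"` a numeric vector of predictions.
#' @param target Integer class labels (1-based) for `"ce"`, 0/1 for
#'   `"bce"`, numeric for `"l1"`.
#' @param kind Loss kind.
#' @return Scalar loss (mean over residues).
#' @export
loss_hcf <- function(pred, target, kind = c("ce", "bce", "l1")) {
  kind <- match.arg(kind)
  n <- if (kind == "ce") nrow(pred) else length(pred)
  if (is.null(n) || n == 0L || length(target) == 0L)
    stop("no residues to score")
  switch(kind,
         ce  = .ce_loss(pred, target),
         bce = .bce_loss(drop(pred), target),
         l1  = .l1_loss(drop(pred), target))
}

#' Total adapter loss
#'
#' The weighted sum `lambda_rec * Lrec + sum_t lambda_hcf[t] * Lhcf[t] +
#' sum_t lambda_adv[t] * Ladv[t]`.
#'
#' @param breakdown A list (or `loss_breakdown`) with `l_rec` and named
#'   numeric vectors `l_hcf`, `l_adv`.
#' @param lambda_rec Reconstruction weight.
#' @param lambda_hcf,lambda_adv Scalars or named per-task weight vectors;
#'   every task present in the breakdown must have a weight.
#' @return The scalar total loss.
#' @export
loss_total <- function(breakdown, lambda_rec = 1, lambda_hcf = 1,
                       lambda_adv = 1) {
  wh <- .task_weights(lambda_hcf, names(breakdown$l_hcf))
  wa <- .task_weights(lambda_adv, names(breakdown$l_adv))
  lambda_rec * breakdown$l_rec +
    sum(wh * breakdown$l_hcf) + sum(wa * breakdown$l_adv)
}

# expand a scalar or partial named vector to a full named per-task vector
.task_weights <- function(w, task_names) {
  if (length(w) == 1L && is.null(names(w)))
    return(stats::setNames(rep(w, length(task_names)), task_names))
  missing <- setdiff(task_names, names(w))
  if (length(missing) > 0L)
    stop("missing task weight(s): ", paste(missing, collapse = ", "))
  w[task_names]
}

# ---- dataset stacking ------------------------------------------------------

# flatten embeddings + annotations for a set of protein ids into one
# residue-level design: X (n x D), mask, per-task targets
.stack_dataset <- function(embeddings, annotations, ids) {
  stopifnot(all(ids %in% names(embeddings)), all(ids %in% names(annotations)))
  X <- do.call(rbind, lapply(ids, function(id) embeddings[[id]]))
  feats <- do.call(rbind, lapply(ids, function(id) annotations[[id]]$features))
  mask <- unlist(lapply(ids, function(id) annotations[[id]]$mask),
                 use.names = FALSE)
  lens <- vapply(ids, function(id) nrow(embeddings[[id]]), integer(1))
  if (nrow(feats) != nrow(X))
    stop("embedding rows (", nrow(X), ") do not match annotation rows (",
         nrow(feats), ")")
  lay <- feature_layout()
  targets <- list(
    ss3 = max.col(feats[, lay$tasks[[1]]$idx, drop = FALSE], "first"),
    ss8 = max.col(feats[, lay$tasks[[2]]$idx, drop = FALSE], "first"),
    asa = feats[, lay$tasks[[3]]$idx],
    gravy = feats[, lay$tasks[[4]]$idx],
    aromatic = feats[, lay$tasks[[5]]$idx],
    aa = max.col(feats[, lay$tasks[[6]]$idx, drop = FALSE], "first")
  )
  list(X = X, mask = mask, targets = targets,
       protein = rep(ids, lens), features = feats)
}

# ---- parameters ------------------------------------------------------------

.adapter_init_params <- function(D, scale_init) {
  R <- D - 34L
  H <- floor(D / 2)
  p <- list(
    enc_W1 = .init_mat(D, D),  enc_b1 = numeric(D),
    enc_W2 = .init_mat(D, 34L), enc_b2 = numeric(34L),
    enc_rho = log(scale_init),                 # per-task positive scales
    res_W1 = .init_mat(D, D),  res_b1 = numeric(D),
    res_W2 = .init_mat(D, R),  res_b2 = numeric(R),

    dec_W1 = .init_mat(D, D),  dec_b1 = numeric(D),
    dec_W2 = .init_mat(D, D),  dec_b2 = numeric(D)
  )
  for (tk in feature_layout()$tasks) {
    p[[paste0("adv_", tk$name, "_W1")]] <- .init_mat(R, H)
    p[[paste0("adv_", tk$name, "_b1")]] <- numeric(H)
    p[[paste0("adv_", tk$name, "_W2")]] <- .init_mat(H, 34L)
    p[[paste0("adv_", tk$name, "_b2")]] <- numeric(34L)
  }
  p
}

# map each of the 34 informed columns to its task index (1..6)
.col_task <- function() {
  ct <- integer(34)
  tasks <- feature_layout()$tasks
  for (t in seq_along(tasks)) ct[tasks[[t]]$idx] <- t
  ct
}

# ---- forward passes --------------------------------------------------------

.encode_forward <- function(p, X) {
  h1p <- sweep(X %*% p$enc_W1, 2L, p$enc_b1, "+")
  h1 <- .relu(h1p)
  tpre <- sweep(h1 %*% p$enc_W2, 2L, p$enc_b2, "+")
  tt <- tanh(tpre)
  svec <- exp(p$enc_rho)[.col_task()]
  informed <- sweep(tt, 2L, svec, "*")
  g1p <- sweep(X %*% p$res_W1, 2L, p$res_b1, "+")
  g1 <- .relu(g1p)
  rpre <- sweep(g1 %*% p$res_W2, 2L, p$res_b2, "+")
  residual <- tanh(rpre)
  list(informed = informed, residual = residual,
       h1p = h1p, h1 = h1, tt = tt, svec = svec, g1p = g1p, g1 = g1)
}

.decode_forward <- function(p, Z) {
  d1p <- sweep(Z %*% p$dec_W1, 2L, p$dec_b1, "+")
  d1 <- .relu(d1p)
  xrec <- sweep(d1 %*% p$dec_W2, 2L, p$dec_b2, "+")
  list(xrec = xrec, d1p = d1p, d1 = d1)
}

.adversary_forward <- function(p, residual, task_name) {
  qp <- sweep(residual %*% p[[paste0("adv_", task_name, "_W1")]], 2L,
              p[[paste0("adv_", task_name, "_b1")]], "+")
  q <- .relu(qp)
  o <- sweep(q %*% p[[paste0("adv_", task_name, "_W2")]], 2L,
             p[[paste0("adv_", task_name, "_b2")]], "+")
  list(o = o, qp = qp, q = q)
}

# slice-level task loss + gradient wrt the 34-wide output rows (masked rows)
.task_loss_grad <- function(out34, targets, rows, task, want_grad = TRUE) {
  sl <- out34[rows, task$idx, drop = FALSE]
  nr <- length(rows)
  if (task$kind == "ce") {
    y <- targets[[task$name]][rows]
    l <- .ce_loss(sl, y)
    g <- if (want_grad) .ce_grad(sl, y) else NULL
  } else if (task$kind == "bce") {
    y <- targets[[task$name]][rows]
    l <- .bce_loss(drop(sl), y)
    g <- if (want_grad) matrix(.bce_grad(drop(sl), y)) else NULL
  } else {
    y <- targets[[task$name]][rows]
    l <- .l1_loss(drop(sl), y)
    g <- if (want_grad) matrix(.l1_grad(drop(sl), y)) else NULL
  }
  list(loss = l, grad = g)
}

# full forward + loss breakdown (no gradients); used for validation
.adapter_eval <- function(p, X, targets, mask, cfg) {
  enc <- .encode_forward(p, X)
  dec <- .decode_forward(p, cbind(enc$informed, enc$residual))
  rows <- which(mask)
  tasks <- feature_layout()$tasks
  l_hcf <- l_adv <- stats::setNames(numeric(length(tasks)),
                                    vapply(tasks, `[[`, "", "name"))
  for (tk in tasks) {
    l_hcf[tk$name] <- .task_loss_grad(enc$informed, targets, rows, tk,
                                      want_grad = FALSE)$loss
    adv <- .adversary_forward(p, enc$residual, tk$name)
    l_adv[tk$name] <- .task_loss_grad(adv$o, targets, rows, tk,
                                      want_grad = FALSE)$loss
  }
  br <- structure(list(l_rec = loss_rec(X, dec$xrec),
                       l_hcf = l_hcf, l_adv = l_adv),
                  class = "loss_breakdown")
  br$l_total <- loss_total(br, cfg$lambda_rec, cfg$lambda_hcf, cfg$lambda_adv)
  br
}

# ---- one training step: forward, losses, full backward ---------------------

.adapter_step <- function(p, X, targets, mask, cfg) {
  n <- nrow(X); D <- ncol(X)
  enc <- .encode_forward(p, X)
  Z <- cbind(enc$informed, enc$residual)
  dec <- .decode_forward(p, Z)
  rows <- which(mask)
  tasks <- feature_layout()$tasks
  tnames <- vapply(tasks, `[[`, "", "name")
  l_hcf <- l_adv <- stats::setNames(numeric(length(tasks)), tnames)
  g <- lapply(p, function(x) x * 0)

  # reconstruction path (all residues, masked included)
  l_rec <- loss_rec(X, dec$xrec)
  d_xrec <- cfg$lambda_rec * sign(dec$xrec - X) / (n * D)
  g$dec_W2 <- crossprod(dec$d1, d_xrec)
  g$dec_b2 <- colSums(d_xrec)
  d_d1 <- (d_xrec %*% t(p$dec_W2)) * (dec$d1p > 0)
  g$dec_W1 <- crossprod(Z, d_d1)
  g$dec_b1 <- colSums(d_d1)
  d_Z <- d_d1 %*% t(p$dec_W1)
  d_informed <- d_Z[, 1:34, drop = FALSE]
  d_residual <- d_Z[, -(1:34), drop = FALSE]

  # informed-subspace feature losses (masked-in residues only)
  for (ti in seq_along(tasks)) {
    tk <- tasks[[ti]]
    tl <- .task_loss_grad(enc$informed, targets, rows, tk)
    l_hcf[tk$name] <- tl$loss
    w <- cfg$lambda_hcf[tk$name]
    if (w > 0)
      d_informed[rows, tk$idx] <- d_informed[rows, tk$idx] + w * tl$grad
  }

  # adversarial heads: heads minimize their loss; the encoder receives the
  # gradient through the reversal layer (grl_backward) and so maximizes it
  for (ti in seq_along(tasks)) {
    tk <- tasks[[ti]]
    adv <- .adversary_forward(p, enc$residual, tk$name)
    tl <- .task_loss_grad(adv$o, targets, rows, tk)
    l_adv[tk$name] <- tl$loss
    w <- cfg$lambda_adv[tk$name]
    if (w > 0) {
      d_o <- matrix(0, n, 34L)
      d_o[rows, tk$idx] <- w * tl$grad
      nm <- paste0("adv_", tk$name, "_")
      g[[paste0(nm, "W2")]] <- crossprod(adv$q, d_o)
      g[[paste0(nm, "b2")]] <- colSums(d_o)
      d_q <- (d_o %*% t(p[[paste0(nm, "W2")]])) * (adv$qp > 0)
      g[[paste0(nm, "W1")]] <- crossprod(enc$residual, d_q)
      g[[paste0(nm, "b1")]] <- colSums(d_q)
      d_residual <- d_residual +
        grl_backward(d_q %*% t(p[[paste0(nm, "W1")]]), cfg$grl_scale)
    }
  }

  # back through the residual branch
  d_rpre <- d_residual * (1 - enc$residual^2)
  g$res_W2 <- crossprod(enc$g1, d_rpre)
  g$res_b2 <- colSums(d_rpre)
  d_g1 <- (d_rpre %*% t(p$res_W2)) * (enc$g1p > 0)
  g$res_W1 <- crossprod(X, d_g1)
  g$res_b1 <- colSums(d_g1)

  # back through the informed branch (scale, tanh, two dense layers)
  ct <- .col_task()
  drho_cols <- colSums(d_informed * enc$informed)
  g$enc_rho <- vapply(seq_along(tasks), function(t)
    sum(drho_cols[ct == t]), numeric(1))
  d_tt <- sweep(d_informed, 2L, enc$svec, "*")
  d_tpre <- d_tt * (1 - enc$tt^2)
  g$enc_W2 <- crossprod(enc$h1, d_tpre)
  g$enc_b2 <- colSums(d_tpre)
  d_h1 <- (d_tpre %*% t(p$enc_W2)) * (enc$h1p > 0)
  g$enc_W1 <- crossprod(X, d_h1)
  g$enc_b1 <- colSums(d_h1)

  br <- structure(list(l_rec = l_rec, l_hcf = l_hcf, l_adv = l_adv),
                  class = "loss_breakdown")
  br$l_total <- loss_total(br, cfg$lambda_rec, cfg$lambda_hcf, cfg$lambda_adv)
  list(grads = g, breakdown = br)
}

# ---- the fitting function --------------------------------------------------

#' Fit a partitioning adapter to per-residue PLM embeddings
#'
#' Trains the encoder-decoder with adversarial disentanglement: the
#' informed branch (`D -> D` ReLU `-> 34` Tanh, one learned positive
#' scale per task) is fit to the handcrafted features; the residual
#' branch (`D -> D` ReLU `-> D-34` Tanh) feeds, through a gradient
#' reversal layer, six per-task adversarial heads
#' (`D-34 -> floor(D/2)` ReLU `-> 34`) whose loss the encoder is driven
#' to *increase*; and the decoder (`D -> D` ReLU `-> D`, linear output)
#' reconstructs the original embedding from the concatenated partition.
#' The total objective is
#' `lambda_rec * Lrec + sum_t lambda_hcf[t] * Lhcf[t] + sum_t
#' lambda_adv[t] * Ladv[t]`, optimized jointly with Adam. Feature and
#' adversarial losses use only residues whose annotation mask is TRUE
#' (high-pLDDT, standard, structurally covered); the reconstruction loss
#' uses every residue.
#'
#' @param x Named list of L x D embedding matrices, or a `plmx_synthetic`
#'   dataset (in which case `annotations` is taken from it).
#' @param annotations Named list of `protein_annotation` objects aligned
#'   with `x`.
#' @param lambda_rec Reconstruction weight (default 1).
#' @param lambda_hcf,lambda_adv Scalar or named per-task weights for the
#'   feature and adversarial losses (default 1 each; the operating point
#'   at which reconstruction stays low while features are partly
#'   suppressed).
#' @param grl_scale Gradient-reversal scale (default 1; the adversarial
#'   sweep is carried by `lambda_adv`).
#' @param epochs,batch_size,learning_rate Adam settings (defaults 30,
#'   256 residues, 1e-3).
#' @param lr_decay Step learning-rate schedule: the rate is multiplied by
#'   0.3 after 60% and again after 85% of the epochs (default TRUE;
#'   damps the adversarial oscillation late in training). Set FALSE for
#'   a constant rate.
#' @param clip Global gradient-norm clip (default 5; keeps the reversed
#'   adversarial gradients from destabilizing training at large
#'   `lambda_adv`).
#' @param seed Seed controlling initialization, batch order and splits.
#' @param splits Optional `dataset_split`; default `make_splits(ids, seed
#'   = seed)`.
#' @param verbose Print per-epoch validation losses.
#' @return An object of class `plmx_adapter` with components `params`
#'   (best-validation weights), `config`, `splits`, `history` (per-step
#'   training loss breakdown), `epoch_log` (per-epoch train/validation
#'   breakdowns), `best_epoch`, and `layout`. Methods: `print`,
#'   `summary`, `predict`, `residuals`, `plot`, `coef`.
#' @export
plmx_adapter <- function(x, annotations = NULL, lambda_rec = 1,
                         lambda_hcf = 1, lambda_adv = 1, grl_scale = 1,
                         epochs = 30, batch_size = 256,
                         learning_rate = 1e-3, lr_decay = TRUE, clip = 5,
                         seed = 1, splits = NULL, verbose = FALSE) {
  if (inherits(x, "plmx_synthetic")) {
    annotations <- x$annotations
    x <- x$embeddings
  }
  stopifnot(is.list(x), is.list(annotations))
  D <- ncol(x[[1]])
  if (D <= 34L) stop("embedding dimension D = ", D, " must exceed 34")
  ids <- names(x)
  if (is.null(splits)) splits <- make_splits(ids, seed = seed)

  tasks <- feature_layout()$tasks
  tnames <- vapply(tasks, `[[`, "", "name")
  cfg <- list(D = D, n_informed = 34L, lambda_rec = lambda_rec,
              lambda_hcf = .task_weights(lambda_hcf, tnames),
              lambda_adv = .task_weights(lambda_adv, tnames),
              grl_scale = grl_scale, epochs = epochs,
              batch_size = batch_size, learning_rate = learning_rate,
              clip = clip, seed = seed)

  train <- .stack_dataset(x, annotations, splits$train)
  val <- if (length(splits$validation) > 0L)
    .stack_dataset(x, annotations, splits$validation) else NULL
  if (!any(train$mask)) stop("no residues to score: training mask is empty")

  # L1-task scales start at the training-set max |target|; CE/BCE at 1
  scale_init <- stats::setNames(rep(1, length(tasks)), tnames)
  rows <- which(train$mask)
  scale_init["asa"] <- max(abs(train$targets$asa[rows]), 1)
  scale_init["gravy"] <- max(abs(train$targets$gravy[rows]), 1)

  n <- nrow(train$X)
  hist_rows <- vector("list", ceiling(n / batch_size) * epochs)
  epoch_log <- vector("list", epochs)
  hr <- 0L

  .with_seed(seed, {
    params <- .adapter_init_params(D, scale_init)
    state <- .adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    for (ep in seq_len(epochs)) {
      lr_ep <- learning_rate *
        if (!lr_decay) 1
        else if (ep > 0.85 * epochs) 0.09
        else if (ep > 0.60 * epochs) 0.3
        else 1
      ord <- sample.int(n)
      step <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        rows_b <- ord[start:min(start + batch_size - 1L, n)]
        if (!any(train$mask[rows_b])) next  # cannot score features
        step <- step + 1L
        st <- .adapter_step(params,
                            train$X[rows_b, , drop = FALSE],
                            lapply(train$targets, function(t) t[rows_b]),
                            train$mask[rows_b], cfg)
        if (!is.finite(st$breakdown$l_total))
          stop("training diverged (non-finite loss) at epoch ", ep,
               ", step ", step)
        grads <- .clip_grads(st$grads, clip)
        upd <- .adam_step(params, grads, state, lr_ep)
        params <- upd$params
        state <- upd$state
        hr <- hr + 1L
        hist_rows[[hr]] <- c(epoch = ep, step = step,
                             l_rec = st$breakdown$l_rec,
                             stats::setNames(st$breakdown$l_hcf,
                                             paste0("l_hcf_", tnames)),
                             stats::setNames(st$breakdown$l_adv,
                                             paste0("l_adv_", tnames)),
                             l_total = st$breakdown$l_total)
      }
      vb <- if (!is.null(val))
        .adapter_eval(params, val$X, val$targets, val$mask, cfg)
      else .adapter_eval(params, train$X, train$targets, train$mask, cfg)
      epoch_log[[ep]] <- c(epoch = ep, val_l_rec = vb$l_rec,
                           val_l_total = vb$l_total,
                           stats::setNames(vb$l_hcf,
                                           paste0("val_l_hcf_", tnames)),
                           stats::setNames(vb$l_adv,
                                           paste0("val_l_adv_", tnames)))
      if (verbose)
        cat(sprintf("epoch %3d  val Lrec %.5f  val Ltotal %.5f\n",
                    ep, vb$l_rec, vb$l_total))
      if (vb$l_total < best$loss)
        best <- list(loss = vb$l_total, params = params, epoch = ep)
    }
    structure(
      list(params = best$params, final_params = params, config = cfg,
           splits = splits, best_epoch = best$epoch,
           history = as.data.frame(do.call(rbind, hist_rows[seq_len(hr)])),
           epoch_log = as.data.frame(do.call(rbind, epoch_log)),
           layout = feature_layout(), backbone_tag = attr(x, "backbone_tag")),
      class = "plmx_adapter")
  })
}

# ---- public encoder/decoder/adversary surfaces -----------------------------

#' Encode embeddings into the partitioned representation
#'
#' @param adapter A fitted `plmx_adapter`.
#' @param x An L x D matrix of per-residue embeddings.
#' @return List with `informed` (L x 34, Tanh-scaled) and `residual`
#'   (L x (D-34)).
#' @export
adapter_encode <- function(adapter, x) {
  x <- as.matrix(x)
  if (ncol(x) != adapter$config$D)
    stop("input width ", ncol(x), " does not match adapter D = ",
         adapter$config$D)
  enc <- .encode_forward(adapter$params, x)
  list(informed = enc$informed, residual = enc$residual)
}

#' Decode a partitioned representation back to the embedding space
#'
#' @param adapter A fitted `plmx_adapter`.
#' @param informed L x 34 informed matrix (or an L x D concatenated
#'   partition if `residual` is missing).
#' @param residual L x (D-34) residual matrix.
#' @return L x D reconstruction.
#' @export
adapter_decode <- function(adapter, informed, residual = NULL) {
  Z <- if (is.null(residual)) as.matrix(informed)
       else cbind(as.matrix(informed), as.matrix(residual))
  if (ncol(Z) != adapter$config$D)
    stop("partitioned width ", ncol(Z), " does not match adapter D = ",
         adapter$config$D)
  .decode_forward(adapter$params, Z)$xrec
}

#' Run the adversarial heads on residual vectors
#'
#' @param adapter A fitted `plmx_adapter`.
#' @param residual L x (D-34) residual matrix.
#' @return Named list (one element per task) of L x 34 head outputs; the
#'   task's own slice of the 34 positions carries its prediction.
#' @export
adapter_adversary <- function(adapter, residual) {
  residual <- as.matrix(residual)
  if (ncol(residual) != adapter$config$D - 34L)
    stop("residual width ", ncol(residual), " does not match D - 34 = ",
         adapter$config$D - 34L)
  out <- lapply(feature_layout()$tasks, function(tk)
    .adversary_forward(adapter$params, residual, tk$name)$o)
  names(out) <- vapply(feature_layout()$tasks, `[[`, "", "name")
  out
}

# ---- S3 methods ------------------------------------------------------------

#' Transform embeddings with a fitted adapter
#'
#' @param object A fitted `plmx_adapter`.
#' @param newdata An L x D matrix or a named list of such matrices.
#' @param type `"partitioned"` (L x D matrix: informed columns then
#'   residual columns, named `ss3_H ... aa_Y, feature_35 ... feature_D`),
#'   `"informed"`, `"residual"`, or `"reconstruction"`. No residues are
#'   filtered at transform time.
#' @param ... Unused.
#' @return A matrix (or named list of matrices, mirroring the input).
#' @export
predict.plmx_adapter <- function(object, newdata,
                                 type = c("partitioned", "informed",
                                          "residual", "reconstruction"),
                                 ...) {
  type <- match.arg(type)
  one <- function(m) {
    enc <- adapter_encode(object, m)
    switch(type,
           partitioned = {
             out <- cbind(enc$informed, enc$residual)
             colnames(out) <- partitioned_feature_names(object$config$D)
             out
           },
           informed = { colnames(enc$informed) <- object$layout$names
                        enc$informed },
           residual = enc$residual,
           reconstruction = adapter_decode(object, enc$informed,
                                           enc$residual))
  }
  if (is.list(newdata)) lapply(newdata, one) else one(as.matrix(newdata))
}

#' Feature names of the partitioned embedding space
#'
#' The 34 informed names from [feature_layout()] followed by the residual
#' coordinates, labelled by their global index (`feature_35` ...
#' `feature_D`) as in attribution reports.
#'
#' @param D Backbone dimension.
#' @return Character vector of length `D`.
#' @export
partitioned_feature_names <- function(D) {
  c(feature_layout()$names, paste0("feature_", seq.int(35L, D)))
}

#' @export
print.plmx_adapter <- function(x, ...) {
  cfg <- x$config
  cat("Partitioning adapter (informed 34 + residual", cfg$D - 34L,
      "= D =", cfg$D, ")\n")
  cat("  lambda_rec =", cfg$lambda_rec,
      " lambda_adv =", paste(unique(cfg$lambda_adv), collapse = "/"),
      " grl_scale =", cfg$grl_scale, "\n")
  cat("  trained", cfg$epochs, "epochs; best epoch", x$best_epoch,
      sprintf("(validation Lrec %.5f, Ltotal %.4f)\n",
              x$epoch_log$val_l_rec[x$best_epoch],
              x$epoch_log$val_l_total[x$best_epoch]))
  invisible(x)
}

#' @export
coef.plmx_adapter <- function(object, ...) {
  tnames <- vapply(object$layout$tasks, `[[`, "", "name")
  list(task_scale = stats::setNames(exp(object$params$enc_rho), tnames),
       lambda_rec = object$config$lambda_rec,
       lambda_hcf = object$config$lambda_hcf,
       lambda_adv = object$config$lambda_adv)
}

#' @export
residuals.plmx_adapter <- function(object, x, ...) {
  one <- function(m) m - predict(object, m, type = "reconstruction")
  if (is.list(x)) lapply(x, one) else one(as.matrix(x))
}

#' @export
plot.plmx_adapter <- function(x, ...) {
  el <- x$epoch_log
  graphics::par(mfrow = c(1, 2))
  graphics::plot(el$epoch, el$val_l_total, type = "l", xlab = "epoch",
                 ylab = "validation L_total", main = "Total loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::plot(el$epoch, el$val_l_rec, type = "l", xlab = "epoch",
                 ylab = "validation L_rec (MAE)", main = "Reconstruction",
                 ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Summarize informed-subspace fidelity of a fitted adapter
#'
#' Evaluates the informed head on a set of proteins (default: the test
#' split is not available here, so the caller passes embeddings and
#' annotations): classification accuracy for SS3/SS8/amino
#' acid/aromaticity and mean absolute error for ASA/GRAVY, over
#' masked-in residues.
#'
#' @param object A fitted `plmx_adapter`.
#' @param x Named list of embedding matrices.
#' @param annotations Matching annotations.
#' @param ids Protein ids to evaluate (default all of `x`).
#' @param ... Unused.
#' @return A data frame with columns `task`, `metric`, `value`, plus the
#'   validation loss breakdown as attributes.
#' @export
summary.plmx_adapter <- function(object, x = NULL, annotations = NULL,
                                 ids = NULL, ...) {
  if (is.null(x)) {
    cat("Fitted adapter; supply embeddings and annotations for informed-",
        "head metrics.\n", sep = "")
    return(invisible(print(object)))
  }
  if (inherits(x, "plmx_synthetic")) { annotations <- x$annotations
                                       x <- x$embeddings }
  if (is.null(ids)) ids <- names(x)
  ds <- .stack_dataset(x, annotations, ids)
  enc <- adapter_encode(object, ds$X)
  rows <- which(ds$mask)
  out <- lapply(object$layout$tasks, function(tk) {
    sl <- enc$informed[rows, tk$idx, drop = FALSE]
    y <- ds$targets[[tk$name]][rows]
    if (tk$kind == "ce")
      data.frame(task = tk$name, metric = "accuracy",
                 value = mean(max.col(sl, "first") == y))
    else if (tk$kind == "bce")
      data.frame(task = tk$name, metric = "accuracy",
                 value = mean((drop(sl) > 0) == (y > 0.5)))
    else
      data.frame(task = tk$name, metric = "l1",
                 value = mean(abs(drop(sl) - y)))
  })
  res <- do.call(rbind, out)
  class(res) <- c("summary.plmx_adapter", "data.frame")
  res
}
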