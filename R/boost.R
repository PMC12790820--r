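# Gradient-boosted decision trees for binary classification (logistic
# loss, Newton leaf values), equivalent in configuration to the classic
# scikit-learn GradientBoostingClassifier. Trees are stored as flat
# arrays (feature, threshold, children, value, cover) so exact tree-SHAP
# can walk them directly.

# fit one SSE regression tree to targets r; returns flat node arrays and
# the training-row assignment of every node (cover)
.fit_tree <- function(X, r, max_depth, min_leaf = 1L) {
  nodes <- new.env(parent = emptyenv())
  nodes$feature <- integer(0)    # NA_integer_ for leaves
  nodes$threshold <- numeric(0)
  nodes$left <- integer(0)
  nodes$right <- integer(0)
  nodes$value <- numeric(0)
  nodes$cover <- numeric(0)
  nodes$rows <- list()

  new_node <- function() {
    id <- length(nodes$feature) + 1L
    nodes$feature[id] <- NA_integer_
    nodes$threshold[id] <- NA_real_
    nodes$left[id] <- 0L; nodes$right[id] <- 0L
    nodes$value[id] <- 0; nodes$cover[id] <- 0
    id
  }

  grow <- function(rows, depth) {
    id <- new_node()
    nodes$cover[id] <- length(rows)
    nodes$rows[[id]] <- rows
    nodes$value[id] <- mean(r[rows])
    if (depth >= max_depth || length(rows) < 2L * min_leaf ||
        length(rows) < 2L) return(id)
    y <- r[rows]
    sy <- sum(y); n <- length(y)
    best <- list(gain = 1e-12, feature = NA_integer_, thr = NA_real_)
    for (j in seq_len(ncol(X))) {
      xj <- X[rows, j]
      o <- order(xj)
      xs <- xj[o]; ys <- y[o]
      cs <- cumsum(ys)
      nl <- seq_len(n - 1L)
      ok <- xs[nl] < xs[nl + 1L] & nl >= min_leaf & (n - nl) >= min_leaf
      if (!any(ok)) next
      gain <- cs[nl]^2 / nl + (sy - cs[nl])^2 / (n - nl) - sy^2 / n
      gain[!ok] <- -Inf
      bi <- which.max(gain)
      if (gain[bi] > best$gain) {
        best <- list(gain = gain[bi], feature = j,
                     thr = (xs[bi] + xs[bi + 1L]) / 2)
      }
    }
    if (is.na(best$feature)) return(id)
    go_left <- X[rows, best$feature] <= best$thr
    nodes$feature[id] <- best$feature
    nodes$threshold[id] <- best$thr
    lid <- grow(rows[go_left], depth + 1L)
    rid <- grow(rows[!go_left], depth + 1L)
    nodes$feature[id] <- best$feature   # re-set: vectors grew during recursion
    nodes$threshold[id] <- best$thr
    nodes$left[id] <- lid; nodes$right[id] <- rid
    id
  }
  grow(seq_len(nrow(X)), 0L)
  list(feature = nodes$feature, threshold = nodes$threshold,
       left = nodes$left, right = nodes$right, value = nodes$value,
       cover = nodes$cover, rows = nodes$rows)
}

.tree_leaf_of <- function(tree, x) {
  id <- 1L
  while (!is.na(tree$feature[id]))
    id <- if (x[tree$feature[id]] <= tree$threshold[id]) tree$left[id]
          else tree$right[id]
  id
}

.tree_predict <- function(tree, X) {
  vapply(seq_len(nrow(X)), function(i)
    tree$value[.tree_leaf_of(tree, X[i, ])], numeric(1))
}

#' Fit a gradient-boosting classifier on pooled embeddings
#'
#' Binary gradient-boosted trees with logistic loss and Newton leaf
#' updates; the downstream-evaluation configuration is a maximum of 100
#' boosting iterations, maximum tree depth 4 and learning rate 0.05.
#'
#' @param X Numeric feature matrix (one pooled embedding per row).
#' @param y 0/1 labels (both classes must be present).
#' @param n_trees,max_depth,learning_rate Boosting hyperparameters
#'   (defaults 100, 4, 0.05).
#' @return An object of class `plmx_gbc` with `trees`, `f0` (intercept
#'   log-odds), the configuration, and `feature_names`.
#' @export
gbc_fit <- function(X, y, n_trees = 100, max_depth = 4,
                    learning_rate = 0.05) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("single-class labels: gradient boosting needs both classes")
  n <- nrow(X)
  p0 <- mean(y)
  f0 <- log(p0 / (1 - p0))
  Fv <- rep(f0, n)
  trees <- vector("list", n_trees)
  for (m in seq_len(n_trees)) {
    p <- .sigmoid(Fv)
    tree <- .fit_tree(X, y - p, max_depth)
    # Newton step per leaf, scaled by the learning rate
    leaves <- which(is.na(tree$feature))
    for (id in leaves) {
      rows <- tree$rows[[id]]
      num <- sum(y[rows] - p[rows])
      den <- sum(p[rows] * (1 - p[rows]))
      tree$value[id] <- learning_rate * num / max(den, 1e-12)
    }
    tree$value[!is.na(tree$feature)] <- 0
    tree$rows <- NULL
    trees[[m]] <- tree
    Fv <- Fv + .tree_predict(tree, X)
  }
  structure(list(trees = trees, f0 = f0, n_trees = n_trees,
                 max_depth = max_depth, learning_rate = learning_rate,
                 dim = ncol(X), feature_names = colnames(X)),
            class = "plmx_gbc")
}

#' @rdname gbc_fit
#' @param object A fitted `plmx_gbc`.
#' @param newdata Feature matrix to score.
#' @param type `"response"` (probability of class 1), `"link"`
#'   (log-odds), or `"class"`.
#' @param ... Unused.
#' @export
predict.plmx_gbc <- function(object, newdata,
                             type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != object$dim)
    stop("feature-space mismatch: model has ", object$dim,
         " features, data has ", ncol(X))
  Fv <- rep(object$f0, nrow(X))
  for (tree in object$trees) Fv <- Fv + .tree_predict(tree, X)
  switch(type,
         link = Fv,
         response = .sigmoid(Fv),
         class = as.integer(Fv > 0))
}

#' @export
print.plmx_gbc <- function(x, ...) {
  cat("Gradient-boosting classifier:", x$n_trees, "trees, depth",
      x$max_depth, ", learning rate", x$learning_rate, ",",
      x$dim, "features\n")
  invisible(x)
}
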