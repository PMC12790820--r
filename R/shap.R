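# Exact SHAP attribution. For the tree ensemble: the path-dependent
# tree-SHAP recursion (polynomial in tree depth), whose output satisfies
# local accuracy exactly: per-sample SHAP values sum to the model's
# log-odds output minus the cover-weighted expected output. A brute-force
# subset-enumeration oracle lives in the test suite. For the CNN filter
# game a permutation estimator is used (also exactly efficient).

# ---- path-dependent tree SHAP ---------------------------------------------

# m is a list of equal-length vectors d, z, o, w describing the active path
.shap_extend <- function(m, pz, po, pi) {
  l <- length(m$d)
  m$d <- c(m$d, pi); m$z <- c(m$z, pz); m$o <- c(m$o, po)
  m$w <- c(m$w, if (l == 0L) 1 else 0)
  if (l >= 1L) for (i in l:1) {
    m$w[i + 1L] <- m$w[i + 1L] + po * m$w[i] * i / (l + 1)
    m$w[i] <- pz * m$w[i] * (l + 1 - i) / (l + 1)
  }
  m
}

.shap_unwind <- function(m, i) {
  l <- length(m$d)
  n <- m$w[l]
  if (l >= 2L) for (j in (l - 1L):1L) {
    if (m$o[i] != 0) {
      t0 <- m$w[j]
      m$w[j] <- n * l / (j * m$o[i])
      n <- t0 - m$w[j] * m$z[i] * (l - j) / l
    } else {
      m$w[j] <- m$w[j] * l / (m$z[i] * (l - j))
    }
  }
  if (i <= l - 1L) for (j in i:(l - 1L)) {
    m$d[j] <- m$d[j + 1L]; m$z[j] <- m$z[j + 1L]; m$o[j] <- m$o[j + 1L]
  }
  m$d <- m$d[-l]; m$z <- m$z[-l]; m$o <- m$o[-l]; m$w <- m$w[-l]
  m
}

.shap_unwound_sum <- function(m, i) {
  sum(.shap_unwind(m, i)$w)
}

# SHAP values of one tree at one point x; phi has one entry per feature
.tree_shap_one <- function(tree, x, n_features) {
  phi <- numeric(n_features)
  recurse <- function(j, m, pz, po, pi) {
    m <- .shap_extend(m, pz, po, pi)
    if (is.na(tree$feature[j])) {
      l <- length(m$d)
      if (l >= 2L) for (i in 2:l) {
        w <- .shap_unwound_sum(m, i)
        phi[m$d[i]] <<- phi[m$d[i]] + w * (m$o[i] - m$z[i]) * tree$value[j]
      }
    } else {
      d <- tree$feature[j]
      if (x[d] <= tree$threshold[j]) { h <- tree$left[j]; c <- tree$right[j] }
      else                           { h <- tree$right[j]; c <- tree$left[j] }
      iz <- 1; io <- 1
      k <- which(m$d == d)[1]
      if (!is.na(k)) {
        iz <- m$z[k]; io <- m$o[k]
        m <- .shap_unwind(m, k)
      }
      rj <- tree$cover[j]
      recurse(h, m, iz * tree$cover[h] / rj, io, d)
      recurse(c, m, iz * tree$cover[c] / rj, 0, d)
    }
  }
  recurse(1L, list(d = integer(0), z = numeric(0), o = numeric(0),
                   w = numeric(0)), 1, 1, 0L)
  phi
}

# cover-weighted expected value of a tree
.tree_expected <- function(tree) {
  leaves <- which(is.na(tree$feature))
  sum(tree$value[leaves] * tree$cover[leaves]) / tree$cover[1]
}

#' Exact SHAP values for a gradient-boosting classifier
#'
#' Path-dependent tree SHAP over all trees of a [gbc_fit()] model, on the
#' log-odds (link) scale. For every sample, `rowSums(shap) + base_value`
#' equals `predict(model, X, type = "link")` exactly.
#'
#' @param model A fitted `plmx_gbc`.
#' @param X Matrix of samples to explain (same feature space).
#' @return A list with `shap` (n x D matrix) and `base_value` (scalar:
#'   intercept plus the cover-weighted expectation of every tree).
#' @export
gbc_shap <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$dim)
    stop("feature-space mismatch: model has ", model$dim,
         " features, data has ", ncol(X))
  phi <- matrix(0, nrow(X), ncol(X))
  base <- model$f0
  for (tree in model$trees) {
    base <- base + .tree_expected(tree)
    for (i in seq_len(nrow(X)))
      phi[i, ] <- phi[i, ] + .tree_shap_one(tree, X[i, ], ncol(X))
  }
  colnames(phi) <- model$feature_names
  list(shap = phi, base_value = base)
}

# ---- global attribution report --------------------------------------------

#' Global SHAP attribution report for a pooled-embedding classifier
#'
#' Computes exact tree-SHAP values for every sample and aggregates them
#' per feature: mean absolute SHAP (importance) and the sign of the mean
#' SHAP (contribution direction). Informed features carry their
#' biochemical names; residual coordinates are tagged by their global
#' index.
#'
#' @param model A fitted `plmx_gbc` over a partitioned (or any named)
#'   feature space.
#' @param X Samples to explain.
#' @return An `attribution_report` data frame with columns `feature`,
#'   `subspace` (`"informed"` or `"residual"`), `mean_abs_shap`,
#'   `mean_shap`, `direction`; the per-sample SHAP matrix and base value
#'   are attached as attributes `"shap"` and `"base_value"`.
#' @export
global_attribution <- function(model, X) {
  sh <- gbc_shap(model, X)
  nm <- model$feature_names
  if (is.null(nm)) nm <- paste0("x", seq_len(model$dim))
  informed <- feature_layout()$names
  rep <- data.frame(
    feature = nm,
    subspace = ifelse(nm %in% informed, "informed", "residual"),
    mean_abs_shap = colMeans(abs(sh$shap)),
    mean_shap = colMeans(sh$shap),
    row.names = NULL
  )
  rep$direction <- sign(rep$mean_shap)
  attr(rep, "shap") <- sh$shap
  attr(rep, "base_value") <- sh$base_value
  class(rep) <- c("attribution_report", "data.frame")
  rep
}

#' Top-k feature occurrence across bootstrap attribution reports
#'
#' For each feature, counts in how many bootstrap runs it ranks among the
#' top `k` by mean absolute SHAP (ties at rank `k` broken by feature
#' index, lower index first) -- the quantity shown by occurrence bar
#' plots of global feature importance.
#'
#' @param reports List of `attribution_report`s (one per bootstrap run).
#' @param k Rank cutoff (default 10).
#' @return Data frame `feature`, `subspace`, `count`, sorted by
#'   decreasing count (ties by feature index).
#' @export
top_feature_occurrence <- function(reports, k = 10) {
  stopifnot(length(reports) >= 1L)
  base <- reports[[1]]
  counts <- integer(nrow(base))
  for (r in reports) {
    ord <- order(-r$mean_abs_shap, seq_len(nrow(r)))
    top <- ord[seq_len(min(k, length(ord)))]
    counts[top] <- counts[top] + 1L
  }
  out <- data.frame(feature = base$feature, subspace = base$subspace,
                    count = counts)
  out[order(-out$count, seq_len(nrow(out))), , drop = FALSE]
}

#' @export
plot.attribution_report <- function(x, top = 10, ...) {
  ord <- order(-x$mean_abs_shap, seq_len(nrow(x)))[seq_len(min(top, nrow(x)))]
  sel <- x[rev(ord), ]
  vals <- sign(sel$mean_shap) * sel$mean_abs_shap
  graphics::barplot(vals, names.arg = sel$feature, horiz = TRUE, las = 1,
                    col = ifelse(sel$subspace == "informed",
                                 "steelblue", "firebrick"),
                    xlab = "signed mean |SHAP|", ...)
  invisible(x)
}

# ---- permutation SHAP for the CNN filter game -----------------------------

# exact-efficiency permutation estimator for the game
# v(S) = relu(sum_{d in S} con[d] + sum_{d notin S} ref[d] + bias)
.permutation_shap_relu <- function(con, ref, bias, n_perm) {
  D <- length(con)
  phi <- numeric(D)
  delta <- con - ref
  base <- sum(ref) + bias
  for (p in seq_len(n_perm)) {
    perm <- sample.int(D)
    path <- base + c(0, cumsum(delta[perm]))
    contrib <- diff(pmax(path, 0))
    phi[perm] <- phi[perm] + contrib
  }
  phi / n_perm
}
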