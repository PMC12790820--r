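# SHAP attribution: exactness of the tree recursion against brute-force
# subset enumeration, local accuracy, occurrence counting, and the local
# CNN filter analysis.

test_that("tree SHAP equals brute-force Shapley enumeration", {
  set.seed(17)
  for (rep in 1:3) {
    X <- matrix(rnorm(60 * 5), 60, 5)
    y <- as.integer(X[, 2] - X[, 4] + 0.3 * rnorm(60) > 0)
    model <- gbc_fit(X, y, n_trees = 4, max_depth = 3, learning_rate = 0.2)
    for (i in c(1, 7, 33)) {
      for (tree in model$trees) {
        fast <- plmx:::.tree_shap_one(tree, X[i, ], 5L)
        slow <- tree_shap_bruteforce(tree, X[i, ], 5L)
        expect_equal(fast, slow, tolerance = 1e-8)
      }
    }
  }
})

test_that("SHAP local accuracy holds on every explained sample", {
  set.seed(19)
  X <- matrix(rnorm(80 * 6), 80, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- as.integer(X[, 1] + 0.5 * X[, 5] > 0)
  model <- gbc_fit(X, y, n_trees = 30, max_depth = 4, learning_rate = 0.1)
  sh <- gbc_shap(model, X)
  link <- predict(model, X, type = "link")
  expect_lt(max(abs(rowSums(sh$shap) + sh$base_value - link)), 1e-6)
})

test_that("a single stump puts all SHAP mass on its split feature", {
  set.seed(23)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- as.integer(X[, 3] > 0)
  model <- gbc_fit(X, y, n_trees = 1, max_depth = 1, learning_rate = 1)
  sh <- gbc_shap(model, X)
  expect_true(all(sh$shap[, -3] == 0))
  expect_gt(max(abs(sh$shap[, 3])), 0)
})

test_that("attribution reports label subspaces and count occurrences", {
  set.seed(29)
  nms <- partitioned_feature_names(40)
  X <- matrix(rnorm(100 * 40), 100, 40)
  colnames(X) <- nms
  y <- as.integer(X[, 13] > 0)           # the gravy column drives the label
  model <- gbc_fit(X, y, n_trees = 20, max_depth = 3, learning_rate = 0.2)
  rep1 <- global_attribution(model, X)
  expect_s3_class(rep1, "attribution_report")
  expect_identical(rep1$feature, nms)
  expect_identical(rep1$subspace,
                   c(rep("informed", 34), rep("residual", 6)))
  expect_identical(rep1$feature[which.max(rep1$mean_abs_shap)], "gravy")
  # feature names round-trip the layout bijectively
  expect_identical(anyDuplicated(nms), 0L)
  expect_identical(nms[1:34], feature_layout()$names)

  # occurrence counting vs brute-force re-ranking
  reports <- lapply(1:5, function(s) {
    idx <- plmx:::.with_seed(s, sample.int(100, 80))
    m <- gbc_fit(X[idx, ], y[idx], n_trees = 10, max_depth = 3,
                 learning_rate = 0.2)
    global_attribution(m, X)
  })
  occ <- top_feature_occurrence(reports, k = 10)
  brute <- integer(length(nms))
  for (r in reports) {
    top <- order(-r$mean_abs_shap, seq_along(nms))[1:10]
    brute[top] <- brute[top] + 1L
  }
  expect_identical(occ$count[match(nms, occ$feature)], brute)
  expect_identical(occ$count[occ$feature == "gravy"], 5L)
  # a feature never in any top-10 has count 0
  expect_true(any(occ$count == 0L))
  # identical runs: the top feature appears in all of them
  same <- top_feature_occurrence(rep(list(rep1), 10), k = 10)
  expect_identical(same$count[same$feature == "gravy"], 10L)
})

test_that("local filter attribution selects, explains and flags filters", {
  motif <- plmx:::.with_seed(37, matrix(rnorm(6 * 12, sd = 2), 6, 12))
  tr <- make_motif_data(100, L = 30, D = 12, motif = motif, seed = 41)
  cnn <- cnn_fit(tr$X, tr$y, kernel = 6, n_filters = 8, seed = 2)
  pos_protein <- make_motif_data(2, L = 30, D = 12, motif = motif, seed = 43)
  X <- pos_protein$X[[2]]                # the positive one
  rep <- local_filter_attribution(cnn, X, background = tr$X[1:10], seed = 1)
  expect_s3_class(rep, "local_filter_report")
  # the selected filter is the argmax of the max post-ReLU activation
  acts <- conv_activations(cnn, X)
  expect_identical(rep$filter, which.max(apply(acts, 2, max)))
  expect_equal(rep$activation, acts[, rep$filter])
  # per-position efficiency: SHAP sums to activation - baseline
  expect_lt(max(abs(rowSums(rep$shap) - (rep$activation - rep$baseline))),
            1e-9)
  # the window containing the motif carries the maximal summed |SHAP|
  motif_pos <- pos_protein$pos[2]
  best <- which.max(rowSums(abs(rep$shap)))
  expect_true(best >= motif_pos - 5 && best <= motif_pos + 5)
  # top-5 lists and low-confidence flags are well formed
  expect_true(all(lengths(rep$top_features) == 5L))
  expect_identical(rep$low_confidence,
                   rep$activation < 0.1 * max(rep$activation))
})

test_that("degenerate filter activations fall back to tie-breaks", {
  # a one-filter CNN is always selected; all-zero activations are flagged
  cnn <- structure(list(params = list(W = matrix(0, 6 * 4, 2),
                                      b = c(0, 0), w = matrix(1, 2, 1),
                                      c = 0),
                        kernel = 6L, n_filters = 2L, dim = 4L),
                   class = "plmx_cnn")
  X <- matrix(rnorm(40), 10, 4)
  rep <- local_filter_attribution(cnn, X, background = X, seed = 1)
  expect_identical(rep$filter, 1L)       # identical filters: lowest index
  expect_true(rep$all_zero)
  expect_true(all(rep$shap == 0))
})

test_that("attribution reports serialize to TSV and JSON", {
  set.seed(43)
  X <- matrix(rnorm(40 * 6), 40, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- as.integer(X[, 1] > 0)
  model <- gbc_fit(X, y, n_trees = 5, max_depth = 2, learning_rate = 0.3)
  rep <- global_attribution(model, X)
  paths <- write_attribution(rep, tempfile())
  expect_true(all(file.exists(paths)))
  tab <- read.delim(paths[1])
  expect_identical(tab$feature, colnames(X))
})
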