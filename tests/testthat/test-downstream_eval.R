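# Downstream evaluation protocol: pooling, the crafted-only reduction,
# the pooled gradient-boosting classifier, the CNN, bootstrap confidence
# intervals, and residual probes.

test_that("mean pooling matches the naive loop and ignores residue order", {
  expect_equal(mean_pool(matrix(3, 5, 4)), rep(3, 4))
  expect_equal(mean_pool(rbind(rep(0, 6), rep(2, 6))), rep(1, 6))
  set.seed(1)
  m <- matrix(rnorm(35), 5, 7)
  naive <- numeric(7)
  for (j in 1:7) for (i in 1:5) naive[j] <- naive[j] + m[i, j] / 5
  expect_equal(mean_pool(m), naive, tolerance = 1e-12)
  for (s in 1:20) {
    perm <- sample.int(nrow(m))
    expect_equal(mean_pool(m[perm, ]), mean_pool(m))
  }
  expect_error(mean_pool(matrix(numeric(0), 0, 3)), "empty")
})

test_that("crafted-only reduction discretizes multi-class blocks", {
  lay <- feature_layout()
  x <- matrix(0, 1, 34)
  x[1, 1:3] <- c(0.2, 0.7, 0.1)        # ss3 argmax -> class 2
  x[1, 12] <- 87.2                      # asa passthrough
  x[1, 14] <- 1.2                       # aromatic logit > 0 -> 1
  r <- crafted_only_reduce(x)
  expect_equal(unname(r[1, 1:3]), c(0, 1, 0))
  expect_equal(unname(r[1, 12]), 87.2)
  expect_equal(unname(r[1, 14]), 1)
  # exact ties break to the lowest index
  x[1, 1:3] <- c(0.5, 0.5, 0)
  expect_equal(unname(crafted_only_reduce(x)[1, 1:3]), c(1, 0, 0))
  # idempotent on random informed matrices
  set.seed(9)
  m <- matrix(rnorm(20 * 34), 20, 34)
  once <- crafted_only_reduce(m)
  expect_identical(crafted_only_reduce(once), once)
})

test_that("gradient boosting uses the published configuration and learns", {
  m0 <- train_pooled_classifier(cbind(c(rnorm(10), rnorm(10, 4)), rnorm(20)),
                                rep(0:1, each = 10))
  expect_identical(m0$n_trees, 100)
  expect_identical(m0$max_depth, 4)
  expect_identical(m0$learning_rate, 0.05)
  # linearly separable 2-D toy is memorized
  set.seed(5)
  X <- cbind(c(rnorm(10, -2), rnorm(10, 2)), rnorm(20))
  y <- rep(0:1, each = 10)
  expect_equal(mean(predict(train_pooled_classifier(X, y), X, type = "class")
                    == y), 1.0)
  expect_error(gbc_fit(X, rep(1, 20)), "single-class")
})

test_that("gradient boosting stays at chance on label-free features", {
  set.seed(11)
  X <- matrix(rnorm(200 * 8), 200, 8)
  y <- rep(0:1, 100)
  fit <- train_pooled_classifier(X[1:120, ], y[1:120])
  auc <- roc_auc(predict(fit, X[121:200, ]), y[121:200])
  expect_lt(abs(auc - 0.5), 0.15)
})

test_that("classification metrics match hand computations", {
  y <- c(1, 1, 0, 0)
  s <- c(0.9, 0.4, 0.6, 0.1)
  expect_equal(roc_auc(s, y), 3 / 4)     # 3 of 4 pairs concordant
  expect_equal(accuracy(s, y), 0.5)
  # precision 1/2, recall 1/2
  expect_equal(f1_score(s, y), 0.5)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), y), 0.5)  # all tied
})

test_that("the CNN uses task-specific kernels and learns a planted motif", {
  expect_identical(kernel_for_task("aggregation"), 6L)
  expect_identical(kernel_for_task("ev"), 8L)
  expect_identical(kernel_for_task("transmembrane"), 8L)
  motif <- plmx:::.with_seed(13, matrix(rnorm(6 * 20, sd = 2), 6, 20))
  tr <- make_motif_data(120, motif = motif, seed = 21)
  te <- make_motif_data(60, motif = motif, seed = 22)
  cnn <- cnn_fit(tr$X, tr$y, kernel = 6, seed = 1)
  expect_gte(roc_auc(predict(cnn, te$X), te$y), 0.9)
  # seeded runs are bit-identical
  cnn2 <- cnn_fit(tr$X, tr$y, kernel = 6, seed = 1)
  expect_identical(cnn$val_curve, cnn2$val_curve)
  expect_identical(cnn$params, cnn2$params)
  # sequences shorter than the kernel are zero-padded, not rejected
  short <- matrix(rnorm(3 * 20), 3, 20)
  expect_length(predict(cnn, list(short)), 1L)
})

test_that("bootstrap CIs follow the closed-form t interval", {
  # mock models returning predetermined scores: AUC alternates 0.7 / 0.9
  y_test <- rep(c(1, 0), each = 10)
  neg <- 1:10
  pos_70 <- c(10.5, 10.5, 10.5, 10.5, 10.5, 5.5, 5.5, 5.5, 5.5, 0.5)
  pos_90 <- c(rep(10.5, 8), 5.5, 5.5)
  stopifnot(sum(outer(pos_70, neg, ">")) == 70,
            sum(outer(pos_90, neg, ">")) == 90)
  counter <- new.env(); counter$i <- 0
  train_fn <- function(X, y) {
    counter$i <- counter$i + 1
    structure(list(odd = counter$i %% 2 == 1), class = "mock_clf")
  }
  assign("predict.mock_clf",
         function(object, newdata, ...)
           c(if (object$odd) pos_70 else pos_90, neg) / 11,
         envir = globalenv())
  on.exit(rm("predict.mock_clf", envir = globalenv()), add = TRUE)
  Xtr <- matrix(rnorm(40), 20, 2)
  ev <- bootstrap_evaluate(Xtr, rep(0:1, 10), matrix(0, 20, 2), y_test,
                           train_fn = train_fn, n_rounds = 2, seed = 1)
  auc_row <- ev[ev$metric == "roc_auc", ]
  expect_equal(auc_row$mean, 0.8)
  expect_equal(auc_row$ci_halfwidth,
               qt(0.975, 1) * sd(c(0.7, 0.9)) / sqrt(2), tolerance = 1e-9)
  # zero-variance metrics give a zero half-width, not an error
  const_fn <- function(X, y) structure(list(odd = TRUE), class = "mock_clf")
  ev0 <- bootstrap_evaluate(Xtr, rep(0:1, 10), matrix(0, 20, 2), y_test,
                            train_fn = const_fn, n_rounds = 3, seed = 1)
  expect_equal(ev0[ev0$metric == "roc_auc", "ci_halfwidth"], 0)
  expect_identical(unique(ev0$n_bootstrap), 3)
})

test_that("probes recover copied features and fail on independent ones", {
  set.seed(31)
  # residuals that are an exact copy of the SS8 one-hot: trivially learnable
  y <- sample.int(8, 1500, replace = TRUE)
  X <- diag(8)[y, ]
  fit <- mlp_fit(X[1:1000, ], y[1:1000], kind = "ce", n_classes = 8,
                 hidden = 16, epochs = 60, seed = 1)
  expect_gte(mean(predict(fit, X[1001:1500, ], type = "class")
                  == y[1001:1500]), 0.99)
})

test_that("pooled variants have the documented widths and names", {
  ds <- shared_synth()
  ad <- plmx_adapter(ds, epochs = 2, seed = 5)
  ids <- names(ds$embeddings)[1:8]
  po <- pooled_variant(ds$embeddings, NULL, "original", ids)
  pp <- pooled_variant(ds$embeddings, ad, "partitioned", ids)
  pc <- pooled_variant(ds$embeddings, ad, "crafted_only", ids)
  pi_ <- pooled_variant(ds$embeddings, ad, "informed", ids)
  D <- ncol(ds$embeddings[[1]])
  expect_identical(dim(po), c(8L, D))
  expect_identical(dim(pp), c(8L, D))
  expect_identical(dim(pc), c(8L, 34L))
  expect_identical(dim(pi_), c(8L, 34L))
  expect_identical(colnames(pp), partitioned_feature_names(D))
  expect_error(pooled_variant(ds$embeddings, NULL, "informed", ids),
               "needs a fitted adapter")
})
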