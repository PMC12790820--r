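# The partitioning adapter: architecture shapes, the gradient reversal
# contract, the composite loss, and training behaviour.

test_that("encoder partitions every backbone width into 34 + (D - 34)", {
  for (D in c(48L, 64L, 480L)) {
    p <- plmx:::.adapter_init_params(
      D, stats::setNames(rep(1, 6),
                         c("ss3", "ss8", "asa", "gravy", "aromatic", "aa")))
    x <- matrix(rnorm(3 * D), 3, D)
    enc <- plmx:::.encode_forward(p, x)
    expect_identical(ncol(enc$informed), 34L)
    expect_identical(ncol(enc$residual), D - 34L)
    expect_identical(ncol(enc$informed) + ncol(enc$residual), D)
    # zero input with zero (initial) biases maps to exactly zero informed
    z <- matrix(0, 1, D)
    expect_equal(unname(plmx:::.encode_forward(p, z)$informed),
                 matrix(0, 1, 34))
    # decoder returns to the embedding space deterministically
    dec1 <- plmx:::.decode_forward(p, cbind(enc$informed, enc$residual))
    dec2 <- plmx:::.decode_forward(p, cbind(enc$informed, enc$residual))
    expect_identical(dim(dec1$xrec), c(3L, D))
    expect_identical(dec1$xrec, dec2$xrec)
    # adversary: hidden width floor(D/2), 34-wide output
    adv <- plmx:::.adversary_forward(p, enc$residual, "ss8")
    expect_identical(ncol(adv$q), as.integer(floor(D / 2)))
    expect_identical(ncol(adv$o), 34L)
  }
})

test_that("untrained adversary predicts balanced classes at chance", {
  D <- 64L
  p <- plmx:::.with_seed(3, plmx:::.adapter_init_params(
    D, stats::setNames(rep(1, 6),
                       c("ss3", "ss8", "asa", "gravy", "aromatic", "aa"))))
  res <- plmx:::.with_seed(4, matrix(rnorm(4000 * (D - 34L)), 4000))
  o <- plmx:::.adversary_forward(p, res, "ss8")$o[, 4:11]
  y <- plmx:::.with_seed(5, sample.int(8L, 4000, replace = TRUE))
  acc <- mean(max.col(o, "first") == y)
  expect_lt(abs(acc - 0.125), 0.05)
})

test_that("gradient reversal is identity forward, negated scaled backward", {
  v <- rnorm(10)
  expect_identical(grl_forward(v), v)
  g <- rnorm(10)
  expect_equal(grl_backward(g, scale = 1), -g)
  expect_equal(grl_backward(g, scale = 2.5), -2.5 * g)
  # numerical contract: for f(x) = sum(grl(x)^2), the gradient seen by the
  # upstream parameters equals -scale times the analytic gradient 2x,
  # checked against central finite differences of the unreversed composite
  x <- c(0.3, -1.2, 0.7)
  scale <- 1.7
  analytic <- 2 * x
  fd <- vapply(seq_along(x), function(i) {
    h <- 1e-6
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (sum(grl_forward(xp)^2) - sum(grl_forward(xm)^2)) / (2 * h)
  }, numeric(1))
  expect_equal(fd, analytic, tolerance = 1e-6)
  expect_equal(grl_backward(fd, scale), -scale * analytic, tolerance = 1e-6)
})

test_that("task losses match their closed forms", {
  # perfect continuous prediction
  expect_equal(loss_hcf(c(1, 2, 3), c(1, 2, 3), "l1"), 0)
  # uniform logits over 3 classes: CE = ln 3
  expect_equal(loss_hcf(matrix(0, 4, 3), c(1, 2, 3, 1), "ce"), log(3))
  # the ASA example: |10-12| and |20-16| average to 3
  expect_equal(loss_hcf(c(10, 20), c(12, 16), "l1"), 3)
  # BCE of logit 0 is ln 2 regardless of the label
  expect_equal(loss_hcf(c(0, 0), c(0, 1), "bce"), log(2))
  expect_error(loss_hcf(numeric(0), numeric(0), "l1"), "no residues")
})

test_that("reconstruction loss is the mean absolute error", {
  z <- matrix(rnorm(12), 3, 4)
  expect_equal(loss_rec(z, z), 0)
  expect_equal(loss_rec(matrix(0, 5, 7), matrix(0.018, 5, 7)), 0.018)
  set.seed(2)
  a <- matrix(rnorm(30), 5, 6); b <- matrix(rnorm(30), 5, 6)
  # naive double loop oracle
  acc <- 0
  for (i in 1:5) for (j in 1:6) acc <- acc + abs(a[i, j] - b[i, j])
  expect_equal(loss_rec(a, b), acc / 30, tolerance = 1e-10)
  expect_error(loss_rec(a, b[, 1:3]), "shape mismatch")
})

test_that("the total loss is the exact weighted sum of its parts", {
  tn <- c("ss3", "ss8", "asa", "gravy", "aromatic", "aa")
  br <- list(l_rec = 0.5,
             l_hcf = stats::setNames(c(0.05, 0.05, 0.04, 0.02, 0.02, 0.02), tn),
             l_adv = stats::setNames(c(0.1, 0.05, 0.05, 0.04, 0.03, 0.03), tn))
  expect_equal(loss_total(br, 1, 1, 1), 0.5 + 0.2 + 0.3)
  expect_equal(loss_total(br, 2, 0, 0), 1.0)
  br0 <- list(l_rec = 0, l_hcf = stats::setNames(numeric(6), tn),
              l_adv = stats::setNames(numeric(6), tn))
  expect_equal(loss_total(br0, 1, 1, 1), 0)
  expect_error(loss_total(br, 1, c(ss3 = 1), 1), "missing task weight")
})

test_that("training is deterministic and logs exact loss breakdowns", {
  ds <- shared_synth()
  a1 <- plmx_adapter(ds, epochs = 3, seed = 7)
  a2 <- plmx_adapter(ds, epochs = 3, seed = 7)
  expect_identical(a1$history, a2$history)
  expect_identical(a1$params, a2$params)
  # every logged step satisfies the weighted-sum identity
  tn <- c("ss3", "ss8", "asa", "gravy", "aromatic", "aa")
  h <- a1$history
  recomputed <- h$l_rec + rowSums(h[, paste0("l_hcf_", tn)]) +
    rowSums(h[, paste0("l_adv_", tn)])
  expect_lt(max(abs(recomputed - h$l_total) / abs(h$l_total)), 1e-6)
  # validation reconstruction improves over training
  a3 <- plmx_adapter(ds, lambda_adv = 0, epochs = 6, seed = 7)
  expect_lt(a3$epoch_log$val_l_rec[a3$best_epoch], a3$epoch_log$val_l_rec[1])
})

test_that("encoder gradient step on the adversarial path raises L_adv", {
  ds <- shared_synth()
  ad <- plmx_adapter(ds, epochs = 2, seed = 1)
  st <- plmx:::.stack_dataset(ds$embeddings, ds$annotations,
                              ad$splits$train)
  rows <- 1:256
  X <- st$X[rows, , drop = FALSE]
  targets <- lapply(st$targets, function(t) t[rows])
  mask <- st$mask[rows]
  cfg <- ad$config
  # isolate the adversarial path: gradients of the residual branch then
  # come purely through the reversal layer
  cfg0 <- cfg
  cfg0$lambda_rec <- 0
  cfg0$lambda_hcf[] <- 0
  stp <- plmx:::.adapter_step(ad$params, X, targets, mask, cfg0)
  ladv0 <- sum(stp$breakdown$l_adv)
  p2 <- ad$params
  eps <- 1e-3
  for (nm in c("res_W1", "res_b1", "res_W2", "res_b2"))
    p2[[nm]] <- p2[[nm]] - eps * stp$grads[[nm]]
  after <- plmx:::.adapter_eval(p2, X, targets, mask, cfg0)
  expect_gt(sum(after$l_adv), ladv0)
})

test_that("transform is deterministic, complete, and decode-consistent", {
  ds <- shared_synth()
  ad <- plmx_adapter(ds, epochs = 3, seed = 2)
  m <- ds$embeddings[[1]]
  pt <- predict(ad, m, type = "partitioned")
  expect_identical(dim(pt), dim(m))
  expect_identical(colnames(pt)[1:34], feature_layout()$names)
  expect_identical(pt, predict(ad, m, type = "partitioned"))
  inf <- predict(ad, m, type = "informed")
  res <- predict(ad, m, type = "residual")
  expect_identical(ncol(inf), 34L)
  expect_identical(ncol(res), ncol(m) - 34L)
  expect_equal(unname(pt), unname(cbind(inf, res)))
  # low-pLDDT residues are transformed too (no filtering at inference)
  expect_identical(nrow(pt), nrow(m))
  # reconstruction agrees with loss_rec on the same rows
  rec <- predict(ad, m, type = "reconstruction")
  expect_equal(loss_rec(m, rec), mean(abs(residuals(ad, m))))
  expect_error(predict(ad, m[, 1:10]), "width")
})

test_that("fitted adapter methods expose configuration and scales", {
  ds <- shared_synth()
  ad <- plmx_adapter(ds, epochs = 2, seed = 3)
  co <- coef(ad)
  expect_named(co$task_scale,
               c("ss3", "ss8", "asa", "gravy", "aromatic", "aa"))
  expect_true(all(co$task_scale > 0))
  # L1-task scales start near the target range maxima, so ASA's is large
  expect_gt(co$task_scale[["asa"]], co$task_scale[["ss3"]])
  expect_output(print(ad), "informed 34")
  s <- summary(ad, ds)
  expect_identical(nrow(s), 6L)
  expect_true(all(s$value[s$metric == "accuracy"] <= 1))
})
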