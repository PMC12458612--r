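test_that("masked affine matches the naive summation oracle", {
  set.seed(19)
  X <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(8), 4, 2)
  expect_equal(masked_affine(X, matrix(1, 4, 2), W, c(0, 0)),
               X %*% W, tolerance = 1e-12)
  # identity weights under an all-ones mask reproduce the input
  I4 <- diag(4)
  expect_equal(masked_affine(X, matrix(1, 4, 4), I4, rep(0, 4)), X)
  # all-zero mask: every row is act(B)
  B <- c(-1, 2)
  out <- masked_affine(X, matrix(0, 4, 2), W, B, act = "relu")
  expect_equal(out, matrix(rep(pmax(B, 0), each = 3), 3, 2))

  for (i in 1:20) {
    X <- matrix(rnorm(80), 10, 8)
    M <- matrix(rbinom(40, 1, 0.5), 8, 5)
    W <- matrix(rnorm(40), 8, 5)
    B <- rnorm(5)
    expect_equal(masked_affine(X, M, W, B, act = "relu"),
                 masked_affine_oracle(X, M, W, B, act = "relu"),
                 tolerance = 1e-6)
  }
  expect_error(masked_affine(X, M[, 1:3], W, B), "shape")
})

test_that("feature-wise scaling equals a diagonal masked affine", {
  set.seed(20)
  X <- matrix(rnorm(30), 5, 6)
  expect_equal(featurewise_scale(X, rep(1, 6)), X)
  expect_equal(featurewise_scale(X, rep(2, 6)), 2 * X)
  d <- rnorm(6)
  expect_equal(featurewise_scale(X, d),
               masked_affine(X, diag(6), diag(d), rep(0, 6)),
               tolerance = 1e-12)
  expect_error(featurewise_scale(X, d[1:3]), "length")
})

test_that("micro-network forward matches the hand-unrolled computation", {
  mk <- structure(list(
    snp_ids = c("s1", "s2"), cpg_ids = c("c1", "c2"),
    probe_ids = c("p1", "p2"), term_ids = "t1",
    M1 = matrix(c(1, 0, 1, 1), 2, 2,
                dimnames = list(c("s1", "s2"), c("c1", "c2"))),
    M2 = matrix(c(1, 1, 0, 1), 2, 2,
                dimnames = list(c("c1", "c2"), c("p1", "p2"))),
    M3 = matrix(1, 2, 1, dimnames = list(c("p1", "p2"), "t1")),
    variant = "biological"), class = "mask_set")
  cfg <- architecture_config(bypass_width = 1L)
  model <- build_variant(cfg, mk, demo_width = 2L, init_seed = 23L)
  set.seed(24)
  X <- list(snp = matrix(sample(0:2, 10, TRUE), 5, 2),
            cpg = matrix(runif(10), 5, 2),
            expr = matrix(runif(10), 5, 2),
            demo = matrix(rnorm(10), 5, 2))
  expect_equal(predict_hinn(model, X), oracle_hinn_forward(model, X),
               tolerance = 1e-6)

  # zeroing every parameter zeroes the prediction
  zero <- model
  for (p in zero$params) p$value <- p$value * 0
  expect_equal(predict_hinn(zero, X), rep(0, 5))
})

test_that("masked-out weights can never influence outputs or gradients", {
  mk <- toy_masks()
  model <- build_variant(architecture_config(dropout = 0), mk,
                         demo_width = 3L, init_seed = 25L)
  X <- toy_inputs(mk)
  y <- matrix(rnorm(8), ncol = 1)
  base_pred <- predict_hinn(model, X)
  grads_of <- function(m) {
    fw <- hinn_forward(m, X, training = FALSE)
    loss <- hinnlab:::op_mse_loss(fw$out, y, fw$tape)
    hinnlab:::tape_backward(fw$tape, loss)
    lapply(m$params, function(p) p$grad)
  }
  base_grads <- grads_of(model)
  for (nm in c("W1", "Wf2", "Wf3")) {
    mask <- switch(nm, W1 = mk$M1, Wf2 = mk$M2, Wf3 = mk$M3)
    off <- which(mask == 0)
    expect_gt(length(off), 0)
    old <- model$params[[nm]]$value
    model$params[[nm]]$value[off] <- model$params[[nm]]$value[off] + 7
    expect_identical(predict_hinn(model, X), base_pred)
    new_grads <- grads_of(model)
    for (g in names(base_grads))
      expect_identical(new_grads[[g]], base_grads[[g]])
    expect_true(all(new_grads[[nm]][off] == 0))
    model$params[[nm]]$value <- old
  }
})

test_that("backward pass matches central finite differences", {
  mk <- toy_masks()
  model <- build_variant(architecture_config(dropout = 0), mk,
                         demo_width = 3L, init_seed = 26L)
  X <- toy_inputs(mk)
  y <- matrix(rnorm(8), ncol = 1)
  loss_value <- function() {
    fw <- hinn_forward(model, X, training = FALSE)
    mean((fw$out$value - y)^2)
  }
  fw <- hinn_forward(model, X, training = FALSE)
  loss <- hinnlab:::op_mse_loss(fw$out, y, fw$tape)
  hinnlab:::tape_backward(fw$tape, loss)
  h <- 1e-5
  set.seed(27)
  for (nm in c("W1", "D2", "Wf2", "B3", "W_hd1", "G_hb1", "W_out",
               "W_by2")) {
    p <- model$params[[nm]]
    idx <- sample(length(p$value), min(3, length(p$value)))
    for (i in idx) {
      orig <- p$value[i]
      p$value[i] <- orig + h; up <- loss_value()
      p$value[i] <- orig - h; dn <- loss_value()
      p$value[i] <- orig
      fd <- (up - dn) / (2 * h)
      an <- as.numeric(p$grad)[i]
      expect_equal(an, fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("variant construction follows the declared semantics", {
  mk <- toy_masks()
  X <- toy_inputs(mk)
  effective <- function(m) sum(m$masks$M1) + sum(m$masks$M2) +
    sum(m$masks$M3)
  bio <- build_variant(architecture_config(), mk, 3L, init_seed = 1L)
  full <- build_variant(architecture_config(variant = "fully_connected"),
                        mk, 3L, init_seed = 1L)
  expect_gte(effective(full), effective(bio))
  expect_identical(full$masks$snp_ids, bio$masks$snp_ids)

  rnd <- build_variant(architecture_config(variant = "randomized",
                                           randomized_seed = 9L),
                       mk, 3L, init_seed = 1L)
  expect_identical(sum(rnd$masks$M1), sum(mk$M1))

  # drop_snp predictions are invariant to the SNP input
  ds <- build_variant(architecture_config(variant = "drop_snp"), mk, 3L,
                      init_seed = 2L)
  X2 <- X
  X2$snp <- X$snp + 5
  expect_identical(predict_hinn(ds, X), predict_hinn(ds, X2))

  # every variant produces finite predictions of the right length
  for (v in c("hierarchy_only", "drop_cpg", "drop_expr", "no_go",
              "pgnn")) {
    m <- build_variant(architecture_config(variant = v), mk, 3L,
                       init_seed = 3L)
    pr <- predict_hinn(m, X)
    expect_length(pr, nrow(X$snp))
    expect_true(all(is.finite(pr)))
  }

  # pgnn first-layer mask has one entry per (feature, term) path pair
  pg <- build_variant(architecture_config(variant = "pgnn"), mk, 3L,
                      init_seed = 4L)
  snp_term <- (mk$M1 %*% mk$M2 %*% mk$M3) > 0
  cpg_term <- (mk$M2 %*% mk$M3) > 0
  expect_identical(sum(pg$pgnn_mask),
                   sum(snp_term) + sum(cpg_term) + sum(mk$M3))
  expect_identical(dim(pg$pgnn_mask),
                   c(length(mk$snp_ids) + length(mk$cpg_ids) +
                       length(mk$probe_ids), length(mk$term_ids)))
})

test_that("training is deterministic and fits a degenerate target", {
  mk <- toy_masks()
  set.seed(28)
  n <- 60
  X <- list(snp = matrix(sample(0:2, n * 3, TRUE), n),
            cpg = matrix(runif(n * 4), n),
            expr = matrix(runif(n * 3), n),
            demo = matrix(rnorm(n * 2), n))
  tc <- train_config(n_repeats = 2L, max_epochs = 15L, patience = 5L,
                     seed = 5L)
  y <- rnorm(n)
  m1 <- build_variant(architecture_config(), mk, 2L)
  f1 <- train_model(m1, X, y, tc)
  f2 <- train_model(build_variant(architecture_config(), mk, 2L), X, y, tc)
  expect_identical(f1$metrics$per_repeat, f2$metrics$per_repeat)
  expect_identical(f1$splits[[1]]$test, f2$splits[[1]]$test)
  expect_equal(f1$metrics$aggregate$mae_mean,
               mean(f1$metrics$per_repeat$mae))

  # identically-zero phenotype: the learned function collapses onto the
  # target; a proportionate head and enough samples keep the residual at
  # the bias-drift scale
  set.seed(44)
  n0 <- 200
  X0 <- list(snp = matrix(sample(0:2, n0 * 3, TRUE), n0),
             cpg = matrix(runif(n0 * 4), n0),
             expr = matrix(runif(n0 * 3), n0),
             demo = matrix(rnorm(n0 * 2), n0))
  cfg0 <- architecture_config(dropout = 0, head_blocks = 1L,
                              head_width = 8L, bottleneck_width = 4L,
                              bypass_width = 2L)
  f0 <- train_model(build_variant(cfg0, mk, 2L), X0, rep(0, n0),
                    train_config(n_repeats = 1L, max_epochs = 1500L,
                                 patience = 300L, learning_rate = 1e-3,
                                 seed = 6L))
  expect_lte(f0$metrics$per_repeat$mae, 0.05)
})

test_that("baselines share splits, tune by CV and fit linear targets", {
  mk <- toy_masks()
  set.seed(29)
  n <- 80
  X <- list(snp = matrix(sample(0:2, n * 3, TRUE), n),
            cpg = matrix(runif(n * 4), n),
            expr = matrix(runif(n * 3), n),
            demo = matrix(rnorm(n * 2), n))
  colnames(X$snp) <- paste0("s", 1:3)
  colnames(X$cpg) <- paste0("c", 1:4)
  colnames(X$expr) <- paste0("p", 1:3)
  colnames(X$demo) <- paste0("d", 1:2)
  # noiseless linear target is realizable by the lasso
  beta <- rnorm(12)
  y <- as.numeric(cbind(X$snp, X$cpg, X$expr, X$demo) %*% beta)
  tc <- train_config(n_repeats = 2L, seed = 7L)
  res <- run_baselines(X, y, tc, methods = c("l1", "nn"))
  expect_lt(res$l1$aggregate$mse_mean, 1e-3)
  expect_named(res, c("l1", "nn"))
  for (m in res) {
    expect_s3_class(m, "eval_metrics")
    expect_identical(nrow(m$per_repeat), 2L)
    expect_true(all(m$per_repeat$mse >= 0))
  }
  # identical test indices across methods and the network protocol
  sp <- hinnlab:::make_split(n, tc, 1L)
  sp2 <- hinnlab:::make_split(n, tc, 1L)
  expect_identical(sp$test, sp2$test)
})
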