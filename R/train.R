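#' Training configuration
#'
#' The protocol: 70% training / 30% testing, 20% of the training data
#' held out as validation for early stopping with restoration of the best
#' parameters, squared-error loss with L2 regularization, and the whole
#' procedure executed `n_repeats` times (fresh split and initialization
#' per repeat) to report mean and standard deviation of the evaluation
#' metrics.
#'
#' @param test_fraction held-out test fraction.
#' @param validation_fraction fraction of the training data used for
#'   early stopping.
#' @param n_repeats independent repeats.
#' @param patience epochs without validation improvement before stopping.
#' @param max_epochs training-epoch budget.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param seed base seed; repeat seeds are derived from it.
#' @return A `train_config`.
#' @export
train_config <- function(test_fraction = 0.30,
                         validation_fraction = 0.20,
                         n_repeats = 3L,
                         patience = 20L,
                         max_epochs = 500L,
                         learning_rate = 3e-3,
                         batch_size = 64L,
                         seed = 1L) {
  tc <- list(test_fraction = test_fraction,
             validation_fraction = validation_fraction,
             n_repeats = as.integer(n_repeats),
             patience = as.integer(patience),
             max_epochs = as.integer(max_epochs),
             learning_rate = learning_rate,
             batch_size = as.integer(batch_size),
             seed = as.integer(seed))
  if (tc$test_fraction <= 0 || tc$test_fraction >= 1 ||
      tc$validation_fraction <= 0 || tc$validation_fraction >= 1)
    stop("fractions must lie in (0, 1)")
  if (tc$n_repeats < 1) stop("n_repeats must be >= 1")
  structure(tc, class = c("train_config", "list"))
}

# deterministic split shared by all repeats, variants and baselines of a
# run: repeats re-randomize initialization and minibatch order, not the
# split, so variant comparisons are paired on one test set
make_split <- function(n, tc, r) {
  set.seed(tc$seed)
  test <- sort(sample.int(n, floor(tc$test_fraction * n)))
  rest <- setdiff(seq_len(n), test)
  val <- sort(sample(rest, floor(tc$validation_fraction * length(rest))))
  train <- setdiff(rest, val)
  list(train = train, val = val, test = test,
       seed = (tc$seed + 7919L * r) %% 2147483647L)
}

subset_inputs <- function(X, idx) {
  list(snp = X$snp[idx, , drop = FALSE], cpg = X$cpg[idx, , drop = FALSE],
       expr = X$expr[idx, , drop = FALSE],
       demo = X$demo[idx, , drop = FALSE])
}

snapshot_model <- function(model) {
  list(params = lapply(model$params, function(p) p$value),
       bn = lapply(model$bn, function(st)
         list(mean = st$mean, var = st$var)))
}

restore_model <- function(model, snap) {
  for (nm in names(snap$params)) model$params[[nm]]$value <- snap$params[[nm]]
  for (nm in names(snap$bn)) {
    model$bn[[nm]]$mean <- snap$bn[[nm]]$mean
    model$bn[[nm]]$var <- snap$bn[[nm]]$var
  }
  invisible(model)
}

# weight-decay gradients; masked weights decay only inside the mask so
# masked-out entries stay inert
add_l2_grads <- function(model) {
  l2 <- model$cfg$l2_strength
  if (l2 <= 0) return(invisible())
  masks <- list(W1 = model$masks$M1, Wf2 = model$masks$M2,
                Wf3 = if (model$cfg$variant == "drop_expr")
                  model$ct_mask else model$masks$M3,
                W_pgnn = model$pgnn_mask)
  for (nm in names(model$params)) {
    if (!startsWith(nm, "W")) next
    p <- model$params[[nm]]
    if (is.null(p$grad)) next
    dec <- 2 * l2 * p$value
    if (!is.null(masks[[nm]])) dec <- dec * masks[[nm]]
    p$grad <- p$grad + dec
  }
  invisible()
}

#' Train a hierarchical model
#'
#' Per repeat: a seeded 70/30 split with a 20% validation hold-out of the
#' training data, fresh variance-scaled initialization, minibatch Adam on
#' the squared-error loss with L2 weight decay, early stopping on
#' validation loss with restoration of the best parameters, and test-set
#' MAE/MSE. Metrics are aggregated as mean and standard deviation over
#' repeats. Fixed seeds give bit-identical metrics.
#'
#' @param model a `hinn_model` (its architecture is retrained from
#'   scratch each repeat).
#' @param X input list from [prepare_model_data()].
#' @param y numeric phenotype vector aligned with `X`.
#' @param tc a [train_config()].
#' @param phenotype_name label carried into the metrics.
#' @return List with `model` (trained, from the last repeat), `metrics`
#'   (an `eval_metrics`: per-repeat table plus aggregate), `splits`.
#' @export
train_model <- function(model, X, y, tc = train_config(),
                        phenotype_name = "phenotype") {
  n <- length(y)
  if (nrow(X$snp) != n) stop("phenotype length must match sample count")
  per <- data.frame()
  splits <- list()
  for (r in seq_len(tc$n_repeats)) {
    sp <- make_split(n, tc, r)
    splits[[r]] <- sp
    model <- init_model_params(model, seed = (sp$seed + 1L) %% 2147483647L)
    tr_idx <- sp$train
    model$params$B_out$value <- mean(y[tr_idx])
    Xtr <- subset_inputs(X, tr_idx); ytr <- y[tr_idx]
    Xva <- subset_inputs(X, sp$val); yva <- y[sp$val]

    best <- snapshot_model(model)
    best_loss <- Inf
    wait <- 0L
    t_adam <- 0L
    for (epoch in seq_len(tc$max_epochs)) {
      set.seed((sp$seed + 131L * epoch) %% 2147483647L)
      perm <- sample(length(ytr))
      starts <- seq(1L, length(perm), by = tc$batch_size)
      for (s in starts) {
        bi <- perm[s:min(s + tc$batch_size - 1L, length(perm))]
        if (length(bi) < 2L) next   # batch norm needs >= 2 samples
        fw <- hinn_forward(model, subset_inputs(Xtr, bi), training = TRUE)
        loss <- op_mse_loss(fw$out, matrix(ytr[bi], ncol = 1L), fw$tape)
        if (!is.finite(loss$value[1L]))
          stop("non-finite training loss (repeat ", r, ", epoch ",
               epoch, ")")
        tape_backward(fw$tape, loss)
        add_l2_grads(model)
        t_adam <- t_adam + 1L
        adam_step(model$params, tc$learning_rate, t_adam)
      }
      pv <- predict_hinn(model, Xva)
      vloss <- mean((pv - yva)^2)
      if (vloss < best_loss - 1e-12) {
        best_loss <- vloss
        best <- snapshot_model(model)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tc$patience) break
      }
    }
    restore_model(model, best)
    pt <- predict_hinn(model, subset_inputs(X, sp$test))
    per <- rbind(per, data.frame(
      repeat_id = r,
      mae = mean(abs(pt - y[sp$test])),
      mse = mean((pt - y[sp$test])^2)))
  }
  metrics <- eval_metrics(per, variant = model$cfg$variant,
                          phenotype = phenotype_name)
  list(model = model, metrics = metrics, splits = splits)
}

#' Evaluation metrics container
#'
#' @param per_repeat data frame with columns `repeat_id`, `mae`, `mse`.
#' @param variant architecture variant tag.
#' @param phenotype phenotype name.
#' @return An `eval_metrics` with the per-repeat table and aggregate
#'   means and standard deviations.
#' @export
eval_metrics <- function(per_repeat, variant, phenotype) {
  stopifnot(all(per_repeat$mae >= 0), all(per_repeat$mse >= 0))
  structure(list(
    per_repeat = per_repeat,
    aggregate = data.frame(
      mae_mean = mean(per_repeat$mae),
      mae_sd = stats::sd(per_repeat$mae),
      mse_mean = mean(per_repeat$mse),
      mse_sd = stats::sd(per_repeat$mse)),
    variant = variant, phenotype = phenotype),
    class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<eval_metrics> %s / %s: MAE %.3f +/- %.3f, MSE %.3f +/- %.3f (%d repeats)\n",
              x$variant, x$phenotype, a$mae_mean,
              ifelse(is.na(a$mae_sd), 0, a$mae_sd), a$mse_mean,
              ifelse(is.na(a$mse_sd), 0, a$mse_sd),
              nrow(x$per_repeat)))
  invisible(x)
}

#' Classical baseline models
#'
#' Flat concatenated features (SNP dosages, betas, normalized expression,
#' demographics), the same seeded 70/30 splits as [train_model()], a small
#' documented hyperparameter grid per method tuned by 10-fold
#' cross-validation on the training data, and test MAE/MSE per repeat.
#' Methods: `l1` (lasso via glmnet, lambda by 10-fold `cv.glmnet`), `svm`
#' (RBF epsilon-regression, cost grid), `rf` (random forest, mtry grid),
#' `nn` (single-hidden-layer network, decay grid).
#'
#' @param X input list from [prepare_model_data()].
#' @param y numeric phenotype vector.
#' @param tc a [train_config()].
#' @param methods subset of `c("l1", "svm", "rf", "nn")`.
#' @param phenotype_name label carried into the metrics.
#' @return Named list of `eval_metrics`, one per method.
#' @export
run_baselines <- function(X, y, tc = train_config(),
                          methods = c("l1", "svm", "rf", "nn"),
                          phenotype_name = "phenotype") {
  methods <- match.arg(methods, several.ok = TRUE)
  Xf <- cbind(X$snp, X$cpg, X$expr, X$demo)
  n <- length(y)
  out <- list()
  for (m in methods) {
    per <- data.frame()
    for (r in seq_len(tc$n_repeats)) {
      sp <- make_split(n, tc, r)
      tr <- c(sp$train, sp$val)   # baselines tune by CV on all training data
      set.seed((sp$seed + 2L) %% 2147483647L)
      pred <- baseline_fit_predict(m, Xf[tr, , drop = FALSE], y[tr],
                                   Xf[sp$test, , drop = FALSE])
      per <- rbind(per, data.frame(
        repeat_id = r,
        mae = mean(abs(pred - y[sp$test])),
        mse = mean((pred - y[sp$test])^2)))
    }
    out[[m]] <- eval_metrics(per, variant = m, phenotype = phenotype_name)
  }
  out
}

baseline_fit_predict <- function(method, Xtr, ytr, Xte) {
  switch(method,
    l1 = {
      # relaxed lasso: 10-fold CV tunes both lambda and the relaxation,
      # so an unbiased refit on the active set is in the menu
      cv <- glmnet::cv.glmnet(Xtr, ytr, alpha = 1, nfolds = 10,
                              relax = TRUE)
      as.numeric(stats::predict(cv, Xte, s = "lambda.min",
                                gamma = "gamma.min"))
    },
    svm = {
      grid <- expand.grid(cost = c(1, 10))
      best <- tune_by_cv(grid, Xtr, ytr, function(par, xi, yi)
        e1071::svm(xi, yi, type = "eps-regression", cost = par$cost))
      fit <- e1071::svm(Xtr, ytr, type = "eps-regression",
                        cost = best$cost)
      as.numeric(stats::predict(fit, Xte))
    },
    rf = {
      p <- ncol(Xtr)
      grid <- expand.grid(mtry = unique(pmax(1, round(
        c(sqrt(p), p / 3)))))
      best <- tune_by_cv(grid, Xtr, ytr, function(par, xi, yi)
        randomForest::randomForest(xi, yi, ntree = 200, mtry = par$mtry))
      fit <- randomForest::randomForest(Xtr, ytr, ntree = 200,
                                        mtry = best$mtry)
      as.numeric(stats::predict(fit, Xte))
    },
    nn = {
      grid <- expand.grid(decay = c(0.1, 0.01))
      best <- tune_by_cv(grid, Xtr, ytr, function(par, xi, yi)
        nnet::nnet(xi, yi, size = 8, decay = par$decay, linout = TRUE,
                   maxit = 200, trace = FALSE, MaxNWts = 100000))
      fit <- nnet::nnet(Xtr, ytr, size = 8, decay = best$decay,
                        linout = TRUE, maxit = 200, trace = FALSE,
                        MaxNWts = 100000)
      as.numeric(stats::predict(fit, Xte))
    },
    stop("unknown baseline method: ", method))
}

tune_by_cv <- function(grid, Xtr, ytr, fit_fn, nfolds = 10) {
  if (nrow(grid) < 1) stop("hyperparameter grid is empty")
  if (nrow(grid) == 1) return(grid[1, , drop = FALSE])
  folds <- sample(rep_len(seq_len(nfolds), length(ytr)))
  cv_mse <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- vapply(seq_len(nfolds), function(f) {
      tr <- folds != f
      fit <- fit_fn(grid[i, , drop = FALSE],
                    Xtr[tr, , drop = FALSE], ytr[tr])
      pr <- as.numeric(stats::predict(fit, Xtr[!tr, , drop = FALSE]))
      mean((pr - ytr[!tr])^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  grid[which.min(cv_mse), , drop = FALSE]
}
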