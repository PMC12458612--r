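# Minimal reverse-mode differentiation tape.
#
# Every forward pass builds a fresh tape of nodes in topological order;
# backward sweeps run in reverse creation order. Each op defines two
# backward rules: `bw` propagates loss gradients, `dl` propagates DeepLIFT
# multipliers (Rescale rule for elementwise nonlinearities, the exact
# symmetric split for elementwise products, plain linear propagation for
# affine ops). When a tape is built with references (`with_ref`), every
# node also carries the activation of the reference input, which the
# multiplier rules need.

tape_new <- function(with_ref = FALSE) {
  e <- new.env(parent = emptyenv())
  e$nodes <- list()
  e$with_ref <- with_ref
  e
}

node_new <- function(tape, value, ref = NULL, parents = list(),
                     bw = NULL, dl = NULL, param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$ref <- ref
  nd$parents <- parents
  nd$bw <- bw
  nd$dl <- dl
  nd$param <- param
  nd$grad <- NULL
  nd$mult <- NULL
  tape$nodes[[length(tape$nodes) + 1L]] <- nd
  nd
}

tape_backward <- function(tape, out, seed_grad = NULL) {
  out$grad <- if (is.null(seed_grad))
    matrix(1, nrow(out$value), ncol(out$value)) else seed_grad
  for (nd in rev(tape$nodes)) {
    if (is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd$grad)
    for (i in seq_along(nd$parents)) {
      if (is.null(gs[[i]])) next
      p <- nd$parents[[i]]
      p$grad <- if (is.null(p$grad)) gs[[i]] else p$grad + gs[[i]]
    }
  }
  # fold node gradients back into parameter environments
  for (nd in tape$nodes) {
    if (!is.null(nd$param) && !is.null(nd$grad))
      nd$param$grad <- nd$grad
  }
  invisible(out)
}

tape_deeplift <- function(tape, out) {
  out$mult <- matrix(1, nrow(out$value), ncol(out$value))
  for (nd in rev(tape$nodes)) {
    if (is.null(nd$mult) || is.null(nd$dl)) next
    ms <- nd$dl(nd$mult)
    for (i in seq_along(nd$parents)) {
      if (is.null(ms[[i]])) next
      p <- nd$parents[[i]]
      p$mult <- if (is.null(p$mult)) ms[[i]] else p$mult + ms[[i]]
    }
  }
  invisible(out)
}

# ---- leaves -----------------------------------------------------------

op_input <- function(tape, value, ref = NULL) {
  if (tape$with_ref && is.null(ref)) ref <- value
  node_new(tape, value, ref = ref)
}

op_param <- function(tape, p, as_row = FALSE) {
  v <- p$value
  if (as_row) v <- matrix(v, 1L)
  node_new(tape, v, ref = if (tape$with_ref) v, param = p)
}

# ---- linear ops -------------------------------------------------------

# X %*% (mask * W); gradients to W are masked, so masked-out entries can
# never influence outputs or updates
op_matmul <- function(x, w, mask = NULL, tape) {
  We <- if (is.null(mask)) w$value else mask * w$value
  val <- x$value %*% We
  ref <- if (tape$with_ref) x$ref %*% We
  node_new(tape, val, ref = ref, parents = list(x, w),
           bw = function(g) {
             gw <- crossprod(x$value, g)
             if (!is.null(mask)) gw <- gw * mask
             list(g %*% t(We), gw)
           },
           dl = function(m) list(m %*% t(We), NULL))
}

op_bias <- function(x, b, tape) {
  bv <- as.numeric(b$value)
  val <- sweep(x$value, 2, bv, `+`)
  ref <- if (tape$with_ref) sweep(x$ref, 2, bv, `+`)
  node_new(tape, val, ref = ref, parents = list(x, b),
           bw = function(g) list(g, matrix(colSums(g), 1L)),
           dl = function(m) list(m, NULL))
}

# feature-wise (diagonal) scaling: column j multiplied by d[j]
op_colscale <- function(x, d, tape) {
  dv <- as.numeric(d$value)
  val <- sweep(x$value, 2, dv, `*`)
  ref <- if (tape$with_ref) sweep(x$ref, 2, dv, `*`)
  node_new(tape, val, ref = ref, parents = list(x, d),
           bw = function(g) list(sweep(g, 2, dv, `*`),
                                 matrix(colSums(g * x$value), 1L)),
           dl = function(m) list(sweep(m, 2, dv, `*`), NULL))
}

op_concat <- function(xs, tape) {
  widths <- vapply(xs, function(x) ncol(x$value), integer(1))
  val <- do.call(cbind, lapply(xs, function(x) x$value))
  ref <- if (tape$with_ref) do.call(cbind, lapply(xs, function(x) x$ref))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  split_cols <- function(g) lapply(seq_along(xs), function(i)
    g[, starts[i]:ends[i], drop = FALSE])
  node_new(tape, val, ref = ref, parents = xs,
           bw = split_cols, dl = split_cols)
}

# ---- elementwise nonlinearities (Rescale rule for multipliers) --------

op_unary <- function(x, f, df, tape) {
  val <- f(x$value)
  ref <- if (tape$with_ref) f(x$ref)
  node_new(tape, val, ref = ref, parents = list(x),
           bw = function(g) list(g * df(x$value)),
           dl = function(m) {
             dx <- x$value - x$ref
             coef <- ifelse(abs(dx) > 1e-7, (val - ref) / dx,
                            df(x$value))
             list(m * coef)
           })
}

op_relu <- function(x, tape)
  op_unary(x, function(v) pmax(v, 0), function(v) (v > 0) * 1, tape)

op_tanh <- function(x, tape)
  op_unary(x, tanh, function(v) 1 - tanh(v)^2, tape)

op_sigmoid <- function(x, tape)
  op_unary(x, stats::plogis,
           function(v) stats::plogis(v) * (1 - stats::plogis(v)), tape)

op_activation <- function(x, act, tape) {
  switch(act,
         relu = op_relu(x, tape),
         tanh = op_tanh(x, tape),
         sigmoid = op_sigmoid(x, tape),
         identity = x,
         stop("unknown activation: ", act))
}

# reciprocal with epsilon clamp; the clamp is part of the unit, so the
# Rescale multiplier is computed on the composed clamp+reciprocal map
op_recip_clamp <- function(x, eps, tape) {
  f <- function(v) 1 / pmax(v, eps)
  val <- f(x$value)
  ref <- if (tape$with_ref) f(x$ref)
  node_new(tape, val, ref = ref, parents = list(x),
           bw = function(g) list(g * ifelse(x$value > eps, -val^2, 0)),
           dl = function(m) {
             dx <- x$value - x$ref
             coef <- ifelse(abs(dx) > 1e-7, (val - ref) / dx,
                            ifelse(x$value > eps, -val^2, 0))
             list(m * coef)
           })
}

# elementwise product of two activations; multipliers use the exact
# symmetric decomposition a*b - a0*b0 = (b+b0)/2*(a-a0) + (a+a0)/2*(b-b0)
op_mul <- function(a, b, tape) {
  val <- a$value * b$value
  ref <- if (tape$with_ref) a$ref * b$ref
  node_new(tape, val, ref = ref, parents = list(a, b),
           bw = function(g) list(g * b$value, g * a$value),
           dl = function(m) list(m * (b$value + b$ref) / 2,
                                 m * (a$value + a$ref) / 2))
}

# ---- batch normalization ---------------------------------------------

bn_state <- function() {
  st <- new.env(parent = emptyenv())
  st$mean <- NULL
  st$var <- NULL
  st
}

op_batchnorm <- function(x, gamma, beta, state, training, tape,
                         momentum = 0.9, eps = 0.005) {
  gv <- as.numeric(gamma$value)
  bv <- as.numeric(beta$value)
  if (training) {
    n <- nrow(x$value)
    mu <- colMeans(x$value)
    va <- colMeans(sweep(x$value, 2, mu, `-`)^2)
    if (is.null(state$mean)) {
      state$mean <- mu
      state$var <- va
    } else {
      state$mean <- momentum * state$mean + (1 - momentum) * mu
      state$var <- momentum * state$var + (1 - momentum) * va
    }
    s <- sqrt(va + eps)
    xc <- sweep(x$value, 2, mu, `-`)
    xhat <- sweep(xc, 2, s, `/`)
    val <- sweep(sweep(xhat, 2, gv, `*`), 2, bv, `+`)
    node_new(tape, val, parents = list(x, gamma, beta),
             bw = function(g) {
               gxhat <- sweep(g, 2, gv, `*`)
               gvar <- colSums(gxhat * xc) * (-0.5) / s^3
               gmu <- -colSums(gxhat) / s
               gx <- sweep(gxhat, 2, s, `/`) +
                 sweep(xc, 2, 2 * gvar / n, `*`) +
                 matrix(gmu / n, n, length(mu), byrow = TRUE)
               list(gx, matrix(colSums(g * xhat), 1L),
                    matrix(colSums(g), 1L))
             })
  } else {
    mu <- if (is.null(state$mean)) rep(0, ncol(x$value)) else state$mean
    va <- if (is.null(state$var)) rep(1, ncol(x$value)) else state$var
    s <- sqrt(va + eps)
    scale <- gv / s
    shift <- bv - mu * scale
    val <- sweep(sweep(x$value, 2, scale, `*`), 2, shift, `+`)
    ref <- if (tape$with_ref)
      sweep(sweep(x$ref, 2, scale, `*`), 2, shift, `+`)
    xhat <- sweep(sweep(x$value, 2, mu, `-`), 2, s, `/`)
    node_new(tape, val, ref = ref, parents = list(x, gamma, beta),
             bw = function(g) list(sweep(g, 2, scale, `*`),
                                   matrix(colSums(g * xhat), 1L),
                                   matrix(colSums(g), 1L)),
             dl = function(m) list(sweep(m, 2, scale, `*`), NULL, NULL))
  }
}

# ---- dropout ----------------------------------------------------------

op_dropout <- function(x, rate, training, tape) {
  if (!training || rate <= 0) return(x)
  keep <- matrix(stats::runif(length(x$value)) >= rate,
                 nrow(x$value), ncol(x$value)) / (1 - rate)
  node_new(tape, x$value * keep, parents = list(x),
           bw = function(g) list(g * keep))
}

# ---- loss -------------------------------------------------------------

op_mse_loss <- function(pred, target, tape) {
  d <- pred$value - target
  node_new(tape, matrix(mean(d^2), 1L, 1L), parents = list(pred),
           bw = function(g) list(g[1L] * 2 * d / length(d)))
}

# parameter container with Adam state
new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- 0
  p$v <- 0
  p
}

adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    if (is.null(dim(p$value))) g <- as.numeric(g)
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
}
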