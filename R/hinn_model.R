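#' Architecture configuration
#'
#' Defaults follow the published architecture: a 20-node fully connected
#' bypass at each hierarchical stage, four dense head blocks of 128 units
#' (batch norm with momentum 0.9 and epsilon 0.005, ReLU, dropout 0.7,
#' L2 regularization), a 20-unit bottleneck before demographic
#' concatenation, then one more batch-norm/dense-128/dropout block and a
#' linear output. The omics-layer activation is configurable (default
#' ReLU, matching the head); the division stage clamps its denominator at
#' `denominator_epsilon`.
#'
#' @param variant one of `"hinn"`, `"fully_connected"`, `"hierarchy_only"`,
#'   `"randomized"`, `"drop_snp"`, `"drop_cpg"`, `"drop_expr"`, `"no_go"`,
#'   `"pgnn"`.
#' @param bypass_width nodes per fully connected bypass stage.
#' @param head_blocks,head_width dense head depth and width.
#' @param bottleneck_width dense layer before demographic concatenation.
#' @param bn_momentum,bn_epsilon batch-norm running-statistics momentum and
#'   variance floor.
#' @param dropout dropout rate in the head.
#' @param l2_strength L2 penalty on all weight matrices.
#' @param omics_activation activation of the hierarchical omics layers.
#' @param denominator_epsilon clamp for the division-based coupling. With
#'   ReLU omics activations the denominator is exactly zero whenever the
#'   unit is inactive, so the clamp bounds the attenuation gain at
#'   `1 / denominator_epsilon`; the default 1e-2 caps it at 100x, which
#'   keeps test-time predictions stable (see the vignette).
#' @param randomized_seed mask-shuffle seed for the randomized variant.
#' @return An `architecture_config`.
#' @export
architecture_config <- function(variant = "hinn",
                                bypass_width = 20L,
                                head_blocks = 4L,
                                head_width = 128L,
                                bottleneck_width = 20L,
                                bn_momentum = 0.9,
                                bn_epsilon = 0.005,
                                dropout = 0.7,
                                l2_strength = 1e-4,
                                omics_activation = "relu",
                                denominator_epsilon = 1e-2,
                                randomized_seed = 1L) {
  variants <- c("hinn", "fully_connected", "hierarchy_only", "randomized",
                "drop_snp", "drop_cpg", "drop_expr", "no_go", "pgnn")
  if (!variant %in% variants)
    stop("unknown variant: ", variant)
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (denominator_epsilon <= 0) stop("denominator_epsilon must be > 0")
  if (bypass_width < 1 || head_width < 1 || bottleneck_width < 1)
    stop("layer widths must be positive")
  structure(list(variant = variant, bypass_width = as.integer(bypass_width),
                 head_blocks = as.integer(head_blocks),
                 head_width = as.integer(head_width),
                 bottleneck_width = as.integer(bottleneck_width),
                 bn_momentum = bn_momentum, bn_epsilon = bn_epsilon,
                 dropout = dropout, l2_strength = l2_strength,
                 omics_activation = omics_activation,
                 denominator_epsilon = denominator_epsilon,
                 randomized_seed = as.integer(randomized_seed)),
            class = c("architecture_config", "list"))
}

#' Masked affine layer (standalone)
#'
#' `act(X %*% (M * W) + B)`: the Hadamard product of mask and weights
#' guarantees that masked-out weight entries have provably zero influence
#' on the output.
#'
#' @param X activation matrix (samples x d).
#' @param M binary mask (d x e).
#' @param W weight matrix (d x e).
#' @param B bias vector (length e).
#' @param act activation: `"relu"`, `"tanh"`, `"sigmoid"` or `"identity"`.
#' @return Activation matrix (samples x e).
#' @export
masked_affine <- function(X, M, W, B = rep(0, ncol(W)),
                          act = "identity") {
  if (ncol(X) != nrow(W) || !identical(dim(M), dim(W)))
    stop("masked_affine: shape mismatch between X, M and W")
  if (!all(M %in% c(0, 1))) stop("mask entries must be binary")
  Z <- sweep(X %*% (M * W), 2, B, `+`)
  apply_activation(Z, act)
}

#' Feature-wise scaling (standalone)
#'
#' Multiplies column j of `X` by `diag[j]` — the identity-masked diagonal
#' map that gives each input feature exactly one trainable weight while
#' preserving dimensionality.
#'
#' @param X activation matrix.
#' @param diag weight vector, one entry per column of `X`.
#' @return The scaled matrix.
#' @export
featurewise_scale <- function(X, diag) {
  if (length(diag) != ncol(X))
    stop("featurewise_scale: diag length must equal input width")
  sweep(X, 2, diag, `*`)
}

apply_activation <- function(Z, act) {
  switch(act,
         identity = Z,
         relu = pmax(Z, 0),
         tanh = tanh(Z),
         sigmoid = stats::plogis(Z),
         stop("unknown activation: ", act))
}

#' Build a model under variant semantics
#'
#' Constructs the parameter set and wiring for the requested architecture
#' variant: `hinn` (biological masks), `fully_connected` (all-ones masks),
#' `randomized` (shuffled pairings, edge count preserved),
#' `hierarchy_only` (dense stages concatenated in layer order, no
#' elementwise coupling), `drop_snp`/`drop_cpg`/`drop_expr` (one modality
#' removed, neighbors rewired), `no_go` (expression stage feeds the head
#' directly), and `pgnn` (all omics concatenated into one input sparsely
#' wired to a GO-term-width layer).
#'
#' @param cfg an [architecture_config()].
#' @param masks a biological `mask_set` from [build_masks()].
#' @param demo_width number of demographic columns fed to the head.
#' @param init_seed seed for weight initialization.
#' @return A `hinn_model`.
#' @export
build_variant <- function(cfg, masks, demo_width, init_seed = 1L) {
  if (masks$variant != "biological")
    stop("build_variant expects the biological mask_set")
  masks <- switch(cfg$variant,
                  fully_connected = ablate_full(masks),
                  randomized = ablate_randomized(masks,
                                                 cfg$randomized_seed),
                  masks)
  model <- structure(list(cfg = cfg, masks = masks,
                          demo_width = as.integer(demo_width),
                          params = NULL, bn = NULL),
                     class = "hinn_model")
  init_model_params(model, init_seed)
}

#' @export
print.hinn_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("<hinn_model> variant=%s | %d parameters | bypass %d\n",
              x$cfg$variant, np, x$cfg$bypass_width))
  invisible(x)
}

# variance-scaling (He) initialization; masked layers use per-unit
# fan-in given the mask
vs_init <- function(d, e, seed_env) {
  matrix(stats::rnorm(d * e, 0, sqrt(2 / max(d, 1))), d, e)
}

vs_init_masked <- function(mask) {
  fan <- pmax(colSums(mask), 1)
  W <- matrix(stats::rnorm(length(mask)), nrow(mask), ncol(mask))
  sweep(W, 2, sqrt(2 / fan), `*`)
}

init_model_params <- function(model, seed = 1L) {
  force(model)   # evaluate any constructor promise before seeding
  set.seed(seed)
  cfg <- model$cfg
  mk <- model$masks
  nS <- nrow(mk$M1); nC <- ncol(mk$M1)
  nP <- ncol(mk$M2); nT <- ncol(mk$M3)
  bw <- cfg$bypass_width
  P <- list()
  add_dense <- function(name, d, e) {
    P[[paste0("W_", name)]] <<- new_param(vs_init(d, e))
    P[[paste0("B_", name)]] <<- new_param(rep(0, e))
  }
  add_bn <- function(name, e) {
    P[[paste0("G_", name)]] <<- new_param(rep(1, e))
    P[[paste0("Be_", name)]] <<- new_param(rep(0, e))
  }
  v <- cfg$variant
  hier <- !v %in% c("pgnn", "hierarchy_only")

  if (v == "pgnn") {
    model$pgnn_mask <- pgnn_mask(mk)
    P$W_pgnn <- new_param(vs_init_masked(model$pgnn_mask))
    P$B_pgnn <- new_param(rep(0, nT))
    head_in <- nT
  } else if (v == "hierarchy_only") {
    add_dense("h1", nS, nC)
    add_dense("h2", nC + nC, nP)
    add_dense("h3", nP + nP, nT)
    add_dense("by1", nS, bw)
    add_dense("by2", bw + nP, bw)
    add_dense("by3", bw + nT, bw)
    head_in <- nT + bw
  } else {
    stages <- hier_stages(v)
    if (stages$use_snp) {
      P$W1 <- new_param(vs_init_masked(mk$M1))
      P$B1 <- new_param(rep(0, nC))
    }
    if (stages$use_cpg) {
      P$D2 <- new_param(rep(1, nC))
      P$B2 <- new_param(rep(0, nC))
    }
    if (stages$use_expr) {
      P$Wf2 <- new_param(vs_init_masked(mk$M2))
      P$Bf2 <- new_param(rep(0, nP))
      P$D3 <- new_param(rep(1, nP))
      P$B3 <- new_param(rep(0, nP))
    }
    if (stages$use_go) {
      if (v == "drop_expr") {
        model$ct_mask <- ((mk$M2 %*% mk$M3) > 0) * 1
        P$Wf3 <- new_param(vs_init_masked(model$ct_mask))
      } else {
        P$Wf3 <- new_param(vs_init_masked(mk$M3))
      }
      P$Bf3 <- new_param(rep(0, nT))
    }
    # bypass chain: first stage reads the first available raw omics
    # input; each later stage reads the previous bypass concatenated
    # with that hierarchical stage's output
    stage_list <- c(if (stages$use_cpg) "Y2", if (stages$use_expr) "Y3")
    first_w <- if (stages$use_snp) nS else if (stages$use_cpg) nC else nP
    widths_in <- c(first_w,
                   vapply(stage_list, function(s)
                     bw + if (s == "Y2") nC else nP, numeric(1)))
    for (i in seq_along(widths_in))
      add_dense(paste0("by", i), widths_in[i], bw)
    model$bypass_stages <- stage_list
    top_w <- if (stages$use_go) nT else nP
    head_in <- top_w + bw
  }

  for (i in seq_len(cfg$head_blocks)) {
    add_bn(paste0("hb", i), if (i == 1) head_in else cfg$head_width)
    add_dense(paste0("hd", i),
              if (i == 1) head_in else cfg$head_width, cfg$head_width)
  }
  add_dense("bottleneck", cfg$head_width, cfg$bottleneck_width)
  add_bn("demo", cfg$bottleneck_width + model$demo_width)
  add_dense("demo", cfg$bottleneck_width + model$demo_width,
            cfg$head_width)
  add_dense("out", cfg$head_width, 1L)

  model$params <- P
  model$bn <- stats::setNames(
    lapply(seq_len(cfg$head_blocks + 1L), function(i) bn_state()),
    c(paste0("hb", seq_len(cfg$head_blocks)), "demo"))
  model
}

hier_stages <- function(variant) {
  list(use_snp = !variant %in% c("drop_snp"),
       use_cpg = !variant %in% c("drop_cpg"),
       use_expr = !variant %in% c("drop_expr"),
       use_go = !variant %in% c("no_go"))
}

pgnn_mask <- function(mk) {
  snp_term <- ((mk$M1 %*% mk$M2 %*% mk$M3) > 0) * 1
  cpg_term <- ((mk$M2 %*% mk$M3) > 0) * 1
  rbind(snp_term, cpg_term, mk$M3)
}
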