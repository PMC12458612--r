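#' Forward pass of a hierarchical model
#'
#' Builds the computation tape for one batch. The hierarchical stages are:
#' `Y1 = f(X_snp, M1)` (masked affine), `Y2 = act(g(X_cpg) * Y1 + B2)`
#' (multiplicative coupling of the feature-scaled CpG input with the
#' upstream signal), `Y3 = act(g(X_expr) / max(f(Y2, M2), eps) + B3)`
#' (division-based attenuation by promoter methylation) and
#' `Y4 = f(Y3, M3)` (GO-term aggregation). A fully connected bypass chain
#' (width `bypass_width`) runs alongside, and the concatenation of the top
#' hierarchical output with the final bypass enters the dense head, which
#' appends the demographic block before the linear output. In eval mode
#' batch-norm statistics are frozen and dropout is disabled.
#'
#' @param model a `hinn_model`.
#' @param X named list of input matrices: `snp`, `cpg`, `expr`, `demo`
#'   (columns ordered to match the model's masks).
#' @param training logical; training mode updates batch-norm statistics
#'   and applies dropout.
#' @param refs optional named list of reference inputs; when supplied the
#'   tape also tracks reference activations (needed for DeepLIFT).
#' @return List with `out` (prediction node), `tape`, and `inputs`
#'   (the input nodes, for attribution).
#' @keywords internal
hinn_forward <- function(model, X, training = FALSE, refs = NULL) {
  cfg <- model$cfg
  mk <- model$masks
  act <- cfg$omics_activation
  tape <- tape_new(with_ref = !is.null(refs))
  check_input_widths(model, X)

  pcache <- new.env(parent = emptyenv())
  pn <- function(name, row = TRUE) {
    if (is.null(pcache[[name]]))
      pcache[[name]] <- op_param(tape, model$params[[name]],
                                 as_row = row)
    pcache[[name]]
  }
  inp <- function(name) {
    v <- X[[name]]
    op_input(tape, v, ref = if (!is.null(refs)) refs[[name]] else NULL)
  }
  dense <- function(x, name, activation = "relu") {
    z <- op_bias(op_matmul(x, pn(paste0("W_", name), row = FALSE),
                           NULL, tape),
                 pn(paste0("B_", name)), tape)
    op_activation(z, activation, tape)
  }
  bnorm <- function(x, name) {
    op_batchnorm(x, pn(paste0("G_", name)), pn(paste0("Be_", name)),
                 model$bn[[name]], training, tape,
                 momentum = cfg$bn_momentum, eps = cfg$bn_epsilon)
  }

  Xs <- inp("snp"); Xc <- inp("cpg"); Xe <- inp("expr"); Xd <- inp("demo")
  v <- cfg$variant

  if (v == "pgnn") {
    xall <- op_concat(list(Xs, Xc, Xe), tape)
    z <- op_bias(op_matmul(xall, pn("W_pgnn", row = FALSE),
                           model$pgnn_mask, tape), pn("B_pgnn"), tape)
    head_in <- op_activation(z, act, tape)
  } else if (v == "hierarchy_only") {
    h1 <- dense(Xs, "h1", act)
    h2 <- dense(op_concat(list(Xc, h1), tape), "h2", act)
    h3 <- dense(op_concat(list(Xe, h2), tape), "h3", act)
    b <- dense(Xs, "by1")
    b <- dense(op_concat(list(b, h2), tape), "by2")
    b <- dense(op_concat(list(b, h3), tape), "by3")
    head_in <- op_concat(list(h3, b), tape)
  } else {
    st <- hier_stages(v)
    Y1 <- Y2 <- Y3 <- NULL
    if (st$use_snp) {
      z1 <- op_bias(op_matmul(Xs, pn("W1", row = FALSE), mk$M1, tape),
                    pn("B1"), tape)
      Y1 <- op_activation(z1, act, tape)
    }
    if (st$use_cpg) {
      g2 <- op_colscale(Xc, pn("D2"), tape)
      z2 <- if (!is.null(Y1)) op_mul(g2, Y1, tape) else g2
      Y2 <- op_activation(op_bias(z2, pn("B2"), tape), act, tape)
    }
    if (st$use_expr) {
      prev <- if (!is.null(Y2)) Y2 else Y1  # drop_cpg rewiring
      den <- op_activation(
        op_bias(op_matmul(prev, pn("Wf2", row = FALSE), mk$M2, tape),
                pn("Bf2"), tape), act, tape)
      r <- op_recip_clamp(den, cfg$denominator_epsilon, tape)
      g3 <- op_colscale(Xe, pn("D3"), tape)
      Y3 <- op_activation(op_bias(op_mul(g3, r, tape), pn("B3"), tape),
                          act, tape)
    }
    top <- if (st$use_go) {
      src <- if (!is.null(Y3)) Y3 else Y2   # drop_expr rewiring
      m3 <- if (v == "drop_expr") model$ct_mask else mk$M3
      op_activation(
        op_bias(op_matmul(src, pn("Wf3", row = FALSE), m3, tape),
                pn("Bf3"), tape), act, tape)
    } else Y3
    first_in <- if (st$use_snp) Xs else if (st$use_cpg) Xc else Xe
    b <- dense(first_in, "by1")
    i <- 1L
    for (s in model$bypass_stages) {
      i <- i + 1L
      stage_node <- if (s == "Y2") Y2 else Y3
      b <- dense(op_concat(list(b, stage_node), tape), paste0("by", i))
    }
    head_in <- op_concat(list(top, b), tape)
  }

  cur <- head_in
  for (i in seq_len(cfg$head_blocks)) {
    cur <- bnorm(cur, paste0("hb", i))
    cur <- dense(cur, paste0("hd", i))
    cur <- op_dropout(cur, cfg$dropout, training, tape)
  }
  cur <- dense(cur, "bottleneck")
  cur <- op_concat(list(cur, Xd), tape)
  cur <- bnorm(cur, "demo")
  cur <- dense(cur, "demo")
  cur <- op_dropout(cur, cfg$dropout, training, tape)
  out <- op_bias(op_matmul(cur, pn("W_out", row = FALSE), NULL, tape),
                 pn("B_out"), tape)

  list(out = out, tape = tape,
       inputs = list(snp = Xs, cpg = Xc, expr = Xe, demo = Xd))
}

check_input_widths <- function(model, X) {
  mk <- model$masks
  want <- c(snp = nrow(mk$M1), cpg = ncol(mk$M1), expr = ncol(mk$M2),
            demo = model$demo_width)
  for (nm in names(want)) {
    if (is.null(X[[nm]]))
      stop("missing input matrix: ", nm)
    if (ncol(X[[nm]]) != want[[nm]])
      stop(sprintf("input '%s' has width %d, layer expects %d",
                   nm, ncol(X[[nm]]), want[[nm]]))
  }
}

#' Predict with a hierarchical model
#'
#' Runs the forward pass in eval mode (frozen batch-norm statistics, no
#' dropout).
#'
#' @param model a trained `hinn_model`.
#' @param X named list of input matrices (`snp`, `cpg`, `expr`, `demo`).
#' @return Numeric prediction vector.
#' @export
predict_hinn <- function(model, X) {
  as.numeric(hinn_forward(model, X, training = FALSE)$out$value)
}

#' Assemble model inputs from a cohort
#'
#' Restricts each omics matrix to the retained, mask-ordered features:
#' genotype dosages with missing calls imputed to the per-SNP mean of the
#' observed calls, methylation betas as-is, expression min-max normalized
#' per probe, and the demographic block (age, sex, education, APOE4 and
#' optionally the p-Tau measurement) with continuous columns standardized.
#'
#' @param cohort a `multiomics_cohort`.
#' @param masks a `mask_set` (defines feature order).
#' @param include_ptau include the p-Tau column among demographics.
#' @return List of matrices `snp`, `cpg`, `expr`, `demo` plus
#'   `sample_ids`.
#' @export
prepare_model_data <- function(cohort, masks, include_ptau = TRUE) {
  G <- cohort$genotype$values[, masks$snp_ids, drop = FALSE]
  mc <- cohort$genotype$missing_code
  for (j in seq_len(ncol(G))) {
    mi <- G[, j] == mc
    if (any(mi)) G[mi, j] <- mean(G[!mi, j])
  }
  B <- cohort$methylation$values[, masks$cpg_ids, drop = FALSE]
  E <- min_max_normalize(cohort$expression)$values[, masks$probe_ids,
                                                   drop = FALSE]
  cv <- cohort$covariates
  demo <- cbind(age = as.numeric(scale(cv$age)),
                sex = cv$sex,
                education = as.numeric(scale(cv$education)),
                apoe4 = cv$apoe4)
  if (include_ptau)
    demo <- cbind(demo, ptau = as.numeric(scale(log(cv$ptau))))
  rownames(demo) <- cv$sample_id
  list(snp = G, cpg = B, expr = E, demo = demo,
       sample_ids = rownames(G))
}
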