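# shared fixtures, built in code at test time

# small cohort used by several suites; cached per session
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(simulation_params(
        n_samples = 200L, n_snps = 60L, n_cpgs = 90L, n_genes = 40L,
        n_go_terms = 12L, n_causal_cascades = 4L, seed = 7L))
    cache
  }
})

# tiny trained-free model on hand-made masks for forward/attribution tests
toy_masks <- function(n_snp = 3, n_cpg = 4, n_probe = 3, n_term = 2,
                      seed = 5) {
  set.seed(seed)
  rand_mask <- function(r, c, rn, cn) {
    M <- matrix(0, r, c, dimnames = list(rn, cn))
    M[cbind(seq_len(r), sample.int(c, r, replace = TRUE))] <- 1
    M[cbind(sample.int(r, c, replace = TRUE), seq_len(c))] <- 1
    M
  }
  structure(list(
    snp_ids = paste0("s", seq_len(n_snp)),
    cpg_ids = paste0("c", seq_len(n_cpg)),
    probe_ids = paste0("p", seq_len(n_probe)),
    term_ids = paste0("t", seq_len(n_term)),
    M1 = rand_mask(n_snp, n_cpg, paste0("s", 1:n_snp), paste0("c", 1:n_cpg)),
    M2 = rand_mask(n_cpg, n_probe, paste0("c", 1:n_cpg), paste0("p", 1:n_probe)),
    M3 = rand_mask(n_probe, n_term, paste0("p", 1:n_probe), paste0("t", 1:n_term)),
    variant = "biological"), class = "mask_set")
}

toy_inputs <- function(masks, n = 8, demo_width = 3, seed = 9) {
  set.seed(seed)
  list(snp = matrix(sample(0:2, n * nrow(masks$M1), TRUE), n,
                    dimnames = list(NULL, masks$snp_ids)),
       cpg = matrix(runif(n * ncol(masks$M1)), n,
                    dimnames = list(NULL, masks$cpg_ids)),
       expr = matrix(runif(n * ncol(masks$M2)), n,
                     dimnames = list(NULL, masks$probe_ids)),
       demo = matrix(rnorm(n * demo_width), n,
                     dimnames = list(NULL, paste0("d", seq_len(demo_width)))))
}

# Hardy-Weinberg conditional distribution by the Wigginton-style
# recurrence (independent of the package's lgamma route): unnormalized
# probabilities from the ratio
#   P(h+2)/P(h) = h_hom_A * h_hom_a * 4 / ((h+2) * (h+1))  (in counts)
hwe_oracle_dist <- function(nA, na, n) {
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  p <- numeric(length(hets))
  p[1] <- 1
  if (length(hets) > 1) {
    for (i in seq_len(length(hets) - 1)) {
      h <- hets[i]
      hom_A <- (nA - h) / 2
      hom_a <- (na - h) / 2
      p[i + 1] <- p[i] * 4 * hom_A * hom_a / ((h + 2) * (h + 1))
    }
  }
  list(hets = hets, prob = p / sum(p))
}

hwe_oracle_p <- function(n_AA, n_Aa, n_aa) {
  d <- hwe_oracle_dist(2 * n_AA + n_Aa, 2 * n_aa + n_Aa,
                       n_AA + n_Aa + n_aa)
  obs <- d$prob[match(n_Aa, d$hets)]
  min(1, sum(d$prob[d$prob <= obs * (1 + 1e-7)]))
}

# brute-force triple-loop masked affine oracle
masked_affine_oracle <- function(X, M, W, B, act = "identity") {
  n <- nrow(X); e <- ncol(W)
  out <- matrix(0, n, e)
  for (i in seq_len(n)) {
    for (j in seq_len(e)) {
      acc <- B[j]
      for (k in seq_len(ncol(X)))
        acc <- acc + X[i, k] * M[k, j] * W[k, j]
      out[i, j] <- acc
    }
  }
  switch(act, identity = out, relu = pmax(out, 0), tanh = tanh(out),
         sigmoid = stats::plogis(out))
}

# hand-built selection fixture with counts forced by construction.
# 60 samples in three blocks of 20; 10 SNPs:
#   s1 (block dosage 0/1/2) and s2 (1/0/2) drive y = s1 + 2*s2 exactly,
#   s3, s4 have per-block dosage sums of 20, hence exactly zero
#     covariance with y (slope 0, p = 1),
#   s5, s6 monomorphic (MAF filter), s7, s8 carry 10% missing calls
#     spread one per sample (SNP missingness filter, sample filter
#     tolerant at 0.15), s9, s10 all-heterozygous (HWE filter).
# QC keeps exactly s1-s4; the scan flags exactly {s1, s2}.
# Geometry: c1 sits exactly 1 Mb from s1 (inclusive boundary) and in
# TSS200 of g1 (+ strand); c2 sits 1 kb from s2 and in TSS1500 of g2
# (- strand); c3 is unlinked. Universe of 10 genes; t1 = {g1, g2} gives
# hypergeometric p = 1/45, BH-adjusted 0.044 over two terms.
# Expected relation map: 2 SNPs, 2 CpGs, 2 probes, 1 term; 2/2/2 edges.
toy_selection_fixture <- function() {
  n <- 60L
  blk <- function(a, b, c) c(rep(a, 20L), rep(b, 20L), rep(c, 20L))
  null_block <- c(rep(0, 7L), rep(1, 6L), rep(2, 7L))   # sum 20
  g <- matrix(0, n, 10L)
  g[, 1] <- blk(0, 1, 2)
  g[, 2] <- blk(1, 0, 2)
  g[, 3] <- rep(null_block, 3L)
  g[, 4] <- rep(rev(null_block), 3L)
  g[, 5] <- 0
  g[, 6] <- 2
  g[, 7] <- blk(0, 1, 2); g[1:6, 7] <- -1
  g[, 8] <- blk(0, 1, 2); g[7:12, 8] <- -1
  g[, 9] <- 1
  g[, 10] <- 1
  colnames(g) <- paste0("s", 1:10)
  rownames(g) <- sprintf("S%02d", 1:n)
  y <- blk(0, 1, 2) + 2 * blk(1, 0, 2)    # (2, 1, 6) per block
  geno <- feature_matrix(g, modality = "genotype", missing_code = -1)

  snps <- data.frame(feature_id = paste0("s", 1:10), chromosome = "chr1",
                     position = c(1000L, 3000000L, 5000000L, 7000000L,
                                  9000000L, 9100000L, 9200000L, 9300000L,
                                  9400000L, 9500000L),
                     stringsAsFactors = FALSE)
  cpgs <- data.frame(feature_id = c("c1", "c2", "c3"),
                     chromosome = "chr1",
                     position = c(1001000L, 2999000L, 20000000L),
                     stringsAsFactors = FALSE)
  gene_pos <- c(1001150L, 2998000L, seq(30000000L, by = 1000000L,
                                        length.out = 8L))
  genes <- data.frame(feature_id = paste0("g", 1:10), chromosome = "chr1",
                      position = gene_pos, tss = gene_pos,
                      strand = c("+", "-", rep("+", 8L)),
                      gene_symbol = paste0("g", 1:10),
                      stringsAsFactors = FALSE)
  probe_map <- data.frame(probe_id = paste0("p", 1:10),
                          gene_symbol = paste0("g", 1:10),
                          stringsAsFactors = FALSE)
  sets <- gene_set_collection(list(t1 = c("g1", "g2"),
                                   t2 = c("g3", "g4", "g5")))
  scores <- data.frame(sample_id = rownames(g), score = y,
                       stringsAsFactors = FALSE)
  set.seed(4)
  meth <- feature_matrix(matrix(runif(n * 3), n,
                                dimnames = list(rownames(g),
                                                c("c1", "c2", "c3"))),
                         modality = "methylation")
  expr <- feature_matrix(matrix(rnorm(n * 10, 7), n,
                                dimnames = list(rownames(g),
                                                paste0("p", 1:10))),
                         modality = "expression")
  structure(list(genotype = geno, methylation = meth, expression = expr,
                 covariates = data.frame(sample_id = rownames(g),
                                         age = rnorm(n, 70), sex = 0,
                                         education = 16, apoe4 = 0,
                                         ptau = exp(rnorm(n, 3, 0.3)),
                                         diagnosis = rep(c("CN", "CI"),
                                                         length.out = n),
                                         stringsAsFactors = FALSE),
                 scores = scores,
                 annotations = list(snp = snps, cpg = cpgs, gene = genes),
                 probe_map = probe_map, gene_sets = sets),
            class = "multiomics_cohort")
}

toy_thresholds <- function(...) {
  qc_thresholds(max_sample_missing_rate = 0.15, ...)
}

# scalar-loop oracle for the eval-mode forward pass of the hinn variant
# with untrained batch-norm state
oracle_hinn_forward <- function(model, X) {
  P <- lapply(model$params, function(p) p$value)
  cfg <- model$cfg
  mk <- model$masks
  relu <- function(z) pmax(z, 0)
  mat <- function(A, W, B) {          # explicit triple loop
    out <- matrix(0, nrow(A), ncol(W))
    for (i in seq_len(nrow(A)))
      for (j in seq_len(ncol(W))) {
        acc <- B[j]
        for (k in seq_len(ncol(A))) acc <- acc + A[i, k] * W[k, j]
        out[i, j] <- acc
      }
    out
  }
  bn_eval <- function(A, gamma, beta) {
    s <- gamma / sqrt(1 + cfg$bn_epsilon)   # untrained state: mu 0, var 1
    sweep(sweep(A, 2, s, `*`), 2, beta, `+`)
  }
  Y1 <- relu(mat(X$snp, mk$M1 * P$W1, P$B1))
  g2 <- sweep(X$cpg, 2, P$D2, `*`)
  Y2 <- relu(sweep(g2 * Y1, 2, P$B2, `+`))
  den <- relu(mat(Y2, mk$M2 * P$Wf2, P$Bf2))
  r <- 1 / pmax(den, cfg$denominator_epsilon)
  g3 <- sweep(X$expr, 2, P$D3, `*`)
  Y3 <- relu(sweep(g3 * r, 2, P$B3, `+`))
  Y4 <- relu(mat(Y3, mk$M3 * P$Wf3, P$Bf3))
  b <- relu(mat(X$snp, P$W_by1, P$B_by1))
  b <- relu(mat(cbind(b, Y2), P$W_by2, P$B_by2))
  b <- relu(mat(cbind(b, Y3), P$W_by3, P$B_by3))
  cur <- cbind(Y4, b)
  for (i in seq_len(cfg$head_blocks)) {
    cur <- bn_eval(cur, P[[paste0("G_hb", i)]], P[[paste0("Be_hb", i)]])
    cur <- relu(mat(cur, P[[paste0("W_hd", i)]], P[[paste0("B_hd", i)]]))
  }
  cur <- relu(mat(cur, P$W_bottleneck, P$B_bottleneck))
  cur <- cbind(cur, X$demo)
  cur <- bn_eval(cur, P$G_demo, P$Be_demo)
  cur <- relu(mat(cur, P$W_demo, P$B_demo))
  as.numeric(mat(cur, P$W_out, P$B_out))
}
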