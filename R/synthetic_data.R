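#' Simulation parameters for synthetic multi-omics cohorts
#'
#' Defaults describe a desk-scale cohort with strong planted regulatory
#' cascades: each of `n_causal_cascades` cascades consists of a SNP within
#' `window_bp` of a CpG that sits in the promoter (TSS200/TSS1500) of a
#' gene whose expression contributes to the latent cognitive score. Effect
#' sizes are chosen so that a per-SNP linear scan at Bonferroni-adjusted
#' alpha 0.01 has high power at the default sample size (see the package
#' vignette for the power computation behind these values).
#'
#' @param n_samples cohort size.
#' @param n_snps,n_cpgs,n_genes,n_go_terms feature counts per layer; probes
#'   map one-to-one onto genes.
#' @param n_causal_cascades number of planted SNP->CpG->gene cascades.
#' @param n_enriched_terms GO terms deliberately over-populated with causal
#'   genes.
#' @param maf_range minor-allele-frequency range, each in (0, 0.5].
#' @param meqtl_effect logit-scale methylation shift per risk allele.
#' @param meth_expr_effect expression decrease per unit beta (the default
#'   coupling is inhibitory: higher promoter methylation, lower expression).
#' @param score_heritability fraction of latent-score variance explained by
#'   the causal expression combination.
#' @param covariate_r2 fraction of latent-score variance from demographics.
#' @param noise_sd named numeric: `methylation` (logit scale),
#'   `expression`, and `test` (per-assessment noise in latent-sd units).
#' @param genotype_missing_rate fraction of genotype calls masked to the
#'   missing sentinel.
#' @param chromosome_length single linear chromosome length in bp.
#' @param window_bp SNP-CpG cis window (inclusive).
#' @param promoter_bp upstream promoter offsets (TSS200, TSS1500).
#' @param ptau_coupling magnitude of the negative coupling between the
#'   p-Tau proxy and the latent score.
#' @param seed RNG seed giving bit-identical cohorts.
#' @return A validated `simulation_params` object.
#' @export
simulation_params <- function(n_samples = 500L,
                              n_snps = 200L,
                              n_cpgs = 300L,
                              n_genes = 100L,
                              n_go_terms = 30L,
                              n_causal_cascades = 8L,
                              n_enriched_terms = 5L,
                              maf_range = c(0.2, 0.5),
                              meqtl_effect = 2.0,
                              meth_expr_effect = 3.0,
                              score_heritability = 0.7,
                              covariate_r2 = 0.05,
                              noise_sd = c(methylation = 0.3,
                                           expression = 0.3,
                                           test = 0.25),
                              genotype_missing_rate = 0.01,
                              chromosome_length = 5e7,
                              window_bp = 1e6,
                              promoter_bp = c(200L, 1500L),
                              ptau_coupling = 0.6,
                              seed = 1L) {
  p <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
            n_cpgs = as.integer(n_cpgs), n_genes = as.integer(n_genes),
            n_go_terms = as.integer(n_go_terms),
            n_causal_cascades = as.integer(n_causal_cascades),
            n_enriched_terms = as.integer(n_enriched_terms),
            maf_range = as.numeric(maf_range),
            meqtl_effect = meqtl_effect,
            meth_expr_effect = meth_expr_effect,
            score_heritability = score_heritability,
            covariate_r2 = covariate_r2,
            noise_sd = unlist(noise_sd),
            genotype_missing_rate = genotype_missing_rate,
            chromosome_length = chromosome_length,
            window_bp = window_bp,
            promoter_bp = as.integer(promoter_bp),
            ptau_coupling = ptau_coupling,
            seed = as.integer(seed))
  counts <- c(p$n_samples, p$n_snps, p$n_cpgs, p$n_genes, p$n_go_terms,
              p$n_causal_cascades)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (p$n_causal_cascades > min(p$n_snps, p$n_cpgs, p$n_genes))
    stop("n_causal_cascades exceeds a layer's feature count")
  if (any(p$maf_range <= 0) || any(p$maf_range > 0.5) ||
      p$maf_range[1] > p$maf_range[2])
    stop("maf_range must be increasing within (0, 0.5]")
  if (p$score_heritability < 0 || p$score_heritability > 1)
    stop("score_heritability must lie in [0, 1]")
  if (p$score_heritability + p$covariate_r2 > 1)
    stop("score_heritability + covariate_r2 must not exceed 1")
  if (!all(c("methylation", "expression", "test") %in% names(p$noise_sd)))
    stop("noise_sd needs methylation, expression and test components")
  if (p$genotype_missing_rate < 0 || p$genotype_missing_rate >= 1)
    stop("genotype_missing_rate must lie in [0, 1)")
  if (p$ptau_coupling < 0 || p$ptau_coupling > 1)
    stop("ptau_coupling must lie in [0, 1]")
  structure(p, class = c("simulation_params", "list"))
}

#' Simulate a multi-omics cohort with planted regulatory cascades
#'
#' Genotypes are Binomial(2, MAF) dosages; causal CpG methylation is
#' generated on the logit scale as baseline + `meqtl_effect` x centered
#' dosage + noise and mapped through the logistic function, so beta values
#' respect \[0, 1\] without truncation; each causal gene has a latent
#' transcriptional activity that decreases by `meth_expr_effect` per unit
#' beta, measured by its probe with additive assay noise; the latent
#' cognitive score is the standardized causal-activity combination scaled
#' to `score_heritability` of variance plus demographic effects and noise
#' (so methylation and genotype carry information about the score beyond
#' the measured expression, as a hierarchical integration model assumes).
#' Four bounded assessment scores (MMSE/MoCA-like increasing, ADAS-like
#' decreasing, RAVLT-like increasing) are monotone transforms of the
#' latent score plus independent per-test noise. Diagnosis is cognitively
#' normal (CN) for the top latent-score tertile and cognitively impaired
#' (CI) otherwise; the plasma p-Tau proxy is a noisy decreasing monotone
#' transform of the latent score.
#'
#' @param params a [simulation_params()] object.
#' @return A list with elements `cohort` (class `multiomics_cohort`) and
#'   `truth` (class `ground_truth`: cascade table, enriched term ids,
#'   latent score).
#' @export
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  if (p$chromosome_length < 2 * p$window_bp + 2 * max(p$promoter_bp))
    stop("chromosome too short for the requested window placement")
  set.seed(p$seed)
  n <- p$n_samples
  snp_ids <- sprintf("rs%04d", seq_len(p$n_snps))
  cpg_ids <- sprintf("cg%05d", seq_len(p$n_cpgs))
  gene_ids <- sprintf("GENE%03d", seq_len(p$n_genes))
  probe_ids <- sprintf("probe_%03d_at", seq_len(p$n_genes))
  term_ids <- sprintf("GO:%07d", seq_len(p$n_go_terms))
  sample_ids <- sprintf("S%04d", seq_len(n))

  # --- genomic placement (one linear chromosome) ---
  margin <- max(p$promoter_bp) + 10L
  tss <- sort(as.integer(round(seq(margin, p$chromosome_length - margin,
                                   length.out = p$n_genes))))
  strand <- sample(c("+", "-"), p$n_genes, replace = TRUE)
  genes <- data.frame(feature_id = gene_ids, chromosome = "chr1",
                      position = tss, tss = tss, strand = strand,
                      gene_symbol = gene_ids, stringsAsFactors = FALSE)

  causal_gene_idx <- round(seq(1, p$n_genes,
                               length.out = p$n_causal_cascades))
  cpg_pos <- integer(p$n_cpgs)
  # causal CpGs live in the promoter of their cascade gene
  for (k in seq_len(p$n_causal_cascades)) {
    g <- causal_gene_idx[k]
    off <- sample.int(max(p$promoter_bp), 1L)
    cpg_pos[k] <- if (strand[g] == "+") tss[g] - off else tss[g] + off
  }
  null_cpg <- (p$n_causal_cascades + 1):p$n_cpgs
  cpg_pos[null_cpg] <- sample.int(p$chromosome_length - 1L,
                                  length(null_cpg), replace = TRUE)
  cpgs <- data.frame(feature_id = cpg_ids, chromosome = "chr1",
                     position = cpg_pos, stringsAsFactors = FALSE)

  snp_pos <- integer(p$n_snps)
  for (k in seq_len(p$n_causal_cascades)) {
    delta <- sample.int(floor(p$window_bp / 2), 1L) *
      sample(c(-1L, 1L), 1L)
    snp_pos[k] <- min(max(cpg_pos[k] + delta, 0L),
                      as.integer(p$chromosome_length - 1L))
  }
  null_snp <- (p$n_causal_cascades + 1):p$n_snps
  snp_pos[null_snp] <- sample.int(p$chromosome_length - 1L,
                                  length(null_snp), replace = TRUE)
  snps <- data.frame(feature_id = snp_ids, chromosome = "chr1",
                     position = snp_pos, stringsAsFactors = FALSE)

  # --- genotypes ---
  maf <- stats::runif(p$n_snps, p$maf_range[1], p$maf_range[2])
  G <- vapply(seq_len(p$n_snps),
              function(j) stats::rbinom(n, 2L, maf[j]),
              numeric(n))
  dimnames(G) <- list(sample_ids, snp_ids)

  # --- methylation (logit scale) ---
  base_logit <- stats::runif(p$n_cpgs, -1.5, 1.5)
  L <- matrix(stats::rnorm(n * p$n_cpgs, 0, p$noise_sd[["methylation"]]),
              n, p$n_cpgs)
  L <- sweep(L, 2, base_logit, `+`)
  for (k in seq_len(p$n_causal_cascades)) {
    L[, k] <- L[, k] + p$meqtl_effect * (G[, k] - 2 * maf[k])
  }
  B <- stats::plogis(L)
  dimnames(B) <- list(sample_ids, cpg_ids)

  # --- expression (one probe per gene) ---
  # causal probes have a latent transcriptional activity driven by
  # promoter methylation; the assay measures it with noise, and the
  # cognitive score depends on the activity itself (errors-in-variables:
  # upstream methylation and genotype carry information about the
  # activity beyond the measured probe value)
  base_expr <- stats::rnorm(p$n_genes, 7, 1)
  E <- matrix(stats::rnorm(n * p$n_genes, 0, 0.8), n, p$n_genes)
  E <- sweep(E, 2, base_expr, `+`)
  activity <- matrix(0, n, p$n_causal_cascades)
  for (k in seq_len(p$n_causal_cascades)) {
    g <- causal_gene_idx[k]
    activity[, k] <- base_expr[g] -
      p$meth_expr_effect * (B[, k] - mean(B[, k]))
    E[, g] <- activity[, k] + stats::rnorm(n, 0, p$noise_sd[["expression"]])
  }
  dimnames(E) <- list(sample_ids, probe_ids)

  # --- covariates ---
  age <- stats::rnorm(n, 75, 6)
  sex <- stats::rbinom(n, 1L, 0.57)
  education <- stats::rnorm(n, 16, 2.5)
  apoe4 <- sample(0:2, n, replace = TRUE, prob = c(0.574, 0.352, 0.074))
  cov_comb <- -0.5 * scale(age)[, 1] + 0.3 * scale(education)[, 1] -
    0.8 * (apoe4 - mean(apoe4))
  cov_comb <- cov_comb / stats::sd(cov_comb)

  # --- latent score and assessments ---
  zc <- scale(activity)
  gen_comb <- rowSums(zc) / sqrt(p$n_causal_cascades)
  gen_comb <- (gen_comb - mean(gen_comb)) / stats::sd(gen_comb)
  resid_var <- max(1 - p$score_heritability - p$covariate_r2, 0)
  latent <- sqrt(p$score_heritability) * gen_comb +
    sqrt(p$covariate_r2) * cov_comb +
    sqrt(resid_var) * stats::rnorm(n)
  tn <- p$noise_sd[["test"]]
  t1 <- latent + stats::rnorm(n, 0, tn)
  t2 <- latent + stats::rnorm(n, 0, tn)
  t3 <- latent + stats::rnorm(n, 0, tn)
  t4 <- latent + stats::rnorm(n, 0, tn)
  scores <- data.frame(
    sample_id = sample_ids,
    mmse = 18 + 12 * stats::pnorm(t1),
    moca = 10 + 20 * stats::pnorm(t2),
    adas11 = 70 * stats::pnorm(-t3),
    ravlt = 75 * stats::pnorm(t4),
    stringsAsFactors = FALSE)

  diagnosis <- ifelse(latent >= stats::quantile(latent, 2 / 3), "CN", "CI")
  ptau_latent <- -p$ptau_coupling * latent +
    sqrt(1 - p$ptau_coupling^2) * stats::rnorm(n)
  ptau <- exp(2.7 + 0.9 * ptau_latent)
  covariates <- data.frame(sample_id = sample_ids, age = age, sex = sex,
                           education = education, apoe4 = apoe4,
                           ptau = ptau, diagnosis = diagnosis,
                           stringsAsFactors = FALSE)

  # --- gene sets: every gene annotated; enriched terms over-populated
  #     with causal genes ---
  terms <- stats::setNames(vector("list", p$n_go_terms), term_ids)
  for (g in seq_len(p$n_genes)) {
    k <- sample.int(3L, 1L)
    for (t in sample.int(p$n_go_terms, k))
      terms[[t]] <- c(terms[[t]], gene_ids[g])
  }
  n_enr <- min(p$n_enriched_terms, p$n_go_terms)
  causal_genes <- gene_ids[causal_gene_idx]
  for (t in seq_len(n_enr)) {
    take <- sample(causal_genes,
                   max(2L, ceiling(0.75 * length(causal_genes))))
    terms[[t]] <- c(terms[[t]], take)
  }
  # no term may be empty
  for (t in seq_len(p$n_go_terms)) {
    if (!length(terms[[t]]))
      terms[[t]] <- sample(gene_ids, 2L)
    terms[[t]] <- unique(terms[[t]])
  }
  sets <- gene_set_collection(terms,
                              stats::setNames(sprintf("synthetic process %d",
                                                      seq_len(p$n_go_terms)),
                                              term_ids))

  # --- genotype missingness applied last so effects use true dosages ---
  Gm <- G
  if (p$genotype_missing_rate > 0) {
    idx <- which(stats::runif(length(Gm)) < p$genotype_missing_rate)
    Gm[idx] <- -1
  }

  cohort <- structure(list(
    genotype = feature_matrix(Gm, modality = "genotype", missing_code = -1),
    methylation = feature_matrix(B, modality = "methylation"),
    expression = feature_matrix(E, modality = "expression"),
    covariates = covariates,
    scores = scores,
    annotations = list(snp = snps, cpg = cpgs, gene = genes),
    probe_map = data.frame(probe_id = probe_ids, gene_symbol = gene_ids,
                           stringsAsFactors = FALSE),
    gene_sets = sets), class = "multiomics_cohort")

  truth <- structure(list(
    cascades = data.frame(
      snp_id = snp_ids[seq_len(p$n_causal_cascades)],
      cpg_id = cpg_ids[seq_len(p$n_causal_cascades)],
      gene_symbol = causal_genes,
      probe_id = probe_ids[causal_gene_idx],
      meqtl_effect = p$meqtl_effect,
      meth_expr_effect = p$meth_expr_effect,
      stringsAsFactors = FALSE),
    enriched_terms = term_ids[seq_len(n_enr)],
    latent_score = stats::setNames(as.numeric(latent), sample_ids)),
    class = "ground_truth")

  list(cohort = cohort, truth = truth)
}

#' @export
print.multiomics_cohort <- function(x, ...) {
  cat(sprintf(paste0("<multiomics_cohort> %d samples | %d SNPs, %d CpGs, ",
                     "%d probes | %d GO terms | %d assessments\n"),
              nrow(x$genotype$values), ncol(x$genotype$values),
              ncol(x$methylation$values), ncol(x$expression$values),
              length(x$gene_sets), ncol(x$scores) - 1L))
  invisible(x)
}

#' Write a cohort bundle to disk
#'
#' Emits the TSV/BED/GMT/JSON bundle consumed by the selection and training
#' stages, plus a manifest of MD5 file hashes. A failed write removes the
#' partially written directory.
#'
#' @param cohort a `multiomics_cohort`.
#' @param truth the matching `ground_truth` (optional; omitted from the
#'   bundle when `NULL`).
#' @param dir output directory (created if absent).
#' @return Invisibly, the manifest data frame (file, md5).
#' @export
write_cohort <- function(cohort, truth = NULL, dir) {
  created <- !dir.exists(dir)
  if (created) dir.create(dir, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(dir, recursive = TRUE), add = TRUE)
  fp <- function(f) file.path(dir, f)
  write_matrix(cohort$genotype, fp("genotype.tsv"))
  write_matrix(cohort$methylation, fp("methylation.tsv"))
  write_matrix(cohort$expression, fp("expression.tsv"))
  utils::write.table(cohort$covariates, fp("covariates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$scores, fp("scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed_annotations(cohort$annotations$snp, fp("snps.bed"), "snp")
  write_bed_annotations(cohort$annotations$cpg, fp("cpgs.bed"), "cpg")
  write_bed_annotations(cohort$annotations$gene, fp("genes.bed"), "gene")
  utils::write.table(cohort$probe_map, fp("probe_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(cohort$gene_sets, fp("gene_sets.gmt"))
  if (!is.null(truth)) {
    jsonlite::write_json(list(cascades = truth$cascades,
                              enriched_terms = truth$enriched_terms,
                              latent_score = as.list(truth$latent_score)),
                         fp("ground_truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, fp("manifest.json"), digits = NA)
  ok <- TRUE
  invisible(manifest)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir bundle directory.
#' @return A `multiomics_cohort`; if `ground_truth.json` is present it is
#'   attached as attribute `truth`.
#' @export
read_cohort <- function(dir) {
  fp <- function(f) file.path(dir, f)
  scores <- utils::read.delim(fp("scores.tsv"), stringsAsFactors = FALSE,
                              check.names = FALSE)
  cohort <- structure(list(
    genotype = read_matrix(fp("genotype.tsv"), "genotype"),
    methylation = read_matrix(fp("methylation.tsv"), "methylation"),
    expression = read_matrix(fp("expression.tsv"), "expression"),
    covariates = utils::read.delim(fp("covariates.tsv"),
                                   stringsAsFactors = FALSE),
    scores = scores,
    annotations = list(snp = read_bed_annotations(fp("snps.bed"), "snp"),
                       cpg = read_bed_annotations(fp("cpgs.bed"), "cpg"),
                       gene = read_bed_annotations(fp("genes.bed"), "gene")),
    probe_map = utils::read.delim(fp("probe_map.tsv"),
                                  stringsAsFactors = FALSE),
    gene_sets = read_gmt(fp("gene_sets.gmt"))), class = "multiomics_cohort")
  tf <- fp("ground_truth.json")
  if (file.exists(tf)) {
    tj <- jsonlite::read_json(tf, simplifyVector = TRUE)
    attr(cohort, "truth") <- structure(
      list(cascades = as.data.frame(tj$cascades),
           enriched_terms = unlist(tj$enriched_terms),
           latent_score = unlist(tj$latent_score)),
      class = "ground_truth")
  }
  cohort
}
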