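#' QC and selection thresholds
#'
#' Defaults follow conventional GWAS semantics: SNPs and samples are
#' removed when their missing-call rate exceeds `max_missing_rate`, SNPs
#' when MAF falls below `min_maf` or the Hardy-Weinberg exact p drops
#' below `hwe_alpha`. A literal switch (`literal_qc_directions`) instead
#' removes features with missing rate above 95% and HWE p above the
#' threshold — the printed form of the protocol this package mirrors —
#' which discards almost nothing; it exists for comparability only.
#'
#' @param max_missing_rate maximum tolerated missing-call fraction per SNP.
#' @param max_sample_missing_rate maximum tolerated missing-call fraction
#'   per sample.
#' @param min_maf minimum minor allele frequency (computed on non-missing
#'   calls).
#' @param hwe_alpha Hardy-Weinberg exact-test threshold.
#' @param literal_qc_directions use the literal printed directions (see above).
#' @param gwas_adjustment multiple-testing method for the per-SNP scan.
#' @param gwas_adjusted_alpha significance threshold on adjusted p.
#' @param window_bp SNP-CpG cis window in bp (inclusive boundary).
#' @param promoter_offsets_bp upstream promoter offsets (TSS200, TSS1500).
#' @param enrichment_alpha GO-term enrichment threshold.
#' @param enrichment_adjustment `"BH"`, `"bonferroni"` or `"none"`.
#' @param require_go_connected drop probes lacking an enriched-term edge
#'   during pruning (off by default: bypass nodes carry unannotated
#'   probes).
#' @param strict_cpg_promoter require CpGs to satisfy window AND promoter
#'   membership up front rather than gating genes afterwards.
#' @return A `qc_thresholds` object.
#' @export
qc_thresholds <- function(max_missing_rate = 0.05,
                          max_sample_missing_rate = 0.05,
                          min_maf = 0.05,
                          hwe_alpha = 1e-6,
                          literal_qc_directions = FALSE,
                          gwas_adjustment = "bonferroni",
                          gwas_adjusted_alpha = 0.01,
                          window_bp = 1e6,
                          promoter_offsets_bp = c(200L, 1500L),
                          enrichment_alpha = 0.05,
                          enrichment_adjustment = "BH",
                          require_go_connected = FALSE,
                          strict_cpg_promoter = FALSE) {
  thr <- list(max_missing_rate = max_missing_rate,
              max_sample_missing_rate = max_sample_missing_rate,
              min_maf = min_maf,
              hwe_alpha = hwe_alpha, literal_qc_directions = literal_qc_directions,
              gwas_adjustment = gwas_adjustment,
              gwas_adjusted_alpha = gwas_adjusted_alpha,
              window_bp = window_bp,
              promoter_offsets_bp = as.integer(promoter_offsets_bp),
              enrichment_alpha = enrichment_alpha,
              enrichment_adjustment = enrichment_adjustment,
              require_go_connected = require_go_connected,
              strict_cpg_promoter = strict_cpg_promoter)
  frac <- c(thr$max_missing_rate, thr$max_sample_missing_rate,
            thr$min_maf, thr$hwe_alpha,
            thr$gwas_adjusted_alpha, thr$enrichment_alpha)
  if (any(frac <= 0) || any(frac > 1))
    stop("fractional thresholds must lie in (0, 1]")
  if (thr$window_bp <= 0) stop("window_bp must be positive")
  if (!thr$gwas_adjustment %in% c("bonferroni", "BH", "none"))
    stop("gwas_adjustment must be bonferroni, BH or none")
  if (!thr$enrichment_adjustment %in% c("BH", "bonferroni", "none"))
    stop("enrichment_adjustment must be BH, bonferroni or none")
  structure(thr, class = c("qc_thresholds", "list"))
}

#' Compute methylation beta values from intensity pairs
#'
#' beta = M / (M + U) elementwise. Cells with zero total intensity carry no
#' signal; they are set missing (`NA`) and counted in the attached QC
#' report.
#'
#' @param methylated,unmethylated nonnegative intensity matrices of equal
#'   shape with sample rows and CpG columns.
#' @return A methylation [feature_matrix()] with attribute `qc`, a list
#'   holding `n_zero_total`.
#' @export
compute_beta <- function(methylated, unmethylated) {
  M <- as.matrix(methylated)
  U <- as.matrix(unmethylated)
  if (!identical(dim(M), dim(U)))
    stop("methylated and unmethylated matrices must have identical shape")
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("intensities must be nonnegative")
  tot <- M + U
  beta <- M / tot
  zero <- which(tot == 0)
  beta[zero] <- NA_real_
  fm <- feature_matrix(beta,
                       sample_ids = rownames(M),
                       feature_ids = colnames(M),
                       modality = "methylation")
  attr(fm, "qc") <- list(n_zero_total = length(zero))
  fm
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (with a 1e-7 relative tolerance guarding floating-point ties, as is
#' conventional for this test).
#'
#' @param n_AA,n_Aa,n_aa nonnegative integer genotype counts.
#' @return The exact p-value in \[0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped sample required")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- hwe_log_prob(hets, nA, na, n)
  p_obs <- exp(lp[match(n_Aa, hets)])
  min(1, sum(exp(lp)[exp(lp) <= p_obs * (1 + 1e-7)]))
}

# log conditional probability of heterozygote counts given allele counts
hwe_log_prob <- function(h, nA, na, n) {
  lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2) + h * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
}

#' Genotype quality control
#'
#' Applies, in order: per-sample missingness, per-SNP missingness, MAF and
#' Hardy-Weinberg filters. MAF is computed on non-missing calls; HWE uses
#' [hwe_exact_test()] on the non-missing genotype counts. Filter
#' directions follow `thr$literal_qc_directions` (see [qc_thresholds()]).
#'
#' @param geno genotype [feature_matrix()] with values in
#'   \{0, 1, 2, missing sentinel\}.
#' @param thr a [qc_thresholds()] object.
#' @return A list with elements `genotype` (filtered matrix) and `report`
#'   (counts removed per rule plus per-SNP statistics).
#' @export
qc_filter_genotypes <- function(geno, thr = qc_thresholds()) {
  G <- geno$values
  miss <- G == geno$missing_code
  ok_vals <- G %in% c(0, 1, 2) | miss
  if (!all(ok_vals))
    stop("genotype values must be 0, 1, 2 or the missing sentinel")

  lit <- isTRUE(thr$literal_qc_directions)
  samp_limit <- if (lit) 0.95 else thr$max_sample_missing_rate
  snp_limit <- if (lit) 0.95 else thr$max_missing_rate
  samp_rate <- rowMeans(miss)
  keep_samp <- samp_rate <= samp_limit
  G <- G[keep_samp, , drop = FALSE]
  miss <- miss[keep_samp, , drop = FALSE]

  snp_rate <- colMeans(miss)
  keep_missing <- snp_rate <= snp_limit
  n_removed_missing <- sum(!keep_missing)

  maf <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[!miss[, j], j]
    if (!length(g)) return(0)
    f <- mean(g) / 2
    min(f, 1 - f)
  }, numeric(1))
  keep_maf <- keep_missing & maf >= thr$min_maf
  n_removed_maf <- sum(keep_missing & !keep_maf)

  hwe_p <- rep(NA_real_, ncol(G))
  for (j in which(keep_maf)) {
    g <- G[!miss[, j], j]
    hwe_p[j] <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  keep_hwe <- keep_maf &
    (if (lit) hwe_p <= thr$hwe_alpha else hwe_p >= thr$hwe_alpha)
  keep_hwe[is.na(keep_hwe)] <- FALSE
  n_removed_hwe <- sum(keep_maf & !keep_hwe)

  if (!any(keep_hwe) || !nrow(G))
    stop("no SNPs or samples survive genotype QC")
  out <- feature_matrix(G[, keep_hwe, drop = FALSE],
                        modality = "genotype",
                        missing_code = geno$missing_code)
  report <- list(
    n_samples_removed = sum(!keep_samp),
    n_snps_removed_missing = n_removed_missing,
    n_snps_removed_maf = n_removed_maf,
    n_snps_removed_hwe = n_removed_hwe,
    n_snps_retained = sum(keep_hwe),
    per_snp = data.frame(snp_id = colnames(geno$values),
                         missing_rate = snp_rate, maf = maf, hwe_p = hwe_p,
                         retained = keep_hwe, stringsAsFactors = FALSE))
  list(genotype = out, report = report)
}

#' Per-SNP linear-regression scan
#'
#' Simple linear regression of the phenotype on additive dosage, per SNP,
#' over non-missing samples, with a two-sided t-test on the slope and the
#' chosen multiple-testing adjustment (default Bonferroni over the tested
#' SNPs). SNPs with zero dosage variance are flagged untestable with
#' p = 1 by convention.
#'
#' @param geno genotype [feature_matrix()].
#' @param phenotype numeric vector named by (or aligned with) sample ids.
#' @param adjustment `"bonferroni"`, `"BH"` or `"none"`.
#' @param phenotype_name label carried into the result table.
#' @return Data frame with columns `snp_id`, `phenotype`, `slope`, `se`,
#'   `t`, `p`, `p_adj`, `n`, `untestable`.
#' @export
gwas_linear_scan <- function(geno, phenotype,
                             adjustment = c("bonferroni", "BH", "none"),
                             phenotype_name = "phenotype") {
  adjustment <- match.arg(adjustment)
  G <- geno$values
  if (!is.null(names(phenotype))) {
    if (!all(rownames(G) %in% names(phenotype)))
      stop("phenotype missing values for some samples")
    phenotype <- phenotype[rownames(G)]
  }
  if (length(phenotype) != nrow(G))
    stop("phenotype length does not match sample count")
  m <- ncol(G)
  slope <- se <- tval <- p <- rep(NA_real_, m)
  nn <- integer(m)
  untestable <- logical(m)
  for (j in seq_len(m)) {
    obs <- G[, j] != geno$missing_code & !is.na(phenotype)
    g <- G[obs, j]
    y <- phenotype[obs]
    nn[j] <- length(g)
    if (nn[j] < 3) {
      untestable[j] <- TRUE
      slope[j] <- 0; p[j] <- 1
      next
    }
    sxx <- sum((g - mean(g))^2)
    if (sxx == 0) {
      untestable[j] <- TRUE
      slope[j] <- 0; p[j] <- 1
      next
    }
    b <- sum((g - mean(g)) * (y - mean(y))) / sxx
    resid <- y - mean(y) - b * (g - mean(g))
    s2 <- sum(resid^2) / (nn[j] - 2)
    se[j] <- sqrt(s2 / sxx)
    slope[j] <- b
    if (se[j] == 0) {
      # perfect fit: infinitely significant unless slope is zero
      tval[j] <- if (b == 0) 0 else Inf
      p[j] <- if (b == 0) 1 else 0
    } else {
      tval[j] <- b / se[j]
      p[j] <- 2 * stats::pt(-abs(tval[j]), df = nn[j] - 2)
    }
  }
  p_adj <- switch(adjustment,
                  bonferroni = pmin(1, p * m),
                  BH = stats::p.adjust(p, "BH"),
                  none = p)
  data.frame(snp_id = colnames(G), phenotype = phenotype_name,
             slope = slope, se = se, t = tval, p = p, p_adj = p_adj,
             n = nn, untestable = untestable, stringsAsFactors = FALSE)
}

#' Intersect significant SNPs across phenotypes
#'
#' @param results list of [gwas_linear_scan()] result tables, one per
#'   phenotype.
#' @param alpha threshold on adjusted p.
#' @return Character vector of SNP ids significant in every phenotype.
#' @export
intersect_significant <- function(results, alpha) {
  if (!length(results)) stop("at least one phenotype scan required")
  sets <- lapply(results, function(r) r$snp_id[r$p_adj <= alpha])
  Reduce(intersect, sets)
}

#' Link SNPs to CpGs by cis window
#'
#' Edge (snp, cpg) iff same chromosome and |pos_snp - pos_cpg| <=
#' `window_bp` (inclusive; co-located features at distance 0 are linked).
#'
#' @param snps,cpgs annotation data frames (see [read_bed_annotations()]).
#' @param window_bp window half-width in bp.
#' @return Data frame `snp_id`, `cpg_id`, `distance`, `provenance`.
#' @export
link_snp_cpg_window <- function(snps, cpgs, window_bp = 1e6) {
  out <- list()
  for (chr in unique(snps$chromosome)) {
    s <- snps[snps$chromosome == chr, , drop = FALSE]
    c_ <- cpgs[cpgs$chromosome == chr, , drop = FALSE]
    if (!nrow(c_)) next
    ord <- order(c_$position)
    c_ <- c_[ord, , drop = FALSE]
    lo <- findInterval(s$position - window_bp - 0.5, c_$position) + 1L
    hi <- findInterval(s$position + window_bp + 0.5, c_$position)
    for (i in seq_len(nrow(s))) {
      if (hi[i] < lo[i]) next
      idx <- lo[i]:hi[i]
      out[[length(out) + 1L]] <- data.frame(
        snp_id = s$feature_id[i], cpg_id = c_$feature_id[idx],
        distance = abs(c_$position[idx] - s$position[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(snp_id = character(), cpg_id = character(),
                      distance = numeric(), provenance = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$provenance <- "window"
  res
}

#' Map CpGs to promoter windows of genes
#'
#' Strand-aware promoter membership: with upstream distance
#' d = tss - pos on the + strand (pos - tss on the - strand), a CpG is
#' tagged TSS200 when 1 <= d <= `offsets[1]` and TSS1500 when
#' `offsets[1]` < d <= `offsets[2]`.
#'
#' @param cpgs CpG annotation data frame.
#' @param genes gene annotation data frame (with `tss`, `strand`).
#' @param offsets upstream offsets, default `c(200, 1500)`.
#' @return Data frame `cpg_id`, `gene_symbol`, `window`, `distance`,
#'   `provenance`.
#' @export
map_cpg_promoter <- function(cpgs, genes, offsets = c(200L, 1500L)) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    same <- cpgs$chromosome == g$chromosome
    if (!any(same)) next
    cc <- cpgs[same, , drop = FALSE]
    d <- if (g$strand == "+") g$tss - cc$position else cc$position - g$tss
    hit <- d >= 1 & d <= offsets[2]
    if (!any(hit)) next
    out[[length(out) + 1L]] <- data.frame(
      cpg_id = cc$feature_id[hit],
      gene_symbol = g$gene_symbol,
      window = ifelse(d[hit] <= offsets[1], "TSS200", "TSS1500"),
      distance = d[hit], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(cpg_id = character(), gene_symbol = character(),
                      window = character(), distance = numeric(),
                      provenance = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$provenance <- "promoter"
  res
}

#' Min-max normalize an expression matrix
#'
#' Per-feature (x - min) / (max - min) into \[0, 1\]. Constant features
#' carry no usable signal; they are mapped to 0.5 with a warning.
#'
#' @param expr an expression [feature_matrix()].
#' @return The normalized [feature_matrix()].
#' @export
min_max_normalize <- function(expr) {
  X <- expr$values
  rng <- apply(X, 2, range, na.rm = TRUE)
  span <- rng[2, ] - rng[1, ]
  const <- span == 0
  if (any(const))
    warning(sprintf("%d constant feature(s) mapped to 0.5", sum(const)))
  span[const] <- 1
  Xn <- sweep(sweep(X, 2, rng[1, ], `-`), 2, span, `/`)
  Xn[, const] <- 0.5
  feature_matrix(Xn, modality = expr$modality,
                 missing_code = expr$missing_code)
}

#' GO-term hypergeometric enrichment
#'
#' One-sided hypergeometric test per term (probability of an overlap at
#' least as large as observed), with term members intersected with the
#' declared universe before testing. Terms passing `enrichment_alpha` on
#' the adjusted p (method per `thr$enrichment_adjustment`) are retained
#' together with their contributing gene lists.
#'
#' @param selected_genes character vector of selected gene symbols
#'   (subset of `universe`).
#' @param universe character vector of all testable gene symbols.
#' @param sets a `gene_set_collection`.
#' @param thr a [qc_thresholds()] object.
#' @return List with `table` (per-term statistics) and `genes` (named list
#'   of contributing genes for enriched terms).
#' @export
enrich_go_terms <- function(selected_genes, universe, sets,
                            thr = qc_thresholds()) {
  selected_genes <- unique(selected_genes)
  universe <- unique(universe)
  if (!length(selected_genes)) stop("selected gene set is empty")
  if (!all(selected_genes %in% universe))
    stop("selected genes must be contained in the universe")
  N <- length(universe)
  k <- length(selected_genes)
  rows <- lapply(names(sets), function(tid) {
    members <- intersect(sets[[tid]], universe)
    ov <- intersect(members, selected_genes)
    m <- length(members)
    p <- if (m == 0) 1 else
      stats::phyper(length(ov) - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(term_id = tid, n_members = m, n_overlap = length(ov),
               p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- switch(thr$enrichment_adjustment,
                      BH = stats::p.adjust(tab$p, "BH"),
                      bonferroni = pmin(1, tab$p * nrow(tab)),
                      none = tab$p)
  tab$significant <- tab$p_adj <= thr$enrichment_alpha & tab$n_overlap > 0
  tab <- tab[order(tab$p), ]
  rownames(tab) <- NULL
  genes <- lapply(tab$term_id[tab$significant], function(tid)
    intersect(intersect(sets[[tid]], universe), selected_genes))
  names(genes) <- tab$term_id[tab$significant]
  list(table = tab, genes = genes)
}

#' Prune features without cross-layer relationships
#'
#' Iterates to a fixed point: SNPs need an outgoing CpG edge, CpGs both an
#' incoming SNP edge and an outgoing probe edge, probes an incoming CpG
#' edge (and, only when `require_go` is set, an outgoing GO-term edge);
#' orphans created by a removal cascade until the retained sets are
#' stable.
#'
#' @param snp_cpg,cpg_probe,probe_term edge data frames with columns
#'   (`snp_id`,`cpg_id`), (`cpg_id`,`probe_id`), (`probe_id`,`term_id`).
#' @param require_go demand GO-connectedness of probes.
#' @return A `relation_map`.
#' @export
prune_unconnected <- function(snp_cpg, cpg_probe, probe_term,
                              require_go = FALSE) {
  repeat {
    snps <- unique(snp_cpg$snp_id)
    cpgs <- intersect(unique(snp_cpg$cpg_id), unique(cpg_probe$cpg_id))
    probes <- unique(cpg_probe$probe_id)
    if (require_go)
      probes <- intersect(probes, unique(probe_term$probe_id))
    terms <- unique(probe_term$term_id)

    e1 <- snp_cpg[snp_cpg$cpg_id %in% cpgs, , drop = FALSE]
    e2 <- cpg_probe[cpg_probe$cpg_id %in% cpgs &
                      cpg_probe$probe_id %in% probes, , drop = FALSE]
    e3 <- probe_term[probe_term$probe_id %in% probes, , drop = FALSE]
    stable <- nrow(e1) == nrow(snp_cpg) && nrow(e2) == nrow(cpg_probe) &&
      nrow(e3) == nrow(probe_term)
    snp_cpg <- e1; cpg_probe <- e2; probe_term <- e3
    if (stable) break
  }
  if (!nrow(snp_cpg) || !nrow(cpg_probe))
    stop("a layer is empty after pruning")
  relation_map(snp_cpg, cpg_probe, probe_term)
}

#' Cross-layer relation map
#'
#' Directed edge sets connecting retained SNPs to CpGs (cis window), CpGs
#' to expression probes (promoter membership) and probes to GO terms
#' (enrichment annotation), at the pruned fixed point.
#'
#' @param snp_cpg,cpg_probe,probe_term edge data frames.
#' @return A `relation_map` with the three edge tables and `layers`, the
#'   ordered retained id lists.
#' @export
relation_map <- function(snp_cpg, cpg_probe, probe_term) {
  layers <- list(
    snp_ids = sort(unique(snp_cpg$snp_id)),
    cpg_ids = sort(unique(c(snp_cpg$cpg_id, cpg_probe$cpg_id))),
    probe_ids = sort(unique(c(cpg_probe$probe_id, probe_term$probe_id))),
    term_ids = sort(unique(probe_term$term_id)))
  stopifnot(all(snp_cpg$cpg_id %in% layers$cpg_ids),
            all(cpg_probe$cpg_id %in% layers$cpg_ids),
            all(probe_term$probe_id %in% layers$probe_ids))
  structure(list(snp_cpg = snp_cpg, cpg_probe = cpg_probe,
                 probe_term = probe_term, layers = layers),
            class = "relation_map")
}

#' @export
print.relation_map <- function(x, ...) {
  cat(sprintf(paste0("<relation_map> %d SNPs -> %d CpGs -> %d probes -> ",
                     "%d terms | %d/%d/%d edges\n"),
              length(x$layers$snp_ids), length(x$layers$cpg_ids),
              length(x$layers$probe_ids), length(x$layers$term_ids),
              nrow(x$snp_cpg), nrow(x$cpg_probe), nrow(x$probe_term)))
  invisible(x)
}

#' Biologically-related feature selection
#'
#' The full selection pipeline: genotype QC, per-SNP linear scans for every
#' assessment with multiple-testing control, intersection of significant
#' SNPs across assessments, cis-window CpG linking, promoter mapping of
#' CpGs to genes, GO enrichment of the retained genes, and cross-layer
#' pruning to a fixed point.
#'
#' @param cohort a `multiomics_cohort`.
#' @param thr a [qc_thresholds()] object.
#' @param phenotypes assessment columns of `cohort$scores` to scan
#'   (default: all).
#' @return List with `relation_map`, `qc_report`, `associations` (row-bound
#'   scan tables), `significant_snps`, `enrichment`.
#' @export
select_features <- function(cohort, thr = qc_thresholds(),
                            phenotypes = NULL) {
  qc <- qc_filter_genotypes(cohort$genotype, thr)
  if (is.null(phenotypes))
    phenotypes <- setdiff(colnames(cohort$scores), "sample_id")
  scans <- lapply(phenotypes, function(ph) {
    y <- stats::setNames(cohort$scores[[ph]], cohort$scores$sample_id)
    gwas_linear_scan(qc$genotype, y, adjustment = thr$gwas_adjustment,
                     phenotype_name = ph)
  })
  sig <- intersect_significant(scans, thr$gwas_adjusted_alpha)
  if (!length(sig)) stop("no SNP is significant in every phenotype scan")

  snp_ann <- cohort$annotations$snp
  snp_ann <- snp_ann[snp_ann$feature_id %in% sig, , drop = FALSE]
  sc <- link_snp_cpg_window(snp_ann, cohort$annotations$cpg, thr$window_bp)
  cp_gene <- map_cpg_promoter(cohort$annotations$cpg,
                              cohort$annotations$gene,
                              thr$promoter_offsets_bp)
  if (isTRUE(thr$strict_cpg_promoter)) {
    # stricter reading: CpG candidates must satisfy window AND promoter
    sc <- sc[sc$cpg_id %in% cp_gene$cpg_id, , drop = FALSE]
  }
  cp_gene <- cp_gene[cp_gene$cpg_id %in% sc$cpg_id, , drop = FALSE]
  if (!nrow(cp_gene)) stop("no CpG maps to a promoter window")

  pm <- cohort$probe_map
  cpg_probe <- merge(cp_gene, pm, by = "gene_symbol")
  cpg_probe <- cpg_probe[, c("cpg_id", "probe_id", "window", "distance",
                             "provenance")]

  universe <- unique(pm$gene_symbol)
  selected_genes <- unique(cp_gene$gene_symbol)
  enr <- enrich_go_terms(selected_genes, universe, cohort$gene_sets, thr)
  probe_term <- do.call(rbind, lapply(names(enr$genes), function(tid) {
    pr <- pm$probe_id[pm$gene_symbol %in% enr$genes[[tid]]]
    if (!length(pr)) return(NULL)
    data.frame(probe_id = pr, term_id = tid, provenance = "annotation",
               stringsAsFactors = FALSE)
  }))
  if (is.null(probe_term))
    probe_term <- data.frame(probe_id = character(), term_id = character(),
                             provenance = character(),
                             stringsAsFactors = FALSE)

  rel <- prune_unconnected(sc, cpg_probe, probe_term,
                           require_go = thr$require_go_connected)
  list(relation_map = rel, qc_report = qc$report,
       associations = do.call(rbind, scans), significant_snps = sig,
       enrichment = enr$table)
}

#' Write a relation map as JSON
#'
#' @param rel a [relation_map()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_relation_map <- function(rel, path) {
  jsonlite::write_json(list(snp_cpg = rel$snp_cpg,
                            cpg_probe = rel$cpg_probe,
                            probe_term = rel$probe_term),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a relation map written by [write_relation_map()]
#'
#' @param path JSON path.
#' @return A [relation_map()].
#' @export
read_relation_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  relation_map(as.data.frame(j$snp_cpg), as.data.frame(j$cpg_probe),
               as.data.frame(j$probe_term))
}
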