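test_that("beta values follow M/(M+U) with zero-total cells flagged", {
  M <- matrix(c(30, 5, 0), 1, dimnames = list("s1", c("a", "b", "c")))
  U <- matrix(c(70, 5, 0), 1, dimnames = list("s1", c("a", "b", "c")))
  fm <- compute_beta(M, U)
  expect_equal(fm$values[1, "a"], 0.30)
  expect_equal(fm$values[1, "b"], 0.5)
  expect_true(is.na(fm$values[1, "c"]))
  expect_identical(attr(fm, "qc")$n_zero_total, 1L)

  set.seed(8)
  M <- matrix(rgamma(200, 5), 10, 20,
              dimnames = list(sprintf("s%02d", 1:10),
                              sprintf("c%02d", 1:20)))
  U <- matrix(rgamma(200, 5), 10, 20, dimnames = dimnames(M))
  expect_equal(compute_beta(M, U)$values, M / (M + U), tolerance = 1e-12)
  expect_error(compute_beta(M[1:3, ], U), "identical shape")
})

test_that("HWE exact test matches enumeration and is symmetric", {
  expect_equal(hwe_exact_test(0, 0, 50), 1)
  expect_equal(hwe_exact_test(50, 0, 0), 1)
  # frozen value from the independent recurrence oracle
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle_p(25, 50, 25),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:50) {
    n <- sample(3:120, 1)
    cnts <- as.vector(rmultinom(1, n, c(0.3, 0.45, 0.25)))
    p <- hwe_exact_test(cnts[1], cnts[2], cnts[3])
    expect_equal(p, hwe_oracle_p(cnts[1], cnts[2], cnts[3]),
                 tolerance = 1e-12)
    expect_equal(p, hwe_exact_test(cnts[3], cnts[2], cnts[1]),
                 tolerance = 1e-12)
    expect_true(p >= 0 && p <= 1)
  }
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("genotype QC applies missingness, MAF and HWE in order", {
  co <- toy_selection_fixture()
  qc <- qc_filter_genotypes(co$genotype, toy_thresholds())
  expect_identical(colnames(qc$genotype$values),
                   c("s1", "s2", "s3", "s4"))
  expect_identical(qc$report$n_snps_removed_missing, 2L)
  expect_identical(qc$report$n_snps_removed_maf, 2L)
  expect_identical(qc$report$n_snps_removed_hwe, 2L)
  expect_identical(qc$report$n_samples_removed, 0L)

  # monomorphic SNP removed by the MAF rule specifically
  g <- cbind(mono = rep(0, 40), ok = rep(c(0, 1, 2, 1), 10))
  rownames(g) <- sprintf("s%02d", 1:40)
  fm <- feature_matrix(g, modality = "genotype")
  qc2 <- qc_filter_genotypes(fm, qc_thresholds())
  expect_identical(colnames(qc2$genotype$values), "ok")
  expect_identical(qc2$report$n_snps_removed_maf, 1L)

  # literal printed directions invert the HWE rule: only the
  # equilibrium-violating SNPs survive it, and 10%-missing SNPs pass
  # the 95% missingness bar
  qc3 <- qc_filter_genotypes(co$genotype,
                             toy_thresholds(literal_qc_directions = TRUE))
  expect_identical(colnames(qc3$genotype$values), c("s9", "s10"))
  expect_error(qc_filter_genotypes(fm, qc_thresholds(min_maf = 0.9)),
               "survive")
})

test_that("per-SNP linear scan matches the closed-form OLS oracle", {
  set.seed(12)
  n <- 8
  g <- matrix(sample(0:2, n * 1, TRUE), n,
              dimnames = list(sprintf("s%d", 1:n), "snp1"))
  y <- setNames(2.5 * g[, 1] + rnorm(n), rownames(g))
  fm <- feature_matrix(g, modality = "genotype")
  res <- gwas_linear_scan(fm, y, adjustment = "none")
  fit <- summary(lm(y ~ g[, 1]))$coefficients
  expect_equal(res$slope, fit[2, 1], tolerance = 1e-10)
  expect_equal(res$se, fit[2, 2], tolerance = 1e-10)
  expect_equal(res$t, fit[2, 3], tolerance = 1e-10)
  expect_equal(res$p, fit[2, 4], tolerance = 1e-10)

  # constant phenotype: slope exactly 0 everywhere
  g2 <- matrix(sample(0:2, 60, TRUE), 20, 3,
               dimnames = list(sprintf("s%d", 1:20), c("a", "b", "c")))
  res2 <- gwas_linear_scan(feature_matrix(g2, modality = "genotype"),
                           setNames(rep(3, 20), rownames(g2)))
  expect_true(all(res2$slope == 0))

  # Bonferroni is min(1, m * p); zero-variance SNP is untestable
  g3 <- cbind(g2, const = 1)
  res3 <- gwas_linear_scan(feature_matrix(g3, modality = "genotype"),
                           setNames(rnorm(20), rownames(g3)),
                           adjustment = "bonferroni")
  expect_equal(res3$p_adj, pmin(1, res3$p * 4))
  expect_true(res3$untestable[res3$snp_id == "const"])
  expect_equal(res3$p[res3$snp_id == "const"], 1)

  # missing calls are excluded from the per-SNP fit
  g4 <- g
  g4[1:2, 1] <- -1
  res4 <- gwas_linear_scan(feature_matrix(g4, modality = "genotype"), y,
                           adjustment = "none")
  fit4 <- summary(lm(y[-(1:2)] ~ g[-(1:2), 1]))$coefficients
  expect_equal(res4$slope, fit4[2, 1], tolerance = 1e-10)
  expect_identical(res4$n, 6L)
})

test_that("significant-SNP intersection across phenotypes", {
  mk <- function(ids, ps) data.frame(snp_id = ids, p_adj = ps)
  one <- mk(c("a", "b", "c"), c(0.001, 0.5, 0.004))
  expect_setequal(intersect_significant(list(one), 0.01), c("a", "c"))
  two <- mk(c("a", "b", "c"), c(0.5, 0.001, 0.001))
  expect_length(intersect_significant(list(one, two), 0.01), 1L)
  expect_identical(intersect_significant(list(one, two), 0.01), "c")
  disj <- mk(c("a", "b", "c"), c(0.5, 0.001, 0.9))
  expect_length(intersect_significant(list(one, disj), 0.01), 0L)
  three <- mk(c("a", "b", "c", "d"), c(0.002, 0.003, 0.004, 0.9))
  expect_setequal(intersect_significant(list(one, three), 0.01),
                  c("a", "c"))
  expect_error(intersect_significant(list(), 0.01), "at least one")
})

test_that("window linking is inclusive at the boundary and matches brute force", {
  snps <- data.frame(feature_id = "s", chromosome = "chr1",
                     position = 5000L, stringsAsFactors = FALSE)
  mkc <- function(pos) data.frame(feature_id = paste0("c", seq_along(pos)),
                                  chromosome = "chr1", position = pos,
                                  stringsAsFactors = FALSE)
  expect_identical(nrow(link_snp_cpg_window(snps, mkc(5000L), 100)), 1L)
  expect_identical(nrow(link_snp_cpg_window(snps, mkc(5100L), 100)), 1L)
  expect_identical(nrow(link_snp_cpg_window(snps, mkc(5101L), 100)), 0L)
  expect_identical(nrow(link_snp_cpg_window(snps, mkc(4900L), 100)), 1L)

  set.seed(13)
  rsnp <- data.frame(feature_id = sprintf("s%02d", 1:30),
                     chromosome = sample(c("chr1", "chr2"), 30, TRUE),
                     position = sample.int(1e5, 30),
                     stringsAsFactors = FALSE)
  rcpg <- data.frame(feature_id = sprintf("c%02d", 1:40),
                     chromosome = sample(c("chr1", "chr2"), 40, TRUE),
                     position = sample.int(1e5, 40),
                     stringsAsFactors = FALSE)
  got <- link_snp_cpg_window(rsnp, rcpg, 7000)
  brute <- do.call(rbind, lapply(seq_len(30), function(i)
    do.call(rbind, lapply(seq_len(40), function(j) {
      if (rsnp$chromosome[i] == rcpg$chromosome[j] &&
          abs(rsnp$position[i] - rcpg$position[j]) <= 7000)
        data.frame(snp_id = rsnp$feature_id[i],
                   cpg_id = rcpg$feature_id[j])
    }))))
  key <- function(d) sort(paste(d$snp_id, d$cpg_id))
  expect_identical(key(got), key(brute))

  # monotonicity: enlarging the window never removes an edge
  wider <- link_snp_cpg_window(rsnp, rcpg, 20000)
  expect_true(all(key(got) %in% key(wider)))
})

test_that("promoter mapping is strand-aware and matches brute force", {
  gene_plus <- data.frame(feature_id = "G", chromosome = "chr1",
                          position = 10000L, tss = 10000L, strand = "+",
                          gene_symbol = "G", stringsAsFactors = FALSE)
  gene_minus <- gene_plus
  gene_minus$strand <- "-"
  cpg_at <- function(pos) data.frame(feature_id = "c", chromosome = "chr1",
                                     position = pos,
                                     stringsAsFactors = FALSE)
  hit <- map_cpg_promoter(cpg_at(9999L), gene_plus)
  expect_identical(hit$window, "TSS200")
  # same CpG, same TSS, opposite strand: the window flips away
  expect_identical(nrow(map_cpg_promoter(cpg_at(9999L), gene_minus)), 0L)
  expect_identical(map_cpg_promoter(cpg_at(10001L), gene_minus)$window,
                   "TSS200")
  expect_identical(map_cpg_promoter(cpg_at(9800L), gene_plus)$window,
                   "TSS200")
  expect_identical(map_cpg_promoter(cpg_at(9799L), gene_plus)$window,
                   "TSS1500")
  expect_identical(map_cpg_promoter(cpg_at(8500L), gene_plus)$window,
                   "TSS1500")
  expect_identical(nrow(map_cpg_promoter(cpg_at(8499L), gene_plus)), 0L)
  expect_identical(nrow(map_cpg_promoter(cpg_at(10000L), gene_plus)), 0L)

  set.seed(14)
  genes <- data.frame(feature_id = sprintf("g%02d", 1:15),
                      chromosome = "chr1",
                      position = 0L,
                      tss = sample.int(50000, 15) + 2000L,
                      strand = sample(c("+", "-"), 15, TRUE),
                      gene_symbol = sprintf("g%02d", 1:15),
                      stringsAsFactors = FALSE)
  cpgs <- data.frame(feature_id = sprintf("c%03d", 1:200),
                     chromosome = "chr1",
                     position = sample.int(55000, 200),
                     stringsAsFactors = FALSE)
  got <- map_cpg_promoter(cpgs, genes)
  brute <- do.call(rbind, lapply(seq_len(200), function(i)
    do.call(rbind, lapply(seq_len(15), function(j) {
      d <- if (genes$strand[j] == "+") genes$tss[j] - cpgs$position[i]
      else cpgs$position[i] - genes$tss[j]
      if (d >= 1 && d <= 1500)
        data.frame(cpg_id = cpgs$feature_id[i],
                   gene_symbol = genes$gene_symbol[j],
                   window = if (d <= 200) "TSS200" else "TSS1500")
    }))))
  key <- function(d) sort(paste(d$cpg_id, d$gene_symbol, d$window))
  expect_identical(key(got), key(brute))
})

test_that("min-max normalization maps every feature onto [0, 1]", {
  fm <- feature_matrix(matrix(c(2, 4, 6, 0, 0.5, 1), 3, 2,
                              dimnames = list(c("a", "b", "c"),
                                              c("x", "y"))),
                       modality = "expression")
  norm <- min_max_normalize(fm)
  expect_equal(norm$values[, "x"], c(a = 0, b = 0.5, c = 1))
  expect_equal(norm$values[, "y"], fm$values[, "y"])  # idempotent

  set.seed(15)
  r <- feature_matrix(matrix(rnorm(200, 5, 3), 20, 10,
                             dimnames = list(sprintf("s%02d", 1:20),
                                             sprintf("f%02d", 1:10))),
                      modality = "expression")
  rn <- min_max_normalize(r)
  expect_equal(unname(apply(rn$values, 2, min)), rep(0, 10))
  expect_equal(unname(apply(rn$values, 2, max)), rep(1, 10))

  cf <- feature_matrix(matrix(c(1, 1, 1, 2, 3, 4), 3, 2,
                              dimnames = list(letters[1:3], c("k", "m"))),
                       modality = "expression")
  expect_warning(cn <- min_max_normalize(cf), "constant")
  expect_equal(unname(cn$values[, "k"]), rep(0.5, 3))
})

test_that("GO enrichment equals the closed-form hypergeometric tail", {
  sets <- gene_set_collection(list(t1 = letters[1:5], t2 = letters[6:8]))
  enr <- enrich_go_terms(letters[1:5], letters[1:10], sets,
                         qc_thresholds(enrichment_adjustment = "none"))
  t1 <- enr$table[enr$table$term_id == "t1", ]
  expect_equal(t1$p, 1 / choose(10, 5), tolerance = 1e-10)
  t2 <- enr$table[enr$table$term_id == "t2", ]
  expect_gte(t2$p, 0.5)

  # selected = universe: every overlap maximal, p = 1 for all terms
  enr2 <- enrich_go_terms(letters[1:10], letters[1:10], sets)
  expect_true(all(enr2$table$p == 1))

  # random instances against an explicit hypergeometric sum
  set.seed(16)
  uni <- sprintf("G%03d", 1:40)
  for (i in 1:20) {
    members <- sample(uni, sample(4:15, 1))
    sel <- sample(uni, sample(5:20, 1))
    ov <- length(intersect(members, sel))
    oracle <- sum(vapply(ov:min(length(members), length(sel)), function(x)
      choose(length(members), x) *
        choose(40 - length(members), length(sel) - x) /
        choose(40, length(sel)), numeric(1)))
    enr3 <- enrich_go_terms(sel, uni,
                            gene_set_collection(list(t = members)),
                            qc_thresholds(enrichment_adjustment = "none"))
    expect_equal(enr3$table$p, oracle, tolerance = 1e-10)
  }
  expect_error(enrich_go_terms(character(), uni, sets), "empty")
})

test_that("pruning reaches the connected fixed point", {
  sc <- data.frame(snp_id = c("s1", "s2"), cpg_id = c("c1", "c9"))
  cp <- data.frame(cpg_id = "c1", probe_id = "p1")
  pt <- data.frame(probe_id = "p1", term_id = "t1")
  rel <- prune_unconnected(sc, cp, pt)
  expect_identical(rel$layers$snp_ids, "s1")    # s2 -> orphan CpG dropped
  expect_identical(rel$layers$cpg_ids, "c1")

  # removing the middle of a chain cascades both ways
  sc2 <- data.frame(snp_id = c("s1", "s2"), cpg_id = c("c1", "c2"))
  cp2 <- data.frame(cpg_id = "c2", probe_id = "p2")
  pt2 <- data.frame(probe_id = c("p1", "p2"), term_id = "t1")
  rel2 <- prune_unconnected(sc2, cp2, pt2)
  expect_identical(rel2$layers$snp_ids, "s2")
  expect_identical(rel2$layers$probe_ids, "p2")

  expect_error(prune_unconnected(
    data.frame(snp_id = "s1", cpg_id = "c1"),
    data.frame(cpg_id = "c9", probe_id = "p1"),
    data.frame(probe_id = "p1", term_id = "t1")), "empty")

  # random bipartite fixtures against a naive repeated-sweep oracle
  set.seed(17)
  for (i in 1:10) {
    sc3 <- unique(data.frame(
      snp_id = sample(sprintf("s%d", 1:8), 12, TRUE),
      cpg_id = sample(sprintf("c%d", 1:8), 12, TRUE)))
    cp3 <- unique(data.frame(
      cpg_id = sample(sprintf("c%d", 1:8), 10, TRUE),
      probe_id = sample(sprintf("p%d", 1:6), 10, TRUE)))
    pt3 <- unique(data.frame(
      probe_id = sample(sprintf("p%d", 1:6), 8, TRUE),
      term_id = sample(sprintf("t%d", 1:4), 8, TRUE)))
    oracle <- local({
      s <- unique(sc3$snp_id); c_ <- unique(c(sc3$cpg_id, cp3$cpg_id))
      p <- unique(cp3$probe_id)
      repeat {
        c2 <- intersect(intersect(c_, sc3$cpg_id[sc3$snp_id %in% s]),
                        cp3$cpg_id[cp3$probe_id %in% p])
        s2 <- intersect(s, sc3$snp_id[sc3$cpg_id %in% c2])
        p2 <- intersect(p, cp3$probe_id[cp3$cpg_id %in% c2])
        if (identical(s2, s) && identical(c2, c_) && identical(p2, p))
          break
        s <- s2; c_ <- c2; p <- p2
      }
      list(s = sort(s), c = sort(c_), p = sort(p))
    })
    if (!length(oracle$s) || !length(oracle$c) || !length(oracle$p)) {
      expect_error(prune_unconnected(sc3, cp3, pt3), "empty")
    } else {
      rel3 <- prune_unconnected(sc3, cp3, pt3)
      expect_identical(rel3$layers$snp_ids, oracle$s)
      expect_identical(rel3$layers$cpg_ids, oracle$c)
      expect_identical(rel3$layers$probe_ids, oracle$p)
    }
  }
})

test_that("the selection pipeline is deterministic and JSON round-trips", {
  co <- toy_selection_fixture()
  a <- select_features(co, toy_thresholds(), phenotypes = "score")
  b <- select_features(co, toy_thresholds(), phenotypes = "score")
  expect_identical(a$relation_map$snp_cpg, b$relation_map$snp_cpg)
  expect_identical(a$relation_map$layers, b$relation_map$layers)

  path <- withr::local_tempfile(fileext = ".json")
  write_relation_map(a$relation_map, path)
  back <- read_relation_map(path)
  expect_identical(back$layers, a$relation_map$layers)
  expect_equal(back$snp_cpg$distance, a$relation_map$snp_cpg$distance)
})
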