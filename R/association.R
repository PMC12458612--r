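#' Spearman rank correlation
#'
#' Average-rank (midrank) Spearman rho computed as the Pearson
#' correlation of the rank-transformed vectors; two-sided p-value from
#' the t approximation with n - 2 degrees of freedom, replaced by an
#' exact permutation p (full enumeration of rank permutations) for
#' n <= 9 without ties. Pairwise-complete observations are used.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return List with `rho`, `p`, `n`, and `method` (`"exact"` or
#'   `"t-approx"`). Zero variance in either vector yields `rho = NA` with
#'   `method = "degenerate"`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n,
                method = "degenerate"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    p <- spearman_exact_p(rx, ry)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approx"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

# exact two-sided permutation p for untied ranks: enumerate all n!
# permutations of one rank vector (Heap's algorithm) and count |rho|
# at least as extreme as observed
spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  obs <- abs(stats::cor(rx, ry))
  perms <- all_permutations(n)
  rhos <- abs(as.numeric(stats::cor(rx, t(matrix(ry[perms], ncol = n)))))
  mean(rhos >= obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                         drop = FALSE]
    out[row + seq_len(nrow(sub)), ] <- blk
    row <- row + nrow(sub)
  }
  out
}

#' Cohort group assignment
#'
#' Maps diagnosis labels to the two analysis strata: `CN` (cognitively
#' normal) and `CI` (cognitive impairment, comprising MCI and AD).
#'
#' @param diagnosis character vector of per-sample labels (`CN`, `CI`,
#'   `MCI`, `AD`).
#' @param sample_ids optional ids used as names.
#' @return Named character vector of group labels.
#' @export
cohort_groups <- function(diagnosis, sample_ids = NULL) {
  grp <- ifelse(diagnosis %in% c("MCI", "AD", "CI"), "CI",
                ifelse(diagnosis == "CN", "CN", NA_character_))
  if (any(is.na(grp)))
    stop("unknown diagnosis label(s): ",
         paste(unique(diagnosis[is.na(grp)]), collapse = ", "))
  if (!is.null(sample_ids)) names(grp) <- sample_ids
  grp
}

correlate_pairs <- function(get_x, get_y, pairs, groups, alpha,
                            flag_on = "raw") {
  rows <- list()
  levels <- unique(groups)
  for (i in seq_len(nrow(pairs))) {
    for (g in levels) {
      idx <- which(groups == g)
      if (length(idx) < 3) {
        warning("group ", g, " has fewer than 3 samples; skipped")
        next
      }
      x <- get_x(i, idx); y <- get_y(i, idx)
      if (stats::sd(x, na.rm = TRUE) == 0 ||
          stats::sd(y, na.rm = TRUE) == 0) {
        warning("constant values for pair ", i, " in group ", g,
                "; excluded")
        next
      }
      sc <- spearman_correlation(x, y)
      rows[[length(rows) + 1L]] <- cbind(pairs[i, , drop = FALSE],
        data.frame(group = g, n = sc$n, rho = sc$rho, p = sc$p,
                   stringsAsFactors = FALSE))
    }
  }
  if (!length(rows))
    return(cbind(pairs[0, , drop = FALSE],
                 data.frame(group = character(), n = integer(),
                            rho = numeric(), p = numeric(),
                            p_adj = numeric(), significant = logical())))
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p, "BH")
  tab$significant <- (if (flag_on == "raw") tab$p else tab$p_adj) <= alpha
  rownames(tab) <- NULL
  tab
}

#' CpG-expression correlations by cognitive group
#'
#' Per CpG-probe pair and group: midrank Spearman rho, raw p, and
#' BH-adjusted p. Pairs are typically the promoter edges of a relation
#' map. The significance flag mirrors the conventional reporting (raw
#' p <= alpha) by default; set `flag_on = "adjusted"` for the corrected
#' criterion.
#'
#' @param betas methylation [feature_matrix()].
#' @param expr expression [feature_matrix()].
#' @param pairs data frame with columns `cpg_id`, `probe_id` (extra
#'   columns are carried through).
#' @param groups named group vector from [cohort_groups()], or `NULL` for
#'   a single pooled group.
#' @param alpha significance threshold.
#' @param flag_on `"raw"` or `"adjusted"`.
#' @return Correlation table sorted by pair then group.
#' @export
methylation_expression_correlation <- function(betas, expr, pairs,
                                               groups = NULL,
                                               alpha = 0.05,
                                               flag_on = "raw") {
  sids <- sample_ids(betas)
  stopifnot(identical(sids, sample_ids(expr)))
  if (is.null(groups)) groups <- stats::setNames(rep("all", length(sids)),
                                                 sids)
  groups <- groups[sids]
  keep <- pairs$cpg_id %in% feature_ids(betas) &
    pairs$probe_id %in% feature_ids(expr)
  pairs <- pairs[keep, c("cpg_id", "probe_id"), drop = FALSE]
  correlate_pairs(
    get_x = function(i, idx) betas$values[idx, pairs$cpg_id[i]],
    get_y = function(i, idx) expr$values[idx, pairs$probe_id[i]],
    pairs, groups, alpha, flag_on)
}

#' Feature correlations with the p-Tau measurement by group
#'
#' @param features any [feature_matrix()] (SNP dosages, betas,
#'   expression); feature ids select columns.
#' @param ptau numeric vector named by sample id.
#' @param feature_ids features to test (default: all columns).
#' @param groups named group vector or `NULL` for pooled.
#' @inheritParams methylation_expression_correlation
#' @return Correlation table (feature x group).
#' @export
ptau_feature_correlation <- function(features, ptau,
                                     feature_ids = NULL,
                                     groups = NULL, alpha = 0.05,
                                     flag_on = "raw") {
  sids <- rownames(features$values)
  ptau <- ptau[sids]
  if (is.null(feature_ids)) feature_ids <- colnames(features$values)
  feature_ids <- intersect(feature_ids, colnames(features$values))
  if (is.null(groups)) groups <- stats::setNames(rep("all", length(sids)),
                                                 sids)
  groups <- groups[sids]
  mc <- features$missing_code
  pairs <- data.frame(feature_id = feature_ids, stringsAsFactors = FALSE)
  correlate_pairs(
    get_x = function(i, idx) {
      v <- features$values[idx, pairs$feature_id[i]]
      if (features$modality == "genotype") v[v == mc] <- NA
      v
    },
    get_y = function(i, idx) ptau[idx],
    pairs, groups, alpha, flag_on)
}

#' Cognitive score correlations with the p-Tau measurement
#'
#' One whole-cohort Spearman correlation per assessment (no grouping).
#'
#' @param scores data frame with `sample_id` plus one column per
#'   assessment.
#' @param ptau numeric vector named by sample id.
#' @param alpha significance threshold.
#' @return Table with one row per assessment.
#' @export
ptau_cognition_correlation <- function(scores, ptau, alpha = 0.05) {
  ptau <- ptau[scores$sample_id]
  tests <- setdiff(colnames(scores), "sample_id")
  rows <- lapply(tests, function(ph) {
    sc <- spearman_correlation(scores[[ph]], ptau)
    data.frame(phenotype = ph, n = sc$n, rho = sc$rho, p = sc$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p, "BH")
  tab$significant <- tab$p <= alpha
  tab
}
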