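#' Build binary connectivity masks from a relation map
#'
#' Converts the pruned cross-layer edge sets into the ordered binary mask
#' matrices that gate the hierarchical network: M1 (SNP x CpG), M2
#' (CpG x probe), M3 (probe x GO term). Layer orderings are deterministic
#' (lexicographic by id, matching the sorted retained lists of the
#' relation map), so the same relation map always yields bit-identical
#' masks.
#'
#' @param rel a [relation_map()] at the pruned fixed point.
#' @return A `mask_set`: list with `snp_ids`, `cpg_ids`, `probe_ids`,
#'   `term_ids`, binary matrices `M1`, `M2`, `M3`, and `variant`
#'   (`"biological"`).
#' @export
build_masks <- function(rel) {
  ly <- rel$layers
  if (!length(ly$snp_ids) || !length(ly$cpg_ids) ||
      !length(ly$probe_ids) || !length(ly$term_ids))
    stop("cannot build masks: a layer is empty")
  M1 <- edge_mask(rel$snp_cpg$snp_id, rel$snp_cpg$cpg_id,
                  ly$snp_ids, ly$cpg_ids)
  M2 <- edge_mask(rel$cpg_probe$cpg_id, rel$cpg_probe$probe_id,
                  ly$cpg_ids, ly$probe_ids)
  M3 <- edge_mask(rel$probe_term$probe_id, rel$probe_term$term_id,
                  ly$probe_ids, ly$term_ids)
  structure(list(snp_ids = ly$snp_ids, cpg_ids = ly$cpg_ids,
                 probe_ids = ly$probe_ids, term_ids = ly$term_ids,
                 M1 = M1, M2 = M2, M3 = M3, variant = "biological"),
            class = "mask_set")
}

edge_mask <- function(from, to, from_ids, to_ids) {
  M <- matrix(0, length(from_ids), length(to_ids),
              dimnames = list(from_ids, to_ids))
  M[cbind(match(from, from_ids), match(to, to_ids))] <- 1
  M
}

#' @export
print.mask_set <- function(x, ...) {
  dens <- function(M) mean(M)
  cat(sprintf(paste0("<mask_set> variant=%s | M1 %dx%d (density %.3f), ",
                     "M2 %dx%d (%.3f), M3 %dx%d (%.3f)\n"),
              x$variant, nrow(x$M1), ncol(x$M1), dens(x$M1),
              nrow(x$M2), ncol(x$M2), dens(x$M2),
              nrow(x$M3), ncol(x$M3), dens(x$M3)))
  invisible(x)
}

#' Fully-connected ablation masks
#'
#' Replaces every mask with an all-ones matrix of identical shape,
#' removing the curated cross-layer structure while preserving layer
#' sizes and orderings.
#'
#' @param masks a `mask_set`.
#' @return The `mask_set` with all-ones masks and variant `"full"`.
#' @export
ablate_full <- function(masks) {
  for (m in c("M1", "M2", "M3")) {
    masks[[m]][] <- 1
  }
  masks$variant <- "full"
  masks
}

#' Randomized-pairing ablation masks
#'
#' Preserves the number of inter-layer connections in each mask but
#' redraws their positions uniformly at random (without replacement) over
#' the whole matrix, destroying the biological pairings while keeping
#' sparsity. A degree-preserving alternative reshuffles the column targets
#' within each row, keeping every source node's out-degree.
#'
#' @param masks a `mask_set`.
#' @param seed integer seed; the draw is reproducible.
#' @param preserve_degree reshuffle within rows instead of globally.
#' @return The `mask_set` with randomized masks and variant `"randomized"`.
#' @export
ablate_randomized <- function(masks, seed = 1L, preserve_degree = FALSE) {
  set.seed(seed)
  for (m in c("M1", "M2", "M3")) {
    M <- masks[[m]]
    if (preserve_degree) {
      for (i in seq_len(nrow(M)))
        M[i, ] <- M[i, sample.int(ncol(M))]
    } else {
      k <- sum(M)
      M[] <- 0
      M[sample.int(length(M), k)] <- 1
    }
    masks[[m]] <- M
  }
  masks$variant <- "randomized"
  masks
}
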