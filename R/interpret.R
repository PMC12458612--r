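#' DeepLIFT (Rescale rule) attributions
#'
#' Attributes the scalar prediction to every input feature against a
#' reference input, propagating multipliers backwards through the
#' eval-mode network: linear ops pass multipliers like gradients,
#' elementwise nonlinearities use the Rescale rule (finite-difference
#' slope between actual and reference activation, falling back to the
#' derivative for near-zero input differences), elementwise products use
#' the exact symmetric decomposition, and the clamped division stage is
#' attributed through its composed clamp-plus-reciprocal unit. The
#' sum-to-delta identity (sum of contributions equals
#' `f(x) - f(reference)` per sample) holds by construction.
#'
#' @param model a trained `hinn_model` (attribution always runs in eval
#'   mode: frozen batch-norm statistics, no dropout).
#' @param X named input list (`snp`, `cpg`, `expr`, `demo`).
#' @param reference `"train_mean"` (per-feature mean of `ref_X`, default
#'   `X` itself) or `"zeros"`.
#' @param ref_X optional input list whose per-feature means define the
#'   reference (typically the training split).
#' @param phenotype_name label carried into the table.
#' @return List with `table` (per-feature `feature_id`, `layer`, `score` =
#'   mean absolute per-sample contribution, `signed_mean`),
#'   `contributions` (per-layer sample x feature matrices), `prediction`,
#'   `reference_prediction`.
#' @export
deeplift_attributions <- function(model, X,
                                  reference = c("train_mean", "zeros"),
                                  ref_X = NULL,
                                  phenotype_name = "phenotype") {
  reference <- match.arg(reference)
  if (is.null(ref_X)) ref_X <- X
  n <- nrow(X$snp)
  refs <- lapply(X[c("snp", "cpg", "expr", "demo")], function(m)
    matrix(0, n, ncol(m), dimnames = list(NULL, colnames(m))))
  for (nm in names(refs)) {
    if (ncol(ref_X[[nm]]) != ncol(X[[nm]]))
      stop("reference shape mismatch for input '", nm, "'")
  }
  if (reference == "train_mean") {
    for (nm in names(refs)) {
      mu <- colMeans(ref_X[[nm]])
      refs[[nm]] <- matrix(mu, n, length(mu), byrow = TRUE,
                           dimnames = list(NULL, colnames(X[[nm]])))
    }
  }
  fw <- hinn_forward(model, X, training = FALSE, refs = refs)
  tape_deeplift(fw$tape, fw$out)
  layer_of <- c(snp = "snp", cpg = "cpg", expr = "probe",
                demo = "demographic")
  contribs <- list()
  rows <- list()
  for (nm in names(layer_of)) {
    node <- fw$inputs[[nm]]
    mult <- if (is.null(node$mult))
      matrix(0, nrow(node$value), ncol(node$value)) else node$mult
    contrib <- mult * (node$value - node$ref)
    colnames(contrib) <- colnames(X[[nm]])
    contribs[[nm]] <- contrib
    rows[[nm]] <- data.frame(feature_id = colnames(contrib),
                             layer = layer_of[[nm]],
                             score = colMeans(abs(contrib)),
                             signed_mean = colMeans(contrib),
                             phenotype = phenotype_name,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, contributions = contribs,
       prediction = as.numeric(fw$out$value),
       reference_prediction = as.numeric(fw$out$ref))
}

#' Aggregate attributions across phenotypes
#'
#' Averages absolute attribution scores across per-phenotype tables (and
#' repeats, if supplied as separate tables) and computes percentile ranks
#' within each molecular layer separately, so that layers of different
#' widths are comparable.
#'
#' @param tables list of attribution tables from
#'   [deeplift_attributions()] (`$table` component or compatible).
#' @return Aggregated table with columns `feature_id`, `layer`, `score`
#'   (cross-table mean of absolute scores) and `percentile` in (0, 100\].
#' @export
aggregate_importance <- function(tables) {
  if (!length(tables)) stop("no attribution tables supplied")
  tables <- lapply(tables, function(t) if (is.list(t) && !is.data.frame(t))
    t$table else t)
  key0 <- paste(tables[[1]]$feature_id, tables[[1]]$layer)
  for (t in tables[-1]) {
    key <- paste(t$feature_id, t$layer)
    if (!setequal(key, key0)) {
      diffs <- c(setdiff(key, key0), setdiff(key0, key))
      stop("attribution tables disagree on features: ",
           paste(utils::head(diffs, 5), collapse = ", "))
    }
  }
  base <- tables[[1]][order(tables[[1]]$layer, tables[[1]]$feature_id),
                      c("feature_id", "layer")]
  scores <- vapply(tables, function(t) {
    t <- t[order(t$layer, t$feature_id), ]
    abs(t$score)
  }, numeric(nrow(base)))
  base$score <- rowMeans(as.matrix(scores))
  base$percentile <- NA_real_
  for (ly in unique(base$layer)) {
    i <- base$layer == ly
    base$percentile[i] <- 100 * rank(base$score[i],
                                     ties.method = "average") / sum(i)
  }
  rownames(base) <- NULL
  base
}

#' Export a Sankey graph of prioritized cascades
#'
#' Selects the `top_k` features per molecular layer by attribution
#' percentile and keeps a link only when both endpoints are selected and
#' the edge exists in the relation map, so every displayed flow satisfies
#' the spatial-functional constraints. GO terms (which carry no input
#' attribution) are ranked by the summed attribution of their selected
#' source probes, and the `top_k` of those are kept. Link weight is the
#' mean attribution score of the source feature.
#'
#' @param agg aggregated attribution table from [aggregate_importance()].
#' @param rel a [relation_map()].
#' @param top_k features kept per layer.
#' @return A `sankey_graph`: list with `nodes` (id, layer, rank) and
#'   `links` (source, target, provenance, weight). Empty graphs trigger a
#'   warning, not an error.
#' @export
export_sankey <- function(agg, rel, top_k = 10L) {
  if (top_k < 1) stop("top_k must be >= 1")
  pick <- function(ly) {
    sub <- agg[agg$layer == ly, ]
    sub <- sub[order(-sub$score, sub$feature_id), ]
    utils::head(sub$feature_id, top_k)
  }
  snps <- pick("snp"); cpgs <- pick("cpg"); probes <- pick("probe")
  score_of <- stats::setNames(agg$score, paste(agg$layer, agg$feature_id))
  l1 <- rel$snp_cpg[rel$snp_cpg$snp_id %in% snps &
                      rel$snp_cpg$cpg_id %in% cpgs, , drop = FALSE]
  l2 <- rel$cpg_probe[rel$cpg_probe$cpg_id %in% cpgs &
                        rel$cpg_probe$probe_id %in% probes, , drop = FALSE]
  l3 <- rel$probe_term[rel$probe_term$probe_id %in% probes, , drop = FALSE]
  if (nrow(l3)) {
    tw <- tapply(score_of[paste("probe", l3$probe_id)], l3$term_id, sum)
    terms <- names(sort(tw, decreasing = TRUE))[
      seq_len(min(top_k, length(tw)))]
    l3 <- l3[l3$term_id %in% terms, , drop = FALSE]
  } else terms <- character()

  links <- rbind(
    if (nrow(l1)) data.frame(source = l1$snp_id, target = l1$cpg_id,
                             provenance = "window",
                             weight = unname(score_of[paste("snp", l1$snp_id)]),
                             stringsAsFactors = FALSE),
    if (nrow(l2)) data.frame(source = l2$cpg_id, target = l2$probe_id,
                             provenance = "promoter",
                             weight = unname(score_of[paste("cpg", l2$cpg_id)]),
                             stringsAsFactors = FALSE),
    if (nrow(l3)) data.frame(source = l3$probe_id, target = l3$term_id,
                             provenance = "annotation",
                             weight = unname(score_of[paste("probe", l3$probe_id)]),
                             stringsAsFactors = FALSE))
  if (is.null(links) || !nrow(links)) {
    warning("no links survive joint prioritization; emitting empty graph")
    links <- data.frame(source = character(), target = character(),
                        provenance = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
  }
  node_rank <- function(ids, ly) {
    if (!length(ids)) return(NULL)
    data.frame(id = ids, layer = ly, rank = seq_along(ids),
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(node_rank(snps, "snp"), node_rank(cpgs, "cpg"),
                 node_rank(probes, "probe"), node_rank(terms, "term"))
  used <- unique(c(links$source, links$target))
  nodes <- nodes[nodes$id %in% used | !nrow(links), , drop = FALSE]
  structure(list(nodes = nodes, links = links), class = "sankey_graph")
}

#' @export
print.sankey_graph <- function(x, ...) {
  cat(sprintf("<sankey_graph> %d nodes, %d links\n",
              nrow(x$nodes), nrow(x$links)))
  invisible(x)
}

#' Write a Sankey graph as render-ready JSON
#'
#' @param graph a `sankey_graph`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_sankey_json <- function(graph, path) {
  jsonlite::write_json(list(nodes = graph$nodes, links = graph$links),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Count complete ground-truth cascades in a Sankey graph
#'
#' A cascade is recovered when its SNP -> CpG -> probe path is present in
#' the graph's links and the probe connects to at least one GO term.
#'
#' @param graph a `sankey_graph`.
#' @param truth a `ground_truth`.
#' @return Integer count of recovered cascades.
#' @export
count_recovered_cascades <- function(graph, truth) {
  lk <- graph$links
  has_link <- function(s, t) any(lk$source == s & lk$target == t)
  n <- 0L
  for (i in seq_len(nrow(truth$cascades))) {
    cc <- truth$cascades[i, ]
    if (has_link(cc$snp_id, cc$cpg_id) &&
        has_link(cc$cpg_id, cc$probe_id) &&
        any(lk$source == cc$probe_id))
      n <- n + 1L
  }
  n
}
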