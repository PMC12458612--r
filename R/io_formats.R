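#' Feature matrices
#'
#' A `feature_matrix` is the common container for all dense omics inputs:
#' a numeric samples-by-features matrix with unique, ordered sample and
#' feature identifiers and a declared modality. Genotype matrices carry an
#' explicit missing-call sentinel (default `-1`) so that QC missingness
#' counts are exact rather than inferred from `NA` semantics; methylation
#' matrices are constrained to beta values in \[0, 1\].
#'
#' @param values numeric matrix (samples x features).
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `rownames(values)`.
#' @param feature_ids character vector of unique feature identifiers;
#'   defaults to `colnames(values)`.
#' @param modality one of `"genotype"`, `"methylation"`, `"expression"`,
#'   `"covariate"`.
#' @param missing_code numeric sentinel marking absent genotype calls.
#'
#' @return An object of class `feature_matrix`: a list with elements
#'   `values` (the matrix, with dimnames set), `modality` and `missing_code`.
#' @export
feature_matrix <- function(values, sample_ids = rownames(values),
                           feature_ids = colnames(values),
                           modality = c("genotype", "methylation",
                                        "expression", "covariate"),
                           missing_code = -1) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(feature_ids))
    stop("feature_matrix requires sample_ids and feature_ids")
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (nrow(values) != length(sample_ids) || ncol(values) != length(feature_ids))
    stop("dimension mismatch between values and ids")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature_ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  dimnames(values) <- list(sample_ids, feature_ids)
  if (modality == "methylation") {
    finite <- values[is.finite(values)]
    if (length(finite) && (min(finite) < 0 || max(finite) > 1))
      stop("methylation beta values must lie in [0, 1]")
  }
  structure(list(values = values, modality = modality,
                 missing_code = missing_code),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d samples x %d features\n",
              x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

sample_ids <- function(fm) rownames(fm$values)
feature_ids <- function(fm) colnames(fm$values)

#' Read a samples-by-features matrix from TSV
#'
#' The canonical exchange format for all matrices is tab-separated text:
#' first row feature identifiers, first column sample identifiers. Genotype
#' missing calls are encoded by the sentinel value and preserved verbatim.
#'
#' @param path file path.
#' @inheritParams feature_matrix
#' @return A [feature_matrix()].
#' @export
read_matrix <- function(path, modality, missing_code = -1) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = NULL,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("matrix file needs an id column plus >= 1 feature")
  sids <- raw[[1]]
  fids <- colnames(raw)[-1]
  vals <- matrix(NA_real_, nrow(raw), length(fids))
  for (j in seq_along(fids)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(col) & !is.na(raw[[j + 1]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s', row '%s'",
                   fids[j], sids[bad[1]]))
    vals[, j] <- col
  }
  feature_matrix(vals, sids, fids, modality = modality,
                 missing_code = missing_code)
}

#' Write a feature matrix to TSV
#'
#' @param fm a [feature_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(fm, path) {
  df <- data.frame(sample_id = sample_ids(fm), fm$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genomic annotations from BED
#'
#' Coordinates are 0-based, half-open throughout the package. Point features
#' (SNPs, CpGs) are encoded as `[p, p + 1)` and get `position = start`.
#' Gene rows carry the gene symbol in column 4 and strand in column 6; the
#' transcription start site is `start` on the `+` strand and `end - 1` on
#' the `-` strand.
#'
#' @param path BED file path.
#' @param modality one of `"snp"`, `"cpg"`, `"gene"`.
#' @return A data frame with columns `feature_id`, `chromosome`, `position`,
#'   and for genes additionally `tss`, `strand`, `gene_symbol`.
#' @export
read_bed_annotations <- function(path, modality = c("snp", "cpg", "gene")) {
  modality <- match.arg(modality)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(empty_annotation(modality))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (modality == "gene") 6L else 4L
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < need)
      stop(sprintf("line %d: expected >= %d BED columns, got %d",
                   i, need, length(f)))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop(sprintf("line %d: non-integer interval bounds", i))
    if (end <= start)
      stop(sprintf("line %d: end (%d) must exceed start (%d)", i, end, start))
    if (start < 0) stop(sprintf("line %d: negative position", i))
    if (modality == "gene") {
      strand <- f[6]
      if (!strand %in% c("+", "-"))
        stop(sprintf("line %d: gene row lacks +/- strand", i))
      out[[i]] <- data.frame(
        feature_id = f[4], chromosome = f[1],
        position = start,
        tss = if (strand == "+") start else end - 1L,
        strand = strand, gene_symbol = f[4],
        stringsAsFactors = FALSE)
    } else {
      out[[i]] <- data.frame(
        feature_id = f[4], chromosome = f[1], position = start,
        stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, out)
  if (anyDuplicated(ann$feature_id))
    stop("duplicate feature ids in annotation: ",
         paste(unique(ann$feature_id[duplicated(ann$feature_id)]),
               collapse = ", "))
  ann
}

empty_annotation <- function(modality) {
  base <- data.frame(feature_id = character(), chromosome = character(),
                     position = integer(), stringsAsFactors = FALSE)
  if (modality == "gene") {
    base$tss <- integer()
    base$strand <- character()
    base$gene_symbol <- character()
  }
  base
}

#' Write genomic annotations as BED
#'
#' Inverse of [read_bed_annotations()]: point features become `[p, p + 1)`
#' intervals; genes are written with their full footprint when available or
#' a 1-bp interval anchored at the TSS otherwise.
#'
#' @param ann annotation data frame (see [read_bed_annotations()]).
#' @param path output path.
#' @param modality one of `"snp"`, `"cpg"`, `"gene"`.
#' @return `path`, invisibly.
#' @export
write_bed_annotations <- function(ann, path, modality = c("snp", "cpg", "gene")) {
  modality <- match.arg(modality)
  if (modality == "gene") {
    # encode as 1-bp feature at the TSS; start/end chosen so that
    # read_bed_annotations recovers tss exactly on either strand
    start <- ifelse(ann$strand == "+", ann$tss, ann$tss)
    end <- start + 1L
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     ann$chromosome, start, end, ann$feature_id, ann$strand)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s",
                     ann$chromosome, ann$position, ann$position + 1L,
                     ann$feature_id)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' Standard GMT dialect: one term per line; term id, description, then
#' member gene symbols, tab-separated. Members are de-duplicated; terms
#' left without members are dropped with a warning.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: a named list of character member
#'   vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  terms <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2)
      stop(sprintf("line %d: GMT rows need term id and description", i))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning(sprintf("dropping empty gene set '%s' (line %d)", f[1], i))
      next
    }
    if (f[1] %in% names(terms))
      stop(sprintf("line %d: duplicate term id '%s'", i, f[1]))
    terms[[f[1]]] <- members
    descs[f[1]] <- f[2]
  }
  gene_set_collection(terms, descs)
}

#' Construct a gene-set collection
#'
#' @param terms named list of character member vectors (term id -> symbols).
#' @param descriptions optional named character vector of term descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(terms, descriptions = NULL) {
  if (length(terms)) {
    if (is.null(names(terms)) || anyDuplicated(names(terms)))
      stop("term ids must be unique and named")
    if (any(!lengths(terms)))
      stop("gene sets may not be empty")
    terms <- lapply(terms, function(m) unique(as.character(m)))
  }
  if (is.null(descriptions)) descriptions <- stats::setNames(
    rep("", length(terms)), names(terms))
  structure(terms, descriptions = descriptions[names(terms)],
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d terms, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param sets a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i],
            if (is.null(descs)) "" else descs[[i]],
            sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
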