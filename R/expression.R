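#' TPM normalization
#'
#' Transcripts per million: per sample, each gene's count is divided by its
#' length in kb, and the rates are scaled to sum to 10^6. Column sums of the
#' result equal 10^6 by construction.
#'
#' @param counts Genes x samples matrix of non-negative counts.
#' @param length_kb Gene lengths in kb (named or in row order).
#' @return TPM matrix of the same shape.
#' @examples
#' tpm_normalize(matrix(c(10, 10), 2, 1,
#'                      dimnames = list(c("a", "b"), "s1")),
#'               c(a = 1, b = 2))
#' @export
tpm_normalize <- function(counts, length_kb) {
  counts <- as.matrix(counts)
  if (!is.null(names(length_kb)) && !is.null(rownames(counts))) {
    missing <- setdiff(rownames(counts), names(length_kb))
    if (length(missing)) {
      stop("gene lengths missing for: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    length_kb <- length_kb[rownames(counts)]
  }
  stopifnot(length(length_kb) == nrow(counts), all(length_kb > 0),
            all(counts >= 0))
  rate <- counts / length_kb
  cs <- colSums(rate)
  zero <- which(cs == 0)
  if (length(zero)) {
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(rate, 2, cs, "/") * 1e6
}

row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1)
}

#' Select the most-variant genes
#'
#' Genes ranked by variance of `log2(TPM + 1)` across samples; the top `n`
#' are returned, ties broken by gene label order.
#'
#' @param tpm TPM matrix with gene rownames.
#' @param n Number of genes to keep (1000 mirrors the usual
#'   most-variant-gene clustering input).
#' @return Character vector of gene identifiers, highest variance first.
#' @export
top_variant_genes <- function(tpm, n = 1000) {
  stopifnot(!is.null(rownames(tpm)), ncol(tpm) >= 2)
  if (n > nrow(tpm)) {
    warning("n exceeds gene count: returning all ", nrow(tpm), " genes")
    n <- nrow(tpm)
  }
  v <- row_vars(log2(tpm + 1))
  rownames(tpm)[order(-v, rownames(tpm))][seq_len(n)]
}

#' Unsupervised hierarchical clustering of samples
#'
#' Distance is 1 - Pearson correlation between sample columns of
#' `log2(TPM + 1)` (configurable to euclidean), agglomerated with average
#' linkage. `hclust` is deterministic given the input order, so results are
#' reproducible.
#'
#' @param tpm TPM matrix (typically restricted to [top_variant_genes()]).
#' @param k Optional number of clusters to cut into.
#' @param dist_method `"correlation"` or `"euclidean"`.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param log_transform Apply `log2(x + 1)` first.
#' @return list: `hclust`, `labels` (k-cut labels or NULL), `dist`.
#' @export
hierarchical_cluster <- function(tpm, k = NULL,
                                 dist_method = c("correlation",
                                                 "euclidean"),
                                 linkage = "average",
                                 log_transform = TRUE) {
  dist_method <- match.arg(dist_method)
  stopifnot(ncol(tpm) >= 2)
  x <- if (log_transform) log2(as.matrix(tpm) + 1) else as.matrix(tpm)
  if (dist_method == "correlation") {
    sds <- apply(x, 2, sd)
    flat <- which(sds == 0)
    if (length(flat)) {
      stop("zero-variance sample column(s), correlation undefined: ",
           paste(colnames(x)[flat], collapse = ", "))
    }
    d <- as.dist(1 - cor(x))
  } else {
    d <- stats::dist(t(x))
  }
  hc <- hclust(d, method = linkage)
  labels <- if (!is.null(k)) cutree(hc, k = k) else NULL
  list(hclust = hc, labels = labels, dist = d)
}

#' Define a gene signature
#'
#' @param name Signature label.
#' @param genes Unique gene symbols.
#' @param direction Optional +1/-1 per gene (default all +1); -1 genes
#'   contribute with flipped sign (e.g. repressed markers).
#' @return list of class `signature_set`.
#' @export
signature_set <- function(name, genes, direction = NULL) {
  stopifnot(length(genes) >= 1, !anyDuplicated(genes))
  if (is.null(direction)) direction <- rep(1, length(genes))
  stopifnot(length(direction) == length(genes),
            all(direction %in% c(-1, 1)))
  structure(list(name = name, genes = as.character(genes),
                 direction = direction),
            class = "signature_set")
}

#' Read a signature from two-column TSV (gene, direction)
#' @param path File path; the file may omit the direction column.
#' @param name Signature name (default: file name).
#' @return A [signature_set()].
#' @export
read_signature_set <- function(path, name = sub("[.][^.]*$", "",
                                                basename(path))) {
  d <- read.delim(path, header = TRUE)
  stopifnot("gene" %in% names(d))
  dir <- if ("direction" %in% names(d)) d$direction else NULL
  signature_set(name, d$gene, dir)
}

#' Per-sample signature score
#'
#' Each signature gene's `log2(TPM + 1)` is z-scored across samples
#' (zero-variance genes score 0); the sample score is the mean of
#' direction-signed z-scores over the signature genes present. Gene symbols
#' match case-insensitively; missing genes are skipped with a warning.
#'
#' @param tpm TPM matrix with gene rownames.
#' @param signature A [signature_set()].
#' @param log_transform Apply `log2(x + 1)` first.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(tpm, signature, log_transform = TRUE) {
  stopifnot(inherits(signature, "signature_set"), !is.null(rownames(tpm)))
  x <- if (log_transform) log2(as.matrix(tpm) + 1) else as.matrix(tpm)
  idx <- match(toupper(signature$genes), toupper(rownames(x)))
  present <- !is.na(idx)
  if (!any(present)) {
    stop("no gene of signature '", signature$name, "' present in matrix")
  }
  if (any(!present)) {
    warning("signature '", signature$name, "': ", sum(!present),
            " gene(s) absent, skipped: ",
            paste(utils::head(signature$genes[!present], 5),
                  collapse = ", "))
  }
  sub <- x[idx[present], , drop = FALSE]
  m <- rowMeans(sub)
  s <- sqrt(row_vars(sub))
  z <- (sub - m) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  colMeans(signature$direction[present] * z)
}

#' Fold-change contrast between two sample clusters
#'
#' Per-gene log2 fold change of mean `log2(TPM + 1)`, cluster 2 minus
#' cluster 1; genes at or above `log2fc_min` are "up", at or below its
#' negative "down". Fold-change-only by design: with a single-sample
#' cluster no replicate-based test is possible.
#'
#' @param tpm TPM matrix.
#' @param labels Two-level cluster labels, one per sample (the smaller
#'   sorted level is cluster 1).
#' @param log2fc_min Absolute fold-change threshold.
#' @return list: `up`, `down` (gene vectors), `log2fc` (named, cluster 2 -
#'   cluster 1), `n_up`, `n_down`.
#' @export
contrast_clusters <- function(tpm, labels, log2fc_min = 2) {
  stopifnot(length(labels) == ncol(tpm))
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("labels must define exactly two clusters")
  x <- log2(as.matrix(tpm) + 1)
  lfc <- rowMeans(x[, labels == lev[2], drop = FALSE]) -
    rowMeans(x[, labels == lev[1], drop = FALSE])
  up <- rownames(tpm)[lfc >= log2fc_min]
  down <- rownames(tpm)[lfc <= -log2fc_min]
  list(up = up, down = down, log2fc = setNames(lfc, rownames(tpm)),
       n_up = length(up), n_down = length(down))
}
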