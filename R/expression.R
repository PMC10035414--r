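# Expression matrix filtering, clustering, fold-change DEG screening and
# GO-union candidate selection.

#' Filter an abundance matrix and log-normalize
#'
#' A gene is retained iff its abundance is strictly greater than
#' `min_abundance` in at least one treatment.  Normalized values are
#' `log2(x + 1)`.
#'
#' @param mat numeric matrix, genes x treatments, nonnegative.
#' @param min_abundance retention threshold (default 1, the classic
#'   RPKM/FPKM > 1 rule).
#' @return list with `abundance` (filtered), `log2` (filtered,
#'   normalized) and `dropped` (gene names failing the filter).
#' @export
filter_and_normalize <- function(mat, min_abundance = 1) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (any(mat < 0)) stop("abundance values must be nonnegative",
                         call. = FALSE)
  keep <- apply(mat, 1, function(x) any(x > min_abundance))
  list(abundance = mat[keep, , drop = FALSE],
       log2 = log2(mat[keep, , drop = FALSE] + 1),
       dropped = rownames(mat)[!keep])
}

#' Cluster expression profiles
#'
#' Rows are z-scored per gene (zero-variance rows get all-zero scores),
#' then clustered by agglomerative hierarchical clustering (average
#' linkage, Euclidean distance by default) and the tree is cut into
#' exactly `k` clusters, labeled `A1..Ak` in order of first appearance
#' along the dendrogram.
#'
#' @param log2mat normalized matrix (genes x treatments).
#' @param k number of clusters.
#' @param linkage linkage criterion for [stats::hclust()].
#' @param metric distance metric for [stats::dist()].
#' @return list with `clusters` (named vector gene -> `"A<i>"`) and
#'   `tree` (the `hclust` object).
#' @export
cluster_expression <- function(log2mat, k = 8, linkage = "average",
                               metric = "euclidean") {
  if (!is.matrix(log2mat)) log2mat <- as.matrix(log2mat)
  if (nrow(log2mat) < k) {
    stop("fewer genes (", nrow(log2mat), ") than clusters (", k, ")",
         call. = FALSE)
  }
  z <- t(apply(log2mat, 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  tree <- stats::hclust(stats::dist(z, method = metric), method = linkage)
  cut <- stats::cutree(tree, k = k)
  # stable labels: number clusters by first gene occurrence in input order
  first <- vapply(seq_len(k), function(c) min(which(cut == c)), integer(1))
  relab <- rank(first)[cut]
  clusters <- stats::setNames(paste0("A", relab), rownames(log2mat))
  list(clusters = clusters, tree = tree)
}

#' Screen differentially expressed genes by fold change
#'
#' For each gene and non-control treatment the fold change is
#' `(t + eps) / (ck + eps)`.  A gene is a DEG iff the maximum absolute
#' log2 fold change over treatments reaches `log2(fc_threshold)`; the
#' direction is the sign at the maximizing treatment.
#'
#' @param mat filtered abundance matrix (genes x treatments).
#' @param control control column label (calibrator), e.g. `"CK"`.
#' @param fc_threshold fold-change threshold (default 3).
#' @param eps pseudo-count added to numerator and denominator.
#' @return data.frame: `gene`, per-treatment `log2fc_<t>` columns,
#'   `max_abs_log2fc`, `direction` (`up`/`down`), `is_deg`.
#' @export
screen_degs <- function(mat, control = "CK", fc_threshold = 3,
                        eps = 0.01) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (!control %in% colnames(mat)) {
    stop("control column '", control, "' not present", call. = FALSE)
  }
  other <- setdiff(colnames(mat), control)
  lfc <- sapply(other, function(t) {
    log2((mat[, t] + eps) / (mat[, control] + eps))
  })
  if (is.null(dim(lfc))) lfc <- matrix(lfc, nrow = nrow(mat),
                                       dimnames = list(rownames(mat), other))
  imax <- apply(abs(lfc), 1, which.max)
  maxabs <- abs(lfc)[cbind(seq_len(nrow(lfc)), imax)]
  dir <- ifelse(lfc[cbind(seq_len(nrow(lfc)), imax)] >= 0, "up", "down")
  out <- data.frame(gene = rownames(mat), stringsAsFactors = FALSE)
  for (t in other) out[[paste0("log2fc_", t)]] <- lfc[, t]
  out$max_abs_log2fc <- maxabs
  out$direction <- dir
  out$is_deg <- maxabs >= log2(fc_threshold)
  rownames(out) <- NULL
  out
}

#' Select salt-stress candidates as the DEG/GO union
#'
#' Candidates are the union of the screened DEG genes and the genes
#' annotated with any of the given GO terms; the provenance records
#' whether a candidate came from the expression screen, the GO
#' annotation, or both.
#'
#' @param degs [screen_degs()] result (or character vector of DEG genes).
#' @param go_table data.frame with columns `gene` and `term_name` (and
#'   optionally `term_id`); terms are matched against `salt_terms` by
#'   name or id.
#' @param salt_terms term names/ids marking salt response (default
#'   `"response to salt stress"`).
#' @return data.frame `gene`, `provenance` in `expression`/`GO`/`both`,
#'   sorted by gene.
#' @export
select_candidates <- function(degs, go_table,
                              salt_terms = "response to salt stress") {
  if (!length(salt_terms)) stop("salt_terms is empty", call. = FALSE)
  deg_genes <- if (is.data.frame(degs)) degs$gene[degs$is_deg] else degs
  go_genes <- character(0)
  if (!is.null(go_table) && nrow(go_table)) {
    hit <- go_table$term_name %in% salt_terms
    if (!is.null(go_table$term_id)) {
      hit <- hit | go_table$term_id %in% salt_terms
    }
    go_genes <- unique(go_table$gene[hit])
  }
  genes <- union(deg_genes, go_genes)
  prov <- ifelse(genes %in% deg_genes & genes %in% go_genes, "both",
                 ifelse(genes %in% deg_genes, "expression", "GO"))
  out <- data.frame(gene = genes, provenance = prov,
                    stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE]
}
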