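# Distance-based phylogeny: p-distances on the model-frame alignment,
# neighbor joining, bootstrap support and subfamily assignment.

#' Pairwise p-distances on a model-frame alignment
#'
#' `d(i,j)` is the proportion of mismatches over columns where neither
#' row is gapped (pairwise deletion).  A pair with no comparable column
#' is an error.
#'
#' @param alignment named character vector of equal-length aligned rows.
#' @return symmetric matrix with zero diagonal, dimnames = row names.
#' @export
pairwise_pdistance <- function(alignment) {
  alignment <- as_named_character(alignment)
  n <- length(alignment)
  if (n < 2) stop("need at least 2 rows", call. = FALSE)
  mat <- do.call(rbind, strsplit(alignment, ""))
  gap <- mat == "-"
  D <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- !gap[i, ] & !gap[j, ]
      nc <- sum(comp)
      if (nc == 0) {
        stop("rows ", names(alignment)[i], " and ", names(alignment)[j],
             " share no comparable columns", call. = FALSE)
      }
      d <- sum(mat[i, comp] != mat[j, comp]) / nc
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on the Q-criterion.  Ties in Q are
#' broken by the lexicographically smallest joined name pair (internal
#' nodes carry synthetic names), making the result deterministic.
#' Negative branch-length estimates are clamped to zero with a warning.
#' On an additive matrix the tree's path-length metric reproduces the
#' input distances exactly.
#'
#' @param D symmetric distance matrix with dimnames.
#' @return an [ape::read.tree()] `phylo` object (unrooted, trifurcating
#'   at the root node).
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("D must be a square matrix", call. = FALSE)
  }
  n0 <- nrow(D)
  if (n0 < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  labels <- rownames(D) %||% paste0("t", seq_len(n0))
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) clamped <<- TRUE
    sprintf("%.12g", max(0, x))
  }
  nodes <- as.list(labels)          # newick fragment per active node
  names(nodes) <- labels
  act <- labels                     # active node names (tie-break keys)
  M <- D
  dimnames(M) <- list(act, act)
  counter <- 0L

  while (length(act) > 3) {
    n <- length(act)
    r <- rowSums(M)
    Q <- (n - 2) * M - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12 & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1) {
      keys <- apply(cand, 1, function(ij) {
        paste(stri_sort_c(c(act[ij[1]], act[ij[2]])), collapse = "\r")
      })
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    dij <- M[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- dij - bi
    counter <- counter + 1L
    newname <- sprintf("node%06d", counter)
    frag <- paste0("(", nodes[[act[i]]], ":", bl(bi), ",",
                   nodes[[act[j]]], ":", bl(bj), ")")
    dk <- (M[i, ] + M[j, ] - dij) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    M2 <- rbind(cbind(M[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    act <- c(act[keep], newname)
    dimnames(M2) <- list(act, act)
    M <- M2
    nodes[[newname]] <- frag
  }

  d12 <- M[1, 2]; d13 <- M[1, 3]; d23 <- M[2, 3]
  b1 <- (d12 + d13 - d23) / 2
  b2 <- (d12 + d23 - d13) / 2
  b3 <- (d13 + d23 - d12) / 2
  newick <- paste0("(", nodes[[act[1]]], ":", bl(b1), ",",
                   nodes[[act[2]]], ":", bl(b2), ",",
                   nodes[[act[3]]], ":", bl(b3), ");")
  if (clamped) {
    warning("negative branch length estimate(s) clamped to zero")
  }
  ape::read.tree(text = newick)
}

# Canonical bipartition keys of the internal edges of an unrooted tree.
# Each internal (non-root) node's subtree defines a split; the side not
# containing the alphabetically first taxon is used as the key.
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  anchor <- stri_sort_c(tree$tip.label)[1]
  parts <- ape::prop.part(tree)
  root <- ntip + 1L
  out <- character(0)
  nodes <- integer(0)
  for (k in seq_along(parts)) {
    node <- ntip + k
    if (node == root) next
    tips <- tree$tip.label[parts[[k]]]
    if (anchor %in% tips) tips <- setdiff(tree$tip.label, tips)
    if (length(tips) < 2 || length(tips) > ntip - 2) next  # trivial split
    out <- c(out, paste(stri_sort_c(tips), collapse = "\r"))
    nodes <- c(nodes, node)
  }
  stats::setNames(out, nodes)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Alignment columns are resampled with replacement `n_reps` times; the
#' support of each internal bipartition of the full-data tree is the
#' percentage of replicate trees containing it.  Supports are stored in
#' `node.label` (empty for the root and for tips).
#'
#' @param alignment named character vector of model-frame rows.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed making the resampling reproducible.
#' @return `phylo` object with `node.label` supports in `[0, 100]`.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000, seed = 1) {
  alignment <- as_named_character(alignment)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  tree <- neighbor_joining(pairwise_pdistance(alignment))
  bip <- tree_bipartitions(tree)
  counts <- stats::setNames(rep(0, length(bip)), bip)
  mat <- do.call(rbind, strsplit(alignment, ""))
  w <- ncol(mat)
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(w, w, replace = TRUE)
    rep_aln <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    names(rep_aln) <- names(alignment)
    rt <- try(neighbor_joining(pairwise_pdistance(rep_aln)), silent = TRUE)
    if (inherits(rt, "try-error")) next
    rb <- tree_bipartitions(rt)
    hit <- bip %in% rb
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / n_reps, 1)
  labs <- rep("", tree$Nnode)
  node_ids <- as.integer(names(bip))
  labs[node_ids - length(tree$tip.label)] <- as.character(support)
  tree$node.label <- labs
  tree
}

#' Assign subfamily labels from labeled references
#'
#' The default `"nearest"` method gives every member the label of its
#' closest reference row by p-distance (ties across different labels ->
#' `"unplaced"`).  The `"clade"` method builds a joint NJ tree and uses
#' the majority label of the smallest clade containing at least one
#' reference (majority ties -> `"unplaced"`).
#'
#' @param member_alignment named model-frame rows of the members.
#' @param ref_alignment named model-frame rows of the references.
#' @param ref_labels named character vector: reference -> subfamily.
#' @param method `"nearest"` or `"clade"`.
#' @return data.frame with `member` and `subfamily`.
#' @export
assign_subfamily <- function(member_alignment, ref_alignment, ref_labels,
                             method = c("nearest", "clade")) {
  method <- match.arg(method)
  member_alignment <- as_named_character(member_alignment)
  ref_alignment <- as_named_character(ref_alignment)
  if (!length(ref_alignment)) stop("no labeled references", call. = FALSE)
  if (is.null(names(ref_labels))) {
    stop("ref_labels must be named by reference id", call. = FALSE)
  }
  miss <- setdiff(names(ref_alignment), names(ref_labels))
  if (length(miss)) stop("references without label: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (method == "nearest") {
    D <- pairwise_pdistance(c(member_alignment, ref_alignment))
    cross <- D[names(member_alignment), names(ref_alignment), drop = FALSE]
    lab <- apply(cross, 1, function(d) {
      best <- names(d)[d - min(d) < 1e-12]
      labs <- unique(unname(ref_labels[best]))
      if (length(labs) == 1) labs else "unplaced"
    })
  } else {
    D <- pairwise_pdistance(c(member_alignment, ref_alignment))
    tree <- neighbor_joining(D)
    lab <- vapply(names(member_alignment), function(m) {
      clade_majority_label(tree, m, ref_labels)
    }, character(1))
  }
  data.frame(member = names(member_alignment),
             subfamily = unname(lab),
             stringsAsFactors = FALSE, row.names = NULL)
}

clade_majority_label <- function(tree, member, ref_labels) {
  ntip <- length(tree$tip.label)
  tip <- match(member, tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  node <- tip
  repeat {
    node <- parent[node]
    if (node == 0) return("unplaced")
    tips <- tree$tip.label[tips_below(tree, node)]
    refs <- intersect(tips, names(ref_labels))
    if (length(refs)) {
      tab <- sort(table(unname(ref_labels[refs])), decreasing = TRUE)
      if (length(tab) > 1 && tab[1] == tab[2]) return("unplaced")
      return(names(tab)[1])
    }
  }
}

tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}
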