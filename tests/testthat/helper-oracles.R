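# Independent oracles used by the property and acceptance tests.

# ---- random additive trees and exhaustive NJ oracle ------------------

# random unrooted binary tree with n leaves; returns an edge list
# (parent, child, length) over node ids; leaves are "t1".."tn"
random_additive_tree <- function(n, bl_range = c(0.1, 1)) {
  stopifnot(n >= 3)
  # adjacency with edge lengths; start from star on 3 leaves
  nodes <- c("t1", "t2", "t3", "i1")
  edges <- data.frame(a = c("i1", "i1", "i1"), b = c("t1", "t2", "t3"),
                      len = stats::runif(3, bl_range[1], bl_range[2]),
                      stringsAsFactors = FALSE)
  n_int <- 1
  for (k in 4:n) {
    if (k > n) break
    e <- sample.int(nrow(edges), 1)
    n_int <- n_int + 1
    mid <- paste0("i", n_int)
    leaf <- paste0("t", k)
    old <- edges[e, ]
    split_at <- stats::runif(1, 0.2, 0.8)
    edges <- edges[-e, ]
    edges <- rbind(edges,
                   data.frame(a = old$a, b = mid,
                              len = old$len * split_at,
                              stringsAsFactors = FALSE),
                   data.frame(a = mid, b = old$b,
                              len = old$len * (1 - split_at),
                              stringsAsFactors = FALSE),
                   data.frame(a = mid, b = leaf,
                              len = stats::runif(1, bl_range[1],
                                                 bl_range[2]),
                              stringsAsFactors = FALSE))
  }
  edges
}

# leaf-to-leaf path distances of an edge list
tree_path_distances <- function(edges) {
  nodes <- unique(c(edges$a, edges$b))
  adj <- lapply(stats::setNames(nodes, nodes), function(x) NULL)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$a[i]]] <- rbind(adj[[edges$a[i]]],
                               data.frame(to = edges$b[i],
                                          len = edges$len[i]))
    adj[[edges$b[i]]] <- rbind(adj[[edges$b[i]]],
                               data.frame(to = edges$a[i],
                                          len = edges$len[i]))
  }
  leaves <- grep("^t", nodes, value = TRUE)
  leaves <- leaves[order(as.integer(sub("t", "", leaves)))]
  D <- matrix(0, length(leaves), length(leaves),
              dimnames = list(leaves, leaves))
  for (L in leaves) {
    # BFS with accumulated distances
    dist <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
    dist[L] <- 0
    queue <- L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      for (i in seq_len(NROW(nb))) {
        w <- nb$to[i]
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + nb$len[i]
          queue <- c(queue, w)
        }
      }
    }
    D[L, leaves] <- dist[leaves]
  }
  D
}

# all unrooted binary topologies on the given taxa (as edge lists
# without lengths), built by stepwise addition
all_topologies <- function(taxa) {
  n <- length(taxa)
  base <- data.frame(a = c("i1", "i1", "i1"),
                     b = taxa[1:3], stringsAsFactors = FALSE)
  tops <- list(base)
  if (n == 3) return(tops)
  for (k in 4:n) {
    new_tops <- list()
    for (tp in tops) {
      n_int <- sum(grepl("^i", unique(c(tp$a, tp$b))))
      for (e in seq_len(nrow(tp))) {
        mid <- paste0("i", n_int + 1)
        nt <- tp[-e, , drop = FALSE]
        nt <- rbind(nt,
                    data.frame(a = tp$a[e], b = mid,
                               stringsAsFactors = FALSE),
                    data.frame(a = mid, b = tp$b[e],
                               stringsAsFactors = FALSE),
                    data.frame(a = mid, b = taxa[k],
                               stringsAsFactors = FALSE))
        new_tops[[length(new_tops) + 1]] <- nt
      }
    }
    tops <- new_tops
  }
  tops
}

# least-squares branch lengths of a topology for distance matrix D;
# returns residual sum of squares
topology_lsq_rss <- function(top, D) {
  taxa <- rownames(D)
  edge_id <- paste(top$a, top$b)
  # path indicator matrix over leaf pairs
  pairs <- utils::combn(taxa, 2)
  A <- matrix(0, ncol(pairs), nrow(top))
  d <- numeric(ncol(pairs))
  # adjacency for path finding
  nodes <- unique(c(top$a, top$b))
  for (p in seq_len(ncol(pairs))) {
    path <- find_path(top, pairs[1, p], pairs[2, p])
    A[p, path] <- 1
    d[p] <- D[pairs[1, p], pairs[2, p]]
  }
  fit <- stats::lm.fit(A, d)
  sum(fit$residuals^2)
}

# edge indices on the path between two nodes (tree as edge list)
find_path <- function(top, from, to) {
  nodes <- unique(c(top$a, top$b))
  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  pedge <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  queue <- from; visited[from] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    inc <- which(top$a == v | top$b == v)
    for (e in inc) {
      w <- if (top$a[e] == v) top$b[e] else top$a[e]
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v
        pedge[w] <- e
        queue <- c(queue, w)
      }
    }
  }
  path <- integer(0)
  v <- to
  while (!is.na(parent[v])) {
    path <- c(path, pedge[v])
    v <- parent[v]
  }
  path
}

# bipartition keys of a topology (edge list form)
topology_bipartitions <- function(top, taxa) {
  anchor <- sort(taxa)[1]
  keys <- character(0)
  for (e in seq_len(nrow(top))) {
    if (!grepl("^i", top$a[e]) || !grepl("^i", top$b[e])) next
    sub <- top[-e, , drop = FALSE]
    side <- reachable(sub, top$b[e])
    tips <- intersect(side, taxa)
    if (anchor %in% tips) tips <- setdiff(taxa, tips)
    if (length(tips) < 2 || length(tips) > length(taxa) - 2) next
    keys <- c(keys, paste(sort(tips), collapse = "\r"))
  }
  sort(keys)
}

reachable <- function(top, from) {
  seen <- from
  repeat {
    inc <- top$a %in% seen | top$b %in% seen
    nxt <- union(top$a[inc], top$b[inc])
    if (all(nxt %in% seen)) return(seen)
    seen <- union(seen, nxt)
  }
}

# bipartition keys of an ape phylo, matching topology_bipartitions
phylo_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (k in seq_along(parts)) {
    node <- ntip + k
    if (node == ntip + 1) next
    tips <- tree$tip.label[parts[[k]]]
    if (anchor %in% tips) tips <- setdiff(tree$tip.label, tips)
    if (length(tips) < 2 || length(tips) > ntip - 2) next
    keys <- c(keys, paste(sort(tips), collapse = "\r"))
  }
  sort(keys)
}

# ---- Duncan letters oracle -------------------------------------------

# brute force: pairwise significance straight from the span definition,
# then letters as maximal non-significant intervals
duncan_oracle_letters <- function(means, n, mse, df, alpha = 0.05) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  n_h <- k / sum(1 / rep(n, length.out = k))
  rng <- function(p) {
    stats::qtukey((1 - alpha)^(p - 1), nmeans = p, df = df) *
      sqrt(mse / n_h)
  }
  # span (a, b) is non-significant iff its gap is within R_(b-a+1)
  span_ns <- matrix(FALSE, k, k)
  for (a in seq_len(k)) for (b in a:k) {
    span_ns[a, b] <- if (b == a) TRUE else
      (m[a] - m[b]) <= rng(b - a + 1)
  }
  # pair (i, j) differs iff NO enclosing span is non-significant
  pair_ns <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    covered <- FALSE
    for (a in seq_len(i)) for (b in j:k) {
      if (span_ns[a, b]) covered <- TRUE
    }
    pair_ns[i, j] <- pair_ns[j, i] <- covered
  }
  diag(pair_ns) <- TRUE
  # letters: maximal intervals of pairwise non-significance
  ivs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && pair_ns[i, j + 1]) j <- j + 1
    ivs[[i]] <- c(i, j)
  }
  keep <- vapply(seq_along(ivs), function(s) {
    !any(vapply(seq_along(ivs), function(t) {
      t != s && ivs[[t]][1] <= ivs[[s]][1] && ivs[[t]][2] >= ivs[[s]][2]
    }, logical(1)))
  }, logical(1))
  ivs <- unique(ivs[keep])
  ivs <- ivs[order(vapply(ivs, `[`, numeric(1), 1))]
  out <- rep("", k)
  for (s in seq_along(ivs)) {
    r <- ivs[[s]][1]:ivs[[s]][2]
    out[r] <- paste0(out[r], letters[s])
  }
  stats::setNames(out, names(m))
}

# ---- adjusted Rand index ---------------------------------------------

adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  maxi <- (b + c) / 2
  (a - expected) / (maxi - expected)
}
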