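# p-distances, neighbor joining (with exhaustive oracle), bootstrap and
# subfamily assignment.

test_that("p-distance: pairwise deletion, symmetry, errors", {
  aln <- c(a = "ACDE", b = "ACDE", c = "ACDF")
  D <- pairwise_pdistance(aln)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.25)
  expect_equal(D, t(D))

  # gap columns excluded pairwise
  aln <- c(a = "AC-E", b = "ACDE")
  expect_equal(pairwise_pdistance(aln)["a", "b"], 0)
  # no comparable columns
  expect_error(pairwise_pdistance(c(a = "--AA", b = "AA--")),
               "comparable")
  expect_error(pairwise_pdistance(c(a = "AAAA")), "at least 2")

  set.seed(31)
  rows <- random_rows(12, 30)
  names(rows) <- paste0("r", 1:12)
  D <- pairwise_pdistance(rows)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("3-taxon NJ has the closed-form star lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co[rownames(D), colnames(D)], D, tolerance = 1e-12)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers random additive matrices (enumeration oracle)", {
  set.seed(32)
  for (rep in 1:30) {
    n <- sample(4:6, 1)
    edges <- random_additive_tree(n)
    D <- tree_path_distances(edges)
    tr <- neighbor_joining(D)
    co <- ape::cophenetic.phylo(tr)
    expect_lt(max(abs(co[rownames(D), colnames(D)] - D)), 1e-9)

    # exhaustive oracle: best least-squares topology
    taxa <- rownames(D)
    tops <- all_topologies(taxa)
    rss <- vapply(tops, topology_lsq_rss, numeric(1), D = D)
    best <- tops[[which.min(rss)]]
    expect_lt(min(rss), 1e-18)
    expect_identical(phylo_bipartitions(tr),
                     topology_bipartitions(best, taxa))
  }
})

test_that("bipartitions are invariant to leaf order", {
  set.seed(33)
  edges <- random_additive_tree(6)
  D <- tree_path_distances(edges)
  perm <- sample(rownames(D))
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D[perm, perm])
  expect_identical(phylo_bipartitions(t1), phylo_bipartitions(t2))
})

test_that("bootstrap supports behave", {
  # two clearly separated 4-leaf clades
  blockA <- strrep("A", 40)
  blockC <- strrep("C", 40)
  set.seed(34)
  jitter <- function(s) {
    v <- strsplit(s, "")[[1]]
    i <- sample(40, 3)
    v[i] <- sample(setdiff(famscan:::AA20, v[i[1]]), 3, replace = TRUE)
    paste(v, collapse = "")
  }
  aln <- c(a1 = jitter(blockA), a2 = jitter(blockA), a3 = jitter(blockA),
           a4 = jitter(blockA), c1 = jitter(blockC), c2 = jitter(blockC),
           c3 = jitter(blockC), c4 = jitter(blockC))
  tr <- bootstrap_support(aln, n_reps = 100, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # the central split is saturated
  expect_true(any(sup == 100))

  # n_reps = 1: supports are 0 or 100
  tr1 <- bootstrap_support(aln, n_reps = 1, seed = 9)
  s1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))

  # determinism
  tr2 <- bootstrap_support(aln, n_reps = 25, seed = 42)
  tr3 <- bootstrap_support(aln, n_reps = 25, seed = 42)
  expect_identical(ape::write.tree(tr2), ape::write.tree(tr3))
})

test_that("subfamily assignment: nearest reference and ties", {
  refs <- c(R1 = strrep("A", 80), R2 = strrep("C", 80))
  labels <- c(R1 = "VIIIb", R2 = "XII")
  # member identical to R1
  m <- c(m1 = strrep("A", 80))
  out <- assign_subfamily(m, refs, labels)
  expect_equal(out$subfamily, "VIIIb")
  # exactly equidistant to two different labels
  half <- paste0(strrep("A", 40), strrep("C", 40))
  out <- assign_subfamily(c(mx = half), refs, labels)
  expect_equal(out$subfamily, "unplaced")
  expect_error(assign_subfamily(m, refs, c(R1 = "x")), "without label")
})

test_that("cp159 subfamily labels are fully recovered", {
  w <- cp159_world()
  out <- assign_subfamily(w$aln, w$fx$references,
                          w$fx$reference_labels)
  truth <- w$truth$subfamily[match(out$member, w$truth$name)]
  expect_equal(out$subfamily, truth)
})
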