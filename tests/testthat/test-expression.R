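# Expression filtering, clustering, DEG screening, candidate union.

test_that("filter keeps genes above threshold in >= 1 treatment", {
  m <- rbind(low = c(0.5, 0.5, 0.5, 0.5),
             one = c(0.2, 1.5, 0.3, 0.1),
             hi = c(3, 3, 3, 3),
             border = c(1, 1, 1, 1))
  colnames(m) <- c("CK", "LS", "MS", "HS")
  fn <- filter_and_normalize(m)
  expect_setequal(rownames(fn$abundance), c("one", "hi"))
  expect_setequal(fn$dropped, c("low", "border"))   # strict >
  expect_equal(fn$log2["hi", "CK"], 2)              # log2(3 + 1)
  expect_error(filter_and_normalize(-m), "nonnegative")

  # raising the threshold never increases the retained count
  set.seed(51)
  m2 <- matrix(stats::rexp(400, 0.3), 100, 4,
               dimnames = list(paste0("g", 1:100),
                               c("CK", "LS", "MS", "HS")))
  ns <- vapply(c(0.5, 1, 2, 4, 8), function(t) {
    nrow(filter_and_normalize(m2, t)$abundance)
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("clustering recovers planted groups and is order-invariant", {
  set.seed(52)
  shapes <- rbind(c(0, 2, 0, 0), c(0, 0, 2, 0), c(0, 0, 0, 2),
                  c(0, -2, -2, 0))
  truth <- rep(1:4, each = 10)
  m <- t(vapply(truth, function(k) 5 + shapes[k, ], numeric(4)))
  rownames(m) <- paste0("g", 1:40)
  colnames(m) <- c("CK", "LS", "MS", "HS")
  cl <- cluster_expression(m, k = 4)
  expect_equal(adjusted_rand_index(cl$clusters, truth), 1)

  # identical rows share a cluster
  expect_equal(length(unique(cl$clusters[truth == 2])), 1L)

  perm <- sample(rownames(m))
  cl2 <- cluster_expression(m[perm, ], k = 4)
  agree <- adjusted_rand_index(cl2$clusters[rownames(m)], cl$clusters)
  expect_equal(agree, 1)

  expect_error(cluster_expression(m[1:3, ], k = 4), "fewer genes")
})

test_that("DEG screen: fold-change rule with pseudo-count", {
  m <- rbind(flat = c(9, 9, 9, 9),
             down3 = c(9, 2.9, 9, 9),
             up4 = c(2, 8.1, 2, 2),
             down9 = c(9, 9, 9, 1))
  colnames(m) <- c("CK", "LS", "MS", "HS")
  degs <- screen_degs(m, control = "CK", fc_threshold = 3)
  expect_false(degs$is_deg[degs$gene == "flat"])
  expect_true(degs$is_deg[degs$gene == "down3"])
  expect_equal(degs$direction[degs$gene == "down3"], "down")
  expect_true(degs$is_deg[degs$gene == "up4"])
  expect_equal(degs$direction[degs$gene == "up4"], "up")
  d9 <- degs[degs$gene == "down9", ]
  expect_equal(d9$max_abs_log2fc, abs(log2((1 + 0.01) / (9 + 0.01))))

  # the pseudo-count makes a CK=9 vs T=3 contrast a 2.993-fold change:
  # marginally below a strict 3-fold rule (documented behavior)
  m2 <- rbind(g = c(9, 3, 9, 9)); colnames(m2) <- colnames(m)
  d <- screen_degs(m2, "CK", fc_threshold = 3)
  expect_equal(2^d$max_abs_log2fc, 3.0, tolerance = 0.01)
  expect_false(d$is_deg)
  expect_true(screen_degs(m2, "CK", fc_threshold = 2.99)$is_deg)

  expect_error(screen_degs(m, control = "XX"), "control")
})

test_that("candidate union and provenance", {
  degs <- data.frame(gene = c("a", "b", "c"), is_deg = c(TRUE, TRUE,
                                                         FALSE))
  go <- data.frame(gene = c("b", "d"),
                   term_name = "response to salt stress")
  out <- select_candidates(degs, go)
  expect_setequal(out$gene, c("a", "b", "d"))
  expect_equal(out$provenance[out$gene == "b"], "both")
  expect_equal(out$provenance[out$gene == "a"], "expression")
  expect_equal(out$provenance[out$gene == "d"], "GO")

  # empty GO table: candidates = DEG set
  out2 <- select_candidates(degs, go[0, ])
  expect_setequal(out2$gene, c("a", "b"))

  # disjoint sets: sizes add
  go3 <- data.frame(gene = c("x", "y"),
                    term_name = "response to salt stress")
  expect_equal(nrow(select_candidates(degs, go3)), 4L)
  expect_error(select_candidates(degs, go, salt_terms = character(0)),
               "empty")
})

test_that("union bounds hold on random inputs", {
  set.seed(53)
  for (i in 1:20) {
    degs <- paste0("g", sample(100, sample(0:20, 1)))
    gos <- paste0("g", sample(100, sample(0:20, 1)))
    go_tab <- data.frame(gene = gos,
                         term_name = "response to salt stress")
    out <- select_candidates(degs, go_tab)
    expect_gte(nrow(out), length(degs))
    expect_lte(nrow(out), length(degs) + length(gos))
  }
})

test_that("cp159 expression screen recovers the planted design", {
  w <- cp159_world()
  mat <- w$fx$expression
  fn <- filter_and_normalize(mat)
  expect_equal(nrow(fn$abundance), 155L)
  tr <- w$truth
  dropped_ranks <- sort(tr$rank[match(fn$dropped, tr$gene_id)])
  expect_equal(dropped_ranks, c(119L, 121L, 138L, 151L))

  degs <- screen_degs(fn$abundance, control = "CK", fc_threshold = 3)
  deg_ranks <- sort(tr$rank[match(degs$gene[degs$is_deg], tr$gene_id)])
  expect_equal(deg_ranks, c(36L, 68L, 69L, 71L, 74L, 75L, 108L, 146L,
                            152L, 158L))
  # the 9-fold-down gene
  g74 <- degs[degs$gene == tr$gene_id[tr$rank == 74 &
                                        !is.na(tr$rank)], ]
  expect_equal(2^g74$max_abs_log2fc, 9, tolerance = 0.35)
  expect_equal(g74$direction, "down")

  # candidates: DEG union GO = 12, overlap flagged "both"
  cand <- select_candidates(degs, w$fx$go_table)
  expect_equal(nrow(cand), 12L)
  cand_ranks <- sort(tr$rank[match(cand$gene, tr$gene_id)])
  expect_equal(cand_ranks, c(36L, 38L, 68L, 69L, 71L, 74L, 75L, 108L,
                             109L, 146L, 152L, 158L))
  both <- cand$gene[cand$provenance == "both"]
  expect_equal(tr$rank[match(both, tr$gene_id)], 68L)
})
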