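# Family validation: dedup rules, naming and physicochemical records.

fake_hit <- function(id, covered = 79, score = 100, start = 10) {
  data.frame(protein_id = id, start = start, end = start + covered,
             score = score, covered = covered,
             alignment = I(list(cbind(model_col = seq_len(covered),
                                      seq_pos = start + seq_len(covered)))),
             stringsAsFactors = FALSE)
}

test_that("filter_and_dedup applies coverage and identity rules", {
  seqs <- c(a = strrep("ACDEF", 20), b = strrep("ACDEF", 20),
            c = strrep("GHIKL", 20))
  hits <- rbind(fake_hit("a"), fake_hit("b"), fake_hit("c", covered = 50))
  out <- filter_and_dedup(hits, seqs)
  # identical sequences "a"/"b": lexicographically smallest id kept;
  # 50/79-column hit dropped
  expect_identical(out$protein_id, "a")
  expect_equal(out$n_collapsed, 2L)

  # idempotent
  out2 <- filter_and_dedup(out, seqs)
  expect_identical(out2$protein_id, out$protein_id)

  # inserting an exact copy never changes the retained set size
  seqs2 <- c(seqs, zz = unname(seqs[["a"]]))
  hits2 <- rbind(hits, fake_hit("zz"))
  expect_equal(nrow(filter_and_dedup(hits2, seqs2)), nrow(out))
})

test_that("gene names follow natural chromosome order and start", {
  gm <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    chromosome = c("chr1", "chr1", "chr2", "chr10"),
    strand = "+", start = c(100L, 50L, 10L, 5L), end = 1000L,
    stringsAsFactors = FALSE)
  members <- rbind(fake_hit("g1_P"), fake_hit("g2_P"), fake_hit("g3_P"),
                   fake_hit("g4_P"))
  out <- assign_gene_names(members, gm, prefix = "X")
  expect_identical(out$gene_id, c("g2", "g1", "g3", "g4"))
  expect_identical(out$name, paste0("X", 1:4))
  # chr2 precedes chr10 despite string order
  expect_lt(which(out$gene_id == "g3"), which(out$gene_id == "g4"))

  # permuting input order leaves names unchanged
  out2 <- assign_gene_names(members[c(3, 1, 4, 2), ], gm, prefix = "X")
  expect_identical(out2$name[match(out$protein_id, out2$protein_id)],
                   out$name)

  # member without gene model
  expect_error(assign_gene_names(fake_hit("nope_P"), gm, "X"), "nope")
})

test_that("physicochemical records match hand calculations", {
  g <- compute_physchem("G")
  expect_equal(g$mw, 57.0519 + 18.01524, tolerance = 1e-6)
  gg <- compute_physchem("GG")
  expect_equal(gg$mw, 2 * 57.0519 + 18.01524, tolerance = 1e-6)
  expect_equal(gg$length, 2)

  polyk <- compute_physchem(strrep("K", 20))
  expect_gt(polyk$pi, 9)
  polyd <- compute_physchem(strrep("D", 20))
  expect_lt(polyd$pi, 5)
  expect_true(polyk$pi < 14 && polyd$pi > 0)
  expect_error(compute_physchem(""), "empty")
})

test_that("cp159: 159 named members with complete domains", {
  w <- cp159_world()
  expect_equal(length(w$fx$proteins), 174L)
  expect_equal(nrow(w$members), 159L)
  expect_identical(w$members$name, paste0("CpbHLH", 1:159))
  # assigned rank equals the generator's chromosomal-order rank
  expect_equal(w$truth$rank[match(w$members$gene_id, w$truth$gene_id)],
               1:159)
  # every retained hit covers a complete domain
  expect_true(all(w$members$covered >= 70))
  # physicochemical invariants
  expect_true(all(w$members$mw > 0))
  expect_true(all(w$members$pi > 0 & w$members$pi < 14))
})
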