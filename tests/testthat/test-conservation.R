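# Consensus profiling and DNA-binding classification.

test_that("align_to_model projects hits onto model columns", {
  protein <- paste(rep("K", 100), collapse = "")
  # ungapped full-length hit
  full <- list(alignment = cbind(model_col = 1:79, seq_pos = 11:89))
  expect_identical(align_to_model(full, protein),
                   paste(rep("K", 79), collapse = ""))
  # deletion of model columns 40-42
  del <- list(alignment = cbind(model_col = c(1:39, 43:79),
                                seq_pos = 11:86))
  row <- align_to_model(del, protein)
  expect_identical(substr(row, 40, 42), "---")
  expect_equal(nchar(row), 79)
})

test_that("consensus ratios, tie-breaks and strict thresholds", {
  # four identical rows: ratio 1, extremely conserved everywhere
  rows <- rep(paste(rep("E", 79), collapse = ""), 4)
  cons <- build_consensus(rows)
  expect_true(all(cons$ratio == 1))
  expect_true(all(cons$extremely))

  # 80 'R' of 159 rows at column 1: highly but not extremely
  col1 <- c(rep("R", 80), rep("K", 79))
  rows <- vapply(col1, function(r) {
    paste(c(r, rep("A", 78)), collapse = "")
  }, character(1))
  cons <- build_consensus(rows)
  expect_equal(cons$ratio[1], 80 / 159)
  expect_true(cons$highly[1])
  expect_false(cons$extremely[1])

  # exactly 50%: NOT highly conserved (strict >)
  rows <- c(rep(paste(rep("A", 79), collapse = ""), 50),
            rep(paste(rep("C", 79), collapse = ""), 50))
  cons <- build_consensus(rows)
  expect_false(any(cons$highly))
  # tie at 50/50 broken alphabetically
  expect_true(all(cons$residue == "A"))

  # gap rows count in the denominator
  rows <- c(rep(paste(rep("E", 79), collapse = ""), 3),
            paste(rep("-", 78), collapse = "") |> paste0("E"))
  cons <- build_consensus(rows)
  expect_equal(cons$ratio[1], 3 / 4)

  # single row: everything conserved at 100%
  one <- build_consensus(rows[1])
  expect_true(all(one$ratio == 1))
  lists <- call_conserved_residues(one)
  expect_equal(nrow(lists$highly), 79)
  expect_equal(nrow(lists$extremely), 79)
})

test_that("conserved-residue lists are sorted and nested", {
  w <- cp159_world()
  cons <- build_consensus(w$aln)
  lists <- call_conserved_residues(cons)
  expect_true(!is.unsorted(lists$highly$pos))
  expect_true(all(paste(lists$extremely$pos, lists$extremely$residue)
                  %in% paste(lists$highly$pos, lists$highly$residue)))
})

test_that("binding classification implements the residue rule", {
  expect_equal(classify_binding(binding_row("H", "E", "R", "R"))$class,
               "G-box")
  expect_equal(classify_binding(binding_row("K", "E", "R", "R"))$class,
               "G-box")
  expect_equal(classify_binding(binding_row("A", "E", "R", "K"))$class,
               "E-box")
  expect_equal(classify_binding(binding_row("H", "A", "R", "R"))$class,
               "non-E-box")
  # E-core broken at 16: non-E-box even with His-9/Arg-17
  expect_equal(classify_binding(binding_row("H", "E", "Q", "R"))$class,
               "non-E-box")
  # gap at a tested position fails that test
  expect_equal(classify_binding(binding_row("-", "E", "R", "R"))$class,
               "E-box")
  expect_equal(classify_binding(binding_row("H", "-", "R", "R"))$class,
               "non-E-box")
  expect_error(classify_binding("SHORT"), "length")
})

test_that("mutating residue 13 away from E always gives non-E-box", {
  set.seed(21)
  for (i in 1:50) {
    r <- sample(famscan:::AA20, 4, replace = TRUE)
    r13 <- sample(setdiff(famscan:::AA20, "E"), 1)
    cls <- classify_binding(binding_row(r[1], r13, r[3], r[4]))$class
    expect_equal(cls, "non-E-box")
  }
})

test_that("census partitions any member set", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    rows <- random_rows(n)
    names(rows) <- paste0("m", seq_len(n))
    bc <- binding_census(rows)
    expect_equal(sum(bc$census), n)
    expect_true(all(bc$calls$class %in%
                      c("G-box", "E-box", "non-E-box")))
  }
  expect_error(binding_census(character(0)), "no members")
})

test_that("cp159 planted conservation and classes are recovered", {
  w <- cp159_world()
  cons <- build_consensus(w$aln)
  lists <- call_conserved_residues(cons)
  planted <- w$fx$truth$conserved
  expect_equal(lists$highly$pos, planted$highly$pos)
  expect_equal(lists$highly$residue, planted$highly$residue)
  expect_equal(lists$extremely$pos, planted$extremely$pos)
  expect_equal(lists$extremely$residue, planted$extremely$residue)

  bc <- binding_census(w$aln)
  truth_cls <- w$truth$binding_class[match(bc$calls$member,
                                           w$truth$name)]
  expect_equal(bc$calls$class, truth_cls)
})
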