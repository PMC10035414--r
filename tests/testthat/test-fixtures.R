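# The synthetic-data generator itself: determinism, invariants and
# Monte-Carlo recovery of its own design.

test_that("identical (preset, seed) bundles write byte-identical files", {
  d1 <- tempfile(); d2 <- tempfile()
  p <- preset_tiny(3)
  write_fixture(make_fixture(p, seed = 7), d1)
  write_fixture(make_fixture(p, seed = 7), d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- file.path(d2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed changes the bundle
  d3 <- tempfile()
  write_fixture(make_fixture(p, seed = 8), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "proteins.faa"))),
    unname(tools::md5sum(file.path(d3, "proteins.faa")))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("bundle invariants: one protein/promoter/expression row per gene", {
  fx <- tiny_world()
  tr <- fx$truth$genes
  expect_setequal(tr$protein_id, names(fx$proteins))
  expect_setequal(tr$gene_id, names(fx$promoters))
  expect_setequal(tr$gene_id, fx$gene_models$gene_id)
  # expression covers exactly the family members (the study's
  # transcript table is family-scoped)
  expect_setequal(rownames(fx$expression),
                  tr$gene_id[tr$is_family_member])
  # all planted member domains are exactly 79 model columns
  expect_true(all(nchar(fx$truth$domains) == 79))
  expect_true(all(tr$exon_count >= 1))
})

test_that("inconsistent presets fail with the violated constraint", {
  p <- preset_tiny(9)
  p$class_composition["G-box"] <- p$class_composition[["G-box"]] - 1L
  expect_error(make_fixture(p, 1), "sum to n_valid")
  p2 <- preset_tiny(9)
  p2$exon_counts <- p2$exon_counts[-1]
  expect_error(make_fixture(p2, 1), "exon_counts")
  p3 <- preset_tiny(9)
  p3$subfamily_sizes[1] <- p3$subfamily_sizes[1] + 5L
  expect_error(make_fixture(p3, 1), "subfamily sizes")
  expect_error(famscan_preset("x", c("G-box" = 3),
                              exon_counts = c(1, 0, 2)), ">= 1")
})

test_that("synth_domain_sequence round-trips through the classifier", {
  set.seed(71)
  for (cls in c("G-box", "E-box", "non-E-box")) {
    for (i in 1:400) {
      d <- synth_domain_sequence(cls, mut_rate = 0.15)
      expect_equal(classify_binding(d$domain)$class, cls)
      # the domain sits where domain_start says
      expect_identical(substr(d$sequence, d$domain_start + 1,
                              d$domain_start + 79), d$domain)
    }
  }
  expect_error(synth_domain_sequence("Z-box"), "should be one of|%in%")
})

test_that("synth_expression: constant cluster has ~zero fold change", {
  set.seed(72)
  shapes <- rbind(flat = c(0, 0, 0, 0))
  colnames(shapes) <- c("CK", "LS", "MS", "HS")
  assign <- stats::setNames(rep(1L, 200), paste0("g", 1:200))
  ex <- synth_expression(list(
    treatments = colnames(shapes), control = "CK", shapes = shapes,
    assignment = assign, baseline_range = c(4, 5),
    amp_range = c(1, 1), sd_log2 = 0.1))
  lfc <- log2(ex$matrix[, "LS"] / ex$matrix[, "CK"])
  expect_lt(abs(mean(lfc)), 0.05)
  expect_true(all(ex$folds == 1))
  expect_true(all(ex$matrix >= 0))
})

test_that("a planted 3-fold decrease is recovered in expectation", {
  set.seed(73)
  shapes <- rbind(dn = c(0, -log2(3), 0, 0))
  colnames(shapes) <- c("CK", "LS", "MS", "HS")
  est <- replicate(200, {
    ex <- synth_expression(list(
      treatments = colnames(shapes), control = "CK", shapes = shapes,
      assignment = c(g = 1L), baseline_range = c(4, 5),
      amp_range = c(1, 1), sd_log2 = 0.15))
    ex$matrix["g", "CK"] / ex$matrix["g", "LS"]
  })
  expect_lt(abs(mean(est) - 3) / 3, 0.2)
})

test_that("designed qPCR ratio 2.0 is recovered within 15% under noise", {
  set.seed(74)
  ratios <- rbind(g = c(1, 2)); colnames(ratios) <- c("CK", "T1")
  est <- replicate(500, {
    ct <- synth_qpcr(list(ratios = ratios, treatments = c("CK", "T1"),
                          calibrator = "CK", reference_gene = "ref",
                          ref_ct = 15, base_dct = 8, n_bio = 3L,
                          n_tech = 3L, sd_tech = 0.2, sd_bio = 0))
    rel <- relative_expression_ddct(ct, "ref", "CK")
    s <- rel$summary
    s$mean[s$treatment == "T1"]
  })
  expect_lt(abs(mean(est) - 2) / 2, 0.15)
})

test_that("noise-free bundle: planted domain offsets recovered 100%", {
  fx <- make_fixture(preset_noisefree(6), seed = 3)
  prof <- build_profile(fx$truth$domains)
  tr <- fx$truth$genes
  for (i in which(tr$is_family_member)) {
    h <- scan_sequence(prof, fx$proteins[[tr$protein_id[i]]], id = "m")
    expect_equal(h$start[1], tr$domain_start[i])
    expect_equal(h$covered[1], 79L)
    expect_identical(align_to_model(h[1, ], fx$proteins[[tr$protein_id[i]]]),
                     unname(fx$truth$domains[[tr$gene_id[i]]]))
  }
})

test_that("cp159 planted truth composition is as stated", {
  w <- cp159_world()
  tr <- w$fx$truth$genes
  expect_equal(sum(tr$is_family_member), 159L)
  expect_equal(sum(tr$decoy_type == "duplicate"), 8L)
  expect_equal(sum(tr$decoy_type == "truncated"), 7L)
  expect_equal(length(unique(tr$chromosome[tr$is_family_member])), 21L)
  cls <- table(tr$binding_class[tr$is_family_member])
  expect_equal(cls[["G-box"]], 93L)
  expect_equal(cls[["E-box"]], 43L)
  expect_equal(cls[["non-E-box"]], 23L)
  expect_equal(sum(tr$exon_count[tr$is_family_member] == 1), 20L)
  expect_equal(sum(!tr$is_expressed[tr$is_family_member]), 4L)
})
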