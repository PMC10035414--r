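# 2^-ddCt arithmetic, one-way ANOVA and Duncan letters.

make_ct <- function(genes, treatments, ct_fun, n_bio = 3, n_tech = 2,
                    ref = "18sRNA", ref_ct = 20) {
  rows <- expand.grid(gene = c(ref, genes), treatment = treatments,
                      bio_rep = seq_len(n_bio),
                      tech_rep = seq_len(n_tech),
                      stringsAsFactors = FALSE)
  rows$ct <- mapply(ct_fun, rows$gene, rows$treatment, rows$bio_rep)
  rows
}

test_that("ddCt arithmetic on hand examples", {
  # all Ct equal: everything is 1
  ct <- make_ct("g", c("CK", "T"), function(g, t, b) 20)
  rel <- relative_expression_ddct(ct, "18sRNA", "CK")
  expect_true(all(rel$per_rep$rel_expr == 1))

  # target CK 24, T 25; reference 20 everywhere -> T value 0.5
  ct <- make_ct("g", c("CK", "T"), function(g, t, b) {
    if (g == "18sRNA") 20 else if (t == "CK") 24 else 25
  })
  rel <- relative_expression_ddct(ct, "18sRNA", "CK")
  s <- rel$summary
  expect_equal(s$mean[s$treatment == "T"], 0.5)
  expect_equal(s$mean[s$treatment == "CK"], 1)

  # scale equivariance: adding a constant to every Ct changes nothing
  ct2 <- ct; ct2$ct <- ct2$ct + 3.7
  rel2 <- relative_expression_ddct(ct2, "18sRNA", "CK")
  expect_equal(rel2$per_rep$rel_expr, rel$per_rep$rel_expr)

  # missing reference rows are named
  bad <- ct[!(ct$gene == "18sRNA" & ct$treatment == "T"), ]
  expect_error(relative_expression_ddct(bad, "18sRNA", "CK"),
               "missing reference")
  expect_error(relative_expression_ddct(ct, "nope", "CK"), "absent")
})

test_that("technical replicates are averaged before dCT", {
  ct <- make_ct("g", c("CK", "T"), function(g, t, b) 20, n_tech = 3)
  # perturb technical replicates symmetrically: average unchanged
  idx <- ct$gene == "g" & ct$treatment == "T"
  ct$ct[idx][ct$tech_rep[idx] == 1] <- 21
  ct$ct[idx][ct$tech_rep[idx] == 2] <- 19
  rel <- relative_expression_ddct(ct, "18sRNA", "CK")
  expect_equal(rel$summary$mean, c(1, 1))
})

test_that("one-way ANOVA matches hand computation and stats::aov", {
  av <- anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(av$ss_between, 13.5)
  expect_equal(av$ss_within, 4)
  expect_equal(av$f, 13.5)
  expect_equal(av$df_between, 1L)
  expect_equal(av$df_within, 4L)

  # two identical groups
  expect_equal(anova_oneway(list(a = 1:3, b = 1:3))$f, 0)
  # degenerate: zero within-variance, unequal means
  av0 <- anova_oneway(list(a = c(1, 1), b = c(2, 2)))
  expect_equal(av0$f, Inf)
  expect_equal(av0$p, 0)

  # cross-check against stats::aov on random data
  set.seed(61)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:6, 1),
                                                   mean = j))
    names(groups) <- paste0("t", seq_len(k))
    av <- anova_oneway(groups)
    df <- data.frame(y = unlist(groups),
                     g = rep(names(groups), lengths(groups)))
    ref <- summary(stats::aov(y ~ g, df))[[1]]
    expect_equal(av$f, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(av$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    # permutation invariance
    av2 <- anova_oneway(rev(groups))
    expect_equal(av2$f, av$f)
  }
  expect_error(anova_oneway(list(a = 1:3)), "2 groups")
  expect_error(anova_oneway(list(a = 1, b = 1:2)), "2 values")
})

test_that("Duncan letters: degenerate and saturated cases", {
  all_eq <- duncan_letters(c(CK = 5, T1 = 5, T2 = 5), n = 3, mse = 1,
                           df = 6)
  expect_true(all(all_eq$letters == "a"))

  far <- duncan_letters(c(CK = 100, T1 = 50, T2 = 0), n = 3,
                        mse = 0.01, df = 6)
  expect_equal(unname(far$letters), c("a", "b", "c"))
  expect_equal(names(far$letters), c("CK", "T1", "T2"))

  expect_warning(duncan_letters(c(a = 1, b = 2), n = c(3, 5), mse = 1,
                                df = 6), "harmonic")
  expect_error(duncan_letters(c(a = 1, b = 2), n = 3, mse = -1, df = 6),
               "MSE")
})

test_that("Duncan letters match the brute-force span oracle", {
  set.seed(62)
  for (i in 1:40) {
    k <- sample(3:5, 1)
    means <- stats::setNames(rnorm(k, 10, 2), paste0("t", seq_len(k)))
    mse <- stats::runif(1, 0.1, 4)
    n <- sample(3:6, 1)
    df <- k * (n - 1)
    got <- duncan_letters(means, n = n, mse = mse, df = df)
    want <- duncan_oracle_letters(means, n = n, mse = mse, df = df)
    expect_identical(got$letters, want)
    # letters are contiguous over the sorted means
    for (L in letters[1:5]) {
      has <- grepl(L, got$letters)
      if (any(has)) {
        rng <- range(which(has))
        expect_true(all(has[rng[1]:rng[2]]))
      }
    }
  }
})

test_that("synthetic qPCR recovers designed ratios", {
  ratios <- rbind(gA = c(1, 0.5, 2), gB = c(1, 1, 0.25))
  colnames(ratios) <- c("CK", "T1", "T2")
  design <- list(ratios = ratios, treatments = colnames(ratios),
                 calibrator = "CK", reference_gene = "18sRNA",
                 ref_ct = 15, base_dct = 8, n_bio = 3L, n_tech = 3L,
                 sd_tech = 0, sd_bio = 0)
  ct <- synth_qpcr(design)
  rel <- relative_expression_ddct(ct, "18sRNA", "CK")
  s <- rel$summary
  for (g in rownames(ratios)) for (t in colnames(ratios)) {
    expect_equal(s$mean[s$gene == g & s$treatment == t],
                 ratios[g, t], tolerance = 1e-12)
  }
})

test_that("qpcr_analysis produces letters per gene", {
  ratios <- rbind(gA = c(1, 0.1, 4))
  colnames(ratios) <- c("CK", "T1", "T2")
  set.seed(63)
  ct <- synth_qpcr(list(ratios = ratios, treatments = colnames(ratios),
                        calibrator = "CK", reference_gene = "18sRNA",
                        ref_ct = 15, base_dct = 8, n_bio = 3L,
                        n_tech = 3L, sd_tech = 0.05, sd_bio = 0.05))
  out <- qpcr_analysis(ct, "18sRNA", "CK")
  expect_equal(nrow(out), 3L)
  # means separated by 40x: three distinct letters, highest mean = "a"
  expect_equal(out$letter[order(-out$mean)], c("a", "b", "c"))
  expect_equal(out$treatment[which.max(out$mean)], "T2")
})
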