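# make_fixture(): assemble a complete synthetic bundle from a preset,
# plus the on-disk writers.

#' Generate a synthetic fixture bundle
#'
#' Builds the full synthetic world described by a preset: putative
#' proteins with planted 79-column domains (including exact-duplicate
#' and domain-truncated decoys), gene models on pseudo-chromosomes,
#' promoters with planted cis-elements, an expression matrix with
#' planted clusters/DEGs/unexpressed genes, a GO table, a replicated
#' qPCR Ct table, labeled reference domains for subfamily assignment,
#' and a truth record for every stage.  Identical (preset, seed) pairs
#' produce identical bundles (and byte-identical files via
#' [write_fixture()]).
#'
#' @param preset a [famscan_preset()].
#' @param seed integer seed.
#' @param catalog cis-element catalog (default: the shipped one).
#' @param promoter_length promoter length in bp.
#' @return object of class `famscan_fixture`.
#' @export
make_fixture <- function(preset, seed = 1, catalog = NULL,
                         promoter_length = 2000) {
  validate_preset(preset)
  if (is.null(catalog)) catalog <- read_cis_catalog()
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  n <- preset$n_valid
  classes <- sample(rep(names(preset$class_composition),
                        preset$class_composition))
  subfam_labels <- names(preset$subfamily_sizes)
  subfams <- sample(rep(subfam_labels, preset$subfamily_sizes))

  # subfamily signature rows (also the labeled references)
  signatures <- lapply(subfam_labels, function(s) random_template())
  names(signatures) <- subfam_labels

  domains <- synth_domain_cohort(classes, subfams, signatures,
                                 preset$mut_background,
                                 preset$keep_high, preset$keep_extreme)

  # ---- identities ----------------------------------------------------
  gene_ids <- sprintf("CPAG%04d", sample(1000:9999, n))
  protein_ids <- paste0(gene_ids, "_P")

  # ---- proteins ------------------------------------------------------
  proteins <- character(n)
  domain_start <- integer(n)
  for (i in seq_len(n)) {
    nf <- sample(20:80, 1); cf <- sample(20:120, 1)
    proteins[i] <- paste(c(sample(AA20, nf, replace = TRUE),
                           domains[i, ],
                           sample(AA20, cf, replace = TRUE)),
                         collapse = "")
    domain_start[i] <- nf
  }
  names(proteins) <- protein_ids

  # decoys: exact duplicates of members, and domain-truncated sequences
  dup_src <- if (preset$n_dup > 0) sample.int(n, preset$n_dup) else
    integer(0)
  dup_ids <- sprintf("ZDUPG%02d", seq_len(preset$n_dup))
  dup_prot <- stats::setNames(unname(proteins[dup_src]),
                              sprintf("ZDUPG%02d_P",
                                      seq_len(preset$n_dup)))
  trunc_ids <- sprintf("ZTRNG%02d", seq_len(preset$n_trunc))
  keep_cols <- seq_len(BHLH_MODEL_LENGTH - preset$trunc_columns)
  trunc_prot <- character(preset$n_trunc)
  for (i in seq_len(preset$n_trunc)) {
    row <- synth_domain_cohort(sample(names(preset$class_composition), 1),
                               sample(subfam_labels, 1), signatures,
                               preset$mut_background, preset$keep_high,
                               preset$keep_extreme)[1, ]
    trunc_prot[i] <- paste(c(sample(AA20, sample(20:80, 1),
                                    replace = TRUE),
                             row[keep_cols],
                             sample(AA20, sample(20:120, 1),
                                    replace = TRUE)),
                           collapse = "")
  }
  names(trunc_prot) <- sprintf("ZTRNG%02d_P", seq_len(preset$n_trunc))
  all_proteins <- c(proteins, dup_prot, trunc_prot)
  all_gene_ids <- c(gene_ids, dup_ids, trunc_ids)

  # ---- gene models ---------------------------------------------------
  per_chr <- rep(floor(n / preset$n_chromosomes), preset$n_chromosomes)
  extra <- n - sum(per_chr)
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  chrom <- rep(paste0("chr", seq_len(preset$n_chromosomes)), per_chr)
  within_idx <- unlist(lapply(per_chr, seq_len))
  start <- 10000L + (within_idx - 1L) * 20000L +
    sample(0:4000, n, replace = TRUE)

  exon_counts <- assign_exon_counts(preset, subfams)
  member_models <- build_gene_rows(gene_ids, chrom, start, exon_counts)

  decoy_n <- preset$n_dup + preset$n_trunc
  decoy_models <- NULL
  if (decoy_n > 0) {
    dchrom <- paste0("chr", sample.int(preset$n_chromosomes, decoy_n,
                                       replace = TRUE))
    dstart <- 5000000L + seq_len(decoy_n) * 30000L +
      sample(0:4000, decoy_n, replace = TRUE)
    decoy_models <- build_gene_rows(c(dup_ids, trunc_ids), dchrom, dstart,
                                    sample(1:5, decoy_n, replace = TRUE))
  }
  gene_models <- rbind(member_models, decoy_models)

  # a few member genes get a second, shorter transcript so that
  # primary-transcript selection is exercised
  alt_tx <- if (n >= 10) gene_ids[sample.int(n, 5)] else character(0)

  # ---- promoters with planted cis-elements ---------------------------
  pp <- plant_promoters(all_gene_ids, catalog,
                        promoter_length = promoter_length)

  # ---- expression ----------------------------------------------------
  ex <- preset$expression
  assign <- rep(NA_integer_, n)
  amp <- stats::setNames(stats::runif(n, ex$amp_range[1],
                                      ex$amp_range[2]), gene_ids)
  cluster_rows <- match(names(ex$cluster_sizes), rownames(ex$shapes))
  remaining <- stats::setNames(as.integer(ex$cluster_sizes),
                               names(ex$cluster_sizes))
  if (nrow(ex$deg_design)) {
    for (i in seq_len(nrow(ex$deg_design))) {
      r <- ex$deg_design$rank[i]
      cl <- ex$deg_design$cluster[i]
      assign[r] <- match(cl, rownames(ex$shapes))
      amp[r] <- ex$deg_design$amplitude[i]
      remaining[cl] <- remaining[cl] - 1L
    }
  }
  free <- setdiff(which(is.na(assign)), ex$unexpressed_ranks)
  free <- sample(free)
  pool <- rep(match(names(remaining), rownames(ex$shapes)), remaining)
  assign[free] <- pool
  names(assign) <- gene_ids
  expr <- synth_expression(list(
    treatments = ex$treatments, control = ex$control, shapes = ex$shapes,
    assignment = assign, amplitudes = amp,
    baseline_range = ex$baseline_range, sd_log2 = ex$sd_log2,
    unexpressed_range = ex$unexpressed_range))

  # ---- GO table ------------------------------------------------------
  go <- synth_go_table(gene_ids, preset$go_salt_ranks)

  # ---- qPCR ----------------------------------------------------------
  ct_table <- NULL
  qpcr_truth <- NULL
  if (!is.null(preset$qpcr)) {
    q <- preset$qpcr
    ranks <- as.integer(rownames(q$rank_ratios))
    ratios <- q$rank_ratios
    rownames(ratios) <- gene_ids[ranks]
    ct_table <- synth_qpcr(list(
      ratios = ratios, treatments = q$treatments,
      calibrator = q$calibrator, reference_gene = q$reference_gene,
      ref_ct = q$ref_ct, base_dct = q$base_dct, n_bio = q$n_bio,
      n_tech = q$n_tech, sd_tech = q$sd_tech, sd_bio = q$sd_bio))
    qpcr_truth <- list(ratios = ratios, calibrator = q$calibrator,
                       reference_gene = q$reference_gene)
  }

  # ---- truth ---------------------------------------------------------
  genes_truth <- data.frame(
    gene_id = all_gene_ids,
    protein_id = names(all_proteins),
    is_family_member = c(rep(TRUE, n), rep(FALSE, decoy_n)),
    decoy_type = c(rep("none", n), rep("duplicate", preset$n_dup),
                   rep("truncated", preset$n_trunc)),
    rank = c(seq_len(n), rep(NA_integer_, decoy_n)),
    chromosome = gene_models$chromosome,
    start = gene_models$start,
    domain_start = c(domain_start, rep(NA_integer_, decoy_n)),
    binding_class = c(classes, rep(NA_character_, decoy_n)),
    subfamily = c(subfams, rep(NA_character_, decoy_n)),
    exon_count = gene_models$n_exons,
    cluster = c(expr$truth$cluster, rep(NA_character_, decoy_n)),
    is_expressed = c(expr$truth$is_expressed, rep(NA, decoy_n)),
    stringsAsFactors = FALSE)

  cons <- BHLH_CONSERVED
  truth <- list(
    genes = genes_truth,
    domains = stats::setNames(apply(domains, 1, paste, collapse = ""),
                              gene_ids),
    duplicates = data.frame(decoy = dup_ids,
                            source = gene_ids[dup_src],
                            stringsAsFactors = FALSE),
    folds = expr$folds,
    deg_ranks = sort(ex$deg_design$rank),
    unexpressed_ranks = ex$unexpressed_ranks,
    go_salt_ranks = preset$go_salt_ranks,
    cis = pp$truth, cis_planted = pp$planted,
    conserved = list(highly = cons[, c("pos", "residue")],
                     extremely = cons[cons$tier == "extreme",
                                      c("pos", "residue")]),
    qpcr = qpcr_truth)

  structure(list(
    preset = preset, seed = seed,
    proteins = all_proteins,
    gene_models = gene_models,
    alt_transcripts = alt_tx,
    promoters = pp$promoters,
    expression = expr$matrix,
    go_table = go,
    ct_table = ct_table,
    references = stats::setNames(
      vapply(signatures, paste, character(1), collapse = ""),
      paste0("REF_", subfam_labels)),
    reference_labels = stats::setNames(subfam_labels,
                                       paste0("REF_", subfam_labels)),
    truth = truth), class = "famscan_fixture")
}

#' @export
print.famscan_fixture <- function(x, ...) {
  cat("famscan synthetic fixture (preset '", x$preset$name, "', seed ",
      x$seed, ")\n", sep = "")
  cat("  putative proteins: ", length(x$proteins),
      " (", x$preset$n_valid, " valid members)\n", sep = "")
  cat("  chromosomes: ", x$preset$n_chromosomes,
      "; expression genes: ", nrow(x$expression), "\n", sep = "")
  invisible(x)
}

# exon-count assignment: intronless counts go preferentially to members
# of the preset's intronless subfamilies
assign_exon_counts <- function(preset, subfams) {
  n <- preset$n_valid
  counts <- preset$exon_counts
  out <- integer(n)
  singles <- which(counts == 1)
  pref <- which(subfams %in% preset$intronless_subfamilies)
  pref <- sample(pref)
  others <- sample(setdiff(seq_len(n), pref))
  target_order <- c(pref, others)
  single_genes <- target_order[seq_along(singles)]
  out[single_genes] <- 1L
  rest <- sample(counts[counts != 1])
  out[setdiff(seq_len(n), single_genes)] <- rest
  out
}

build_gene_rows <- function(ids, chrom, start, exon_counts) {
  rows <- lapply(seq_along(ids), function(i) {
    m <- exon_counts[i]
    ex_len <- sample(120:300, m, replace = TRUE)
    in_len <- if (m > 1) sample(80:400, m - 1, replace = TRUE) else
      integer(0)
    ex_start <- start[i] + c(0L, cumsum(ex_len[-m] + in_len))
    ex_end <- ex_start + ex_len - 1L
    data.frame(gene_id = ids[i], chromosome = chrom[i],
               strand = sample(c("+", "-"), 1),
               start = start[i], end = max(ex_end),
               n_exons = m,
               exons = I(list(cbind(start = ex_start, end = ex_end))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

synth_go_table <- function(gene_ids, salt_ranks) {
  vocab <- data.frame(
    term_id = c("GO:0003677", "GO:0005634", "GO:0006355", "GO:0006950",
                "GO:0009737"),
    term_name = c("DNA binding", "nucleus",
                  "regulation of transcription, DNA-templated",
                  "response to stress", "response to abscisic acid"),
    aspect = c("MF", "CC", "BP", "BP", "BP"),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_along(gene_ids), function(i) {
    k <- sample(1:3, 1)
    v <- vocab[sample.int(nrow(vocab), k), , drop = FALSE]
    data.frame(gene = gene_ids[i], term_id = v$term_id,
               term_name = v$term_name, aspect = v$aspect,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(salt_ranks)) {
    out <- rbind(out, data.frame(
      gene = gene_ids[salt_ranks], term_id = "GO:0009651",
      term_name = "response to salt stress", aspect = "BP",
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
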