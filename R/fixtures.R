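# Seeded synthetic fixture bundles: proteins with planted domains,
# gene models, promoters with planted cis-elements, expression matrix,
# GO table and qPCR Ct table, all with ground-truth labels.

# ---- low-level domain synthesis -------------------------------------

# 79-char consensus template with background positions drawn uniformly.
random_template <- function() {
  row <- sample(AA20, BHLH_MODEL_LENGTH, replace = TRUE)
  row[BHLH_CONSERVED$pos] <- BHLH_CONSERVED$residue
  row
}

# Set the class-determining residues of a domain row (character vector).
apply_binding_class <- function(row, binding_class) {
  if (binding_class == "G-box") {
    row[9] <- "H"; row[13] <- "E"; row[16] <- "R"; row[17] <- "R"
  } else if (binding_class == "E-box") {
    # E-core present, G-box requirements broken at both 9 and 17 so the
    # per-column census of His-9 / Arg-17 stays deterministic
    row[13] <- "E"; row[16] <- "R"
    row[9] <- "R"          # common non-His/Lys basic residue at 9
    row[17] <- sample(setdiff(AA20, "R"), 1)
  } else if (binding_class == "non-E-box") {
    # the class is decided solely by the broken Glu-13/Arg-16 core;
    # the other basic-region residues keep their family consensus
    row[13] <- sample(setdiff(AA20, "E"), 1)
    row[16] <- "R"
    row[9] <- "H"
    row[17] <- "R"
  } else {
    stop("unknown binding class: ", binding_class, call. = FALSE)
  }
  row
}

#' Synthesize one protein with a planted domain
#'
#' Builds a 79-residue domain from the conserved-consensus template,
#' mutates non-constrained positions at `mut_rate`, forces the
#' class-determining residues at model positions 9/13/16/17 so that
#' [classify_binding()] returns exactly `binding_class`, and embeds the
#' domain between uniform-background flanks.
#'
#' @param binding_class `"G-box"`, `"E-box"` or `"non-E-box"`.
#' @param mut_rate per-site substitution rate at non-constrained domain
#'   positions.
#' @param flank_n,flank_c ranges (length-2 integer) for flank lengths.
#' @return list with `sequence`, `domain_start` (0-based offset of the
#'   domain in the protein) and `domain` (the 79-char planted row).
#' @export
synth_domain_sequence <- function(binding_class, mut_rate = 0.1,
                                  flank_n = c(20L, 80L),
                                  flank_c = c(20L, 120L)) {
  stopifnot(binding_class %in% c("G-box", "E-box", "non-E-box"))
  row <- random_template()
  mut <- stats::runif(BHLH_MODEL_LENGTH) < mut_rate
  mut[BINDING_POSITIONS] <- FALSE
  row[mut] <- sample(AA20, sum(mut), replace = TRUE)
  row <- apply_binding_class(row, binding_class)
  nf <- sample(flank_n[1]:flank_n[2], 1)
  cf <- sample(flank_c[1]:flank_c[2], 1)
  seq <- paste(c(sample(AA20, nf, replace = TRUE), row,
                 sample(AA20, cf, replace = TRUE)), collapse = "")
  list(sequence = seq, domain_start = nf,
       domain = paste(row, collapse = ""))
}

# Domain matrix for a member cohort: subfamily signatures + stratified
# conservation + class constraints.  Returns n x 79 character matrix.
synth_domain_cohort <- function(classes, subfamilies, signatures,
                                mut_background, keep_high, keep_extreme) {
  n <- length(classes)
  mat <- do.call(rbind, signatures[subfamilies])
  # Non-conserved columns come in two interleaved kinds:
  #  - "preference" columns: a primary residue in 45% of rows and a
  #    secondary in 30% (family-wide, never called conserved at >50%),
  #    emulating the weak residue preferences real alignment columns
  #    show; they keep local alignment anchored across the domain;
  #  - "signature" columns: inherited from the subfamily signature with
  #    a small per-site substitution rate; they carry the subfamily
  #    signal used by phylogeny and subfamily assignment.
  # All of the basic region's non-listed columns are preference columns
  # (the basic region as a whole is conserved); elsewhere the two kinds
  # alternate so uninformative columns are never adjacent.
  bg_pos <- setdiff(seq_len(BHLH_MODEL_LENGTH),
                    c(BHLH_CONSERVED$pos, BHLH_SEMICONSERVED_POS))
  pref_pos <- c(BHLH_SEMICONSERVED_POS,
                bg_pos[seq_along(bg_pos) %% 2 == 0])
  sig_pos <- setdiff(bg_pos, pref_pos)
  for (p in pref_pos) {
    pair <- sample(AA20, 2)
    n1 <- floor(0.45 * n); n2 <- floor(0.30 * n)
    rows <- sample.int(n, n)
    mat[rows[seq_len(n1)], p] <- pair[1]
    if (n2 > 0) mat[rows[n1 + seq_len(n2)], p] <- pair[2]
    rest <- if (n1 + n2 < n) rows[(n1 + n2 + 1):n] else integer(0)
    if (length(rest)) {
      mat[rest, p] <- sample(setdiff(AA20, pair), length(rest),
                             replace = TRUE)
    }
  }
  for (p in sig_pos) {
    mut <- which(stats::runif(n) < mut_background)
    if (length(mut)) mat[mut, p] <- sample(AA20, length(mut),
                                           replace = TRUE)
  }
  cons <- BHLH_CONSERVED[!BHLH_CONSERVED$pos %in% BINDING_POSITIONS, ]
  # Per-column keep counts are exact (the conservation bands are part of
  # the stated world).  Within the C-terminal conserved group, at most
  # two substitutions per row: every member must keep an anchored,
  # complete domain terminus (members carry complete domains by
  # definition; only the truncation decoys lack one).
  cterm_group <- cons$pos >= 72
  group_muts <- integer(n)
  for (i in seq_len(nrow(cons))) {
    keep_frac <- if (cons$tier[i] == "extreme") keep_extreme else keep_high
    n_keep <- ceiling(n * keep_frac)
    n_mut <- n - n_keep
    if (cterm_group[i] && n_mut > 0) {
      eligible <- which(group_muts < 2)
      if (length(eligible) < n_mut) eligible <- which(group_muts < 3)
      mut_rows <- eligible[sample.int(length(eligible), n_mut)]
      group_muts[mut_rows] <- group_muts[mut_rows] + 1L
    } else {
      mut_rows <- if (n_mut > 0) sample.int(n, n_mut) else integer(0)
    }
    mat[, cons$pos[i]] <- cons$residue[i]
    if (length(mut_rows)) {
      mat[mut_rows, cons$pos[i]] <-
        sample(setdiff(AA20, cons$residue[i]), length(mut_rows),
               replace = TRUE)
    }
  }
  for (i in seq_len(n)) {
    mat[i, ] <- apply_binding_class(mat[i, ], classes[i])
  }
  mat
}

# ---- expression ------------------------------------------------------

#' Synthesize an expression matrix with planted cluster structure
#'
#' Expressed genes get `log2(mean) = baseline + amplitude * shape` of
#' their cluster (shapes are log2 offsets relative to the control
#' treatment) plus Gaussian noise of `sd_log2` in log2 space;
#' unexpressed genes draw all values uniformly below 1.
#'
#' @param design list with `treatments`, `control`, `shapes` (cluster x
#'   treatment matrix of log2 offsets, 0 in the control column),
#'   `assignment` (named integer vector gene -> cluster row index, `NA`
#'   for unexpressed), optional `amplitudes` and `baselines` (named,
#'   defaults drawn from `amp_range` / `baseline_range`), `sd_log2`,
#'   `unexpressed_range`.
#' @return list with `matrix` (genes x treatments), `truth`
#'   (gene, cluster, is_expressed, amplitude, baseline) and `folds`
#'   (true fold change per gene x treatment, relative to control).
#' @export
synth_expression <- function(design) {
  tr <- design$treatments
  shapes <- design$shapes[, tr, drop = FALSE]
  assign <- design$assignment
  genes <- names(assign)
  if (is.null(genes)) stop("design$assignment must be named by gene",
                           call. = FALSE)
  n <- length(assign)
  amp <- design$amplitudes %||%
    stats::setNames(stats::runif(n, design$amp_range[1],
                                 design$amp_range[2]), genes)
  base <- design$baselines %||%
    stats::setNames(stats::runif(n, design$baseline_range[1],
                                 design$baseline_range[2]), genes)
  sd_log2 <- design$sd_log2 %||% 0
  unr <- design$unexpressed_range %||% c(0.05, 0.7)

  mat <- matrix(NA_real_, n, length(tr), dimnames = list(genes, tr))
  folds <- matrix(1, n, length(tr), dimnames = list(genes, tr))
  for (i in seq_len(n)) {
    if (is.na(assign[i])) {
      mat[i, ] <- stats::runif(length(tr), unr[1], unr[2])
      folds[i, ] <- NA_real_
    } else {
      mu <- base[i] + amp[i] * shapes[assign[i], ]
      noise <- if (sd_log2 > 0) stats::rnorm(length(tr), 0, sd_log2)
               else rep(0, length(tr))
      mat[i, ] <- 2^(mu + noise)
      folds[i, ] <- 2^(amp[i] * shapes[assign[i], ])
    }
  }
  truth <- data.frame(
    gene = genes,
    cluster = ifelse(is.na(assign), NA_character_,
                     rownames(shapes)[assign]),
    is_expressed = !is.na(assign),
    amplitude = ifelse(is.na(assign), NA_real_, unname(amp)),
    baseline = ifelse(is.na(assign), NA_real_, unname(base)),
    stringsAsFactors = FALSE)
  list(matrix = mat, truth = truth, folds = folds)
}

# ---- qPCR ------------------------------------------------------------

#' Synthesize a replicated qPCR Ct table
#'
#' For gene `g` under treatment `T`,
#' `Ct = ref_ct + base_dct - log2(ratio(g, T)) + bio + tech`, with a
#' shared per-sample effect on reference and targets (cancels in dCT), a
#' per-(gene, sample) biological effect of sd `sd_bio`, and technical
#' noise of sd `sd_tech`.  With all sds zero,
#' [relative_expression_ddct()] recovers the designed ratios exactly.
#'
#' @param design list with `ratios` (genes x treatments matrix, 1 in the
#'   calibrator column), `treatments`, `calibrator`, `reference_gene`,
#'   `ref_ct`, `base_dct` (scalar or per-gene), `n_bio`, `n_tech`,
#'   `sd_tech`, `sd_bio`.
#' @return data.frame `gene`, `treatment`, `bio_rep`, `tech_rep`, `ct`
#'   including reference-gene rows for every sample.
#' @export
synth_qpcr <- function(design) {
  ratios <- design$ratios
  tr <- design$treatments %||% colnames(ratios)
  genes <- rownames(ratios)
  base_dct <- design$base_dct %||% 8
  if (length(base_dct) == 1) {
    base_dct <- stats::setNames(rep(base_dct, length(genes)), genes)
  }
  n_bio <- design$n_bio %||% 3L
  n_tech <- design$n_tech %||% 3L
  sd_tech <- design$sd_tech %||% 0
  sd_bio <- design$sd_bio %||% 0
  rows <- list()
  for (t in tr) {
    for (b in seq_len(n_bio)) {
      sample_eff <- if (sd_bio > 0) stats::rnorm(1, 0, sd_bio) else 0
      ref_base <- design$ref_ct + sample_eff
      rows[[length(rows) + 1]] <- data.frame(
        gene = design$reference_gene, treatment = t, bio_rep = b,
        tech_rep = seq_len(n_tech),
        ct = ref_base + rnorm0(n_tech, sd_tech),
        stringsAsFactors = FALSE)
      for (g in genes) {
        bio_eff <- if (sd_bio > 0) stats::rnorm(1, 0, sd_bio) else 0
        mu <- design$ref_ct + base_dct[[g]] - log2(ratios[g, t]) +
          sample_eff + bio_eff
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, treatment = t, bio_rep = b,
          tech_rep = seq_len(n_tech),
          ct = mu + rnorm0(n_tech, sd_tech),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$is_reference <- out$gene == design$reference_gene
  rownames(out) <- NULL
  out
}

rnorm0 <- function(n, sd) if (sd > 0) stats::rnorm(n, 0, sd) else rep(0, n)

# ---- promoters with planted cis-elements -----------------------------

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# instantiate an IUPAC pattern into a concrete ACGT string
instantiate_iupac <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]], function(code) {
    opts <- IUPAC_DNA[[code]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

# Plant catalog elements into random-background promoters and scrub the
# background so that the only matches are inside planted intervals.
# Returns list(promoters = named character, truth = data.frame of all
# expected hits, planted = data.frame of the deliberately inserted ones).
plant_promoters <- function(gene_ids, catalog, promoter_length = 2000,
                            n_per_gene = 2:5, min_gap = 12,
                            max_clean_iter = 50) {
  stopifnot(min_gap > max(nchar(catalog$pattern)))
  proms <- character(length(gene_ids))
  names(proms) <- gene_ids
  planted <- list()
  for (g in gene_ids) {
    seqv <- sample(c("A", "C", "G", "T"), promoter_length, replace = TRUE)
    k <- if (length(n_per_gene) == 1) n_per_gene else sample(n_per_gene, 1)
    rows <- catalog[sample.int(nrow(catalog), k, replace = TRUE), ,
                    drop = FALSE]
    placed <- matrix(numeric(0), ncol = 2)   # occupied [start, end] 1-based
    for (r in seq_len(nrow(rows))) {
      w <- nchar(rows$pattern[r])
      for (try in 1:100) {
        off <- sample.int(promoter_length - w + 1, 1)   # 1-based start
        ok <- !nrow(placed) ||
          all(off > placed[, 2] + min_gap | (off + w - 1) <
                placed[, 1] - min_gap)
        if (ok) break
        off <- NA
      }
      if (is.na(off)) next
      inst <- instantiate_iupac(rows$pattern[r])
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "-") revcomp_chr(inst) else inst
      seqv[off:(off + w - 1)] <- strsplit(ins, "")[[1]]
      placed <- rbind(placed, c(off, off + w - 1))
      planted[[length(planted) + 1]] <- data.frame(
        gene_id = g, element = rows$element[r], offset = off - 1L,
        strand = strand, width = w, stringsAsFactors = FALSE)
    }
    proms[[g]] <- paste(seqv, collapse = "")
  }
  planted <- do.call(rbind, planted)

  # expected hits: enumerate every window fully inside a planted
  # interval against every catalog pattern (pure-R IUPAC check)
  truth <- expected_cis_hits(proms, planted, catalog)

  # scrub: mutate background positions inside any scan hit that is not
  # fully inside a planted interval
  for (iter in seq_len(max_clean_iter)) {
    res <- scan_cis_elements(proms, catalog, dedup_palindromes = TRUE)
    sp <- spurious_hits(res$hits, planted, catalog)
    if (!nrow(sp)) break
    if (iter == max_clean_iter) {
      stop("promoter background scrub did not converge", call. = FALSE)
    }
    for (i in seq_len(nrow(sp))) {
      g <- sp$gene_id[i]
      w <- nchar(catalog$pattern[match(sp$element[i], catalog$element)])
      win <- (sp$offset[i] + 1):(sp$offset[i] + w)
      pl <- planted[planted$gene_id == g, , drop = FALSE]
      occupied <- unlist(lapply(seq_len(nrow(pl)), function(j) {
        (pl$offset[j] + 1):(pl$offset[j] + pl$width[j])
      }))
      free <- setdiff(win, occupied)
      if (!length(free)) next   # fully inside planted: part of truth
      pos <- free[sample.int(length(free), 1)]
      cur <- substr(proms[[g]], pos, pos)
      substr(proms[[g]], pos, pos) <- sample(setdiff(c("A", "C", "G",
                                                       "T"), cur), 1)
    }
  }
  list(promoters = proms, truth = truth, planted = planted)
}

# all hits whose window lies fully inside a planted interval, via
# direct IUPAC window checks (independent of the Biostrings scanner)
expected_cis_hits <- function(proms, planted, catalog) {
  out <- list()
  for (j in seq_len(nrow(planted))) {
    g <- planted$gene_id[j]
    lo <- planted$offset[j] + 1
    hi <- planted$offset[j] + planted$width[j]
    region <- substr(proms[[g]], lo, hi)
    for (k in seq_len(nrow(catalog))) {
      w <- nchar(catalog$pattern[k])
      if (w > nchar(region)) next
      for (s in 0:(nchar(region) - w)) {
        win <- substr(region, s + 1, s + w)
        fwd <- iupac_matches(win, catalog$pattern[k])
        rev <- iupac_matches(revcomp_chr(win), catalog$pattern[k])
        if (fwd || rev) {
          strand <- if (fwd) "+" else "-"   # palindromes collapse to "+"
          out[[length(out) + 1]] <- data.frame(
            gene_id = g, element = catalog$element[k],
            category = catalog$category[k],
            offset = lo - 1L + s, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), element = character(0),
                      category = character(0), offset = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  }
  unique(out)
}

spurious_hits <- function(hits, planted, catalog) {
  if (!nrow(hits)) return(hits)
  widths <- nchar(catalog$pattern)[match(hits$element, catalog$element)]
  inside <- vapply(seq_len(nrow(hits)), function(i) {
    pl <- planted[planted$gene_id == hits$gene_id[i], , drop = FALSE]
    any(hits$offset[i] >= pl$offset &
          hits$offset[i] + widths[i] <= pl$offset + pl$width)
  }, logical(1))
  hits[!inside, , drop = FALSE]
}
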