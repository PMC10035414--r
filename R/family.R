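# Family validation: domain-completeness filtering, redundancy removal,
# chromosomal naming and physicochemical properties.

#' Filter domain hits and collapse redundant sequences
#'
#' A protein is validated when it has at least one hit covering at least
#' `min_covered` model columns (a "complete" domain).  Exact duplicate
#' sequences are then collapsed, keeping the lexicographically smallest
#' protein id.  The operation is idempotent.
#'
#' @param hits data.frame of hits from [scan_proteins()].
#' @param proteins named character vector (or `AAStringSet`) of all
#'   scanned proteins.
#' @param min_covered minimum model columns covered by the best hit
#'   (default 70 of the 79-column model).
#' @return data.frame with one row per retained protein: `protein_id`,
#'   `start`, `end`, `score`, `covered`, list-column `alignment` (its
#'   best hit), plus `n_collapsed` (number of identical sequences it
#'   represents, including itself).
#' @export
filter_and_dedup <- function(hits, proteins, min_covered = 70) {
  proteins <- as_named_character(proteins)
  if (!nrow(hits)) {
    return(hits[, c("protein_id", "start", "end", "score", "covered",
                    "alignment")])
  }
  ok <- hits[hits$covered >= min_covered, , drop = FALSE]
  if (!nrow(ok)) {
    out <- ok
    out$n_collapsed <- integer(0)
    return(out)
  }
  # best hit per protein (hits are already best-first within protein,
  # but be explicit: max score, ties by covered then start)
  ord <- order(ok$protein_id, -ok$score, -ok$covered, ok$start)
  ok <- ok[ord, , drop = FALSE]
  best <- ok[!duplicated(ok$protein_id), , drop = FALSE]

  seqs <- proteins[best$protein_id]
  if (anyNA(seqs)) {
    stop("hits refer to proteins absent from the protein set",
         call. = FALSE)
  }
  # collapse exact duplicates: keep smallest id per sequence (C collation
  # so the rule is locale-independent)
  ids_sorted <- stri_sort_c(best$protein_id)
  best <- best[match(ids_sorted, best$protein_id), , drop = FALSE]
  seqs <- proteins[best$protein_id]
  keep <- !duplicated(unname(seqs))
  out <- best[keep, , drop = FALSE]
  out$n_collapsed <- as.integer(table(unname(seqs))[unname(seqs[keep])])
  rownames(out) <- NULL
  out
}

# locale-independent lexicographic sort
stri_sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x)
}

#' Assign family names by chromosomal order
#'
#' Members are ranked by (chromosome, gene start), chromosomes in natural
#' numeric order of their labels (`chr2` before `chr10`), ties broken by
#' start then gene id, and named `prefix1 .. prefixN`.
#'
#' @param members data.frame from [filter_and_dedup()].
#' @param gene_models gene-model set from [parse_gene_models()] (or any
#'   data.frame with `gene_id`, `chromosome`, `start`).
#' @param prefix name prefix, e.g. `"CpbHLH"`.
#' @param gene_of either a named character vector mapping protein id ->
#'   gene id, or a function applied to protein ids; the default strips a
#'   trailing `_P`/`.p<n>` suffix.
#' @return `members` with added columns `gene_id`, `chromosome`, `start`,
#'   `gene_end`, `strand`, `name`, `rank`, ordered by rank.
#' @export
assign_gene_names <- function(members, gene_models, prefix = "bHLH",
                              gene_of = default_gene_of) {
  gm <- if (is.data.frame(gene_models)) gene_models else
    gene_models_table(gene_models)
  gid <- if (is.function(gene_of)) gene_of(members$protein_id) else
    unname(gene_of[members$protein_id])
  idx <- match(gid, gm$gene_id)
  if (anyNA(idx)) {
    stop("no gene model for protein(s): ",
         paste(members$protein_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  members$gene_id <- gid
  members$chromosome <- gm$chromosome[idx]
  members$start <- gm$start[idx]
  members$gene_end <- gm$end[idx]
  members$strand <- gm$strand[idx]

  chr_levels <- unique(members$chromosome)
  chr_levels <- chr_levels[order_chromosomes(chr_levels)]
  chr_rank <- match(members$chromosome, chr_levels)
  ord <- order(chr_rank, members$start, members$gene_id)
  members <- members[ord, , drop = FALSE]
  members$rank <- seq_len(nrow(members))
  members$name <- paste0(prefix, members$rank)
  rownames(members) <- NULL
  members
}

#' @keywords internal
default_gene_of <- function(protein_id) {
  sub("(_P[0-9]*|\\.p[0-9]+)$", "", protein_id)
}

#' Physicochemical properties of a protein
#'
#' Molecular weight is the sum of average residue masses plus one water;
#' the isoelectric point solves net charge = 0 by bisection using the
#' Bjellqvist pKa set of the ExPASy Compute pI/Mw tool
#' (Henderson-Hasselbalch over the termini and D, E, C, Y, K, R, H).
#' `X` contributes the average residue mass and no charge.
#'
#' @param protein sequence string.
#' @return list with `length`, `mw` (Da) and `pi`.
#' @export
compute_physchem <- function(protein) {
  if (!is.character(protein) || length(protein) != 1 || !nzchar(protein)) {
    stop("empty sequence", call. = FALSE)
  }
  check_protein(protein)
  res <- strsplit(protein, "")[[1]]
  mass <- AA_MONO_AVG_MASS[res]
  mass[is.na(mass)] <- mean(AA_MONO_AVG_MASS)   # X
  mw <- sum(mass) + WATER_MASS

  counts <- table(factor(res, levels = names(AA_MONO_AVG_MASS)))
  pk <- PKA_BJELLQVIST
  net_charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - pk$nterm)) +
      counts[["K"]] / (1 + 10^(ph - pk$K)) +
      counts[["R"]] / (1 + 10^(ph - pk$R)) +
      counts[["H"]] / (1 + 10^(ph - pk$H))
    neg <- 1 / (1 + 10^(pk$cterm - ph)) +
      counts[["D"]] / (1 + 10^(pk$D - ph)) +
      counts[["E"]] / (1 + 10^(pk$E - ph)) +
      counts[["C"]] / (1 + 10^(pk$C - ph)) +
      counts[["Y"]] / (1 + 10^(pk$Y - ph))
    pos - neg
  }
  lo <- 0; hi <- 14
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (net_charge(mid) > 0) lo <- mid else hi <- mid
  }
  pi <- (lo + hi) / 2
  list(length = length(res), mw = mw, pi = pi)
}

#' Identify and annotate a transcription-factor family
#'
#' Convenience wrapper chaining [scan_proteins()], [filter_and_dedup()],
#' [assign_gene_names()] and [compute_physchem()].
#'
#' @inheritParams scan_proteins
#' @inheritParams filter_and_dedup
#' @inheritParams assign_gene_names
#' @return data.frame of named family members with physicochemical
#'   columns `length`, `mw`, `pi`.
#' @export
identify_family <- function(model, proteins, gene_models,
                            prefix = "bHLH", min_covered = 70,
                            gene_of = default_gene_of) {
  proteins <- as_named_character(proteins)
  hits <- scan_proteins(model, proteins)
  members <- filter_and_dedup(hits, proteins, min_covered = min_covered)
  members <- assign_gene_names(members, gene_models, prefix = prefix,
                               gene_of = gene_of)
  phys <- lapply(proteins[members$protein_id], compute_physchem)
  members$length <- vapply(phys, `[[`, numeric(1), "length")
  members$mw <- vapply(phys, `[[`, numeric(1), "mw")
  members$pi <- vapply(phys, `[[`, numeric(1), "pi")
  members
}
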