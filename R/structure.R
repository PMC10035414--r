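# GFF3 gene models: parsing, primary-transcript selection and
# exon/intron family statistics.

#' Parse gene models from a GFF3 file
#'
#' Reads gene/mRNA/exon(/CDS) features and keeps, per gene, the primary
#' transcript: the mRNA with the longest summed CDS (exon length when no
#' CDS is present), ties broken by first appearance.  Coordinates are
#' 1-based inclusive on disk and are kept that way in the returned
#' table; exons are listed in 5'->3' transcription order (descending
#' coordinates on the minus strand).
#'
#' @param path GFF3 file.
#' @return data.frame with one row per gene: `gene_id`, `chromosome`,
#'   `strand`, `start`, `end`, `transcript_id`, `n_exons`, and a
#'   list-column `exons` of two-column matrices (start, end).
#' @export
parse_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$ID <- as.character(df$ID)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (!nrow(genes)) stop("no gene features in ", path, call. = FALSE)

  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    tx <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == g$ID, , drop = FALSE]
    if (!nrow(tx)) {
      stop("gene ", g$ID, " has no mRNA feature", call. = FALSE)
    }
    cds_len <- vapply(tx$ID, function(t) {
      cc <- cds[!is.na(cds$Parent) & cds$Parent == t, , drop = FALSE]
      if (nrow(cc)) sum(cc$end - cc$start + 1) else {
        ee <- exons[!is.na(exons$Parent) & exons$Parent == t, ,
                    drop = FALSE]
        sum(ee$end - ee$start + 1)
      }
    }, numeric(1))
    primary <- tx$ID[which.max(cds_len)]   # which.max keeps first on tie
    ex <- exons[!is.na(exons$Parent) & exons$Parent == primary, ,
                drop = FALSE]
    if (!nrow(ex)) {
      stop("transcript ", primary, " has no exons", call. = FALSE)
    }
    ord <- order(ex$start, decreasing = identical(as.character(g$strand),
                                                  "-"))
    ex <- ex[ord, , drop = FALSE]
    data.frame(
      gene_id = g$ID, chromosome = as.character(g$seqnames),
      strand = as.character(g$strand),
      start = g$start, end = g$end,
      transcript_id = primary, n_exons = nrow(ex),
      exons = I(list(cbind(start = ex$start, end = ex$end))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Exon/intron summary for a family
#'
#' @param models gene models from [parse_gene_models()].
#' @param member_genes gene ids of the validated family members; must be
#'   a subset of the model set.
#' @param subfamilies optional data.frame (`gene_id`, `subfamily`) used
#'   to annotate the intronless list.
#' @return list with `per_gene` (gene, exon and intron counts) and
#'   `family` (counts and percentages: intronless, one-intron, exon
#'   range); percentages use the family size as denominator and are
#'   rounded half-up to one decimal.
#' @export
exon_intron_summary <- function(models, member_genes,
                                subfamilies = NULL) {
  idx <- match(member_genes, models$gene_id)
  if (anyNA(idx)) {
    stop("member genes missing from models: ",
         paste(member_genes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  per_gene <- data.frame(
    gene_id = member_genes,
    exon_count = models$n_exons[idx],
    intron_count = models$n_exons[idx] - 1L,
    stringsAsFactors = FALSE)
  n <- nrow(per_gene)
  intronless <- per_gene$gene_id[per_gene$exon_count == 1]
  one_intron <- per_gene$gene_id[per_gene$exon_count == 2]
  fam <- list(
    n = n,
    intronless_count = length(intronless),
    intronless_pct = round_half_up(100 * length(intronless) / n, 1),
    one_intron_count = length(one_intron),
    one_intron_pct = round_half_up(100 * length(one_intron) / n, 1),
    min_exons = min(per_gene$exon_count),
    max_exons = max(per_gene$exon_count))
  il <- data.frame(gene_id = intronless, stringsAsFactors = FALSE)
  if (!is.null(subfamilies)) {
    il$subfamily <- subfamilies$subfamily[match(intronless,
                                                subfamilies$gene_id)]
  }
  list(per_gene = per_gene, family = fam, intronless = il)
}
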