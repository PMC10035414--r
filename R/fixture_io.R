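# On-disk representation of a fixture bundle (plain-text formats only).

#' Write a fixture bundle to a directory
#'
#' Writes `proteins.faa`, `genes.gff3`, `promoters.fa`,
#' `expression.tsv`, `go.tsv`, `qpcr.tsv` (when the preset has a qPCR
#' design), `seed_domains.fasta` (the truth domain alignment usable as
#' profile seed), `references.fasta` + `reference_labels.tsv` (labeled
#' subfamily references) and `truth.json`.  Identical bundles produce
#' byte-identical files.
#'
#' @param bundle a [make_fixture()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "famscan_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteins = file.path(dir, "proteins.faa"),
    gff = file.path(dir, "genes.gff3"),
    promoters = file.path(dir, "promoters.fa"),
    expression = file.path(dir, "expression.tsv"),
    go = file.path(dir, "go.tsv"),
    seed_domains = file.path(dir, "seed_domains.fasta"),
    references = file.path(dir, "references.fasta"),
    reference_labels = file.path(dir, "reference_labels.tsv"),
    truth = file.path(dir, "truth.json"))

  write_fasta(bundle$proteins, paths[["proteins"]])
  write_gff3(bundle$gene_models, bundle$alt_transcripts, paths[["gff"]])
  write_fasta(bundle$promoters, paths[["promoters"]])

  expr <- data.frame(gene = rownames(bundle$expression),
                     bundle$expression, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(expr, paths[["expression"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$go_table, paths[["go"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$ct_table)) {
    paths <- c(paths, qpcr = file.path(dir, "qpcr.tsv"))
    utils::write.table(bundle$ct_table, paths[["qpcr"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_fasta(bundle$truth$domains, paths[["seed_domains"]])
  write_fasta(bundle$references, paths[["references"]])
  utils::write.table(
    data.frame(reference = names(bundle$reference_labels),
               subfamily = unname(bundle$reference_labels),
               stringsAsFactors = FALSE),
    paths[["reference_labels"]], sep = "\t", quote = FALSE,
    row.names = FALSE)

  truth <- bundle$truth
  truth$folds <- as.data.frame(truth$folds)
  truth$folds$gene <- rownames(bundle$truth$folds)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(paths)
}

write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "wb")   # binary mode: LF newlines on any platform
  on.exit(close(con))
  for (id in names(seqs)) {
    s <- seqs[[id]]
    lines <- substring(s, seq(1, nchar(s), width),
                       pmin(seq(1, nchar(s), width) + width - 1,
                            nchar(s)))
    writeLines(c(paste0(">", id), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @return named character vector.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path) else
    Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

# GFF3: 1-based inclusive coordinates, gene/mRNA/exon/CDS features.
write_gff3 <- function(gene_models, alt_transcripts, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  for (i in seq_len(nrow(gene_models))) {
    g <- gene_models[i, ]
    ex <- g$exons[[1]]
    lines <- c(
      gff_line(g$chromosome, "gene", g$start, g$end, g$strand,
               paste0("ID=", g$gene_id)),
      gff_line(g$chromosome, "mRNA", g$start, g$end, g$strand,
               paste0("ID=", g$gene_id, ".t1;Parent=", g$gene_id)))
    for (e in seq_len(nrow(ex))) {
      lines <- c(lines,
        gff_line(g$chromosome, "exon", ex[e, "start"], ex[e, "end"],
                 g$strand, paste0("ID=", g$gene_id, ".t1.exon", e,
                                  ";Parent=", g$gene_id, ".t1")),
        gff_line(g$chromosome, "CDS", ex[e, "start"], ex[e, "end"],
                 g$strand, paste0("ID=", g$gene_id, ".t1.cds", e,
                                  ";Parent=", g$gene_id, ".t1")))
    }
    if (g$gene_id %in% alt_transcripts) {
      lines <- c(lines,
        gff_line(g$chromosome, "mRNA", ex[1, "start"], ex[1, "end"],
                 g$strand, paste0("ID=", g$gene_id, ".t2;Parent=",
                                  g$gene_id)),
        gff_line(g$chromosome, "exon", ex[1, "start"], ex[1, "end"],
                 g$strand, paste0("ID=", g$gene_id, ".t2.exon1;Parent=",
                                  g$gene_id, ".t2")),
        gff_line(g$chromosome, "CDS", ex[1, "start"], ex[1, "end"],
                 g$strand, paste0("ID=", g$gene_id, ".t2.cds1;Parent=",
                                  g$gene_id, ".t2")))
    }
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

gff_line <- function(chr, type, start, end, strand, attrs) {
  paste(chr, "famscan", type, start, end, ".", strand,
        if (type == "CDS") "0" else ".", attrs, sep = "\t")
}

#' Read an expression TSV (gene column + one column per treatment)
#' @param path TSV file.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
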