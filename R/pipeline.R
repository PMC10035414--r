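# End-to-end orchestration from a single config, with a machine-readable
# summary report.

#' Default pipeline configuration
#'
#' @param input_dir directory holding the fixture-style inputs
#'   (`proteins.faa`, `genes.gff3`, `promoters.fa`, `expression.tsv`,
#'   `go.tsv`, `seed_domains.fasta`, `references.fasta`,
#'   `reference_labels.tsv`, optional `qpcr.tsv`).
#' @param output_dir where per-stage outputs and `report.json` go.
#' @return config list with documented defaults.
#' @export
pipeline_config <- function(input_dir, output_dir) {
  list(
    input_dir = input_dir,
    output_dir = output_dir,
    prefix = "bHLH",
    min_covered = 70,       # complete-domain columns (of 79)
    score_threshold = 30,   # bits
    min_abundance = 1,      # expression filter (strict >)
    fc_threshold = 3,       # DEG fold-change rule
    k_clusters = 8,
    alpha = 0.05,           # Duncan protection level
    bootstrap = 100,
    seed = 1,
    control = "CK",
    reference_gene = "18sRNA",
    calibrator = "CK",
    salt_terms = "response to salt stress",
    stages = c(identify = TRUE, conserve = TRUE, phylogeny = TRUE,
               structure = TRUE, cis = TRUE, expression = TRUE,
               qpcr = TRUE))
}

read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- pipeline_config(cfg$input_dir, cfg$output_dir)
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base[names(cfg)] <- cfg
  base
}

#' Run the full characterization pipeline
#'
#' Stages run in dependency order: identification -> conservation /
#' binding -> phylogeny + subfamilies -> gene structure -> cis-elements
#' -> expression screen + candidates -> qPCR statistics.  Any stage
#' failure aborts with a stage-tagged error.  Rerunning with identical
#' config and inputs reproduces identical outputs.
#'
#' @param config a [pipeline_config()] list or the path of a JSON file
#'   with the same keys.
#' @return the report list (also written to `report.json`), containing
#'   summary counts, the per-stage file manifest and a config hash.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  report <- list(tool = "famscan",
                 version = as.character(utils::packageVersion("famscan")),
                 config_hash = config_hash(cfg))
  emit <- function(df, name) {
    p <- file.path(cfg$output_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <<- c(manifest, p)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inp <- function(f) file.path(cfg$input_dir, f)

  proteins <- stage("load", read_fasta(inp("proteins.faa"), "AA"))
  models <- stage("load", parse_gene_models(inp("genes.gff3")))

  # identify ----------------------------------------------------------
  seed_aln <- read_fasta(inp("seed_domains.fasta"), "AA")
  profile <- stage("identify",
                   build_profile(seed_aln, threshold = cfg$score_threshold))
  members <- stage("identify",
                   identify_family(profile, proteins, models,
                                   prefix = cfg$prefix,
                                   min_covered = cfg$min_covered))
  emit(members[, c("name", "protein_id", "gene_id", "chromosome",
                   "start", "gene_end", "score", "covered", "length",
                   "mw", "pi")], "members.tsv")
  report$n_putative <- length(proteins)
  report$n_members <- nrow(members)

  # conservation + binding --------------------------------------------
  aln <- NULL
  if (cfg$stages[["conserve"]]) {
    aln <- stage("conserve", domain_alignment(members, proteins))
    cons <- stage("conserve", build_consensus(aln))
    calls <- stage("conserve", binding_census(aln))
    stopifnot(sum(calls$census) == nrow(members))
    emit(cons, "consensus.tsv")
    emit(calls$calls, "binding.tsv")
    write_fasta(aln, file.path(cfg$output_dir, "domain_alignment.fasta"))
    manifest <- c(manifest, file.path(cfg$output_dir,
                                      "domain_alignment.fasta"))
    report$binding_census <- as.list(calls$census)
    report$n_highly_conserved <- sum(cons$highly)
    report$n_extremely_conserved <- sum(cons$extremely)
  }

  # phylogeny + subfamilies -------------------------------------------
  if (cfg$stages[["phylogeny"]]) {
    refs <- read_fasta(inp("references.fasta"), "AA")
    lab <- utils::read.delim(inp("reference_labels.tsv"),
                             stringsAsFactors = FALSE)
    ref_labels <- stats::setNames(lab$subfamily, lab$reference)
    if (is.null(aln)) aln <- domain_alignment(members, proteins)
    tree <- stage("phylogeny",
                  bootstrap_support(c(aln, refs), n_reps = cfg$bootstrap,
                                    seed = cfg$seed))
    ape::write.tree(tree, file.path(cfg$output_dir, "tree.nwk"))
    manifest <- c(manifest, file.path(cfg$output_dir, "tree.nwk"))
    subf <- stage("phylogeny",
                  assign_subfamily(aln, refs, ref_labels))
    emit(subf, "subfamilies.tsv")
    report$subfamily_counts <- as.list(table(subf$subfamily))
  }

  # gene structure -----------------------------------------------------
  if (cfg$stages[["structure"]]) {
    subf_tab <- NULL
    if (cfg$stages[["phylogeny"]]) {
      subf_tab <- data.frame(gene_id = members$gene_id,
                             subfamily = subf$subfamily[
                               match(members$name, subf$member)],
                             stringsAsFactors = FALSE)
    }
    es <- stage("structure",
                exon_intron_summary(models, members$gene_id, subf_tab))
    emit(es$per_gene, "structure.tsv")
    report$intronless_count <- es$family$intronless_count
    report$intronless_pct <- es$family$intronless_pct
    report$exon_range <- c(es$family$min_exons, es$family$max_exons)
  }

  # cis elements --------------------------------------------------------
  if (cfg$stages[["cis"]]) {
    promoters <- read_fasta(inp("promoters.fa"), "DNA")
    catalog <- read_cis_catalog()
    cis <- stage("cis", scan_cis_elements(promoters[members$gene_id],
                                          catalog))
    emit(cis$hits, "cis_hits.tsv")
    emit(data.frame(element = names(cis$per_element),
                    count = cis$per_element), "cis_summary.tsv")
    report$cis_per_category <- as.list(cis$per_category)
  }

  # expression screen ---------------------------------------------------
  if (cfg$stages[["expression"]]) {
    mat <- read_expression(inp("expression.tsv"))
    fam_mat <- mat[intersect(rownames(mat), members$gene_id), ,
                   drop = FALSE]
    fn <- stage("expression",
                filter_and_normalize(fam_mat, cfg$min_abundance))
    cl <- stage("expression",
                cluster_expression(fn$log2, k = cfg$k_clusters))
    degs <- stage("expression",
                  screen_degs(fn$abundance, control = cfg$control,
                              fc_threshold = cfg$fc_threshold))
    go_tab <- utils::read.delim(inp("go.tsv"), stringsAsFactors = FALSE)
    cand <- stage("expression",
                  select_candidates(degs, go_tab,
                                    salt_terms = cfg$salt_terms))
    emit(data.frame(gene = names(cl$clusters), cluster = cl$clusters),
         "clusters.tsv")
    emit(degs, "degs.tsv")
    emit(cand, "candidates.tsv")
    emit(data.frame(gene = rownames(fn$log2), fn$log2,
                    check.names = FALSE), "heatmap_matrix.tsv")
    report$n_expressed <- nrow(fn$abundance)
    report$n_degs <- sum(degs$is_deg)
    report$n_candidates <- nrow(cand)
  }

  # qPCR ----------------------------------------------------------------
  if (cfg$stages[["qpcr"]] && file.exists(inp("qpcr.tsv"))) {
    ct <- utils::read.delim(inp("qpcr.tsv"), stringsAsFactors = FALSE)
    qa <- stage("qpcr", qpcr_analysis(ct, cfg$reference_gene,
                                      cfg$calibrator, alpha = cfg$alpha))
    emit(qa, "qpcr_stats.tsv")
    report$n_qpcr_genes <- length(unique(qa$gene))
  }

  # cross-stage consistency ---------------------------------------------
  if (!is.null(report$binding_census)) {
    stopifnot(sum(unlist(report$binding_census)) == report$n_members)
  }
  report$manifest <- basename(manifest)
  jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
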