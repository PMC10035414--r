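# Promoter cis-regulatory element scanning with IUPAC patterns.

#' Read a cis-element catalog
#'
#' The catalog is a TSV with columns `element`, `pattern`, `category`,
#' `description`.  Patterns must use IUPAC nucleotide codes only and
#' categories must be one of `growth_development`, `phytohormone`,
#' `stress`.  The catalog shipped with the package
#' (`system.file("extdata", "cis_catalog.tsv", package = "famscan")`)
#' lists the classic PLACE/PlantCARE elements of the three categories.
#'
#' @param path TSV file; default is the shipped catalog.
#' @return validated data.frame.
#' @export
read_cis_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cis_catalog.tsv", package = "famscan")
  }
  cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("element", "pattern", "category")
  if (!all(need %in% names(cat))) {
    stop("catalog must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  validate_cis_catalog(cat)
  cat
}

validate_cis_catalog <- function(cat) {
  bad <- vapply(cat$pattern, function(p) {
    any(!strsplit(p, "")[[1]] %in% names(IUPAC_DNA))
  }, logical(1))
  if (any(bad)) {
    stop("invalid IUPAC code in catalog pattern(s): ",
         paste(cat$element[bad], collapse = ", "), call. = FALSE)
  }
  okcat <- c("growth_development", "phytohormone", "stress")
  if (any(!cat$category %in% okcat)) {
    stop("catalog categories must be one of ",
         paste(okcat, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# whether an instantiated (ACGT-only) string matches an IUPAC pattern
iupac_matches <- function(string, pattern) {
  s <- strsplit(string, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  if (length(s) != length(p)) return(FALSE)
  all(mapply(function(a, b) a %in% IUPAC_DNA[[b]], s, p))
}

#' Scan promoters for cis-acting elements
#'
#' IUPAC degenerate matching on both strands; all overlapping
#' occurrences are counted.  A hit on the reverse strand is reported at
#' its forward-coordinate offset.  `N` in the promoter sequence matches
#' nothing.  When `dedup_palindromes` is `TRUE` (default), a palindromic
#' pattern producing identical (offset, length) hits on both strands is
#' counted once (strand `+`).
#'
#' @param promoters named character vector or `DNAStringSet` of
#'   promoter sequences (A/C/G/T/N).
#' @param catalog data.frame from [read_cis_catalog()].
#' @param dedup_palindromes collapse identical two-strand hits.
#' @return list with `hits` (gene_id, element, category, offset 0-based,
#'   strand), `per_element` and `per_category` count tables.
#' @export
scan_cis_elements <- function(promoters, catalog,
                              dedup_palindromes = TRUE) {
  validate_cis_catalog(catalog)
  promoters <- as_named_character(promoters)
  if (is.null(names(promoters))) {
    stop("promoters must be named by gene id", call. = FALSE)
  }
  subj <- Biostrings::DNAStringSet(promoters)
  hits <- vector("list", 2 * nrow(catalog))
  flatten <- function(mindex, k, strand) {
    ir <- unlist(mindex)            # IRanges named by subject
    if (!length(ir)) return(NULL)
    gid <- names(ir)
    win <- substr(promoters[gid], BiocGenerics::start(ir),
                  BiocGenerics::end(ir))
    keep <- !grepl("N", win, fixed = TRUE)   # N matches nothing
    if (!any(keep)) return(NULL)
    data.frame(gene_id = gid[keep], element = catalog$element[k],
               category = catalog$category[k],
               offset = BiocGenerics::start(ir)[keep] - 1L,
               strand = strand, stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(catalog))) {
    pat <- Biostrings::DNAString(catalog$pattern[k])
    fwd <- Biostrings::vmatchPattern(pat, subj, fixed = FALSE)
    rev <- Biostrings::vmatchPattern(Biostrings::reverseComplement(pat),
                                     subj, fixed = FALSE)
    hits[[2 * k - 1]] <- flatten(fwd, k, "+")
    hits[[2 * k]] <- flatten(rev, k, "-")
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(gene_id = character(0), element = character(0),
                       category = character(0), offset = integer(0),
                       strand = character(0), stringsAsFactors = FALSE)
  }
  if (dedup_palindromes && nrow(hits)) {
    key <- paste(hits$gene_id, hits$element, hits$offset)
    ord <- order(key, match(hits$strand, c("+", "-")))  # "+" wins the tie
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(paste(hits$gene_id, hits$element,
                                   hits$offset)), , drop = FALSE]
    rownames(hits) <- NULL
  }
  per_element <- table(factor(hits$element, levels = catalog$element))
  per_category <- table(factor(hits$category,
                               levels = unique(catalog$category)))
  list(hits = hits,
       per_element = stats::setNames(as.integer(per_element),
                                     names(per_element)),
       per_category = stats::setNames(as.integer(per_category),
                                      names(per_category)))
}
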