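# Shared fixture cache: the genome-scale cp159 bundle takes ~30 s to
# generate, so all test files share one instance (seed 1) plus its
# identification products.

.fx_cache <- new.env(parent = emptyenv())

cp159_world <- function() {
  if (is.null(.fx_cache$world)) {
    fx <- make_fixture(preset_cp159(), seed = 1)
    profile <- build_profile(fx$truth$domains)
    members <- identify_family(profile, fx$proteins, fx$gene_models,
                               prefix = "CpbHLH")
    aln <- domain_alignment(members, fx$proteins)
    truth <- merge(members[, c("gene_id", "name")],
                   fx$truth$genes, by = "gene_id")
    .fx_cache$world <- list(fx = fx, profile = profile,
                            members = members, aln = aln,
                            truth = truth)
  }
  .fx_cache$world
}

tiny_world <- function() {
  if (is.null(.fx_cache$tiny)) {
    fx <- make_fixture(preset_tiny(9), seed = 7)
    .fx_cache$tiny <- fx
  }
  .fx_cache$tiny
}

# a noise-free all-G-box preset: domains are exact template copies, so
# every planted label must be recovered perfectly
preset_noisefree <- function(n = 6) {
  p <- preset_tiny(n)
  p$class_composition <- c("G-box" = as.integer(n), "E-box" = 0L,
                           "non-E-box" = 0L)
  p$mut_background <- 0
  p$keep_high <- 1
  p$keep_extreme <- 1
  p$expression$sd_log2 <- 0
  p$name <- "noisefree"
  p
}

# model-frame row with given residues at the binding positions
binding_row <- function(r9, r13, r16, r17, fill = "A") {
  row <- rep(fill, 79)
  row[c(9, 13, 16, 17)] <- c(r9, r13, r16, r17)
  paste(row, collapse = "")
}

random_rows <- function(n, width = 79) {
  vapply(seq_len(n), function(i) {
    paste(sample(famscan:::AA20, width, replace = TRUE), collapse = "")
  }, character(1))
}
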