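# Fixture presets: parameter bundles describing a synthetic
# genome + transcriptome + qPCR world with known truth.

#' Construct a fixture preset
#'
#' A preset fixes every count and rate of a synthetic fixture; the same
#' (preset, seed) pair always produces byte-identical files.  See
#' [preset_cp159()] for the versioned genome-scale preset.
#'
#' @param name preset name.
#' @param class_composition named integer vector over `G-box`, `E-box`,
#'   `non-E-box`; its sum is the number of valid members.
#' @param n_dup,n_trunc number of exact-duplicate and domain-truncated
#'   decoys among the putative proteins.
#' @param n_chromosomes number of pseudo-chromosomes.
#' @param subfamily_sizes named integer vector (label -> members);
#'   must sum to the number of valid members.
#' @param exon_counts integer multiset of exon counts, one per valid
#'   member (assignment to genes is seeded but favors
#'   `intronless_subfamilies` for single-exon genes).
#' @param intronless_subfamilies labels preferred for intronless genes.
#' @param expression expression design (see [synth_expression()]); built
#'   by the caller with cluster shapes, sizes, DEG overrides and
#'   unexpressed ranks.
#' @param go_salt_ranks member ranks annotated "response to salt stress".
#' @param qpcr qPCR design (see [synth_qpcr()]) expressed in member
#'   ranks (`rank_ratios`: matrix ranks x treatments).
#' @param mut_background per-site substitution rate at non-conserved
#'   domain columns relative to the subfamily signature.
#' @param keep_high,keep_extreme fraction of members keeping the
#'   consensus residue at highly / extremely conserved columns (applied
#'   as exact stratified counts so the planted conservation bands are
#'   deterministic).
#' @param trunc_columns number of trailing model columns removed from
#'   truncated decoys.
#' @param prefix family name prefix used downstream.
#' @return object of class `famscan_preset`.
#' @export
famscan_preset <- function(name,
                           class_composition,
                           n_dup = 0, n_trunc = 0,
                           n_chromosomes = 3,
                           subfamily_sizes = NULL,
                           exon_counts = NULL,
                           intronless_subfamilies = character(0),
                           expression = NULL,
                           go_salt_ranks = integer(0),
                           qpcr = NULL,
                           mut_background = 0.05,
                           keep_high = 0.65, keep_extreme = 0.90,
                           trunc_columns = 25,
                           prefix = "bHLH") {
  n_valid <- sum(class_composition)
  if (is.null(subfamily_sizes)) {
    subfamily_sizes <- stats::setNames(n_valid, "I")
  }
  if (is.null(exon_counts)) {
    exon_counts <- rep(2L, n_valid)
  }
  p <- structure(list(
    name = name,
    class_composition = class_composition,
    n_valid = n_valid,
    n_dup = n_dup, n_trunc = n_trunc,
    n_putative = n_valid + n_dup + n_trunc,
    n_chromosomes = n_chromosomes,
    subfamily_sizes = subfamily_sizes,
    exon_counts = as.integer(exon_counts),
    intronless_subfamilies = intronless_subfamilies,
    expression = expression,
    go_salt_ranks = go_salt_ranks,
    qpcr = qpcr,
    mut_background = mut_background,
    keep_high = keep_high, keep_extreme = keep_extreme,
    trunc_columns = trunc_columns,
    prefix = prefix), class = "famscan_preset")
  validate_preset(p)
  p
}

#' @keywords internal
validate_preset <- function(p) {
  cls <- c("G-box", "E-box", "non-E-box")
  if (!all(names(p$class_composition) %in% cls)) {
    stop("preset '", p$name, "': class_composition names must be ",
         paste(cls, collapse = "/"), call. = FALSE)
  }
  if (sum(p$class_composition) != p$n_valid) {
    stop("preset '", p$name,
         "': class composition must sum to n_valid (",
         sum(p$class_composition), " != ", p$n_valid, ")", call. = FALSE)
  }
  if (p$n_valid > p$n_putative) {
    stop("preset '", p$name, "': n_valid exceeds n_putative",
         call. = FALSE)
  }
  if (sum(p$subfamily_sizes) != p$n_valid) {
    stop("preset '", p$name, "': subfamily sizes sum to ",
         sum(p$subfamily_sizes), ", expected n_valid = ", p$n_valid,
         call. = FALSE)
  }
  if (length(p$exon_counts) != p$n_valid) {
    stop("preset '", p$name, "': exon_counts must have one entry per ",
         "valid member (", length(p$exon_counts), " != ", p$n_valid, ")",
         call. = FALSE)
  }
  if (any(p$exon_counts < 1)) {
    stop("preset '", p$name, "': exon counts must be >= 1", call. = FALSE)
  }
  if (!is.null(p$expression)) {
    ex <- p$expression
    bad <- intersect(ex$unexpressed_ranks,
                     ex$deg_design$rank %||% integer(0))
    if (length(bad)) {
      stop("preset '", p$name, "': unexpressed ranks overlap DEG ranks: ",
           paste(bad, collapse = ","), call. = FALSE)
    }
    if (sum(ex$cluster_sizes) + length(ex$unexpressed_ranks) !=
        p$n_valid) {
      stop("preset '", p$name, "': cluster sizes + unexpressed (",
           sum(ex$cluster_sizes), " + ", length(ex$unexpressed_ranks),
           ") must equal n_valid = ", p$n_valid, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' The versioned "cp159" genome-scale preset
#'
#' Mirrors the headline composition of a 21-pseudo-chromosome bHLH
#' family survey: 174 putative proteins of which 159 validate (the 15
#' removed split as 8 exact duplicates + 7 domain-truncated sequences),
#' binding-class census 93 G-box / 43 E-box / 23 non-E-box, exon counts
#' from 1 to 13 with 20 intronless (12.6%) and 13 one-intron genes, 26
#' subfamilies (largest 35, smallest 1), four salt treatments
#' (CK/LS/MS/HS) with 4 unexpressed genes (155 expressed) in 8
#' expression clusters, ten fold-change DEGs, three GO salt-annotated
#' genes (one overlapping the DEG set, union = 12 candidates), and a
#' 12-gene qPCR panel over CK/T1/T2.
#'
#' @return a `famscan_preset`.
#' @export
preset_cp159 <- function() {
  classes <- c("G-box" = 93L, "E-box" = 43L, "non-E-box" = 23L)

  subfam <- c(Ia = 6L, Ib1 = 5L, Ib2 = 5L, II = 5L, IIIa = 5L,
              IIIb = 5L, IIId = 6L, IIIe = 5L, IVa = 5L, IVb = 5L,
              IVc = 5L, IVd = 5L, Va = 5L, Vb = 5L, VI = 1L,
              VIIa = 5L, VIIb = 5L, VIIIa = 5L, VIIIb = 6L,
              VIIIc1 = 5L, VIIIc2 = 5L, IX = 5L, XI = 5L, XII = 35L,
              XIII = 5L, XV = 5L)

  exon_counts <- c(rep(1L, 20), rep(2L, 13),
                   rep(3:13, times = c(30, 25, 18, 14, 11, 9, 7, 5,
                                       4, 2, 1)))

  # Cluster mean profiles in log2 space relative to CK.  The eight
  # z-profiles form a square antiprism on the sphere the per-gene
  # z-scores live on (minimum inter-centroid z-distance 1.73), the
  # synthetic analogue of visibly distinct heatmap blocks; each shape
  # keeps a qualitative pattern of the emulated survey (A4/A5/A7 down
  # under salt, A6 induced at low salt, A1/A2 induced at high salt).
  shapes <- rbind(
    A1 = c(0, 0.620, 0.240, 1.000),
    A2 = c(0, -0.732, -0.268, 1.000),
    A3 = c(0, 0.732, -1.000, 0.268),
    A4 = c(0, -0.132, -0.220, -1.000),
    A5 = c(0, -1.000, 0.129, -0.886),
    A6 = c(0, 1.000, 0.886, -0.129),
    A7 = c(0, -0.620, -1.000, -0.240),
    A8 = c(0, 0.132, 1.000, 0.220))
  colnames(shapes) <- c("CK", "LS", "MS", "HS")

  expression <- list(
    treatments = colnames(shapes), control = "CK",
    shapes = shapes,
    cluster_sizes = c(A1 = 20L, A2 = 19L, A3 = 18L, A4 = 22L,
                      A5 = 19L, A6 = 19L, A7 = 20L, A8 = 18L),
    unexpressed_ranks = c(119L, 121L, 138L, 151L),
    # ten planted DEGs: amplitude scales the cluster shape so the gene
    # keeps its cluster's z-profile while its largest fold change
    # clears the 3-fold screen; rank 74 is the 9-fold-down outlier.
    deg_design = data.frame(
      rank = c(36L, 74L, 75L, 68L, 69L, 71L, 108L, 146L, 152L, 158L),
      cluster = c("A4", "A4", "A4", "A5", "A5", "A6", "A6", "A7",
                  "A7", "A7"),
      amplitude = c(2, log2(9), 2, 2, 2, 2, 2, 2.5, 2.5, 2.5),
      stringsAsFactors = FALSE),
    baseline_range = c(3.2, 6), amp_range = c(0.8, 1.05),
    sd_log2 = 0.08, unexpressed_range = c(0.05, 0.7))

  qpcr_ratios <- rbind(
    `36`  = c(1, 0.20, 0.40),
    `38`  = c(1, 1.20, 0.90),
    `68`  = c(1, 2.50, 4.00),
    `69`  = c(1, 0.80, 0.60),
    `71`  = c(1, 2.00, 3.00),
    `74`  = c(1, 0.50, 0.45),
    `75`  = c(1, 0.70, 0.40),
    `108` = c(1, 1.10, 1.30),
    `109` = c(1, 2.00, 3.50),
    `146` = c(1, 0.60, 0.25),
    `152` = c(1, 0.60, 0.25),
    `158` = c(1, 0.70, 0.30))
  colnames(qpcr_ratios) <- c("CK", "T1", "T2")
  qpcr <- list(rank_ratios = qpcr_ratios, treatments = colnames(qpcr_ratios),
               calibrator = "CK", reference_gene = "18sRNA",
               ref_ct = 15, base_dct = 8, n_bio = 3L, n_tech = 3L,
               sd_tech = 0.15, sd_bio = 0.1)

  famscan_preset(
    name = "cp159",
    class_composition = classes,
    n_dup = 8L, n_trunc = 7L,
    n_chromosomes = 21L,
    subfamily_sizes = subfam,
    exon_counts = exon_counts,
    intronless_subfamilies = c("IIId", "IIIe", "VIIIa", "VIIIb",
                               "VIIIc2"),
    expression = expression,
    go_salt_ranks = c(38L, 68L, 109L),
    qpcr = qpcr,
    prefix = "CpbHLH")
}

#' Minimal preset for fast tests
#'
#' @param n_valid number of valid members (>= 3).
#' @param n_dup,n_trunc decoy counts.
#' @return a `famscan_preset` with a single chromosome-triplet layout.
#' @export
preset_tiny <- function(n_valid = 9, n_dup = 0, n_trunc = 0) {
  n_g <- max(1L, n_valid - 2L * (n_valid %/% 3L))
  comp <- c("G-box" = n_valid - 2L * (n_valid %/% 3L),
            "E-box" = n_valid %/% 3L,
            "non-E-box" = n_valid %/% 3L)
  shapes <- rbind(A1 = c(0, 1, 0.5, 0), A2 = c(0, -1, -0.5, 0),
                  A3 = c(0, 0, 1, 1))
  colnames(shapes) <- c("CK", "LS", "MS", "HS")
  n1 <- n_valid %/% 3L
  n3 <- n_valid %/% 3L
  n2 <- n_valid - n1 - n3
  expression <- list(
    treatments = colnames(shapes), control = "CK", shapes = shapes,
    cluster_sizes = c(A1 = n1, A2 = n2, A3 = n3),
    unexpressed_ranks = integer(0),
    deg_design = data.frame(rank = integer(0), cluster = character(0),
                            amplitude = numeric(0)),
    baseline_range = c(3.2, 6), amp_range = c(0.8, 1.05),
    sd_log2 = 0.05, unexpressed_range = c(0.05, 0.7))
  famscan_preset(
    name = "tiny",
    class_composition = comp,
    n_dup = n_dup, n_trunc = n_trunc,
    n_chromosomes = 3L,
    subfamily_sizes = stats::setNames(
      diff(round(seq(0, n_valid, length.out = 4))), c("I", "II", "III")),
    exon_counts = rep(c(1L, 2L, 3L), length.out = n_valid),
    expression = expression,
    go_salt_ranks = integer(0),
    qpcr = NULL,
    prefix = "TbHLH")
}
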