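# Model-frame constants for the 79-column bHLH domain and the
# physicochemical tables used by compute_physchem().

#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Length of the model frame (columns of the domain alignment).
BHLH_MODEL_LENGTH <- 79L

# Model columns whose residues determine DNA-binding class.
BINDING_POSITIONS <- c(9L, 13L, 16L, 17L)

# Default annotation of the four structural regions of the domain.
# Boundaries are annotation-only: conserved residues sit at 9-17 (basic),
# 20-32 (helix 1), 64 (loop) and 65-79 (helix 2).
BHLH_REGIONS <- data.frame(
  region = c("basic", "helix1", "loop", "helix2"),
  start  = c(1L, 18L, 43L, 65L),
  end    = c(17L, 42L, 64L, 79L),
  stringsAsFactors = FALSE
)

# Conserved-residue template of the domain: 24 positions carry a
# consensus residue; tier "extreme" marks the most invariant subset.
BHLH_CONSERVED <- data.frame(
  pos = c(9L, 12L, 13L, 14L, 16L, 17L,
          20L, 21L, 23L, 27L, 30L, 31L, 32L,
          64L,
          65L, 66L, 67L, 69L, 72L, 73L, 75L, 76L, 77L, 79L),
  residue = c("H", "A", "E", "R", "R", "R",
              "I", "N", "R", "L", "L", "V", "P",
              "D",
              "K", "A", "S", "L", "A", "I", "Y", "V", "K", "L"),
  tier = c("high", "high", "extreme", "extreme", "extreme", "high",
           "high", "high", "high", "extreme", "high", "high", "extreme",
           "extreme",
           "high", "high", "high", "extreme", "high", "high", "high",
           "high", "high", "extreme"),
  stringsAsFactors = FALSE
)

# Basic-region columns not in the conserved list still show clear
# residue preferences in real families (the basic region as a whole is
# one of the four conserved regions); the generator plants a two-residue
# preference there, deliberately kept below the 50% consensus call.
BHLH_SEMICONSERVED_POS <- c(1L:8L, 10L, 11L, 15L)

# Average residue masses (Da) as used by the ExPASy ProtParam tool,
# plus one water per chain.  X gets the average over the 20 residues.
AA_MONO_AVG_MASS <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760
)
WATER_MASS <- 18.01524

# pKa set of the Bjellqvist scale as published by the ExPASy Compute
# pI/Mw tool.  Basic groups: N-terminus, K, R, H; acidic groups:
# C-terminus, D, E, C, Y.
PKA_BJELLQVIST <- list(
  nterm = 7.50, cterm = 3.55,
  K = 10.00, R = 12.00, H = 5.98,
  D = 4.05, E = 4.45, C = 9.00, Y = 10.00
)

# IUPAC nucleotide code expansion used by the cis-element scanner.
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
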