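---
title: "famscan: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{famscan: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`famscan` re-implements, as a tested and reusable pipeline, the standard
genome-wide characterization workflow for a plant transcription-factor
family — here the basic helix-loop-helix (bHLH) family — together with
the downstream screening of salt-stress response candidates:

1. profile-based detection of the 79-column bHLH domain in a proteome,
   with validation, de-duplication, chromosomal naming and
   physicochemical annotation;
2. model-frame conservation profiling and residue-rule prediction of
   DNA-binding class (G-box / E-box / non-E-box);
3. neighbor-joining phylogeny with bootstrap support and subfamily
   assignment against a labeled reference set;
4. exon/intron structure statistics and promoter cis-element scanning;
5. expression filtering, hierarchical clustering, fold-change DEG
   screening and the union with GO salt-annotated genes;
6. qPCR relative quantification (2^-ddCt) with one-way ANOVA and
   Duncan's multiple range test.

Everything runs on synthetic fixture bundles with complete ground
truth; no external databases, web services or aligners are touched.

# The domain model and scanner

The domain is modeled as a fixed 79-column frame partitioned into four
regions: basic (columns 1–17), helix 1 (18–42), loop (43–64) and helix 2
(65–79). Interior region boundaries are annotation-only and
configurable; the conserved residues that motivate them sit at 9–17,
20–32, 64 and 65–79.

Instead of a profile HMM, detection uses a position-specific scoring
model with affine gaps, built from any user-supplied 79-column seed
alignment (`build_profile()`):

    score(c, r) = log2( ((count_cr + k * bg_r) / (n_c + k)) / bg_r )

with pseudocount `k` (default 1) and background `bg` (default uniform).
`scan_sequence()` performs Smith–Waterman local alignment of a protein
against the model (Gotoh affine gaps, implemented in C++), reports
non-overlapping hits best-first, and records the matched model columns,
from which `align_to_model()` rebuilds the 79-character model-frame row
(insertions relative to the model are discarded).

Tunable parameters, with defaults and rationale:

* `threshold = 30` bits — genuine family domains score roughly 70–100
  bits against a family-derived model, while the best local alignment of
  a random 200-residue sequence stays far below 30; the default is
  roughly a third of a typical true-domain score. Published surveys of
  this kind use HMMER's default E-values without reporting a score
  cut-off, so this is a documented package default, not a reproduction.
* `min_cols = 10` — a hit must cover at least 10 model columns;
  suppresses spurious micro-alignments (and makes sub-10-residue inputs
  trivially hit-free).
* `min_covered = 70` of 79 — the "complete domain" rule used by
  `filter_and_dedup()`. The source analysis requires a "typical complete
  bHLH domain" without giving a number; 70/79 tolerates terminal
  raggedness of local alignment while rejecting seriously truncated
  sequences (the shipped truncation decoys lack 25 columns).
* redundancy = exact sequence identity, keeping the lexicographically
  smallest identifier (C collation, so the rule is locale-independent).

# Binding-class rule

Classes are decided solely by model positions 9, 13, 16, 17. The E-box
core is Glu-13 together with Arg-16. A G-box binder additionally has
His or Lys at 9 and Arg at 17. Breaking the core gives non-E-box.

The published three-way census (G-box / non-G-box / non-E-box) only
partitions the family if the G-box definition *includes* the E-box core
— a G-box (CACGTG) is a special E-box (CANNTG). The classifier
therefore applies the precedence G-box ⊃ E-box core; this is our
design reading of the rule, flagged rather than asserted as the original
authors' intent, and it is exhaustively enumeration-tested (any residue
combination receives exactly one class).

# Phylogeny

Distances are p-distances (mismatch proportion, pairwise deletion) on
the model-frame alignment — not on a full-length MSA — keeping every
column model-anchored and the operation oracle-testable. A substitution
correction can be layered on by the caller; none is applied by default
because the upstream analysis did not state one.

`neighbor_joining()` is the standard Saitou–Nei agglomeration with the
Q-criterion, ties broken by the lexicographically smallest joined name
pair, and negative branch-length estimates clamped to zero (flagged by a
warning). On additive matrices the tree metric reproduces the input
exactly; the test suite checks this against exhaustive topology
enumeration with least-squares fitting for 4–6 taxa.

`bootstrap_support()` resamples alignment columns with replacement and
reports, per internal bipartition of the full-data tree, the percentage
of replicate trees containing it. Supports of bipartitions never seen
in replicates are 0. The pipeline default is 100 replicates (runtime);
the published-analysis convention of 1000 is one config key away.

Subfamily labels come from a labeled reference set. The default
"nearest-reference" method assigns each member the label of its closest
reference row (ties across different labels give "unplaced"); a
"clade-majority" alternative walks up the joint NJ tree to the smallest
reference-containing clade. Nearest-reference is the default because it
is deterministic, fast, and exact on the fixture's truth.

# Gene structure and cis-elements

`parse_gene_models()` reads GFF3 (1-based inclusive on disk) and keeps
one primary transcript per gene: longest summed CDS, first on ties.
Exons are listed 5'→3' (descending coordinates on the minus strand);
intron count is exon count − 1 by construction. Percentages in the
family summary are rounded half-up to one decimal, denominator = family
size.

`scan_cis_elements()` matches IUPAC patterns on both strands, counts
all overlapping occurrences, reports reverse-strand hits at their
forward offsets, and treats `N` in the promoter as matching nothing.
Palindromic patterns would otherwise count twice per site, so identical
(offset, length) two-strand hits collapse to a single occurrence by
default (`dedup_palindromes = FALSE` restores double counting). The
element catalog is data, not code: a versioned TSV naming the classic
growth/phytohormone/stress elements (CAT-box, O2-site, ABRE, MBS, LTR,
…) with PLACE/PlantCARE-style consensus patterns. Absolute per-element
counts of any real genome are out of scope; the scanner's accounting is
validated against planted truth.

The promoter window is 2000 bp upstream in the synthetic world; real
analyses should set whatever window their annotation supports.

# Expression screening

* Filter: a gene is "expressed" iff abundance > `min_abundance`
  (default 1, the classic RPKM/FPKM > 1 rule) in at least one
  treatment; strict inequality.
* Normalization: `log2(x + 1)`.
* Clustering: per-gene z-scores, Euclidean distance, average-linkage
  agglomeration, tree cut at exactly `k = 8` clusters labeled `A1..Ak`
  in dendrogram-appearance order. The upstream tool's exact settings
  are unpublished; these defaults are conventional and configurable
  (`linkage`, `metric`, `k`).
* DEG rule: fold change `(t + 0.01) / (ck + 0.01)`; a gene is a DEG iff
  its maximum |log2 FC| over treatments reaches `log2(3)`. The 3-fold
  default matches the smallest fold change the source analysis calls
  out; replicate-level statistical testing is out of scope because
  per-replicate abundances are not available in that design. Note the
  pseudo-count makes a 9-vs-3 contrast a 2.9933-fold change — strictly
  below a 3-fold threshold; this boundary behavior is tested and
  documented rather than special-cased.
* Candidates: union of the DEG set and genes annotated with any
  configured salt term (default "response to salt stress"), with
  per-gene provenance (expression / GO / both).

# qPCR statistics

Technical replicates are averaged first; ΔCT = Ct_target −
Ct_reference per biological replicate; ΔΔCT subtracts the calibrator
treatment's mean ΔCT; the reported value is 2^−ΔΔCT (calibrator mean 1
by construction). Summary SDs are over biological replicates.

One-way ANOVA is the standard between/within decomposition; a
zero-MSE, unequal-means degenerate case reports F = ∞. Duncan's
multiple range test uses critical ranges

    R_p = q(1 − (1 − α)^(p−1); p, df) · sqrt(MSE / n_h)

computed from the studentized-range quantile (not printed tables) with
harmonic-mean group size for unequal `n` (with a warning). Two means
differ iff their gap exceeds `R_p` and no enclosing non-significant
span covers both; the compact letter display assigns one letter per
maximal non-significant span, highest mean lettered "a". The test
suite checks the display against a brute-force oracle that enumerates
every span straight from this definition.

# What the synthetic generator emulates — and what it does not

A fixture bundle is a self-contained "genome + transcriptome + qPCR"
world with truth labels for every stage. The versioned `cp159` preset
mirrors a published-scale survey: 174 putative proteins → 159 valid
members (8 exact-duplicate + 7 domain-truncated decoys) on 21
pseudo-chromosomes; binding census 93/43/23; 26 subfamilies (largest
35, smallest 1); exon counts 1–13 with 20 intronless (12.6%) and 13
one-intron genes; four treatments (CK/LS/MS/HS) with 4 unexpressed
genes, 8 expression clusters and ten planted DEGs (down to 9-fold);
three GO salt genes overlapping the DEG set in one gene (union 12); a
12-gene qPCR panel over CK/T1/T2 with 3×3 replication.

Design choices inside the generator worth knowing:

* **Domain columns are three-tiered.** The 24 conserved positions keep
  their consensus residue in an exact stratified fraction of members
  (ceiling(0.65·n) for the >50% tier, ceiling(0.90·n) for the >75%
  tier), so the planted conservation bands are deterministic, not
  merely expected. Non-conserved columns alternate between
  *subfamily-signature* columns (inherited within a subfamily, 5%
  per-site substitution — these carry the phylogenetic signal) and
  *preference* columns (a family-wide primary residue in 45% of rows
  and a secondary in 30%, deliberately below the 50% call threshold).
  A purely uniform background would leave local alignment free to trim
  uninformative domain termini, contradicting the stated world in which
  every valid member carries a complete domain; weak but real residue
  preferences at non-conserved columns are also what genuine family
  alignments look like. For the same reason at most two substitutions
  per member are allowed within the C-terminal conserved group.
* **Class residues are planted deterministically.** G-box: His-9,
  Glu-13, Arg-16, Arg-17. E-box: Arg-9 (a common non-His/Lys basic
  residue) and non-Arg-17, keeping the per-column census of His-9 and
  Arg-17 exact. Non-E-box: only Glu-13 is broken. Classes are decided
  by exactly the rule positions, so round-trip recovery is exact.
* **Expression amplitudes, not shape changes, encode DEGs.** Each
  cluster has a log2 shape over treatments (0 at control, max |offset|
  1); genes multiply it by an amplitude drawn from [0.8, 1.05], DEG
  genes by 2–3.17. Because clustering operates on per-gene z-scores,
  scaling leaves a gene's cluster profile invariant — DEGs stay in
  their host cluster while clearing the 3-fold screen with margin.
  Log-normal noise (sd 0.08 in log2) keeps non-DEG excursions ~5 sd
  below the threshold. Unexpressed genes draw all values in
  [0.05, 0.7], strictly below the filter.
* **Promoter backgrounds are scrubbed.** Elements are planted at ≥12 bp
  spacing (wider than any catalog pattern); background positions are
  then iteratively mutated until the only scanner matches lie inside
  planted intervals. Truth includes "implied" hits — windows inside a
  planted instance that happen to match another catalog pattern
  (e.g. every CGTCA instance is a TGACG match on the minus strand) —
  enumerated by a direct pure-R IUPAC window check, independent of the
  Biostrings-based scanner.
* **qPCR Ct values** are ref_ct + base ΔCT − log2(ratio) plus a shared
  per-sample effect (cancels in ΔCT), a per-gene biological effect
  (sd 0.1) and technical noise (sd 0.15). With all noise at zero the
  designed ratios are recovered exactly, to machine precision.

What the generator does **not** emulate: real residue composition and
indel structure (no gaps are planted inside member domains), codon- or
nucleotide-level sequence (gene models carry coordinates only,
promoters are i.i.d. background outside planted sites), chance promoter
motifs (scrubbed by construction), isoform complexity beyond one
decoyed second transcript, replicate-level RNA-seq variance structure,
or amplification-efficiency effects in qPCR. A green recovery test
therefore establishes that the pipeline's accounting and rules are
correct on a world where the truth is knowable — it does not establish
detection power on real genomes.

# Numerical choices and degenerate inputs

* Ties: consensus residue → alphabetical; NJ Q-criterion →
  lexicographically smallest name pair; duplicate collapse → smallest
  id (C collation); primary transcript → first-listed on equal CDS
  length; equidistant subfamily references → "unplaced".
* Zero-variance expression rows z-score to all-zero (they cluster
  together deterministically).
* pI is solved by bisection on the Henderson–Hasselbalch net charge to
  |charge| < 1e−4 (interval width 1e−6), with the Bjellqvist pKa set
  recorded in the package constants; `X` residues carry average mass
  and no charge.
* All randomness in the generator flows through one `set.seed(seed)`
  with fixed RNG kinds, so identical (preset, seed) pairs write
  byte-identical files.
* Negative NJ branch estimates are clamped to zero with a warning;
  bootstrap replicates that fail (no comparable columns for some pair)
  are skipped and count as non-support.

# Known limitations

* Full profile-HMM scoring (match/insert/delete states with
  probabilistic transitions) is intentionally out of scope; the PSSM
  scanner is the documented stand-in.
* p-distance saturates for highly diverged sequences; corrections are
  the caller's choice.
* The DEG rule is a fold-change screen, not an inferential test.
* The Duncan letter display assumes the range-test structure over
  sorted means (contiguous spans); it is not a general graph-coloring
  compact letter display.
* `run_pipeline()` rebuilds the profile from the supplied seed
  alignment; supplying a seed alignment unrelated to the proteins being
  scanned will validate nothing, by design.
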