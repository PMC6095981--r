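---
title: "Methods: isotype-resolved BCR repertoire analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotype-resolved BCR repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `isoclonal`, in the order the pipeline runs.

## The measurement model

Isotype-resolved BCR sequencing tags each cDNA molecule with a 15-nt
molecular barcode of the form `NNNNTNNNNTNNNNT` (conserved T at 1-based
positions 5, 10 and 15) before amplification, and reads each amplicon as a
paired-end fragment spanning, 5' to 3': barcode, the rearranged V(D)J
region, and the start of the constant gene that determines the isotype.
Errors enter at amplification and sequencing; because all reads sharing a
barcode descend from one molecule, a per-barcode consensus removes most of
them, and the disagreement rate within barcode groups estimates the
pre-correction error rate.

### Preprocessing conventions

- **Quality filter.** A pair is retained iff both mates have median Phred
  strictly greater than 34. The median of an even-length read is the mean
  of the two central values; thresholds here and elsewhere are strict.
- **Merging.** Mates merge iff they share an identical (zero-mismatch)
  overlap strictly longer than 50 bp; otherwise the pair is discarded. The
  offset search assumes the forward mate starts at or before the
  reverse-complemented mate, which holds whenever the amplicon is at least
  one read long — the geometry this library design guarantees. A
  consequence worth knowing: retained pairs have error-free overlap
  regions, so error-rate estimates taken downstream of merging sit below
  the instrument error rate. The consensus benchmark therefore runs on
  oriented full-length molecule copies (`emit_molecule_copies()`), the
  consensus builder's actual input contract.
- **Isotype call.** The last 60 bases of the oriented read are scored
  against the first 50 bp of each constant gene by shared-10-mer counting
  (41 windows); the call is the unique argmax, with ties and all-zero
  scores reported as ambiguous. The synthetic constant genes are generated
  with pairwise prefix Hamming distance of at least 5, which makes the
  argmax decidable for error-free reads.
- **Consensus and certainty.** "Sequence certainty" of a barcode group is
  defined here as the mean over positions of the fraction of reads
  matching the majority base — for two reads this equals their pairwise
  identity, and it is symmetric in the reads. Whether the original
  filtering used a per-position or a pairwise definition is not stated in
  the underlying protocol literature; this choice is documented, not
  asserted. Groups are retained at certainty strictly above 0.8;
  singletons have certainty 1 by convention. Majority ties break towards
  the lexicographically smallest base (A < C < G < T) for determinism.
  Groups with mixed read lengths keep only the modal length (ties towards
  the shorter); dropped reads are counted in the log.
- **Error estimate.** Mismatches of member reads against their group
  consensus divided by total member bases, over groups with at least two
  modal-length reads. With no multi-read group the estimate is undefined
  and returned as a flagged `NA`.
- **Frame/Ig filter.** A consensus is kept iff it aligns to some germline
  V (prefix) and J (suffix) at identity of at least 0.8 and its reading
  frame from the V start is open (no stop codon). Identity 0.8 is loose
  enough to pass heavily mutated BCRs (SHM rarely exceeds ~10% of the V)
  and strict enough to reject random sequence (~25% identity).

### Annotation

V and J are assigned by ungapped alignment anchored at the read ends
(primers and constant bases are trimmed by amplicon-design coordinates, so
the V starts at position 1 and the J ends at the last base). Ties break by
fewest mismatches, then name order. Indels are not modelled; a read whose
best identity falls below threshold is dropped and counted. Mutations are
counted within the aligned V region only — whether the original counts
included the junction is unknowable from the methods text, and the V
region is the comparable quantity across records. Counting is per codon:
every mutated base of a codon whose translated amino acid differs from
germline is non-silent; mutated bases of synonymous codons are silent.
Multi-hit codons therefore contribute all their mutated bases to one class,
and silent + non-silent = total holds identically. The CDR3 is translated
strictly between the conserved V-region cysteine codon and the J-region
tryptophan/phenylalanine codon; records whose anchors are mutated away are
flagged rather than guessed.

### Clonal networks

Vertices are unique V(D)J nucleotide sequences with summed read support and
unioned isotypes; edges are pairs of equal-length sequences at Hamming
distance exactly 1; clones are connected components. The contract is the
brute-force all-pairs definition; the implementation buckets by length and
enumerates pairs in compiled code with early exit, and the test suite
checks exact agreement with an independent R oracle on random fixtures.
Equal length is required — "non-indel differences" is read as excluding
any alignment with gaps. Networks are per sample.

## Statistics

All frequency and probability analyses run on *unique BCRs* — distinct
V(D)J nucleotide sequences per sample — because transcript counts per cell
differ by orders of magnitude across B-cell subsets (plasmablasts carry
>1,000-fold more BCR mRNA than naive cells) and would otherwise dominate
read-weighted statistics.

- **Isotype frequencies.** Percentage of unique-sequence presence events
  per isotype class; a sequence observed in k classes contributes k
  events, so percentages sum to 100. The alternative single-assignment
  denominator is available via the `weight` argument's read mode for the
  bias comparison.
- **Overlap coefficients.** Within each of 20 subsamples of 8,000 reads
  (drawn without replacement at the read level, seeded), every unique
  sequence observed in exactly two isotype classes increments its pair;
  pair counts are normalised to sum 1 and averaged over subsamples. IgM
  and IgD merge into one IgD/M class first. The source text defines the
  coefficient on "reads" while all other analyses use unique BCRs; this
  package counts unique sequences within each read-level subsample and
  notes the ambiguity rather than resolving it silently. Samples below the
  subsampling depth are computed in a single full pass and flagged.
- **Conditional switch probabilities.** Ratios of unique-BCR counts as
  given in the README, at gene or gene-family level, restricted to genes
  with more than 100 reads of support (and, for cohort-level isotype
  destination probabilities, presence in more than 5 samples). Zero
  denominators yield `NA` entries rather than fabricated zeros.
- **IGHV profiles.** Per-class gene frequencies over unique presences,
  genes under 100 reads excluded; correlations default to Spearman (the
  method used originally is unnamed; Pearson is available). The "2x2
  chi-squared test of non-randomness" against unmutated IgD/M is
  underspecified in the source; it is implemented as per-gene 2x2 tables
  (gene vs rest x class vs baseline, no continuity correction) with
  Benjamini-Hochberg correction, alongside the full genes-by-2 contingency
  test as the per-class summary p-value.
- **CLL partition.** Malignant = largest cluster (by reads; ties to the
  smallest cluster id, with a warning) plus identical-CDR3 records
  (amino-acid identity by default, per the figure legends; nucleotide
  available). Records sharing only a V-J combination are excluded from the
  non-malignant set but are not part of the leukemic definition, so they
  are quarantined in a third set; the three sets partition the sample
  exactly.
- **Cohort tests.** Wilcoxon rank-sum (normal approximation with
  continuity correction, so identical groups give p = 1 up to ties), and
  one-way / two-way ANOVA of per-sample conditional switch probabilities
  on gene and gene x mutational status with interaction.

## The simulator

The simulator provides the ground truth that every downstream stage is
tested against. It emulates:

- **Germline structure.** Random V/D/J segments and constant genes with
  the anchors and divergence constraints described above. V names carry
  families (IGHV1–IGHV5) for family-level statistics.
- **Clonal structure.** Naive cells are unexpanded single recombinations
  (IgM or IgD, no SHM) — a clone-size law for naive cells would be
  biologically meaningless, so the configured law (geometric by default,
  mean 1/p; power-law available) governs expanded germinal-centre clones.
  GC clones grow as a random recursive lineage: each daughter copies a
  random earlier member, adds Poisson SHM with probability `p_shm_step`,
  and draws a switch opportunity with probability `p_switch_step` from a
  row-stochastic transition matrix over the locus-ordered constant genes.
  Only diagonal and downstream entries may be positive, encoding
  deletional CSR; the matrix itself is a design addition (the source
  quantifies switch outcomes, not a transition model) needed for
  parameter-recovery testing. Switch events that leave the sequence
  unchanged are recorded — they are the ground truth behind isotype
  clonal overlap.
- **Cell types and RNA.** GC cells are plasmablasts with probability 0.06
  if switched and 0.005 otherwise (plasmablasts are rare, ~2% of B cells,
  and mostly switched); transcript copies default to 1 (naive), 4
  (memory), 1000 (plasmablast), encoding the >1,000-fold RNA excess.
- **Junctions.** 0–12 uniform N nucleotides on each side of the D segment,
  with the second insertion length drawn from the frame-compatible
  residue class so the J anchor stays in frame (out-of-frame
  rearrangements are removed during B-cell development and would only be
  discarded by the frame filter). Assembled junctions and all SHM
  proposals are resampled if they would create an in-frame stop codon,
  mimicking the loss of cells with nonsense BCRs.
- **Reads.** One barcode per molecule (globally unique by construction,
  16.7M possible), 1 + Poisson PCR copies, both mates read at length 210
  from amplicons constrained to guarantee an identical true overlap above
  50 bp. Substitution errors are i.i.d. per base at the configured rate,
  realised through a two-quality mixture (a 20% "noisy" fraction at low
  Phred, the rest at Q40) whose marginal equals the configured rate — this
  keeps Phred strings consistent with the error model while the median
  Phred stays above the quality filter's threshold, which a flat
  quality-to-error mapping could not do. At error rate 0 all bases are Q40
  and error-free. An optional dominant clone (CLL-like) is planted as a
  shallow star around a founder with steps of at most 1 nt, so it forms a
  single connected component holding a target fraction of all molecules.

What the simulator does *not* emulate: indel sequencing errors, chimeric
PCR artifacts, barcode collisions or sequencing errors inside barcodes,
SHM hotspot motifs (WRC/GYW bias), allele-level germline variation, light
chains, and biological isotype co-expression (each simulated cell carries
one isotype; IgD/IgM co-expression appears only at the clone level).
Passing tests therefore demonstrate correctness of the computations under
a clean generative model, not robustness to every artifact of real
libraries.

## Problem sizes and numerical choices

The test-suite and acceptance-script simulations use roughly 5,000
molecules for the noiseless round-trip, ~50,000 reads at 0.4% error for
the consensus benchmark, repertoires of 800–1,500 clones (~50,000–200,000
molecules) for overlap and normalisation experiments, ten replicate
repertoires of ~2,000 unique BCRs per gene for switch-probability
recovery, and twenty random fixtures of up to 500 unique sequences for the
clustering oracle — sizes at which the statistics of interest are
well-resolved while a full run stays comfortably interactive.

Determinism: every stochastic function takes an explicit seed and restores
the caller's RNG state; identical seed and configuration give
byte-identical FASTQ and TSV outputs. Floating-point identities
(probability normalisations, frequency sums) are exact by construction —
they are ratios of integer counts — and tested as such.

## Known limitations

- The annotator is ungapped; records with indels are dropped rather than
  realigned. This matches the non-indel edge definition but loses the rare
  real BCR with an in-frame junction indel.
- Unique-sequence counts inflate when single-read barcode groups retain
  sequencing errors; gene-level support filters (>100 reads) absorb most
  of this, but per-sequence analyses on singleton-heavy samples should be
  interpreted with care.
- The overlap coefficient's read-vs-unique ambiguity (above) means
  absolute coefficient values depend on the chosen convention; rankings
  across isotype pairs are the robust quantity.
- CLL partitioning anchors on the largest cluster; on a sample without a
  dominant clone the partition is still well-formed but the malignant
  label is meaningless, and the function warns.
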