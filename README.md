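# isoclonal

Isotype-resolved analysis of B-cell receptor (BCR) repertoire sequencing
data, from barcoded paired-end amplicon reads to clonal networks and
class-switch statistics.

B cells diversify their receptors through V(D)J recombination, somatic
hypermutation (SHM) and class-switch recombination (CSR). Isotype-resolved
repertoire sequencing reads each transcript together with its constant gene,
so the switch state of every clone member is observed directly. `isoclonal`
implements the full analysis chain for such data:

* **Barcode consensus error correction.** Each cDNA molecule carries a
  15-nt molecular barcode (`NNNNTNNNNTNNNNT`, conserved T at positions 5,
  10, 15). Reads are quality-filtered (median Phred > 34), merged on an
  identical overlap of more than 50 bp, oriented V-to-constant, isotyped by
  10-mer matching against the first 50 bp of the constant genes, and
  collapsed per barcode to a majority consensus retained at > 80%
  certainty. Mismatches among reads sharing a barcode estimate the
  pre-correction error rate.
* **Annotation.** A built-in ungapped aligner assigns germline V and J
  segments, counts silent and non-silent SHM per codon in the V region, and
  extracts the CDR3 between the conserved cysteine and tryptophan anchors.
* **Clonal networks.** Vertices are unique V(D)J nucleotide sequences;
  edges join sequences at Hamming distance 1 (single-nucleotide, non-indel
  differences); clones are connected components.
* **Repertoire statistics.** Unique-BCR isotype frequencies (normalising
  away per-cell RNA differences, e.g. the >1,000-fold plasmablast excess),
  CDR3/SHM summaries, isotype clonal overlap coefficients from 20
  subsamples of 8,000 reads, conditional class-switch probabilities
  P(switched | IGHV gene, mutation status), isotype-specific IGHV usage
  profiles with correlation and chi-squared non-randomness tests, Wilcoxon
  cohort comparisons and one/two-way ANOVA models.
* **CLL partitioning.** For chronic lymphocytic leukemia repertoires, the
  malignant compartment is the largest cluster plus all BCRs sharing its
  CDR3; records sharing only a V-J combination with it are quarantined from
  the non-malignant set.
* **A ground-truthed simulator.** Synthetic germline sets, clonally
  structured repertoires (naive singletons, geometric-size GC clones,
  downstream-only switch transitions, per-cell-type RNA copy numbers) and
  barcoded paired reads with i.i.d. substitution errors, with complete
  truth tables for every read, molecule, cell and switch event.

The key statistics, with `fx` counting unique BCRs:

```
P(Mutated|VgeneX)            = fx(VgeneX, >=1 V mutation) / fx(VgeneX)
P(Switched|VgeneX)           = fx(VgeneX in any switched isotype) / fx(VgeneX)
P(Switched|VgeneX, mutated)  = fx(VgeneX, switched, mutated) / fx(VgeneX, mutated)
P(IsotypeY|VgeneX, switched) = fx(VgeneX switched to Y) / fx(VgeneX, switched)
```

"Switched" means any isotype other than IgM/IgD; IgM and IgD are analysed
together (IgM reads are partly transcribed from IgD+ cells by alternative
splicing).

## Worked example

Simulate a healthy-style repertoire, emit barcoded reads at a 0.4% per-base
error rate, and run the full pipeline:

```r
library(isoclonal)

gs  <- make_germline_set(n_v = 10, n_d = 5, n_j = 4, seed = 1)
sim <- simulate_repertoire(gs, sim_config(n_clones = 300), seed = 42)
sim
#> SimRepertoire: 1396 cells in 300 clones (27985 molecules), seed 42

rd <- emit_reads(sim, gs, error_rate = 0.004, pcr_duplicates = 3, seed = 42)
pp <- preprocess_reads(rd, gs)
sprintf("pre-correction error rate: %.4f%%", 100 * pp$error_rate$rate)
#> "pre-correction error rate: 0.2316%"

airr <- annotate_bcrs(pp$consensus, gs, sample_id = "sim1")
net  <- build_network(airr)
net
#> ClonalNetwork: 7398 vertices, 7316 edges, 1813 clusters, 48424 reads

ut <- unique_bcr_table(airr)
switch_probabilities(ut, min_reads = 100)$gene[1:3,
  .(gene, fx, p_mutated, p_switched, p_switched_mutated)]
#>           gene    fx p_mutated p_switched p_switched_mutated
#> 1: IGHV3-sim08   791 0.9860936  0.6826802          0.6910256
#> 2: IGHV5-sim05   783 0.9897829  0.7560664          0.7638710
#> 3: IGHV1-sim01   945 0.9904762  0.7481481          0.7553419
```

Reading the numbers: 27,985 molecules were amplified into read pairs; after
merging and barcode consensus, 48,424 reads survive in retained barcode
groups. The estimated pre-correction error (0.23%) sits below the injected
0.4% because pair merging demands an identical overlap, which removes
errors from the overlap region before consensus; the consensus-correction
benchmark in `scripts/acceptance.R` therefore measures the estimator on
oriented molecule copies, its actual input contract, where it recovers
0.400%. Unique-sequence counts are inflated by residual errors in
single-read barcode groups — one reason downstream gene-level statistics
apply a >100-read support filter. The conditional probabilities show each
gene's mutated BCRs switching far more often than unmutated ones, the
pattern the two-way ANOVA in `switch_anova()` quantifies.

Isotype clonal overlap on the same sample:

```r
overlap_coefficients(ut, depth = 8000, n_sub = 20, seed = 42)
#> OverlapMatrix: 20 subsamples of 8000 reads
#>         IgD/M   IgG3 IgG1/2 IgA1/2   IgG4    IgE
#> IgD/M  0.0000 0.1538 0.3848 0.3238 0.0000 0.0000
#> ...
```

The largest coefficients sit on the IgD/M–IgG1/2 and IgD/M–IgA1/2 pairs:
direct switches out of the unswitched pool are the most common one-step
transitions, matching the simulator's transition matrix.

A multi-sample run (simulate, preprocess, annotate, cluster, summarise,
write TSVs and a JSON manifest) is one call:

```r
cfg <- pipeline_config(seed = 7, samples = data.frame(
  sample_id = c("h1", "cll1"), cohort = c("healthy", "CLL")))
run_pipeline(cfg, "out/")
```

or from the shell: `Rscript inst/scripts/run_pipeline.R config.yaml out/`.

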