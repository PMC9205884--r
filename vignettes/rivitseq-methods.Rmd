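---
title: "Methods: TSS calling, spike-in normalization and regulon assembly in rivitseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS calling, spike-in normalization and regulon assembly in rivitseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivitseq)
```

# The experiment this package analyses

A sigma factor is the dissociable RNA polymerase subunit that reads promoter
sequence. In the assay this package supports, a holoenzyme is reconstituted
in vitro from core RNA polymerase plus one purified sigma factor and allowed
to transcribe restriction-digested genomic DNA; a parallel reaction with core
enzyme alone serves as the no-sigma control, because the core enzyme
initiates non-specifically, most prominently at the ends of the digested
fragments. ERCC spike-in RNAs added after the reaction anchor all
cross-sample comparisons. Two sequencing readouts are produced per reaction:
a 5'-end library, whose read starts mark transcription start sites (TSSs),
and a whole-transcriptome library counted per gene. `rivitseq` starts from
the per-position 5'-end count tracks and the per-gene fragment-count matrix;
read trimming, alignment and counting are upstream of this package.

# TSS calling

5'-end positions observed in the sigma-sample replicates (pooled) are
processed per contig and strand:

1. **Clustering.** Single-linkage gap clustering: consecutive sorted
   positions with a gap of at most `cluster_window_nt` (default 100 nt,
   inclusive) share a cluster. This is the only parameter-free reading of
   grouping 5'-ends "within" a window, and it is checked in the tests
   against an exhaustive transitive-closure oracle.
2. **Subclustering.** A greedy scan in transcription direction (left to
   right on `+`, right to left on `-`) extends the current run while the
   *population* standard deviation (divide by *n*) of its positions stays
   strictly below `subcluster_sd` (default 10). Scanning in transcription
   direction rather than always left-to-right keeps the partition exactly
   strand-symmetric: mirroring all coordinates and strands mirrors the
   calls. Greedy scanning (rather than optimal partitioning) is
   deterministic and order-stable; singletons always qualify (SD 0).
3. **Calling.** The TSS of a subcluster is the member with the largest
   read count summed over the sigma replicates; ties go to the most
   upstream member in transcription direction, on the reasoning that the
   true initiation site precedes downstream degradation or stutter ends.
   The TSS count per replicate is the *sum* over all members, so total
   read mass is conserved — no reads are lost or duplicated by
   clustering, an invariant asserted in the tests.

Control-sample counts are looked up at the same member positions: the sigma
replicates define which positions exist, since the question asked of the
control is "how much signal does the core enzyme alone produce *here*".

# Spike-in normalization

Each spike-in transcript is represented as its own contig, so a single
track type holds genome and spike-in counts. A spike-in qualifies as a
normalization control when its first-nucleotide count is at least
`min_ercc_first_nt_reads` (default 10) in **all** replicates of **both**
conditions under comparison — the comparison is the analysis unit, so
controls are selected and factors computed jointly over the sigma and
no-sigma replicates. For each control the count relative to the maximum
across samples is computed; a sample's factor is the mean relative count
over controls, hence in (0, 1]. Each sample's counts are divided by *its
own* factor (the reading consistent with per-sample normalization; the
per-sample divisor is the only choice under which normalization is
monotone and scale-free per sample). Normalized counts stay real-valued:
the downstream abundance filter is a real comparison.

A TSS is dropped when its normalized count falls strictly below
`min_norm_count` (default 4) in at least one sigma replicate. Surviving
TSSs are sigma-dependent when both hold:

* (i) every sigma-replicate normalized count exceeds every
  control-replicate count, and
* (ii) the 2nd-lowest sigma-replicate count is at least
  `dependence_ratio` (default 4) times the **largest** control replicate
  ("at least four times as much as all the replicates" holds for every
  replicate exactly when it holds for the maximum).

Criterion (ii) needs at least two sigma replicates; the package enforces
this. Both thresholds are monotone: tightening either never enlarges the
dependent set (property-tested).

For the whole-transcriptome matrix the spike-in anchor is a
median-of-ratios size factor computed on the ERCC rows only (ratios to the
ERCC-row geometric means, per-sample median, rescaled to geometric mean 1).
This is a deterministic, self-contained contract; it deliberately does not
attempt unwanted-variation factor analysis.

# Differential transcription

Per gene, condition means are taken on size-factor-normalized counts and
compared as `log2fc = log2((m_sigma + 0.5) / (m_ctrl + 0.5))`; the 0.5
pseudocount keeps genes expressed in only one condition defined. The test
is a Wald statistic `log2fc / SE` with a delta-method SE under the NB
variance `mu + alpha * mu^2` evaluated on the normalized scale, which makes
results exactly invariant to rescaling a sample together with its size
factor.

**Dispersion.** With two replicates per condition a purely genewise moment
estimate of `alpha` has one degree of freedom per condition; plugging it
into a normal-reference Wald test is badly anticonservative (we measured a
null rejection fraction of ~0.11 at nominal 0.05 in an NB simulation with
dispersion 0.05), while referring the same statistic to t(2) overcorrects
to ~0.01 and destroys power. `rivitseq` therefore shrinks the genewise
moment estimate toward a **common** dispersion estimated from all genes
jointly by the pooled ratio estimator `sum(s2 - m) / sum(m^2)` over
within-condition variances (genes with mean >= 1), with prior weight 10
against the genewise residual degrees of freedom, floored at 0.01. Only
within-condition variances enter, so true expression differences do not
inflate the estimate. This is shrinkage toward a constant, not toward a
fitted mean-dispersion trend; trend modelling is out of scope. Under the
package's own calibration test (2000 null genes, n = 2+2, dispersion 0.05)
the null rejection fraction lands inside the 99% binomial envelope of
0.05, and planted 4-fold genes at mean >= 50 are recovered at >= 90% with
default thresholds.

P values are BH-adjusted across the testable genes of one
sigma-versus-control contrast; all-zero genes are flagged not testable and
excluded from adjustment, as are the spike-in rows (they are the
normalization anchor, not hypotheses). A gene is *upregulated* when its
fold change is at least `fc_threshold` (default 2, inclusive) and its
adjusted P is below `padj_threshold` (default 0.01, strict).

# Target integration

A gene is a **direct target** when it is upregulated and at least one
sigma-dependent TSS lies on the same contig and strand within
`upstream_window_nt` (default 300 nt) of its initiation codon, measured in
transcription direction. Distance 0 qualifies: leaderless transcripts
starting at the initiation codon are common in actinobacteria. A TSS
falling inside another gene's coding span still qualifies but is flagged
in the output (`tss_within_gene`), since the biology is ambiguous there.

**Operon extension** iterates to a fixed point: an upregulated gene whose
initiation codon lies at most `operon_gap_nt` (default 50 nt) downstream
of the 3' end of an existing target on the same strand becomes an
operon-extended target, and can itself extend the chain. The gap is
`(downstream start) - (upstream 3' end) - 1` in transcription direction;
negative gaps (overlapping ORFs, also common in operons) qualify. A single
pass would arbitrarily truncate polycistronic operons; the fixed point is
order-independent, which the tests assert under permutation of the input.

# Promoter windows and motif filtering

For motif discovery the package extracts, per dependent TSS, the
`promoter_window_nt` (default 50) nucleotides ending at and including the
TSS, reverse-complemented on the minus strand. Fifty nucleotides
comfortably contain a -35 element, an 18-19 nt spacer and a -10 element;
the exact window is configurable since no single value is canonical.
Motif discovery itself (MEME or similar) is external. Its output is
filtered with the rules: width 22-35 nt inclusive, present in at least 10
sequences, E-value strictly below 1e-5; the retained motif with the
smallest E-value is the consensus. E < 1e-8 is annotated as a
high-confidence tier but never used as a filter.

# Networks and crosstalk

Target tables from one or more sigma factors (optionally merged with prior
known edges, provenance-tagged) form a directed sigma-to-gene network,
exported as SIF and GraphML. Two crosstalk matrices summarize pairwise
sharing: shared-regulon counts (set intersection of target genes; diagonal
= regulon size) and shared-TSS counts. TSS sharing uses one-to-one
matching of sorted position lists per contig/strand — walk both lists in
ascending order, pair positions within `shared_tss_tolerance_nt`, advance
the smaller otherwise — which is symmetric by construction and prevents
double counting in dense regions. Tolerance 0 (exact sharing) and 2 nt
(the precision with which independent experiments typically reproduce a
TSS) are the two documented presets; 2 is the default.

# The synthetic-data generator

`simulate_rivit()` generates a complete experiment with known truth:

* a random 100 kb contig carrying 60 non-overlapping genes on both
  strands, including 3 co-oriented adjacent pairs with 20-40 nt gaps
  (operon-like);
* restriction-fragment ends at every EcoRI/HindIII/BamHI/XhoI site,
  receiving boosted NB counts on *both* strands in *both* conditions
  (end-initiation by the core enzyme is not strand-specific and does not
  need sigma);
* NB background (mean 3) at 150 random positions per strand, shared
  across replicates of both conditions;
* a planted regulon of 15 genes at 4-fold expression: 12 direct targets
  with NB(mean 100) TSSs placed 20-250 nt upstream of their initiation
  codons (counts spread 15/70/15% over TSS +- 1 nt to emulate ragged
  5'-ends), plus 3 operon children with no TSS of their own; 8 further
  intergenic TSSs are planted away from every gene's upstream window;
* 92 spike-in transcripts with log-spaced abundances spanning 1-150
  (about 2 first-nucleotide reads per abundance unit), each a separate
  contig;
* a per-sample library efficiency drawn uniformly from [0.5, 1] that
  scales *every* count of a replicate — exactly the distortion the
  spike-in factors are designed to remove;
* an NB fragment-count matrix (gene base means log-uniform on [20, 500],
  dispersion 0.05, two replicates per condition — the minimum the
  dependence criteria admit, and the realistic budget for this assay).

Everything is deterministic under a single integer seed (R's default
integer-state generator; sub-seeds are drawn once for genome, placement,
tracks and matrix so components can be regenerated independently).

**What the generator does not emulate:** sequence-dependent promoter
strength, RNA degradation and processing ends, mapping artefacts,
transcript-length effects in fragment counting, and batch structure beyond
a scalar efficiency. Passing the end-to-end tests therefore demonstrates
the pipeline's logic and thresholds on data with the right statistical
shape, not performance on real libraries.

# Numerical and degenerate-input choices

* Coordinates are 1-based, fully closed, strand-explicit everywhere;
  bedGraph (0-based half-open) is converted at the boundary only, and the
  conversion preserves total read mass (tested).
* Duplicate positions in a track file are an error, never summed:
  upstream counters emit unique positions, so duplicates indicate
  corruption.
* Empty clusters/tracks/files yield empty results, not errors; an empty
  spike-in control set is a hard error advising a lower threshold, since
  normalization is impossible.
* Ties in the TSS argmax resolve upstream in transcription direction;
  ties in consensus-motif selection resolve by E-value then motif id.
* All-zero genes are not testable; single-spike-in or zero-containing
  spike-in-only matrices are hard errors for size factors.

# Problem sizes used by the test-suite

The tests run 500 random clustering instances (up to 50 positions each)
against the exhaustive oracle, a 2000-gene null and a 2000-gene
planted-fold-change calibration of the differential test, and one full
default simulation (60 genes, 20 planted TSSs, 15-gene regulon) end to
end; these sizes give stable pass/fail behavior at interactive runtimes.

# Known limitations

* With a shared background site within the subcluster SD range of a true
  TSS (roughly 20 nt at the default SD bound), the background counts
  merge into the TSS call and dilute its sigma-to-control ratio; a
  sufficiently strong nearby background site can push a genuine TSS below
  dependence criterion (ii). This mirrors the real assay, where
  core-enzyme background obscures weak promoters.
* At two replicates per condition a true 4-fold gene occasionally
  realizes a sample fold change below 2 and is honestly missed; the
  fold-change threshold, not the test, is then the binding constraint.
* The dependence criteria are threshold rules, not a calibrated test; no
  error rate is attached to a "dependent" verdict.
* Operon extension assumes annotated gene boundaries; it cannot recover
  targets whose operon parent is itself unannotated.
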