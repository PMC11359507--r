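---
title: "Comparative phage genomics with phamkit: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative phage genomics with phamkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phamkit)
```

# The problem

Tailed dsDNA bacteriophage genomes are pervasively mosaic: any two phages
may share most, some, or none of their genes, and the genes they do share
may range from identical to barely recognizable. Illegitimate
recombination keeps shuffling gene content, so no single tree describes
the population and simple hierarchical classification breaks down.
Practical comparative genomics in this field therefore rests on a few
robust quantities:

* **Phams** (gene phamilies): classes of homologous protein-coding
  genes, built by thresholded pairwise amino-acid similarity with
  single-linkage closure. A pham with a single member is an *orpham*.
* **GCS** (gene content similarity): for a genome pair, the fraction of
  each genome's genes whose pham occurs in the partner, averaged over
  both directions, as a percentage.
* **PEQ** (proteomic equivalence quotient): a single 0–100 value that
  combines the shared-gene proportion with the amino-acid identity of
  the shared homologues (defined below).
* **gNI** (genome-wide nucleotide identity): the percentage of identical
  bases across significant local nucleotide alignments, normalized over
  both genome lengths; exactly 0 when nothing passes the significance
  filter.

Thresholding a PEQ matrix at 25% reproduces the community's "cluster"
groupings and at about 60% its "subclusters"; a 50% gNI criterion
approximates genus-level groupings in ICTV taxonomy. phamkit implements
this whole stack — annotation I/O, pham assembly, the four metrics,
threshold clustering, taxonomy concordance, Phamerator-style maps — plus
a synthetic mosaic-genome simulator so that every step is testable
offline with planted ground truth.

# The PEQ definition used here

Published descriptions state that shared-gene proportion and homologue
identity are "distilled into a single value" without printing a formula.
phamkit uses the simplest definition consistent with everything that is
stated, and isolates it in one function (`peq()`) so it can be swapped
if a different normalization is preferred:

$$\mathrm{PEQ}(a,b) \;=\; 100\,
\frac{\sum_{\text{paired homologues}} (l_i^a + l_i^b)\, \mathrm{id}_i}
     {\sum_{\text{all genes of } a,b} l_g}$$

where homologues are paired within each shared pham by greedy
best-identity bipartite matching (leftover paralog copies stay
unpaired; ties broken by gene id), $l$ are amino-acid lengths and
$\mathrm{id}_i$ the pairwise identity of a paired homologue. Properties
that follow directly: PEQ is symmetric; PEQ = 100 exactly for identical
proteomes; PEQ = 0 exactly when no pham is shared; every unshared gene
contributes identity 0, so PEQ is bounded above by the shared length
fraction. This makes PEQ behave like a length-weighted AAI penalized for
content differences — the property that makes a single threshold usable
for both content-divergent and sequence-divergent pairs.

# Pairwise protein identity

`proteinIdentity()` computes an ends-free global alignment (BLOSUM62,
gap open 10, gap extend 0.5, via `Biostrings::pairwiseAlignment`) and
reports identity = identical aligned residues / alignment columns
(terminal gaps excluded; `X` never counts as a match, even against `X`)
and coverage = aligned residues of the shorter sequence / its length.
Arguments are ordered canonically before aligning, so the function is
exactly symmetric even where the optimizer would otherwise break ties
differently.

# Pham assembly

`buildPhams()` runs in three stages:

1. **k-mer prefilter** — candidate pairs are pairs of proteins whose
   5-mer-set Jaccard similarity reaches 0.05, computed for all pairs at
   once from a sparse k-mer-by-gene incidence matrix. Setting
   `minKmerJaccard = 0` disables the prefilter (all pairs aligned),
   which is how the prefilter's soundness is tested.
2. **alignment verification** — candidates with identity ≥ 0.35 and
   coverage ≥ 0.80 become edges.
3. **single-linkage closure** — phams are the connected components of
   the verified-edge graph. Components are ordered by their
   lexicographically smallest `genome:gene` key and numbered from 1, so
   pham ids are invariant under permutation of the input.

Defaults (0.35 / 0.80 / k = 5 / 0.05) are deliberately permissive:
pham semantics are transitive ("related to one another"), and the cost
of splitting a true phamily is higher than occasionally chaining two.
All four knobs are exposed. The prefilter bounds what the assembler can
see: with k = 5 and Jaccard 0.05, pairwise identities much below ~0.63
are invisible *directly* and must be bridged through intermediates.
This matters when interpreting planted-divergence simulations (below).

# Nucleotide-level comparison

`findHsps()` is a transparent seed-and-extend local aligner: exact
11-mer seeds on both strands, ungapped X-drop extension (match +1,
mismatch −2, X-drop 20), greedy merge of overlapping extensions on a
diagonal, and a Karlin–Altschul E-value filter
$E = K m n e^{-\lambda S}$ with the classic ungapped parameters
$\lambda = 1.28$, $K = 0.46$ for +1/−2 scoring. The E-value is a
significance *filter* (default 1e−4, the conventional threshold for map
shading), not a reported statistic, so modest parameter error only
perturbs borderline segments. There is no gapped extension; the +1/−2
economics mean extension dies once local identity drops below about
2/3, which is what makes "0% nucleotide similarity" a meaningful,
exactly-zero outcome for diverged pairs.

`gni()` runs the scan with each genome as query and as subject,
projects every passing HSP onto each genome, resolves overlapping
projections by keeping higher-identity fragments (prorating identities
over the still-uncovered part), and normalizes the summed identities by
the two genome lengths. Normalizing over both lengths (rather than the
shorter) keeps gNI ≤ 100 under duplications and makes the measure
symmetric by construction.

# Clustering and taxonomy concordance

`thresholdClusters()` builds the graph with an edge wherever the
similarity reaches the threshold and reports connected components —
single linkage again, the only parameter-free closure of a pairwise
criterion. Multi-member components are labelled A, B, … (size
descending, then smallest member id); singletons are labelled
`"singleton"`. `assignSubclusters()` re-runs the same machinery inside
each cluster at the higher threshold and numbers the parts (A1, A2, …)
only if the cluster actually fragments. Because raising the threshold
can only remove edges, clustering at 60 provably refines clustering at
25, and `clusterCountCurve()` is non-decreasing.

`gapfillRanks()` makes the taxonomic hierarchy explicit: a named taxon
whose parent rank is unnamed receives a deterministic placeholder
parent (`unnamed_<rank>_<taxon>`), so co-membership at a low rank
implies co-membership at every higher rank, named parents found
elsewhere in the table are reused, given names are never overwritten,
and the operation is idempotent. `intraRankValues()` then enumerates
exactly the unordered co-assigned pairs (self-pairs excluded), and
`concordanceSummary()` reports per-rank pair counts, the fraction of
pairs at ≥ 50 (the informal genus-level identity criterion), the
fraction at exactly 0, and fixed-edge histograms
([0,5), [5,10), …, [95,100] — the closed last bin absorbs values of
exactly 100). Bin width 5 is an implementation choice. When both a gNI
and a PEQ matrix are supplied it also returns the all-pairs scatter and
a least-squares fit (slope, intercept, Pearson R²).

# Comparison maps

`renderComparisonMap()` renders SVG: per genome a ruler with 100-bp
ticks and kbp labels; genes as boxes above (+) or below (−) the ruler,
filled by a deterministic hash of the pham id into a fixed 20-colour
palette with orphams white; the pham number and member count above each
box; putative functions when present; and between consecutive rulers a
shaded quadrilateral per HSP passing the E-value filter,
spectrum-coloured from violet (hue 270°, identity 1.0) linearly to red
(hue 0°) at the lowest identity displayed. SVG was chosen over raster
output precisely so these display rules are text-assertable in tests;
zoomed views are a coordinate-window option on the same renderer. The
hash palette is a stand-in for the (unpublished) historical colour
assignment.

# The synthetic mosaic simulator

`simulateDataset()` plants the structure all other modules are tested
against. Per source pham it draws an ancestral protein (lognormal
length, median 180 aa with a 50-aa floor — phage genomes are dominated
by relatively small genes) and back-translates it **once** with uniform
synonymous codons; descendants inherit those codons. Each genome then:

* inherits the cluster's core phams (`coreFraction`, default 0.8 of its
  30 genes) plus a per-genome draw from a 3×-larger accessory pool;
* substitutes amino acids iid at `aaDivergence` (default 0.05), with
  the affected codon re-drawn uniformly for the new residue (position 1
  stays M so genes keep canonical starts);
* receives iid nucleotide noise at `ntDivergence` (default 0.02) on top
  — so nucleotide sequences diverge faster than proteins, reproducing
  why protein-level homology stays detectable across longer
  evolutionary distances than nucleotide similarity;
* gains Poisson(`hgtRate` = 1) horizontal insertions from a global
  foreign pool shared by all clusters (the mosaic signal).

Gene order, per-slot transcription strand, and the downstream
intergenic spacer (50 bp) are properties of the ancestors and are
inherited, so a zero-divergence dataset is byte-identical across
cluster members — which pins the trivial limits (all metrics exactly
100) and makes seed determinism testable. All randomness flows from one
seed through R's Mersenne-Twister generator.

Stored translations are the diverged proteins and are authoritative for
pham assembly; the nucleotide noise is *not* re-translated (it may even
introduce in-frame stops), modelling annotation-independent
nucleotide-level divergence. Consequently GFF3 round-trips — which must
re-derive translations from the sequence — are only exact for
`ntDivergence = 0` datasets; GenBank round-trips carry translations
explicitly and are always exact.

With two subclusters per cluster, each subcluster ancestor first
diverges from the cluster ancestor at `subclusterDivergence` and draws
accessory genes from a subcluster-private pool. The default of 0.15 was
calibrated to the intended three-band structure (intra-subcluster PEQ
≈ 65–80, cross-subcluster ≈ 40–55, cross-cluster ≈ 0): deeper
subcluster divergence (e.g. 0.2) drops cross-subcluster identity below
what the k-mer prefilter can detect, phams stop bridging the
subclusters, and the planted object degenerates into separate clusters
rather than a two-level hierarchy.

What the simulator does *not* model: indels (alignment-gap robustness
is exercised by hand-built cases instead), recombination breakpoints,
selection, codon bias, tRNAs, and prophage/host context. Passing tests
on this generator therefore demonstrate correctness of the metrics and
clustering machinery under controlled divergence and mosaicism — not
performance on the full messiness of real annotations (variable gene
callers, missed small genes, contaminated records).

# Problem sizes and numerical choices

The test and verification conditions are deliberately desk-scale,
chosen once:

* default study condition: 4 clusters × 5 genomes (20 genomes, ~19 kbp,
  ~31 genes each);
* nested condition: 2 clusters × 2 subclusters × 3 genomes;
* divergence sweep: 9 divergence levels at 0.01–0.20, one cluster of 2
  genomes × 12 phams each, with `ntDivergence` tied to `aaDivergence`;
* HSP verification: 50 seeded pairs ≤ 2 kbp against a quadratic-time
  per-diagonal maximum-segment oracle; prefilter-off pham assembly
  against an all-pairs union-find oracle on 200 proteins.

Numerical conventions worth stating: internal gene coordinates are
0-based half-open on the forward strand (conversion to the 1-based
inclusive GenBank/GFF3 convention happens only at I/O boundaries);
ambiguity characters are rejected, not masked; ORF calling keeps the
longest ORF per stop codon with starts {ATG, GTG, TTG} under
translation table 11 and no RBS model (the choice of gene caller is
essentially arbitrary for consistency-based comparisons, so a
transparent deterministic stand-in is preferred); circular reorientation
to a minus-strand anchor is refused (undefined which end should become
coordinate 1), as is an anchor that would make another gene span the
origin; similarity ties in homologue pairing and component ordering are
broken lexicographically so every output is permutation-invariant.

# Known limitations

* PEQ depends on annotation uniformity: a gene annotated in one genome
  but not its partner lowers PEQ even if the sequence is present. For
  near-identical genomes, gNI is the more robust measure. Re-annotating
  all genomes de novo (`callOrfs()`, or an external caller) before
  comparison avoids the worst of this.
* E-values are approximate by design (fixed Karlin–Altschul parameters,
  ungapped scores) and are not comparable to BLAST-reported values.
* The ORF caller is a stand-in; it has no start-site model and will
  over-call long ORFs on the shadow strand.
* No metric here can reproduce family-level taxonomy: higher-rank viral
  placement uses non-genomic evidence (morphology, packaging), and
  almost a third of intra-family pairs can share no detectable
  nucleotide similarity at all.

# Using the pipeline

```{r, eval = FALSE}
dir.create("project")
runPipeline("project", config = list(seed = 42))
read.delim("project/clusters.tsv")
```

Stages read and write only documented flat artifacts (TSV/FASTA/SVG) in
the project directory; `manifest.json` records the package version, a
hash of the effective configuration, and checksums of every artifact.
Reruns of an unchanged project are byte-identical. The same stages are
available from a shell via the `inst/scripts/phamkit` wrapper.
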