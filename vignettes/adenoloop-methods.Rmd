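---
title: "Methods: dual-genome ChIA-PET analysis of an episomal vector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-genome ChIA-PET analysis of an episomal vector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`adenoloop` analyses chromatin-interaction (ChIA-PET) data mapped to a
combined reference: host chromosomes plus one episomal adenoviral vector
sequence (by default "AdP53", a 35,722 bp recombinant adenovirus carrying
wild-type TP53). A paired-end tag (PET) is two genomic anchors marking loci
that were ligated in spatial proximity; the immunoprecipitated factor (p53
or RNAPII) defines the channel. Every PET falls into exactly one of four
classes given the genome model: `intra_vector`, `vector_host`,
`intra_host_cis`, `intra_host_trans`.

The pipeline has five analysis layers:

1. **Loop calling** (`cluster_pets`): anchors are extended, two PETs are
   linked when *both* extended anchor pairs overlap by at least 1 bp, and
   loops are the connected components of that link (single-linkage
   transitive closure). The loop anchors are the union span of the member
   extended anchors and the PET count is the component size.
2. **Contact maps** (`bin_contacts`, `kr_balance`,
   `observed_over_expected`): symmetric midpoint-binned count matrices,
   Knight–Ruiz balancing to unit row sums, and per-diagonal
   observed/expected normalisation.
3. **Insulation segmentation** (`insulation_score`, `call_boundaries`,
   `segment_region`): sliding-square insulation, significant local minima
   as boundaries, segments tiling the region — used both for the vector's
   internal blocks (500 bp bins) and for host TADs (25/50/100 kb).
4. **Compartments** (`compartment_eigenvector`): the eigenvector of the
   Pearson correlation matrix of O/E columns with the largest-magnitude
   eigenvalue, sign-oriented by a gene-density-like track; A = positive.
5. **Gene association and expression** (`associate_genes`,
   `compare_gene_set`): from high-confidence vector–host loops to
   associated host genes with evidence classes, their chromatin-state
   composition, and paired t-tests of the associated gene set's FPKM
   across conditions.

# Coordinate and overlap conventions

All coordinates are 0-based half-open (`[start, end)`), the BED/BEDPE
convention; IRanges/GenomicRanges do the interval work internally with the
one-off shift applied at the boundary. "Overlap" always means at least one
shared bp — abutting half-open intervals do **not** overlap, and interval
merging (`merge_intervals`, `reduce` with `min.gapwidth = 0`) keeps abutting
intervals separate.

Anchor ordering is canonical: anchor 1 ≤ anchor 2 by (sequence index,
start), with the vector sequence sorting after all host chromosomes. A
vector-host PET therefore always carries the host locus in anchor 1, which
the association layer relies on.

# Parameters and defaults

| Parameter | Default | Unit | Why |
|---|---|---|---|
| span filter, host & vector-host channels | > 8,000 | bp | removes self-ligation products before clustering |
| span filter, intra-vector | > 600 | bp | the vector is only 35,722 bp; a shorter floor is required |
| anchor extension, host channels | 500 | bp | tolerance for anchor scatter when linking PETs |
| anchor extension, intra-vector | 0 | bp | vector anchors are dense; no extension needed |
| high-confidence loop count | > 4 | PETs | loops with ≥ 5 PETs are treated as reproducible contacts |
| promoter extension | 2,000 | bp | strand-aware upstream margin for gene association |
| vector map resolution / window | 500 / 2,500 | bp | 72 bins over the vector; 5-bin insulation square |
| TAD resolutions | 25, 50, 100 | kb | multi-resolution TAD comparison, each reported independently |
| insulation window (host) | 10 × resolution | bp | standard sliding-square width |
| compartment resolution | 500 | kb | megabase-scale A/B structure |
| boundary prominence `delta_min` | 0.1 | log2 | rejects shallow noise dips |
| boundary significance | p < 0.05 | — | one-sided rank-sum, within vs cross contacts |
| top-percent baselines | 1 | % | strongest peaks / loop anchors as composition baselines |

PET span is the absolute distance between anchor **midpoints**
(`floor((start+end)/2)`). The upstream toolchain does not pin down whether
span is midpoint-, inner- or outer-edge distance; midpoints are robust to
anchor width and are used throughout. Spans are undefined across sequences,
so vector-host PETs bypass the span filter (they cannot be self-ligation
artefacts) and are clustered directly with the 500 bp extension.

"More than 4 PETs" is read literally as strict (`> 4`, i.e. ≥ 5). The
count filter is applied to both channels' loops — p53-mediated vector-host
loops and RNAPII intra-host loops — before any anchor-overlap filtering, so
both channels contribute only high-confidence contacts.

# Numerical choices

**Insulation score.** For each interior bin boundary with a full window on
both sides, the raw statistic is the mean contact count in the
`window × window` square spanning the boundary. Scores are `log2` of the
raw statistic normalised by the *geometric* mean over all defined
boundaries, which makes the defined track mean exactly 0 by construction.
Boundaries whose square is empty are masked rather than scored.

**Boundary significance.** A candidate boundary is a local minimum of the
insulation track whose prominence (the smaller rise to its flanking local
maxima) reaches `delta_min`. It is retained when a one-sided Wilcoxon
rank-sum test finds the within-side contacts (the two triangles flanking
the boundary, diagonal excluded) significantly larger than the
cross-boundary contacts (the spanning square). The diagonal cells are
excluded from the within-side sample because the self-ligation span filter
systematically depletes them, which would otherwise dilute the contrast
the test is measuring.

**KR balancing.** The Knight–Ruiz inner–outer Newton iteration (conjugate
gradient inner loop) on the unmasked submatrix, targeting unit row sums,
tolerance 1e-6, at most 3,000 matrix–vector products; failure to converge
is an error reporting the final residual. All-zero rows are masked first
and receive `NA` weights. The implementation is checked in the tests
against an independent plain Sinkhorn fixed-point iteration.

**O/E.** Each cell is divided by the mean of its diagonal (distance
stratum) over unmasked bins. Strata with zero mean map to 0 — not NaN — so
downstream correlations stay defined; masked bins propagate as `NA`.

**Compartment eigenvector.** Pearson correlation of O/E columns over
unmasked bins; non-finite correlations (constant columns) are set to 0; the
eigenvector with the largest-magnitude eigenvalue is taken, which for a
correlation matrix is the plaid mode whenever compartment structure
dominates. The sign convention is fixed by requiring non-negative
correlation with an orientation track (gene density in `run_all`; the
planted labels in simulations, where orientation is the only arbitrary
degree of freedom). Bins with eigenvector exactly 0 stay unlabelled.

**Vector map.** The vector matrix is segmented on raw (unbalanced) counts
by default: at 72 bins with near-uniform coverage, balancing is unnecessary
and the raw map is what is inspected visually.

**Ties and determinism.** Top-percent selection takes
`k = ceiling(pct/100 · n)` and keeps every feature tied with the k-th
score. Cluster output is sorted by (sequence index, start, start); the
cluster partition is invariant to input order. All outputs of `run_all`
are byte-deterministic for a fixed seed and configuration.

**Zero-variance t-tests.** FPKM ties are real, so the conventions are
explicit: all differences zero → `t = 0, p = 1` (no evidence of change);
constant non-zero difference → `p = 0`. Otherwise the paired statistic is
the closed form `t = mean(d)/(sd(d)/sqrt(n))` with `n − 1` df; the
per-gene replicate contrast is an unpaired equal-variance t-test (the
replicate-level test's flavour is not fixed by the upstream analyses;
equal-variance two-sample is the simplest defensible choice and is flagged
here). No multiple-testing correction is applied: the gene-set comparison
is a single test per panel, and per-gene contrasts report raw p-values.

# The synthetic-data generator

The generator (`sim_config`, `simulate_dataset`) emits every input the
pipeline consumes, with planted ground truth recorded in `truth.json`:

* **Vector blocks** — intra-vector PET midpoints uniform, accepted with
  probability 1 within a planted block and `1/contrast` across blocks
  (defaults: boundaries at 9,000 and 18,000 bp, contrast 10:1, 50,000
  PETs).
* **Host structure** — a desk-scale host (2 chromosomes × 20 Mb) with
  planted TADs (0.5–2 Mb on a 50 kb grid, 10:1 within:across contrast) and
  A/B compartment labels per 500 kb bin (runs of 3–8 bins). PET spans
  follow a truncated power law (exponent 1.5, floor 5 kb): spans below the
  self-ligation scale carry no interaction signal, and the floor keeps the
  8 kb span filter non-trivial. Cross-compartment candidate contacts are
  down-weighted by the mixing parameter (0.2).
* **Vector-host contacts** — host-side anchors are placed in
  heterochromatin/quiescent chromatin with probability 0.8 and in the
  complementary states otherwise, so the planted bias equals the expected
  composition (placing the remainder uniformly would inflate it by the
  genomic het/quies fraction). 27 planted contact sites each receive 5–9
  tightly jittered PETs so they cluster into one high-confidence loop;
  background PETs are singletons. Sites split into evidence classes:
  p53-only (gene at the site), both (gene at the site plus an RNAPII loop
  from it), and RNAPII (no gene at the site; an RNAPII loop reaches a
  distal gene).
* **Annotations** — a 6-state chromatin track tiling each chromosome
  (50–150 kb intervals; heterochromatin and quiescent most frequent), the
  planted associated genes over their qualifying sites, ≥ 100 decoy genes
  at least 20 kb from any qualifying region, six fixed vector transcription
  units, and scored peaks whose pileup is boosted inside TSS states so the
  top 1% is TSS-enriched.
* **Expression** — per-gene lognormal baselines shared by all conditions
  and replicates up to multiplicative noise (CV 0.1, 3 replicates): a null
  table by construction, except one induced p53-target-like gene
  (`CDKN1A_like`, 5-fold in the p53-active treated conditions) and a null
  neighbour control (`SRSF3_like`).

Each output file draws from its own RNG stream split from the master seed,
so adding one generator never perturbs the others, and generation restores
the caller's RNG state.

**What the generator does not emulate:** sequence content and read-level
artefacts, ligation-noise structure beyond a uniform background,
genome-wide chromosome counts and lengths, replicate-to-replicate
biological variability in structure, and peak-calling noise. Passing
recovery tests therefore demonstrate that the *procedures* are correct and
calibrated on data of known structure — not that real libraries at real
depths would behave as cleanly.

**Problem sizes.** The default host channel carries 100,000 PETs —
ChIA-PET-like enrichment sparsity at which planted loops are unambiguous
against background, which is what the gene-association analysis assumes.
Structural analyses need depth rather than sparsity: the TAD/compartment
stability analyses generate 3 × 10⁶ host PETs per replicate, the
desk-scale equivalent of a deeply sequenced (~2 × 10⁸ read-pair) library
given the 40 Mb host. The planted-compartment matrix check uses 60 bins at
depth 200. The statistical calibration uses 1,000 null replicates of the
27-gene set.

# Design decisions on genuinely open points

* **Which regions qualify a gene as associated** — the union of the two
  channels' qualifying regions (merged p53 vector-host host anchors, and
  anchors of retained RNAPII loops). The alternative readings (p53 anchors
  only, or RNAPII-filtered anchors only) would make the RNAPII or p53
  evidence classes empty by construction.
* **Association distance** — gene body plus a 2,000 bp strand-aware
  upstream promoter margin, measured as interval overlap (no scoring).
* **Composition unit** — base pairs, not region counts: region widths vary
  by an order of magnitude, and bp fractions are what a genome-browser
  track shows.
* **Multi-resolution TADs** — each resolution is analysed and reported
  independently; no cross-resolution merging is attempted.
* **Evidence classes** — exactly `{p53, RNAPII, both}`.
* **Vector-derived genes** — resolved against a vector gene annotation
  supplied as input; the synthetic annotation carries six transcription
  units, so counts involving it are fixture properties.

# Known limitations

* Single-linkage clustering chains in dense regions: at host-channel
  depths far above enrichment sparsity, chance ≥ 5-PET background clusters
  appear and the association layer's precision depends on the channel
  being enrichment-sparse (as ChIA-PET channels are).
* The insulation caller reports boundaries at bin edges; sub-bin boundary
  placement is out of scope, and boundary agreement metrics use a 1-bin
  slack for that reason.
* With only 40 compartment bins per desk-scale chromosome, the leading
  eigenvector needs deep input; at low depth the plaid mode mixes with
  noise modes and label agreement degrades gracefully rather than failing
  loudly.
* `intra_host_trans` PETs are classified but not further analysed (no
  trans contact maps).
* Expression values are consumed as given (FPKM); no re-quantification or
  normalisation is attempted.
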