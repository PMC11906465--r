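# adenoloop

Dual-genome ChIA-PET analysis of an episomal adenoviral vector inside a
host cell.

Recombinant adenoviral vectors such as Ad-p53 (35,722 bp, carrying
wild-type TP53) persist episomally in the nucleus, where they fold into
their own 3D structure and physically contact host chromatin. The
questions this package addresses, for researchers working on vector–host
chromatin interactions: does the vector have internal TAD-like blocks,
which host loci does it touch and in what chromatin state, do those
contacts change host gene expression, and does infection perturb host TADs
and A/B compartments?

`adenoloop` implements the full computational pipeline downstream of
read alignment, on a combined host + vector reference:

* **PET classification and loop calling.** Paired-end tags (PETs) are
  classified by genome of origin (`intra_vector`, `vector_host`,
  `intra_host_cis`, `intra_host_trans`), span-filtered (> 8 kb for host
  channels, > 600 bp within the vector), anchor-extended (500 / 0 bp) and
  clustered into loops by single-linkage over both-anchor overlap; loops
  with more than 4 PETs are high-confidence.
* **Contact maps.** Midpoint-binned symmetric matrices; Knight–Ruiz (KR)
  balancing to unit row sums, `W = diag(w) C diag(w)`; per-distance
  observed/expected `O/E(i,j) = C(i,j) / mean_{|a-b|=|i-j|} C(a,b)`.
* **Insulation segmentation.** Sliding-square insulation
  `I(b) = log2(mean square across b) − geometric-mean normalisation`;
  boundaries are prominent local minima passing a one-sided rank-sum test
  of within- vs cross-boundary contacts (p < 0.05). Applied at 500 bp to
  the vector map and at 25/50/100 kb to host TADs.
* **A/B compartments.** Leading eigenvector (largest |eigenvalue|) of the
  Pearson correlation of O/E columns at 500 kb, sign-oriented by gene
  density; A = positive. Stability metrics: eigenvector Pearson r,
  boundary Jaccard, compartment-size ECDFs.
* **Gene association.** High-confidence vector-host loops → merged host
  anchor regions → RNAPII loops anchored there → genes whose
  promoter-extended bodies (2 kb, strand-aware) overlap either channel's
  regions, with evidence classes {p53, RNAPII, both}; gene network edges
  weighted by supporting loops; chromatin-state composition in bp against
  top-1% peak and loop-anchor baselines.
* **Expression comparison.** Paired t-test across the associated gene
  set's FPKM between conditions (`t = mean(d)/(sd(d)/√n)`), with explicit
  zero-variance conventions, plus per-gene replicate-level contrasts.
* **Synthetic data with planted truth.** A seeded generator emits every
  input the pipeline consumes — dual-genome PETs with planted vector
  blocks, host TADs/compartments, chromatin-state-biased vector-host
  contacts at planted associated genes, and null/induced FPKM tables — so
  the whole pipeline is tested end to end against known ground truth.

## Worked example

The analysis workflow lives in `analysis/01_simulate.R` …
`analysis/06_expression.R`; each stage is a thin driver over the package
functions and writes its tables under `results/`. Running stages 1–3:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_cluster_loops.R
Rscript analysis/03_vector_blocks.R
```

prints (seed 42):

```
loops: 21006 intra-vector, 4802 vector-host (27 with >4 PETs), 70112 RNAPII intra-host
vector map: 72 bins, 46277 PETs; 3 blocks
  block 1: 0 - 9,000 bp (9,000 bp)
  block 2: 9,000 - 18,000 bp (9,000 bp)
  block 3: 18,000 - 35,722 bp (17,722 bp)
```

i.e. the vector's contact map segments into three blocks with boundaries
at 9,000 and 18,000 bp and the final block running to the 35,722 bp vector
end. Stage 5 maps the 27 high-confidence vector-host loops to host genes:

```
27 vector-associated host genes (evidence: both=6, p53=12, RNAPII=9)
6 vector-derived genes inside vector-side anchors: AdV_TP53, AdV_pIX, AdV_E2B, AdV_L_major, AdV_E2A, AdV_E4
vector-host anchors: 81.7% heterochromatin+quiescent; top-1% peaks: 100.0% TSS
```

— vector contact sites sit overwhelmingly in repressed chromatin, unlike
the TSS-enriched strongest RNAPII peaks. Consistently, stage 6 finds no
significant expression change of the associated gene set between
conditions (paired t-test across the 27 genes, e.g. treated vs untreated
infected cells: t = −1.29, p = 0.21), while the induced p53-target control
gene responds strongly (FPKM 84.5 → 400.8, p = 4.6e-4). Stage 4 shows host
TADs and compartments are reproducible between independent replicates of
the same truth (boundary Jaccard ≥ 0.85 per chromosome/resolution,
compartment eigenvector r = 0.94–0.99).

The same pipeline runs as one call: `run_all(run_config(...))` executes
simulate → cluster → matrices → TADs/compartments → association →
expression and writes a deterministic `summary.json`.

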