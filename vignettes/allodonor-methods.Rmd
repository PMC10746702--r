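---
title: "Methods: inferring the donors of an allotetraploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring the donors of an allotetraploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allodonor)
```

# The inference problem

An allotetraploid carries two complete diploid genomes — subgenomes A and B —
contributed by two parental species at hybridization. Identifying those
parents among extant diploids uses evidence with different inheritance
logic:

* the **chloroplast** is (almost always) maternally inherited, so a
  chloroplast phylogeny placing the tetraploid next to a diploid identifies
  the **maternal** donor only;
* the **nuclear genome** keeps both parents' contributions. Self-synteny of
  the tetraploid reveals homoeologous duplicate regions; the synonymous
  divergence (Ks) of each duplicate copy to a candidate diploid, and the
  depth at which that diploid's reads cover each contig, both assign the
  copy to a subgenome and hence tie each subgenome to a donor;
* **gene-family copy numbers** retain a residual doubling signature that
  corroborates the polyploid origin itself.

`allodonor` implements each route plus a truth-labelled simulator, so the
whole chain is testable without any external data.

# The synthetic study system

`sim_config()` defaults define the desk-scale preset: per progenitor,
20 contigs of 50 kb carrying 10 genes of 900 bp each (180 kb of CDS per
genome); pairwise progenitor divergence Ks = 0.05 and Ka = 0.01 — the scale
of a recent allopolyploidy event, where synonymous distance is far from
saturation yet clearly resolvable; 10% gene fractionation in the
tetraploid; 100 bp single-end reads at 40× with 0.5% substitution error;
1000 gene families of which 100 are amplified.

Design choices worth making explicit:

* **Divergence convention.** `diverge()` applies the *full* pairwise target
  to one lineage while the other keeps the ancestral state, so the one knob
  equals the pairwise dS measured between the two emitted genomes. The
  alternative (mutating both lineages at half rate) yields the same
  pairwise expectation but makes the knob half the measurable quantity.
* **Codon mutation model.** A codon selected for change is replaced by a
  uniform random synonymous (or nonsynonymous, never stop) single-base
  neighbour, with no transition/transversion bias — exactly the model under
  which the Nei–Gojobori site counts are unbiased, which keeps the
  estimator's oracle exact.
* **Calibration.** The number of mutated codons is proposed from the
  inverted Jukes–Cantor expectation, measured with the package's own NG86
  engine, and rescaled until the realised dS and dN are within 2% of target
  (floored at a two-substitution granularity so tiny test genomes remain
  attainable; at ≥ 100 kb of CDS the realised divergence is well within
  ±10% of the knob). Exact mutation counts are drawn (sampling codons
  without replacement) rather than Bernoulli thinning, which removes most
  proposal noise.
* **Post-hybridization divergence.** Each subgenome copy is independently
  re-diverged by a small extra dS (default 0.01) before fractionation,
  emulating the time between hybridization and the sampling of the living
  progenitor accessions. Homoeologous copies therefore sit at roughly
  `target_dS + 2 * extra_ds` from each other, while each copy stays close
  to its own progenitor — the geometry the subgenome partition exploits.
* **Reads are single-end** with a constant quality: mean-depth
  classification uses depth only, so paired-end structure and quality
  modelling would add code without adding signal.

What the simulator does **not** emulate: indels and rearrangements,
repetitive elements, GC/coverage bias, heterozygosity, or sequencing
chimeras. Passing recovery tests therefore demonstrates correctness of the
inference machinery under the model's assumptions, not robustness to every
artefact of real data; the file-based stage interfaces are designed so real
data can replace any stage's inputs.

# Chloroplast consensus and nucleotide diversity

Consensus building applies substitution records with phred quality ≥ 30
(strict `>=`, the conventional calling threshold) to a shared reference;
indel records are skipped with a warning so all accessions stay in
reference coordinates, which substitutes for a multiple alignment. When two
accepted substitutions collide, the higher quality wins.

Genes are retained only if covered at fraction ≥ `min_fraction` (default
1.0, i.e. comprehensive coverage) in *every* accession; the threshold is
exposed because "comprehensive" is a policy, not a law.

Per-gene diversity uses the unbiased average pairwise difference:
$$\pi = \frac{2}{n(n-1)} \sum_{i<j} \frac{d_{ij}}{L}$$
with *complete deletion* of sites carrying a gap or `N` in any sequence
(the convention of the classical diversity software). The reported
standard deviation is the sample SD of the $n(n-1)/2$ per-pair per-site
distances — a simple, documented choice where no single estimator is
canonical.

# Distance phylogenetics

Distances are Jukes–Cantor with pairwise deletion,
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, erroring at saturation
($p \ge 0.75$) rather than truncating. Neighbor-joining agglomeration is
delegated to the reference implementation in `ape`; a clean-up pass clamps
any negative branch length to zero, moving the deficit to the sibling
branch so path lengths through the parent are preserved. Bootstrap
resamples alignment columns, rebuilds the tree per replicate, and counts
each point-estimate bipartition's recurrence; replicates that saturate are
skipped and counted.

Tree comparison is Robinson–Foulds over non-trivial bipartitions of
*unrooted* trees: `maxRF = 2(n − 3)`, `nRF = RF/maxRF`. For 23 taxa,
maxRF = 40 — a useful parity check on any tree pair. Bipartitions are
extracted by the package itself; an independent implementation (`phangorn`)
serves as cross-check in the tests, never as the implementation.

# Synteny chaining

Anchors (homologous gene pairs) come from a homology hit table or from the
built-in seeder: gene pairs sharing protein 5-mers are aligned globally
under BLOSUM62 with affine gaps (open 11, extend 1; a gap of length $L$
costs $11 + L$), and pairs with identity ≥ 0.5 are kept, top 5 per query.

Chaining works in gene-rank space (robust to intergenic length variation):
within a contig pair and orientation, the maximum-score chain under
`score = Σ anchor scores − gap_penalty × Σ (rank gaps)` with strict
monotonicity and per-step gaps ≤ 25 ranks is found by dynamic programming;
disjoint chains are extracted greedily by descending score, and chains
shorter than 5 anchors are discarded — the conventional parameterisation of
collinearity tools, all exposed as arguments. Self-synteny first removes
tandem anchors (same contig, rank distance < 5) and canonicalises each
anchor pair so a duplicated segment is reported once.

# NG86 and the modal Ks

For each codon, the synonymous site count is the fraction of its nine
single-base neighbours that preserve the amino acid (mutations to stop
codons count as nonsynonymous sites); for a codon pair differing at $d$
positions, all $d!$ substitution orders are enumerated, orders passing
through a stop are excluded, and synonymous/nonsynonymous step counts are
averaged over the remaining orders (over all orders if every one is
blocked — a documented fallback for a vanishingly rare case). Proportions
are Jukes–Cantor corrected; $p \ge 0.75$ yields a saturation flag, not a
number. Codon pairs are produced by protein-guided alignment
(translate, align, back-thread), dropping columns gapped in either protein.

A block's Ks is the median of its anchors' defined dS values. Modal Ks uses
a Gaussian kernel density on a 1000-point grid over `[0, max]` with
Silverman's rule-of-thumb bandwidth (overridable): bin-width-free, and the
mode is stable under the distribution sizes the pipeline produces
(hundreds of anchor pairs). No Ks estimator is uniquely "the" field
standard; NG86 was chosen because it admits an exact enumeration oracle,
so the implementation can be proven correct rather than merely plausible.

# Subgenome assignment and reconciliation

*Ks route:* for each self-synteny block pair, each copy's median dS to its
progenitor-A orthologs (best hit required to agree with the family
annotation — the "true ortholog" rule) is compared; the strictly closer
copy becomes A. Ties or missing orthologs leave both copies unassigned —
silence is preferred to coin-flipping.

*DOC route:* reads are assigned to the tetraploid contig sharing the most
canonical 31-mers (ties discarded); this defined, deterministic assigner
replaces a general-purpose mapper and is exact on simulator data. A contig
with depth < 16× from one progenitor but not the other belongs to the
other's subgenome; below 16× in both is unassigned (the organelle/repeat
signature), at or above in both is ambiguous. The 16× threshold is the
observed boundary of the low-depth peak in the motivating data and is
exposed as an argument; classification is monotone in it (raising the
threshold can never turn an unassigned-both contig into an origin call).
Per-condition summaries report contig count, total bp, and the mean (SD)
of the other progenitor's depth, optionally restricted to contigs ≥ the
assembly N90 and optionally length-weighted (default unweighted, since the
table being mirrored does not state a weighting).

Reconciliation maps each Ks-labelled block copy to its contig and compares
with the DOC label, excluding blocks detected within a single contig
(self-contained duplications say nothing about between-subgenome identity).

# Gene families

`count_by_family()` tallies copy numbers per species from gene→family maps
(these maps are inputs — the product of a family-database annotation).
A family is *amplified* when the tetraploid count is ≥ 2× *each* diploid
count with both diploids ≥ 1: the plural "compared to the other species"
reading, which also avoids divide-by-zero artefacts; both the fold and the
zero-diploid policy are arguments. The count generator builds background
rows strictly outside this rule (a guard decrements the corner case where
equal diploid counts with no loss would tie the rule's boundary), so
detection must be exact, not merely accurate.

# k-mer genome size

Canonical k-mer counting (lexicographic minimum of k-mer and reverse
complement; odd k only, since an even k-mer can be its own reverse
complement) feeds a single-peak homozygous model: the error limb is cut at
the first local minimum of the histogram, the main peak is the argmax
above the cut, and genome size is the post-cut k-mer mass divided by the
peak depth. Error-free reads have no error limb; a cutoff of zero is then
accepted. Heterozygosity mixtures are out of scope — the simulator's
genomes are haploid-like.

# Numerical and reproducibility choices

* Every stochastic operation takes an explicit seed; stage seeds are
  derived arithmetically from the run seed, so an end-to-end run is
  byte-reproducible.
* Coordinates are 1-based inclusive on disk (GFF/VCF convention) and
  converted at the I/O boundary; minus-strand CDS are stored 5'→3' on the
  coding strand with terminal stops trimmed.
* Residues outside `{A,C,G,T,N}` are rejected loudly; skipped records are
  always logged at `warn`.
* Q-matrix and chain-extraction ties resolve deterministically (library
  order and block id respectively).
* Problem sizes used by the validation suite: the full desk preset
  (2 × 1 Mb progenitors, 2 Mb tetraploid, 40× reads) for Ks and subgenome
  recovery; 1 Mb at 40× for genome size; enumerated topologies to 6 leaves
  for neighbor-joining; hundreds of randomised instances for each oracle
  comparison. These sizes were chosen so the whole suite validates every
  guarantee at genome-like scale while remaining runnable on a laptop.

# Known limitations

* The k-mer read assigner is not a general aligner: diverged or repetitive
  real reads will inflate the unassigned fraction.
* NG86 (equal path weighting, no ts/tv bias) underestimates dS when
  transition bias is strong; a corrected estimator could sit behind the
  same `ng86()` interface.
* The coverage filter and π assume shared reference coordinates; true
  structural variation between accessions is invisible to this design.
* Self-synteny requires surviving collinear gene runs; fractionation much
  above ~50% leaves blocks below the minimum size and the Ks route
  degrades before the DOC route does.
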