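# allodonor

Infer the maternal and paternal diploid donors of an allotetraploid genome.

Allotetraploids carry two complete diploid genomes (subgenomes A and B)
inherited from two different parental species. `allodonor` implements, as a
tested and reusable R pipeline, the four complementary lines of evidence by
which such donors are identified:

1. **Chloroplast consensus phylogenetics** — the maternal signal. Per-accession
   consensus sequences are built against a shared chloroplast reference by
   applying substitution variants with phred quality ≥ 30; genes
   comprehensively covered in every accession are scored for nucleotide
   diversity (π), and a neighbor-joining tree with bootstrap support is
   compared to a reference phylogeny by Robinson–Foulds distance
   (RF, maxRF = 2(n−3), nRF = RF/maxRF).
2. **Synteny and Ks** — self-synteny blocks of the tetraploid mark
   homoeologous duplicate regions; collinear blocks are found by
   dynamic-programming chaining of homologous anchor pairs in gene-rank space
   (minimum block size 5, maximum rank gap 25). Synonymous divergence per
   anchor pair is estimated with the Nei–Gojobori (1986) method:
   S and N site counts from single-base codon neighbours, path-averaged
   difference counts, Jukes–Cantor correction
   dS = −(3/4)·ln(1 − (4/3)·pS), and the modal Ks of a distribution is the
   argmax of a Gaussian kernel density. The block copy with the lower median
   dS to progenitor A is labelled subgenome A.
3. **Depth-of-coverage (DOC) classification** — reads from each progenitor
   are assigned to tetraploid contigs by shared k-mers; a contig covered
   below 16× by one progenitor's reads but not the other's is assigned to
   the opposite subgenome. The two routes are reconciled per region.
4. **Gene-family amplification** — families whose tetraploid copy number is
   at least twice each diploid's (both diploids ≥ 1) are the residual
   signature of polyploidy, rolled up to pathways.

Because real donor/polyploid data sets are large and external, the package
ships a seeded synthetic-allotetraploid generator
(`simulate_polyploid_dataset()`) that emits two progenitors diverged at a
configurable Ks (default 0.05), their tetraploid union with gene
fractionation, progenitor short reads, accession variant sets, and family
count tables — all with machine-checkable truth tables, so every stage can
be validated end to end.

## Worked example

```r
library(allodonor)

# NG86 on a hand-checkable pair: ten glycine codons, one synonymous change
ng86(rep("GGG", 10), c("GGA", rep("GGG", 9)))
#> NG86 estimate over 10 codons
#>   S = 10.00  N = 20.00  Sd = 1.000  Nd = 0.000
#>   dS = 0.107326  dN = 0.000000

# full pipeline on the desk-scale synthetic preset (about 5 minutes)
report <- run_desk_benchmark(sim_config(seed = 1), seed = 1,
                             out_dir = "bench")
print(report)
#> Desk benchmark report (seed 1)
#>   pi_max                   0.0239
#>   ks_mode_progenitors      0.0474
#>   ks_mode_self             0.0636
#>   ks_partition_accuracy    1.0000
#>   doc_accuracy             1.0000
#>   reconcile_agreement      1.0000
#>   family_precision         1.0000
#>   family_recall            1.0000
```

Reading the report: the progenitors were simulated at pairwise Ks 0.05 and
the synteny→NG86→density route recovers a modal Ks of 0.047; the tetraploid
self-synteny mode (0.064) is higher because each subgenome copy carries
additional post-hybridization divergence. Every contig's subgenome was
recovered both by depth of coverage and by Ks partitioning, the two routes
agree on all reconcilable regions, and the twofold-amplification filter
recovers the amplified family set exactly.

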