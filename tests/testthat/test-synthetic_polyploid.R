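small_cfg <- function(genes_per_contig = 5, cds_length = 300, ...) {
  sim_config(seed = 5, n_contigs = 2, contig_length = 10000,
             genes_per_contig = genes_per_contig, cds_length = cds_length, ...)
}

test_that("simulate_ancestor lays out valid, deterministic gene models", {
  cfg <- small_cfg()
  a1 <- simulate_ancestor(cfg)
  a2 <- simulate_ancestor(cfg)
  expect_identical(a1, a2)
  expect_equal(nrow(a1$genes), 10)
  expect_equal(as.vector(tapply(a1$genes$gene_rank, a1$genes$contig_id, max)),
               c(5, 5))
  for (i in seq_len(nrow(a1$genes))) {
    expect_match(a1$genes$cds[[i]], "^ATG")
    prot <- translate_cds(a1$genes$cds[[i]])
    expect_equal(nchar(prot), 99) # 300/3 codons minus stop, start retained
  }
  # genomic span carries the CDS plus a terminal stop
  g <- a1$genes[1, ]
  span <- substr(a1$genome[[g$contig_id]], g$start, g$end)
  coding <- if (g$strand == "+") span else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(span)))
  expect_equal(substr(coding, 1, nchar(g$cds)), g$cds)
  expect_true(substr(coding, nchar(coding) - 2, nchar(coding)) %in%
                c("TAA", "TAG", "TGA"))
})

test_that("ancestor placement errors when genes cannot fit", {
  cfg <- sim_config(n_contigs = 1, contig_length = 1000,
                    genes_per_contig = 5, cds_length = 300)
  expect_error(simulate_ancestor(cfg), "do not fit")
})

test_that("diverge hits its dS/dN targets and zero targets are no-ops", {
  cfg <- small_cfg(genes_per_contig = 10, cds_length = 900)
  anc <- simulate_ancestor(cfg)
  same <- diverge(anc$genome, anc$genes, 0, 0, seed = 3)
  expect_identical(same$genome, anc$genome)
  div <- diverge(anc$genome, anc$genes, 0.05, 0.01, seed = 3)
  est <- ng86(unlist(lapply(anc$genes$cds, allodonor:::split_codons)),
              unlist(lapply(div$genes$cds, allodonor:::split_codons)))
  expect_lte(abs(est$dS - 0.05), 0.005)
  expect_lte(abs(est$dN - 0.01), 0.001)
  # dN = 0 leaves every protein unchanged
  syn_only <- diverge(anc$genome, anc$genes, 0.05, 0, seed = 4)
  for (i in seq_len(nrow(anc$genes))) {
    expect_equal(as.character(translate_cds(syn_only$genes$cds[[i]])),
                 as.character(translate_cds(anc$genes$cds[[i]])))
  }
})

test_that("allotetraploid union respects fractionation and records truth", {
  cfg <- sim_config(seed = 9, n_contigs = 5, contig_length = 42000,
                    genes_per_contig = 100, cds_length = 300)
  anc <- simulate_ancestor(cfg)
  pa <- allodonor:::relabel_genome(anc$genome, anc$genes, "A.")
  pb <- allodonor:::relabel_genome(anc$genome, anc$genes, "B.")
  tet0 <- build_allotetraploid(pa, pb, fractionation_rate = 0, seed = 3,
                               extra_ds = 0, extra_dn = 0)
  expect_equal(nrow(tet0$genes), 1000)
  tet <- build_allotetraploid(pa, pb, fractionation_rate = 0.1, seed = 3,
                              extra_ds = 0, extra_dn = 0)
  deleted <- 1000 - nrow(tet$genes)
  expect_gte(deleted, 72) # binomial(1000, 0.1) central 99% interval
  expect_lte(deleted, 129)
  expect_setequal(tet$truth$contig_origin$contig_id, names(tet$genome))
  expect_true(all(tet$truth$contig_origin$origin %in% c("A", "B")))
  # per-contig ranks are a 1..n bijection after deletion
  by_ctg <- split(tet$genes$gene_rank, tet$genes$contig_id)
  for (r in by_ctg) expect_equal(sort(r), seq_along(r))
  # ortholog pairs map progenitor genes onto their surviving copies
  op <- tet$truth$ortholog_pairs
  expect_equal(nrow(op), nrow(tet$genes))
  expect_true(all(sub("^tet", "", op$tetraploid_gene) == op$progenitor_gene))
  expect_error(build_allotetraploid(pa, pa, seed = 1), "disjoint")
})

test_that("simulate_reads has the contracted count, content, and error rate", {
  genome <- c(ctg = strrep("A", 200000))
  reads <- simulate_reads(genome, coverage = 10, read_length = 100,
                          error_rate = 0, seed = 2)
  expect_length(reads, 20000)
  expect_true(all(reads %in% c(strrep("A", 100), strrep("T", 100))))
  noisy <- simulate_reads(genome, coverage = 6, read_length = 100,
                          error_rate = 0.01, seed = 2)
  # majority base identifies the strand; the rest are errors
  n_A <- vapply(strsplit(noisy, ""), function(x) sum(x == "A"), 0L)
  mism <- ifelse(n_A >= 50, 100 - n_A,
                 100 - vapply(strsplit(noisy, ""), function(x) sum(x == "T"), 0L))
  rate <- sum(mism) / (100 * length(noisy)) # > 1e6 bases
  expect_gt(rate, 0.008)
  expect_lt(rate, 0.012)
  expect_error(simulate_reads(c(s = "ACGT"), 1, 10, 0, 1), "shortest contig")
})

test_that("family count generator separates truth cleanly", {
  z <- simulate_family_counts(50, 0, seed = 1)
  expect_length(z$amplified, 0)
  f1 <- simulate_family_counts(500, 60, seed = 11)
  f2 <- simulate_family_counts(500, 60, seed = 11)
  expect_identical(f1, f2)
  amp_rows <- f1$rows[f1$rows$family_id %in% f1$amplified, ]
  expect_true(all(amp_rows$tetraploid >= 2 * amp_rows$diploid_A))
  expect_true(all(amp_rows$tetraploid >= 2 * amp_rows$diploid_B))
  expect_true(all(amp_rows$diploid_A >= 1 & amp_rows$diploid_B >= 1))
  bg <- f1$rows[!f1$rows$family_id %in% f1$amplified, ]
  expect_false(any(bg$tetraploid >= 2 * bg$diploid_A &
                     bg$tetraploid >= 2 * bg$diploid_B))
})

test_that("accession variants reconstruct the leaf sequences through the consensus filter", {
  acc <- simulate_accession_set(n_accessions = 6, n_genes = 5,
                                contig_length = 4000, seed = 3)
  for (a in names(acc$variants)[1:3]) {
    cons <- apply_variants(acc$reference, acc$variants[[a]], min_qual = 30)
    expect_equal(unname(cons), unname(acc$leaf_seqs[[a]]))
  }
  # decoy records sit below the quality threshold
  expect_true(all(vapply(acc$variants, function(v) any(v$qual < 30), TRUE)))
})

test_that("the on-disk dataset is complete and seed-reproducible", {
  cfg <- sim_config(seed = 4, n_contigs = 2, contig_length = 8000,
                    genes_per_contig = 4, cds_length = 300, coverage = 2,
                    n_families = 40, n_amplified = 5)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_polyploid_dataset(cfg, d1)
  simulate_polyploid_dataset(cfg, d2)
  files <- c("progenitorA.fa", "progenitorB.gff", "tetraploid.fa",
             "readsA.fastq.gz", "families.tsv", "gene_families_all.tsv",
             "truth/contig_origin.tsv", "chloro/reference.fa")
  for (f in files) expect_true(file.exists(file.path(d1, f)), label = f)
  for (f in c("progenitorA.fa", "families.tsv", "truth/contig_origin.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
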