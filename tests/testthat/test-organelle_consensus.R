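test_that("apply_variants follows the phred-30 rule exactly", {
  ref <- c(chr = "ACGT")
  v <- function(pos, r, a, q) data.frame(contig_id = "chr", pos = pos,
                                         ref = r, alt = a, qual = q,
                                         stringsAsFactors = FALSE)
  none <- data.frame(contig_id = character(), pos = integer(),
                     ref = character(), alt = character(), qual = numeric(),
                     stringsAsFactors = FALSE)
  expect_equal(unname(apply_variants(ref, none)), "ACGT")
  expect_equal(unname(apply_variants(ref, v(2, "C", "T", 45))), "ATGT")
  expect_equal(unname(apply_variants(ref, v(2, "C", "T", 29))), "ACGT")
  expect_equal(unname(apply_variants(ref, v(2, "C", "T", 30))), "ATGT")
  expect_error(apply_variants(ref, v(2, "G", "T", 45)), "chr:2")
})

test_that("apply_variants resolves collisions, skips indels, is idempotent", {
  ref <- c(chr = "AAAAAA")
  v <- data.frame(contig_id = "chr", pos = c(2, 2, 4), ref = "A",
                  alt = c("C", "G", "T"), qual = c(50, 90, 31),
                  stringsAsFactors = FALSE)
  cons <- apply_variants(ref, v)
  expect_equal(unname(cons), "AGATAA") # qual 90 wins at pos 2
  expect_identical(apply_variants(ref, v), cons) # same inputs, same output
  ind <- data.frame(contig_id = "chr", pos = 3, ref = "AA", alt = "A",
                    qual = 99, stringsAsFactors = FALSE)
  expect_equal(unname(apply_variants(ref, ind)), "AAAAAA")
})

test_that("coverage filter keeps only comprehensively covered genes", {
  genes <- data.frame(gene_id = c("g1", "g2"), contig_id = "chr",
                      start = c(11L, 51L), end = c(20L, 60L), strand = "+",
                      cds = "", gene_rank = 1:2, stringsAsFactors = FALSE)
  full <- data.frame(contig_id = "chr", start = 1L, end = 100L)
  half <- data.frame(contig_id = "chr", start = c(1L, 56L), end = c(50L, 100L))
  expect_equal(filter_covered_genes(genes, list(a = full, b = full))$gene_id,
               c("g1", "g2"))
  got <- filter_covered_genes(genes, list(a = full, b = half))
  expect_equal(got$gene_id, "g1") # g2 only half covered in accession b
  expect_equal(filter_covered_genes(genes, list(a = half), min_fraction = 0),
               genes)
})

test_that("nucleotide diversity matches hand case and brute-force oracle", {
  expect_equal(nucleotide_diversity(rep("ACGTACGTAC", 5))$pi, 0)
  hand <- nucleotide_diversity(c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAATT"))
  expect_equal(hand$pi, (4 / 3) / 10)
  expect_equal(hand$n_sites, 10)
  set.seed(17)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    L <- sample(5:60, 1)
    mat <- matrix(sample(c("A", "C", "G", "T", "N", "-"), n * L,
                         replace = TRUE, prob = c(rep(0.23, 4), 0.04, 0.04)),
                  nrow = n)
    seqs <- apply(mat, 1, paste, collapse = "")
    usable <- try(oracle_pi(seqs), silent = TRUE)
    if (inherits(usable, "try-error")) {
      expect_error(nucleotide_diversity(seqs), "no comparable sites")
    } else {
      expect_equal(nucleotide_diversity(seqs)$pi, usable)
    }
  }
})

test_that("pi is order-invariant and duplication scales through n(n-1)", {
  seqs <- c("ACGTAC", "ACGTAT", "ACGAAT", "TCGAAT")
  base <- nucleotide_diversity(seqs)
  expect_equal(nucleotide_diversity(rev(seqs))$pi, base$pi)
  dup <- c(seqs, seqs[[1]])
  expect_equal(nucleotide_diversity(dup)$pi, oracle_pi(dup))
})

test_that("pi_table ranks the variable gene first", {
  genes <- data.frame(gene_id = c("quiet", "loud"), contig_id = "chr",
                      start = c(1L, 7L), end = c(6L, 12L), strand = "+",
                      cds = "", gene_rank = 1:2, stringsAsFactors = FALSE)
  cons <- c(a = "ACGTACGGGGGG", b = "ACGTACGGGTGG", c = "ACGTACGGGTTG")
  tab <- pi_table(cons, genes)
  expect_equal(tab$gene_id, c("loud", "quiet"))
  expect_equal(tab$pi[[2]], 0)
  all_same <- pi_table(c(a = "AAAA", b = "AAAA"),
                       genes = data.frame(gene_id = "g", contig_id = "chr",
                                          start = 1L, end = 4L, strand = "+",
                                          cds = "", gene_rank = 1L))
  expect_equal(all_same$pi, 0)
})

test_that("simulated per-gene mutation rate is recovered by pi", {
  set.seed(23)
  L <- 400
  theta <- 0.05
  ref <- random_dna_str(L)
  seqs <- vapply(1:8, function(i) {
    chars <- strsplit(ref, "")[[1]]
    hit <- which(runif(L) < theta)
    chars[hit] <- vapply(chars[hit],
                         function(b) sample(setdiff(ORACLE_BASES, b), 1), "")
    paste(chars, collapse = "")
  }, "")
  pi <- nucleotide_diversity(seqs)$pi
  # expected pairwise difference per site: 2 theta (1 - 3 theta / 4) approx
  expected <- 2 * theta * (1 - theta) + 2 * (theta^2) * 3 / 4
  se <- 3 * sqrt(expected * (1 - expected) / L)
  expect_lt(abs(pi - expected), se)
})
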