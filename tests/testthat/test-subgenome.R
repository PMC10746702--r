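mk_block <- function(id, ca, cb, genes_a, genes_b) {
  structure(list(block_id = id, contig_a = ca, contig_b = cb,
                 orientation = "plus", score = 1,
                 n_anchors = length(genes_a), ks_summary = NA_real_,
                 anchors = data.frame(gene_a = genes_a, gene_b = genes_b,
                                      stringsAsFactors = FALSE)),
            class = "SyntenyBlock")
}

test_that("Ks partition labels the copy closer to progenitor A", {
  b <- mk_block(1, "c1", "c2", c("x1", "x2", "x3"), c("y1", "y2", "y3"))
  ks <- c(x1 = 0.014, x2 = 0.015, x3 = 0.016,
          y1 = 0.059, y2 = 0.060, y3 = 0.061)
  lab <- partition_ab(list(b), ks)
  expect_equal(lab$label[lab$side == "a"], "A")
  expect_equal(lab$label[lab$side == "b"], "B")
  expect_equal(lab$median_ks, c(0.015, 0.060))
  # tie -> both unassigned
  tie <- partition_ab(list(b), setNames(rep(0.05, 6), names(ks)))
  expect_equal(tie$label, c("unassigned", "unassigned"))
  # missing orthologs on one side -> unassigned
  miss <- partition_ab(list(b), ks[1:3])
  expect_equal(miss$label, c("unassigned", "unassigned"))
  bad <- mk_block(2, "c1", "c2", character(), character())
  expect_error(partition_ab(list(bad), ks), "malformed")
})

test_that("k-mer read assignment recovers exclusive origin and honours ties", {
  set.seed(19)
  contigs <- c(X = random_dna_str(4000), Y = random_dna_str(4000))
  reads <- simulate_reads(contigs["X"], coverage = 8, read_length = 100,
                          error_rate = 0, seed = 4)
  dep <- assign_reads_by_kmer(reads, contigs, k = 31, sample_name = "s")
  expect_equal(dep$s[dep$contig_id == "Y"], 0)
  expect_equal(dep$s[dep$contig_id == "X"], 8, tolerance = 0.05)
  # identical contigs: every read ties, nothing is assigned
  twins <- c(P = contigs[["X"]], Q = contigs[["X"]])
  dep2 <- assign_reads_by_kmer(reads, twins, k = 31, sample_name = "s")
  expect_equal(dep2$s, c(0, 0))
  expect_equal(attr(dep2, "unassigned_fraction"), 1)
})

test_that("DOC classification applies the under-threshold rule symmetrically", {
  depths <- data.frame(
    contig_id = c("c1", "c2", "c3", "c4"),
    length = c(100L, 100L, 100L, 100L),
    trinervia = c(3.2, 91.8, 5.0, 40.0),
    hirtella = c(70.4, 3.0, 5.0, 40.0), stringsAsFactors = FALSE)
  got <- classify_contigs_doc(depths, "trinervia", "hirtella",
                              threshold = 16, n90_filter = FALSE)
  lab <- setNames(got$labels$label, got$labels$contig_id)
  # trinervia reads absent from c1 -> c1 is of the OTHER (hirtella-side) origin
  expect_equal(unname(lab), c("B", "A", "unassigned", "unassigned"))
  cond <- setNames(got$labels$condition, got$labels$contig_id)
  expect_equal(unname(cond["c3"]), "doc_under_both")
  expect_equal(unname(cond["c4"]), "ambiguous")
  # summary totals equal member sums and partition the set
  expect_equal(sum(got$summary$contig_number), 4)
  expect_equal(sum(got$summary$total_size), 400)
  row1 <- got$summary[got$summary$condition == "doc_under_trinervia", ]
  expect_equal(row1$other_depth_mean, 70.4)
  expect_error(classify_contigs_doc(depths, "trinervia", "nope"),
               "missing sample")
})

test_that("raising the threshold never rescues an unassigned-both contig", {
  set.seed(33)
  depths <- data.frame(contig_id = sprintf("c%02d", 1:40),
                       length = sample(50:500, 40),
                       a = runif(40, 0, 60), b = runif(40, 0, 60),
                       stringsAsFactors = FALSE)
  base <- classify_contigs_doc(depths, "a", "b", threshold = 16,
                               n90_filter = FALSE)
  both <- base$labels$contig_id[base$labels$condition == "doc_under_both"]
  for (thr in c(20, 30, 50)) {
    higher <- classify_contigs_doc(depths, "a", "b", threshold = thr,
                                   n90_filter = FALSE)
    lab <- setNames(higher$labels$label, higher$labels$contig_id)
    expect_true(all(lab[both] == "unassigned"))
  }
})

test_that("N90 filtering restricts classification to long contigs", {
  depths <- data.frame(contig_id = c("big1", "big2", "tiny"),
                       length = c(1000L, 900L, 10L),
                       a = c(40, 2, 40), b = c(2, 40, 2),
                       stringsAsFactors = FALSE)
  got <- classify_contigs_doc(depths, "a", "b", threshold = 16,
                              n90_filter = TRUE)
  expect_setequal(got$labels$contig_id, c("big1", "big2"))
})

test_that("reconciliation measures agreement and excludes self-contained blocks", {
  ks_lab <- data.frame(
    unit_id = c("block1_a", "block1_b", "block2_a", "block2_b",
                "block3_a", "block3_b"),
    block_id = c(1, 1, 2, 2, 3, 3), side = rep(c("a", "b"), 3),
    contig_id = c("cA", "cB", "cA2", "cB2", "cSelf", "cSelf"),
    label = c("A", "B", "A", "B", "A", "B"), evidence = "ks",
    median_ks = 0.02, stringsAsFactors = FALSE)
  doc_lab <- data.frame(
    unit_id = c("cA", "cB", "cA2", "cB2", "cSelf"),
    contig_id = c("cA", "cB", "cA2", "cB2", "cSelf"),
    label = c("A", "B", "A", "A", "A"), condition = "x", evidence = "doc",
    stringsAsFactors = FALSE)
  rec <- reconcile(ks_lab, doc_lab)
  # block3 lives inside one contig: excluded; block2_b disagrees (B vs A)
  expect_equal(rec$n_compared, 4)
  expect_equal(rec$agreement, 3 / 4)
  expect_equal(rec$disagreements$unit_id, "block2_b")
  all_agree <- reconcile(ks_lab[1:2, ], doc_lab)
  expect_equal(all_agree$agreement, 1.0)
})
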