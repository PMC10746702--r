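test_that("protein alignment scores equal brute-force enumeration on tiny pairs", {
  ident <- align_proteins("MKVLW", "MKVLW")
  expect_equal(ident$identity, 1)
  expect_error(align_proteins("", "MK"), "empty")
  expect_error(align_proteins("MKB", "MK"), "non-amino-acid")
  set.seed(13)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:20) {
    p1 <- paste(sample(aa, sample(2:5, 1), replace = TRUE), collapse = "")
    p2 <- paste(sample(aa, sample(2:5, 1), replace = TRUE), collapse = "")
    expect_equal(align_proteins(p1, p2)$score, oracle_align_score(p1, p2),
                 label = paste(p1, p2))
  }
})

make_genes <- function(ids, contigs, ranks) {
  data.frame(gene_id = ids, contig_id = contigs, start = ranks * 100L,
             end = ranks * 100L + 50L, strand = "+", cds = "",
             gene_rank = ranks, stringsAsFactors = FALSE)
}

test_that("find_anchors filters hit tables by identity, top_k, and self", {
  gA <- make_genes(paste0("a", 1:3), "cA", 1:3)
  gB <- make_genes(paste0("b", 1:8), "cB", 1:8)
  hit <- function(q, s, pid, score) {
    data.frame(query = q, subject = s, pident = pid, length = 100,
               mismatch = 0, gapopen = 0, qstart = 1, qend = 100, sstart = 1,
               send = 100, evalue = 0, bitscore = score,
               stringsAsFactors = FALSE)
  }
  hits <- rbind(hit("a1", "b1", 90, 200), hit("a1", "b2", 30, 150),
                do.call(rbind, lapply(1:7, function(i)
                  hit("a2", paste0("b", i), 80, 100 + i))))
  anc <- find_anchors(gA, gB, hits = hits)
  expect_equal(sum(anc$gene_a == "a1"), 1) # identity 30% filtered
  expect_equal(sum(anc$gene_a == "a2"), 5) # top_k = 5 of 7
  expect_equal(sort(anc$score[anc$gene_a == "a2"], decreasing = TRUE)[1:2],
               c(107, 106))
  self_hits <- rbind(hit("a1", "a1", 100, 500), hit("a1", "a2", 95, 400))
  got <- find_anchors(gA, gA, hits = self_hits, self = TRUE)
  expect_equal(nrow(got), 1) # the self hit is dropped
  bad <- hit("zz", "b1", 90, 100)
  expect_error(find_anchors(gA, gB, hits = bad), "unknown gene")
})

anchor_df <- function(ra, rb, score = 10, ca = "x", cb = "y") {
  data.frame(gene_a = paste0("ga", seq_along(ra)),
             gene_b = paste0("gb", seq_along(ra)),
             contig_a = ca, contig_b = cb, rank_a = ra, rank_b = rb,
             score = score, stringsAsFactors = FALSE)
}

test_that("chaining honours min_block_size and both orientations", {
  expect_length(chain_collinear(anchor_df(1:4, 1:4)), 0) # below minimum
  plus <- chain_collinear(anchor_df(c(1, 2, 3, 5, 6), c(1, 2, 3, 4, 5)))
  expect_length(plus, 1)
  expect_equal(plus[[1]]$orientation, "plus")
  expect_equal(plus[[1]]$n_anchors, 5)
  minus <- chain_collinear(anchor_df(1:5, c(9, 7, 5, 3, 1)))
  expect_length(minus, 1)
  expect_equal(minus[[1]]$orientation, "minus")
  # gap beyond max_gap breaks the chain
  broken <- chain_collinear(anchor_df(c(1:5, 40:44), c(1:5, 40:44)),
                            max_gap = 25)
  expect_length(broken, 2)
})

test_that("chain score is optimal against exhaustive enumeration", {
  set.seed(47)
  for (rep in 1:40) {
    n <- sample(2:9, 1)
    a <- anchor_df(sample(1:30, n), sample(1:30, n),
                   score = round(runif(n, 1, 15), 2))
    got <- allodonor:::best_chain(a, "plus")
    got_m <- allodonor:::best_chain(a, "minus")
    expect_equal(max(got$score, got_m$score), oracle_best_chain_score(a))
  }
})

test_that("emitted blocks satisfy the monotonicity invariants", {
  set.seed(5)
  a <- anchor_df(sample(1:40, 25), sample(1:40, 25), score = runif(25, 5, 20))
  blocks <- chain_collinear(a, min_block_size = 3)
  seen <- character()
  for (b in blocks) {
    expect_true(all(diff(b$anchors$rank_a) > 0))
    db <- diff(b$anchors$rank_b)
    if (b$orientation == "plus") expect_true(all(db > 0))
    else expect_true(all(db < 0))
    expect_true(all(!b$anchors$gene_a %in% seen)) # anchors disjoint
    seen <- c(seen, b$anchors$gene_a)
  }
})

test_that("self-synteny filters tandems and canonicalises block pairs", {
  tandem <- anchor_df(10, 12, ca = "c1", cb = "c1")
  expect_length(self_synteny(NULL, tandem), 0)
  # duplicated segment across two contigs reported in both directions by the
  # anchor search; must come back as exactly one block
  fwd <- anchor_df(1:5, 1:5, ca = "c1", cb = "c2")
  bwd <- anchor_df(1:5, 1:5, ca = "c2", cb = "c1")
  bwd[c("gene_a", "gene_b")] <- fwd[c("gene_b", "gene_a")]
  blocks <- self_synteny(NULL, rbind(fwd, bwd))
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$contig_a, "c1")
  # distant same-contig pairs survive the tandem filter
  far <- anchor_df(1:5, 21:25, ca = "c1", cb = "c1")
  expect_length(self_synteny(NULL, far, tandem_rank_window = 5), 1)
})

test_that("block TSV writer round-trips the anchor rows", {
  blocks <- chain_collinear(anchor_df(c(1, 2, 3, 5, 6), c(1, 2, 3, 4, 5)))
  tf <- tempfile(fileext = ".tsv")
  write_blocks(blocks, tf)
  df <- read.delim(tf)
  expect_equal(nrow(df), 5)
  expect_equal(unique(df$block_id), 1)
  expect_equal(df$rank_b, 1:5)
})
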