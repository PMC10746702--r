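test_that("codon alignment pairs codons and drops indel columns", {
  same <- codon_align("ATGAAATTTGGG", "ATGAAATTTGGG")
  expect_equal(same$codons1, same$codons2)
  expect_length(same$codons1, 4)
  # one extra codon in the second CDS: its column is dropped
  ins <- codon_align("ATGAAAGATCTGTGGCCG", "ATGAAAGATAAACTGTGGCCG")
  expect_length(ins$codons1, 6)
  expect_equal(ins$codons2, c("ATG", "AAA", "GAT", "CTG", "TGG", "CCG"))
  expect_error(codon_align("ATGTAAAAA", "ATGAAAAAA"), "internal stop")
  expect_error(codon_align("ATGAA", "ATGAAA"), "divisible by 3")
})

test_that("NG86 reproduces hand-derived counts and saturation", {
  zero <- ng86(c("ATG", "AAA"), c("ATG", "AAA"))
  expect_equal(zero$dS, 0)
  expect_equal(zero$dN, 0)
  gly <- ng86(rep("GGG", 10), c("GGA", rep("GGG", 9)))
  expect_equal(gly$S, 10)
  expect_equal(gly$N, 20)
  expect_equal(gly$Sd, 1)
  expect_equal(gly$pS, 0.1)
  expect_equal(gly$dS, 0.107326, tolerance = 1e-5)
  expect_equal(gly$dN, 0)
  # one Phe codon with a synonymous third-position change: pS = 3 saturates
  phe <- ng86("TTT", "TTC")
  expect_true(phe$saturated_s)
  expect_true(is.na(phe$dS))
  expect_equal(phe$pS, 3)
  # S + N always equals 3 x codons
  expect_equal(gly$S + gly$N, 30)
})

test_that("NG86 equals the enumeration oracle on random codon sets", {
  set.seed(61)
  for (rep in 1:60) {
    n <- sample(2:15, 1)
    c1 <- random_sense_codons(n)
    c2 <- perturb_codons(c1)
    got <- ng86(c1, c2)
    exp <- oracle_ng86(c1, c2)
    expect_equal(got$S, exp$S, tolerance = 1e-10)
    expect_equal(got$Sd, exp$Sd, tolerance = 1e-10)
    expect_equal(got$Nd, exp$Nd, tolerance = 1e-10)
    if (is.na(exp$dS)) expect_true(got$saturated_s)
    else expect_equal(got$dS, exp$dS, tolerance = 1e-10)
  }
})

test_that("dS is zero against self and non-decreasing in synonymous changes", {
  set.seed(3)
  cds <- paste(random_sense_codons(80), collapse = "")
  expect_equal(ks_pair(cds, cds)$dS, 0)
  nb <- allodonor:::codon_neighbours()
  codons <- allodonor:::split_codons(cds)
  ds_path <- numeric()
  mutated <- codons
  untouched <- rep(TRUE, length(codons)) # one hit per codon keeps paths exact
  for (step in 1:25) {
    ok <- untouched & vapply(mutated, function(x) length(nb[[x]]$syn) > 0, TRUE)
    i <- sample(which(ok), 1)
    untouched[[i]] <- FALSE
    mutated[[i]] <- sample(nb[[mutated[[i]]]]$syn, 1)
    est <- ng86(codons, mutated)
    if (est$saturated_s) break
    ds_path <- c(ds_path, est$dS)
  }
  expect_true(all(diff(ds_path) >= -1e-12))
})

test_that("block Ks summarises anchors by their median", {
  blk <- function(ks_cds) {
    n <- length(ks_cds) / 2
    structure(list(block_id = 1, contig_a = "x", contig_b = "y",
                   orientation = "plus", score = 1, n_anchors = n,
                   ks_summary = NA_real_,
                   anchors = data.frame(gene_a = paste0("a", 1:n),
                                        gene_b = paste0("b", 1:n),
                                        stringsAsFactors = FALSE)),
              class = "SyntenyBlock")
  }
  set.seed(8)
  base <- vapply(1:3, function(i) paste(random_sense_codons(100), collapse = ""), "")
  nb <- allodonor:::codon_neighbours()
  mut <- vapply(seq_along(base), function(i) {
    codons <- allodonor:::split_codons(base[[i]])
    idx <- sample(seq_along(codons), c(4, 5, 6)[[i]])
    for (j in idx) {
      if (length(nb[[codons[[j]]]]$syn) > 0)
        codons[[j]] <- sample(nb[[codons[[j]]]]$syn, 1)
    }
    paste(codons, collapse = "")
  }, "")
  cds_map <- setNames(c(base, mut), c(paste0("a", 1:3), paste0("b", 1:3)))
  b <- blk(cds_map)
  got <- block_ks(b, cds_map)
  per <- vapply(1:3, function(i) ks_pair(base[[i]], mut[[i]])$dS, 0)
  expect_equal(got$ks_summary, median(per))
  # all-saturated anchors leave the summary undefined
  sat_map <- c(a1 = "TTT", b1 = "TTC")
  bsat <- blk(sat_map)
  expect_true(is.na(block_ks(bsat, sat_map)$ks_summary))
})

test_that("KDE mode detection finds known modes", {
  set.seed(11)
  v <- abs(rnorm(500, 0.05, 0.01))
  m <- ks_mode(v)
  expect_gt(m$mode, 0.04)
  expect_lt(m$mode, 0.06)
  near_const <- 0.2 + rnorm(50, 0, 1e-5)
  mc <- ks_mode(near_const)
  expect_equal(mc$mode, 0.2, tolerance = 1e-3)
  bim <- c(rnorm(400, 0.05, 0.008), rnorm(100, 0.5, 0.008))
  mb <- ks_mode(bim[bim > 0])
  expect_lt(abs(mb$mode - 0.05), 0.01) # taller component wins
  expect_error(ks_mode(c(0.1, 0.2, 0.3)), "at least 5")
})
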